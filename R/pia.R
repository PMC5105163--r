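# Pairwise Interaction Analyser: per-frame geometric interaction
# detection between heavy-atom sets, bootstrapped state-conditional
# interaction frequencies (trajectory resampling with fixed microstate
# definition and re-estimated Markov model), and significant-difference
# calls between metastable states.

#' Geometric interaction criteria
#'
#' Hydrogen-bond thresholds (donor-acceptor and hydrogen-acceptor
#' distances, donor-hydrogen-acceptor angle) and a heavy-atom minimum
#' distance contact criterion.  All thresholds are inclusive.
#'
#' @param d_DA donor--acceptor distance cutoff (Angstrom).
#' @param d_HA hydrogen--acceptor distance cutoff (Angstrom).
#' @param angle_DHA minimum D-H...A angle (degrees).
#' @param d_contact heavy-atom minimum-distance contact cutoff (Angstrom).
#' @return Object of class `msm_criteria`.
#' @export
interaction_criteria <- function(d_DA = 3.5, d_HA = 2.5, angle_DHA = 120,
                                 d_contact = 4.0) {
  if (any(c(d_DA, d_HA, d_contact) <= 0)) stop("distances must be > 0")
  if (angle_DHA <= 0 || angle_DHA > 180) stop("angle must be in (0, 180]")
  structure(list(d_DA = d_DA, d_HA = d_HA, angle_DHA = angle_DHA,
                 d_contact = d_contact),
            class = "msm_criteria")
}

#' Atom group for interaction detection
#'
#' @param heavy integer indices of the group's heavy atoms.
#' @param donors optional 2-column matrix of (donor heavy atom, attached
#'   hydrogen) index pairs.
#' @param acceptors optional integer indices of acceptor heavy atoms.
#' @return list with class `msm_atomgroup`.
#' @export
atom_group <- function(heavy, donors = NULL, acceptors = NULL) {
  if (!length(heavy)) stop("group needs at least one heavy atom")
  if (!is.null(donors)) donors <- matrix(as.integer(donors), ncol = 2)
  structure(list(heavy = as.integer(heavy), donors = donors,
                 acceptors = as.integer(acceptors)),
            class = "msm_atomgroup")
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

.hbond_between <- function(coords, donors, acceptors, crit) {
  if (is.null(donors) || !length(acceptors) || nrow(donors) == 0)
    return(FALSE)
  for (r in seq_len(nrow(donors))) {
    D <- coords[donors[r, 1], ]; H <- coords[donors[r, 2], ]
    for (a in acceptors) {
      A <- coords[a, ]
      if (sqrt(sum((D - A)^2)) <= crit$d_DA &&
          sqrt(sum((H - A)^2)) <= crit$d_HA &&
          .angle_deg(D, H, A) >= crit$angle_DHA)
        return(TRUE)
    }
  }
  FALSE
}

#' Detect a pairwise interaction in one frame
#'
#' An interaction between two heavy-atom sets exists if any
#' donor/acceptor pairing satisfies all hydrogen-bond thresholds, or the
#' minimum heavy-atom distance is within the contact cutoff.  Donors
#' without an attached hydrogen are skipped with a warning when hydrogen
#' bonds are requested.
#'
#' @param coords one frame, `atoms x 3`.
#' @param groupA,groupB `msm_atomgroup` objects (disjoint).
#' @param criteria `msm_criteria`.
#' @return list with `present` (logical) and `kind` (`"hbond"`,
#'   `"contact"`, `"both"` or `"none"`).
#' @export
detect_interaction <- function(coords, groupA, groupB,
                               criteria = interaction_criteria()) {
  if (length(intersect(groupA$heavy, groupB$heavy)))
    stop("groups must be disjoint")
  hb <- .hbond_between(coords, groupA$donors, groupB$acceptors, criteria) ||
    .hbond_between(coords, groupB$donors, groupA$acceptors, criteria)
  mind <- Inf
  for (i in groupA$heavy) {
    d2 <- (coords[groupB$heavy, 1] - coords[i, 1])^2 +
      (coords[groupB$heavy, 2] - coords[i, 2])^2 +
      (coords[groupB$heavy, 3] - coords[i, 3])^2
    mind <- min(mind, sqrt(min(d2)))
  }
  contact <- mind <= criteria$d_contact
  kind <- if (hb && contact) "both" else if (hb) "hbond"
    else if (contact) "contact" else "none"
  list(present = hb || contact, kind = kind)
}

# presence vector of one pair over all frames of all trajectories
.presence_series <- function(ens, groupA, groupB, criteria) {
  lapply(ens$trajs, function(arr) {
    nf <- dim(arr)[1]
    out <- logical(nf)
    for (f in seq_len(nf))
      out[f] <- detect_interaction(arr[f, , ], groupA, groupB,
                                   criteria)$present
    out
  })
}

#' Bootstrapped state-conditional interaction frequencies
#'
#' For each of `n_replicates` bootstrap samples: entire trajectories are
#' resampled with replacement, the reversible Markov model is re-estimated
#' on the fixed microstate definition, `n_frames` frames are drawn from
#' the metastable state's frames with probabilities proportional to the
#' updated stationary weight of each frame's microstate, and every pair's
#' presence fraction is computed.  The mean and standard deviation over
#' replicates are reported per state and pair.
#'
#' @param ens `msm_ensemble`.
#' @param dtrajs discrete trajectories matching `ens` frame-for-frame.
#' @param decomp `msm_pcca` (fixed microstate-to-metastable map).
#' @param pairs list of `list(a = msm_atomgroup, b = msm_atomgroup,
#'   label = ...)`.
#' @param criteria `msm_criteria`.
#' @param lag MSM lag (frames) used for re-estimation.
#' @param n_frames frames per bootstrap sample (default 100).
#' @param n_replicates bootstrap samples (default 50).
#' @param seed integer seed.
#' @return Object of class `msm_interactions`: data frame `profile`
#'   (`state`, `pair`, `mean`, `sd`), plus `n_frames`, `n_replicates`,
#'   `skipped` (replicates per state without frames).
#' @export
interaction_frequencies <- function(ens, dtrajs, decomp, pairs,
                                    criteria = interaction_criteria(),
                                    lag = 1, n_frames = 100,
                                    n_replicates = 50, seed = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  labels <- assign_frames(decomp, dtrajs)
  npair <- length(pairs)
  presence <- lapply(pairs, function(p)
    .presence_series(ens, p$a, p$b, criteria))
  k <- max(unlist(dtrajs), max(decomp$active))
  crisp_full <- rep(NA_integer_, k)
  crisp_full[decomp$active] <- decomp$crisp
  nm <- decomp$n_meta
  set.seed(seed)
  freq <- array(NA_real_, c(n_replicates, nm, npair))
  skipped <- integer(nm)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(length(dtrajs), replace = TRUE)
    m <- tryCatch(
      estimate_reversible_msm(count_transitions(dtrajs[idx], lag,
                                                n_states = k),
                              lag_frames = lag, dt_ns = ens$dt_ns),
      error = function(e) NULL)
    if (is.null(m)) { skipped <- skipped + 1L; next }
    pi_full <- rep(0, k)
    pi_full[m$active] <- m$pi
    # frames of the resample, with microstate and metastable label
    micro <- unlist(dtrajs[idx])
    traj_of <- rep(idx, lengths(dtrajs[idx]))
    frame_of <- unlist(lapply(idx, function(ti) seq_along(dtrajs[[ti]])))
    meta <- crisp_full[micro]
    micro_count <- tabulate(micro, nbins = k)
    w <- pi_full[micro] / micro_count[micro]
    for (s in seq_len(nm)) {
      sel <- which(!is.na(meta) & meta == s & w > 0)
      if (!length(sel)) { skipped[s] <- skipped[s] + 1L; next }
      draw <- sel[sample.int(length(sel), n_frames, replace = TRUE,
                             prob = w[sel])]
      for (p in seq_len(npair)) {
        pres <- presence[[p]]
        vals <- mapply(function(ti, fi) pres[[ti]][fi],
                       traj_of[draw], frame_of[draw])
        freq[b, s, p] <- mean(vals)
      }
    }
  }
  prof <- do.call(rbind, lapply(seq_len(nm), function(s)
    do.call(rbind, lapply(seq_len(npair), function(p) {
      v <- freq[, s, p]
      data.frame(state = s,
                 pair = if (!is.null(pairs[[p]]$label)) pairs[[p]]$label
                        else paste0("pair", p),
                 mean = mean(v, na.rm = TRUE),
                 sd = sd(v, na.rm = TRUE))
    }))))
  structure(list(profile = prof, n_frames = n_frames,
                 n_replicates = n_replicates, skipped = skipped),
            class = "msm_interactions")
}

#' Significant interaction differences between two metastable states
#'
#' Flags pairs with `|mean_A - mean_B| > z * sqrt(sd_A^2 + sd_B^2)`,
#' sorted by effect size.
#'
#' @param profileA,profileB per-state profile data frames (rows of
#'   `$profile` for one state each; identical pair lists required).
#' @param z significance multiplier (default 2).
#' @return data frame of flagged pairs with `pair`, `mean_A`, `mean_B`,
#'   `delta`, `threshold`.
#' @export
significant_differences <- function(profileA, profileB, z = 2) {
  if (!identical(as.character(profileA$pair), as.character(profileB$pair)))
    stop("pair lists differ between profiles")
  delta <- profileA$mean - profileB$mean
  thr <- z * sqrt(profileA$sd^2 + profileB$sd^2)
  flag <- abs(delta) > thr
  out <- data.frame(pair = profileA$pair, mean_A = profileA$mean,
                    mean_B = profileB$mean, delta = delta,
                    threshold = thr)[flag, , drop = FALSE]
  out[order(-abs(out$delta)), , drop = FALSE]
}
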