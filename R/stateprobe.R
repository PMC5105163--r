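# Per-metastable-state structural observables: side-chain flip
# probability, residue contact frequencies, solvent-contact frequencies,
# and helicity profiles.  All frequencies are state-conditional means over
# frames, with trajectory-level bootstrap standard deviations.

#' Assign frames to metastable states
#'
#' Label every frame with the crisp metastable state of its microstate.
#' Frames in microstates pruned from the active set are `NA` (unassigned).
#'
#' @param decomp `msm_pcca`.
#' @param dtrajs list of integer microstate sequences.
#' @return Object of class `msm_labels`: list `labels` (per trajectory,
#'   integer or NA per frame), `n_meta`, `unassigned_fraction`.
#' @export
assign_frames <- function(decomp, dtrajs) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  k <- max(unlist(dtrajs), max(decomp$active))
  map <- rep(NA_integer_, k)
  map[decomp$active] <- decomp$crisp
  labels <- lapply(dtrajs, function(d) map[d])
  nf <- sum(lengths(labels))
  structure(list(labels = labels, n_meta = decomp$n_meta,
                 unassigned_fraction = sum(is.na(unlist(labels))) / nf),
            class = "msm_labels")
}

# dihedral series over the frames of one trajectory array
.dihedral_series <- function(arr, idx) {
  P <- lapply(1:4, function(k) arr[, idx[k], , drop = TRUE])
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  b1 <- P[[2]] - P[[1]]; b2 <- P[[3]] - P[[2]]; b3 <- P[[4]] - P[[3]]
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

# generic state-conditional frequency with trajectory bootstrap.
# values: list per trajectory of logical/numeric vectors (per frame).
.state_frequency <- function(values, labels, n_meta, n_boot, seed) {
  stat <- function(traj_idx) {
    v <- unlist(values[traj_idx]); l <- unlist(labels$labels[traj_idx])
    vapply(seq_len(n_meta), function(s) {
      sel <- !is.na(l) & l == s
      if (!any(sel)) NA_real_ else mean(v[sel])
    }, numeric(1))
  }
  est <- stat(seq_along(values))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, n_meta)
  for (b in seq_len(n_boot))
    boot[b, ] <- stat(sample.int(length(values), replace = TRUE))
  data.frame(state = seq_len(n_meta), frequency = est,
             sd = apply(boot, 2, sd, na.rm = TRUE))
}

#' Side-chain flip probability per metastable state
#'
#' Fraction of a state's frames whose reporter dihedral falls inside the
#' "flipped-out" interval, with a trajectory-level bootstrap standard
#' deviation.
#'
#' @param ens `msm_ensemble`.
#' @param labels `msm_labels` from [assign_frames()].
#' @param flip_atoms four atom indices defining the dihedral.
#' @param interval numeric length-2: dihedral interval (degrees) counted
#'   as flipped-out.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return data frame `state`, `frequency`, `sd` (NA frequency for states
#'   without frames).
#' @export
flip_probability <- function(ens, labels, flip_atoms,
                             interval = c(0, 120), n_boot = 100, seed = 1) {
  if (length(unique(flip_atoms)) != 4) stop("need 4 distinct atoms")
  flips <- lapply(ens$trajs, function(arr) {
    ang <- .dihedral_series(arr, flip_atoms)
    ang >= interval[1] & ang <= interval[2]
  })
  .state_frequency(flips, labels, labels$n_meta, n_boot, seed)
}

.residue_atoms <- function(top, residues, heavy_only = TRUE) {
  a <- top$atoms
  lapply(seq_len(nrow(residues)), function(i) {
    idx <- which(a$chain == residues$chain[i] &
                   a$resno == residues$resno[i] &
                   (!heavy_only | a$heavy))
    if (!length(idx))
      stop("no (heavy) atoms for residue ", residues$chain[i], "/",
           residues$resno[i])
    idx
  })
}

# per-frame minimum distance between two atom index sets, one trajectory
.min_dist_series <- function(arr, ia, ib) {
  nf <- dim(arr)[1]
  out <- rep(Inf, nf)
  for (i in ia) {
    for (j in ib) {
      d <- sqrt((arr[, i, 1] - arr[, j, 1])^2 +
                (arr[, i, 2] - arr[, j, 2])^2 +
                (arr[, i, 3] - arr[, j, 3])^2)
      out <- pmin(out, d)
    }
  }
  out
}

#' Residue contact frequency per metastable state
#'
#' A residue of `groupA` is in contact in a frame iff the minimum
#' heavy-atom distance to any atom of any residue in `groupB` is at most
#' `cutoff` (inclusive).
#'
#' @param ens `msm_ensemble`.
#' @param labels `msm_labels`.
#' @param groupA,groupB data frames with columns `chain`, `resno`.
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @param n_boot,seed bootstrap settings.
#' @return data frame `chain`, `resno`, `state`, `frequency`, `sd`.
#' @export
contact_frequency <- function(ens, labels, groupA, groupB, cutoff = 4.0,
                              n_boot = 100, seed = 1) {
  atomsA <- .residue_atoms(ens$top, groupA)
  atomsB <- unlist(.residue_atoms(ens$top, groupB))
  rows <- list()
  for (r in seq_along(atomsA)) {
    contacts <- lapply(ens$trajs, function(arr)
      .min_dist_series(arr, atomsA[[r]], atomsB) <= cutoff)
    fr <- .state_frequency(contacts, labels, labels$n_meta, n_boot,
                           seed + r)
    fr$chain <- groupA$chain[r]; fr$resno <- groupA$resno[r]
    rows[[r]] <- fr[, c("chain", "resno", "state", "frequency", "sd")]
  }
  do.call(rbind, rows)
}

#' Solvent-contact frequency per metastable state
#'
#' As [contact_frequency()] with the partner group set to all
#' solvent-tagged oxygen atoms.  If the topology carries no solvent, a
#' documented proxy is used instead: the exposure score
#' `1/(1 + n_close)`, where `n_close` counts non-self heavy atoms within
#' the cutoff; the result is flagged via attribute `"proxy"`.
#'
#' @param ens `msm_ensemble` (ideally with solvent atoms).
#' @param labels `msm_labels`.
#' @param residues data frame `chain`, `resno`.
#' @param cutoff solvent-contact cutoff in Angstrom (default 3.5).
#' @param n_boot,seed bootstrap settings.
#' @return data frame as in [contact_frequency()], with attribute
#'   `"proxy"` (logical).
#' @export
solvent_contact_frequency <- function(ens, labels, residues, cutoff = 3.5,
                                      n_boot = 100, seed = 1) {
  top <- ens$top
  solv_chains <- names(top$chain_roles)[top$chain_roles == "solvent"]
  solv <- which(top$atoms$chain %in% solv_chains & top$atoms$elem == "O")
  atomsR <- .residue_atoms(top, residues)
  rows <- list()
  proxy <- length(solv) == 0
  for (r in seq_along(atomsR)) {
    vals <- if (!proxy) {
      lapply(ens$trajs, function(arr)
        .min_dist_series(arr, atomsR[[r]], solv) <= cutoff)
    } else {
      self <- atomsR[[r]]
      others <- setdiff(which(top$atoms$heavy), self)
      lapply(ens$trajs, function(arr) {
        nf <- dim(arr)[1]
        n_close <- integer(nf)
        for (i in self) for (j in others) {
          d <- sqrt((arr[, i, 1] - arr[, j, 1])^2 +
                    (arr[, i, 2] - arr[, j, 2])^2 +
                    (arr[, i, 3] - arr[, j, 3])^2)
          n_close <- n_close + (d <= cutoff)
        }
        1 / (1 + n_close)
      })
    }
    fr <- .state_frequency(vals, labels, labels$n_meta, n_boot, seed + r)
    fr$chain <- residues$chain[r]; fr$resno <- residues$resno[r]
    rows[[r]] <- fr[, c("chain", "resno", "state", "frequency", "sd")]
  }
  out <- do.call(rbind, rows)
  attr(out, "proxy") <- proxy
  if (proxy) message("no solvent in topology; exposure-score proxy used")
  out
}

#' Helicity profile per metastable state
#'
#' Residue `i` counts as helical in a frame iff the backbone
#' `O(i)...N(i+4)` distance is at most `cutoff` (default 3.5 Angstrom),
#' the geometry of the alpha-helical hydrogen bond.
#'
#' @param ens `msm_ensemble` with backbone N and O atoms.
#' @param labels `msm_labels`.
#' @param chain chain id.
#' @param from,to residue-number range (truncated with a warning if it
#'   exceeds the chain).
#' @param cutoff H-bond distance cutoff (Angstrom).
#' @return data frame `chain`, `resno`, `state`, `helicity` (per-state
#'   helical fraction).
#' @export
helicity_profile <- function(ens, labels, chain, from, to, cutoff = 3.5) {
  a <- ens$top$atoms
  chain_res <- sort(unique(a$resno[a$chain == chain]))
  if (to > max(chain_res) - 4) {
    warning("range truncated: O(i)-N(i+4) needs residue i+4 in the chain")
    to <- max(chain_res) - 4
  }
  rows <- list()
  lab_all <- unlist(labels$labels)
  for (i in from:to) {
    oi <- which(a$chain == chain & a$resno == i & a$name == "O")
    ni <- which(a$chain == chain & a$resno == i + 4 & a$name == "N")
    if (!length(oi) || !length(ni))
      stop("backbone O/N missing for residue ", chain, "/", i)
    hel <- unlist(lapply(ens$trajs, function(arr)
      sqrt((arr[, oi, 1] - arr[, ni, 1])^2 +
           (arr[, oi, 2] - arr[, ni, 2])^2 +
           (arr[, oi, 3] - arr[, ni, 3])^2) <= cutoff))
    for (s in seq_len(labels$n_meta)) {
      sel <- !is.na(lab_all) & lab_all == s
      rows[[length(rows) + 1]] <-
        data.frame(chain = chain, resno = i, state = s,
                   helicity = if (any(sel)) mean(hel[sel]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
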