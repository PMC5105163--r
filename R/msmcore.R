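# Markov state model estimation and coarse-graining: shared k-means
# discretization across conditions, reversible maximum-likelihood
# transition matrices, implied timescales, Chapman-Kolmogorov validation,
# PCCA+ metastable decomposition, free energies, coarse rates, and
# trajectory-level bootstrap confidence intervals.

#' Gas constant in kJ K^-1 mol^-1
#' @export
GAS_CONSTANT_KJ <- 0.00831462

# strongly connected components of a boolean adjacency matrix, via
# reachability closure (repeated squaring); returns integer labels.
.strong_components <- function(adj) {
  n <- nrow(adj)
  R <- adj | diag(TRUE, n)
  steps <- ceiling(log2(max(n, 2)))
  for (i in seq_len(steps)) R <- (R %*% R) > 0
  same <- R & t(R)
  labels <- integer(n); lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      lab <- lab + 1L
      labels[which(same[i, ])] <- lab
    }
  }
  labels
}

# k-means++ seeding (Arthur & Vassilvitskii) on a frames x d matrix
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ], "-")^2))
  }
  centers
}

# nearest-center assignment, chunked to bound memory
.assign_centers <- function(x, centers, chunk = 100000L) {
  n <- nrow(x)
  out <- integer(n)
  cc <- rowSums(centers^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xs <- x[s:e, , drop = FALSE]
    d <- -2 * xs %*% t(centers)
    d <- sweep(d, 2, cc, "+")
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Shared k-means discretization of reduced coordinates
#'
#' Clusters the pooled frames of all conditions with one center set
#' (k-means++ seeding, Lloyd iterations), so that models for different
#' conditions live on the same microstates and can be compared.
#'
#' @param reduced a reduced-coordinate object from [transform_tica()], or
#'   a list of them (one per condition).
#' @param k number of microstates.
#' @param seed integer seed.
#' @param iter_max maximum Lloyd iterations.
#' @return Object of class `msm_discretization`: `centers` (`k x d`),
#'   `dtrajs` (per condition: list of integer vectors), `k`, `seed`.
#' @export
kmeans_discretize <- function(reduced, k, seed, iter_max = 500) {
  if (inherits(reduced, "msm_reduced")) reduced <- list(reduced)
  mats <- unlist(lapply(reduced, `[[`, "mats"), recursive = FALSE)
  x <- do.call(rbind, mats)
  if (nrow(x) < k) stop("k exceeds the number of frames")
  set.seed(seed)
  init <- .kmeanspp_init(x, k)
  km <- suppressWarnings(
    stats::kmeans(x, centers = init, iter.max = iter_max,
                  algorithm = "Lloyd"))
  centers <- km$centers
  dtrajs <- lapply(reduced, function(r)
    lapply(r$mats, function(m) .assign_centers(m, centers)))
  names(dtrajs) <- vapply(reduced, function(r)
    if (is.null(r$condition)) "default" else r$condition, character(1))
  structure(list(centers = centers, dtrajs = dtrajs, k = k,
                 seed = as.integer(seed)),
            class = "msm_discretization")
}

#' Transition count matrix at a lag
#'
#' Sliding-window counts: every pair `(t, t + lag)` within a trajectory
#' contributes; trajectories are never concatenated, so no cross-boundary
#' pairs arise.
#'
#' @param dtrajs list of integer state sequences (1-based), or a single
#'   vector.
#' @param lag lag in frames (>= 1).
#' @param n_states number of states; defaults to the largest index seen.
#' @return `n_states x n_states` count matrix.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (lag < 1) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  if (all(vapply(dtrajs, length, 1L) <= lag))
    stop("lag >= length of every trajectory")
  C <- matrix(0, n_states, n_states)
  for (d in dtrajs) {
    nf <- length(d)
    if (nf <= lag) next
    i <- d[1:(nf - lag)]
    j <- d[(lag + 1):nf]
    tab <- tabulate((i - 1L) * n_states + j, nbins = n_states^2)
    C <- C + matrix(tab, n_states, n_states, byrow = TRUE)
  }
  C
}

#' Largest connected set of a count matrix
#'
#' Largest strongly connected component of the directed graph with an edge
#' `i -> j` wherever `C[i, j] > 0`.  Ties are broken by total counts, then
#' by smallest state index.
#'
#' @param C non-negative count matrix.
#' @return sorted integer vector of state indices (1-based).
#' @export
largest_connected_set <- function(C) {
  if (!length(C)) stop("empty count matrix")
  if (any(C < 0)) stop("counts must be non-negative")
  labels <- .strong_components(C > 0)
  comp <- split(seq_len(nrow(C)), labels)
  size <- lengths(comp)
  tot <- vapply(comp, function(s) sum(C[s, , drop = FALSE]) +
                  sum(C[, s, drop = FALSE]), numeric(1))
  first <- vapply(comp, min, 1L)
  ord <- order(-size, -tot, first)
  sort(comp[[ord[1]]])
}

#' Reversible maximum-likelihood Markov state model
#'
#' Estimates the transition matrix maximizing the likelihood of the counts
#' subject to detailed balance, by the standard fixed-point iteration on
#' symmetric edge weights: `x_ij <- (C_ij + C_ji) / (c_i/x_i + c_j/x_j)`
#' with `c_i = sum_j C_ij`, `x_i = sum_j x_ij`, iterated until the
#' stationary distribution moves by less than `tol`.  The estimate is
#' restricted to the largest connected set of the counts.
#'
#' @param C count matrix (any state space; restricted internally).
#' @param lag_frames lag of the counts (frames).
#' @param dt_ns frame interval (ns).
#' @param tol convergence threshold on `max |delta pi|`.
#' @param max_iter iteration cap; non-convergence is an error reporting
#'   the residual.
#' @return Object of class `msm_model`: `T` (transition matrix on the
#'   active set), `pi`, `active` (original state indices), `counts` (the
#'   full input matrix), `eigenvalues`, `right_eigenvectors` (columns,
#'   pi-orthonormal, first is the constant vector), `lag_frames`, `dt_ns`.
#' @export
estimate_reversible_msm <- function(C, lag_frames = 1, dt_ns = 1,
                                    tol = 1e-12, max_iter = 1e6) {
  active <- largest_connected_set(C)
  Ca <- C[active, active, drop = FALSE]
  n <- nrow(Ca)
  Csym <- Ca + t(Ca)
  ci <- rowSums(Ca)
  if (any(ci == 0)) stop("state without outgoing counts in active set")
  x <- Csym / sum(Csym)
  pi_old <- rowSums(x)
  pos <- Csym > 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    xi <- rowSums(x)
    q <- ci / xi
    denom <- outer(q, q, "+")
    x_new <- matrix(0, n, n)
    x_new[pos] <- Csym[pos] / denom[pos]
    x_new <- x_new / sum(x_new)
    pi_new <- rowSums(x_new)
    delta <- max(abs(pi_new - pi_old))
    x <- x_new; pi_old <- pi_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop("reversible estimator did not converge; residual ", delta)
  }
  Tm <- x / rowSums(x)
  pi <- pi_old / sum(pi_old)
  # reversible spectrum via the pi-symmetrized matrix
  s <- sqrt(pi)
  S <- Tm * outer(s, 1 / s)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  psi <- es$vectors / s              # right eigenvectors of T
  # normalize: first eigenvector to the constant 1
  psi <- sweep(psi, 2, psi[1, ] / abs(psi[1, ] + (psi[1, ] == 0)), "/")
  psi[, 1] <- 1
  structure(list(T = Tm, pi = pi, active = active, counts = C,
                 eigenvalues = es$values, right_eigenvectors = psi,
                 lag_frames = lag_frames, dt_ns = dt_ns,
                 iterations = iter),
            class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat("msm_model:", length(x$active), "active states, lag",
      x$lag_frames, "frames (", x$lag_frames * x$dt_ns, "ns )\n")
  cat("  slowest implied timescales (ns):",
      signif(head(implied_timescales_from_model(x), 3), 4), "\n")
  invisible(x)
}

#' Implied timescales of an estimated model
#' @param model `msm_model`.
#' @return vector of relaxation timescales in ns (slowest first,
#'   stationary eigenvalue excluded).
#' @export
implied_timescales_from_model <- function(model) {
  lam <- model$eigenvalues[-1]
  tau_ns <- model$lag_frames * model$dt_ns
  ts <- rep(NA_real_, length(lam))
  pos <- lam > 0 & lam < 1
  ts[pos] <- -tau_ns / log(lam[pos])
  ts[lam >= 1] <- Inf
  ts
}

#' Implied timescales over a set of lags
#'
#' `t_i(tau) = -tau / log(lambda_i(tau))` from a reversible model
#' re-estimated at each lag.  Eigenvalues at or above 1 give infinite
#' timescales (with a warning); the reversible estimator guarantees a real
#' spectrum.
#'
#' @param dtrajs list of integer state sequences.
#' @param lags integer vector of lags (frames).
#' @param dt_ns frame interval (ns).
#' @param n_timescales how many timescales to report.
#' @return data frame with `lag_frames`, `lag_ns`, and `t2 ... t<m+1>`
#'   columns in ns.
#' @export
implied_timescales <- function(dtrajs, lags, dt_ns = 1, n_timescales = 3) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  maxlen <- max(vapply(dtrajs, length, 1L))
  if (any(lags < 1) || any(lags >= maxlen))
    stop("lags must be >= 1 and < the longest trajectory")
  rows <- lapply(lags, function(lag) {
    m <- estimate_reversible_msm(count_transitions(dtrajs, lag),
                                 lag_frames = lag, dt_ns = dt_ns)
    ts <- implied_timescales_from_model(m)
    if (any(is.infinite(ts[seq_len(min(n_timescales, length(ts)))])))
      warning("eigenvalue at 1 at lag ", lag, "; timescale reported as Inf")
    ts <- c(ts, rep(NA_real_, n_timescales))[seq_len(n_timescales)]
    c(lag, lag * dt_ns, ts)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("lag_frames", "lag_ns",
                  paste0("t", seq_len(n_timescales) + 1))
  out
}

# set-to-set transition probability after one application of T, sources
# weighted by pi restricted to the source set
.set_transition <- function(Tm, pi, states, setA, setB) {
  ia <- match(intersect(setA, states), states)
  ib <- match(intersect(setB, states), states)
  if (!length(ia) || !length(ib)) return(NA_real_)
  w <- pi[ia] / sum(pi[ia])
  sum(w * rowSums(Tm[ia, ib, drop = FALSE]))
}

#' Chapman-Kolmogorov test
#'
#' Compares the metastable set-to-set transition probabilities predicted
#' by propagating the model, `T(tau)^k`, against models re-estimated at
#' lag `k*tau`, for `k = 1..n_steps`.  The test passes when every
#' estimated value lies within the predicted value plus/minus `z` bootstrap
#' standard deviations (trajectory-level bootstrap of the estimate).
#'
#' @param model `msm_model` estimated at the base lag.
#' @param dtrajs the discrete trajectories the model came from.
#' @param sets list of integer vectors: the metastable partition in
#'   original microstate indices (e.g. from [pcca()] crisp sets).
#' @param n_steps maximum multiple of the base lag.
#' @param n_boot bootstrap replicates for the error band.
#' @param seed integer seed.
#' @param z band half-width in bootstrap standard deviations.
#' @return Object of class `msm_cktest`: data frame `curves` with columns
#'   `set`, `step`, `predicted`, `estimated`, `sd`, and logical `pass`.
#' @export
ck_test <- function(model, dtrajs, sets, n_steps, n_boot = 50, seed = 1,
                    z = 2) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  maxlen <- max(vapply(dtrajs, length, 1L))
  steps <- seq_len(n_steps)
  usable <- steps[steps * model$lag_frames < maxlen]
  if (length(usable) < n_steps)
    warning("insufficient data beyond step ", max(usable), "; truncated")
  set.seed(seed)
  nset <- length(sets)
  rows <- list()
  Tk <- diag(nrow(model$T))
  for (k in steps) {
    Tk <- Tk %*% model$T
    if (!k %in% usable) break
    mk <- estimate_reversible_msm(
      count_transitions(dtrajs, k * model$lag_frames,
                        n_states = nrow(model$counts)),
      lag_frames = k * model$lag_frames, dt_ns = model$dt_ns)
    boot <- matrix(NA_real_, n_boot, nset)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(dtrajs), replace = TRUE)
      mb <- tryCatch(estimate_reversible_msm(
        count_transitions(dtrajs[idx], k * model$lag_frames,
                          n_states = nrow(model$counts)),
        lag_frames = k * model$lag_frames, dt_ns = model$dt_ns),
        error = function(e) NULL)
      if (is.null(mb)) next
      for (s in seq_len(nset))
        boot[b, s] <- .set_transition(mb$T, mb$pi, mb$active,
                                      sets[[s]], sets[[s]])
    }
    for (s in seq_len(nset)) {
      pred <- .set_transition(Tk, model$pi, model$active,
                              sets[[s]], sets[[s]])
      est <- .set_transition(mk$T, mk$pi, mk$active, sets[[s]], sets[[s]])
      rows[[length(rows) + 1]] <-
        data.frame(set = s, step = k, predicted = pred, estimated = est,
                   sd = sd(boot[, s], na.rm = TRUE))
    }
  }
  curves <- do.call(rbind, rows)
  sd_floor <- 1e-12
  pass <- all(abs(curves$estimated - curves$predicted) <=
                z * pmax(curves$sd, sd_floor) |
                abs(curves$estimated - curves$predicted) < 1e-12,
              na.rm = TRUE)
  structure(list(curves = curves, pass = pass, z = z),
            class = "msm_cktest")
}

#' PCCA+ metastable decomposition
#'
#' Fuzzy memberships from a linear combination of the top `n_meta` right
#' eigenvectors, with the simplex vertices chosen by successive
#' orthogonalization (the inner simplex algorithm).  Memberships are
#' clipped to `[0, 1]` and row-normalized; the crisp assignment is the
#' argmax membership.
#'
#' @param model reversible `msm_model`.
#' @param n_meta number of metastable states.
#' @return Object of class `msm_pcca`: `chi` (memberships, active
#'   microstates x n_meta), `crisp` (per active microstate), `sets` (list
#'   of original microstate indices per metastable state), `populations`
#'   (coarse stationary populations), `active`, `pi_micro`, `n_meta`.
#' @export
pcca <- function(model, n_meta) {
  lam <- model$eigenvalues
  if (n_meta > length(lam))
    stop("n_meta exceeds the number of eigenvalues")
  if (n_meta < length(lam) &&
      abs(lam[n_meta] - lam[n_meta + 1]) < 1e-10)
    stop("degenerate eigenvalues at the spectral cut; try a different n_meta")
  X <- model$right_eigenvectors[, seq_len(n_meta), drop = FALSE]
  n <- nrow(X)
  # inner simplex: pick n_meta rows spanning the largest simplex
  idx <- integer(n_meta)
  resid <- X
  idx[1] <- which.max(rowSums(resid^2))
  v <- resid[idx[1], ]; v <- v / sqrt(sum(v^2))
  if (n_meta > 1) {
    for (l in 2:n_meta) {
      resid <- resid - outer(drop(resid %*% v), v)
      norms <- rowSums(resid^2)
      norms[idx[seq_len(l - 1)]] <- -Inf
      idx[l] <- which.max(norms)
      v <- resid[idx[l], ]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("eigenvector rows are degenerate; reduce n_meta")
      v <- v / nv
    }
  }
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  sets <- lapply(seq_len(n_meta), function(m) model$active[crisp == m])
  if (any(lengths(sets) == 0))
    stop("empty metastable state; reduce n_meta")
  pops <- vapply(seq_len(n_meta), function(m) sum(model$pi[crisp == m]),
                 numeric(1))
  structure(list(chi = chi, crisp = crisp, sets = sets,
                 populations = pops, active = model$active,
                 pi_micro = model$pi, n_meta = n_meta),
            class = "msm_pcca")
}

#' @export
print.msm_pcca <- function(x, ...) {
  cat("msm_pcca:", x$n_meta, "metastable states, populations:",
      paste(signif(x$populations, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Free energies of metastable states from populations
#'
#' `dG_m = -R T log(Pi_m / Pi_ref)` with the most populated state as the
#' zero-energy reference.
#'
#' @param populations coarse population vector (or an `msm_pcca` object).
#' @param temperature_K absolute temperature; default 310 K.
#' @return data frame with `state`, `population`, `dG_kJ_mol`.
#' @export
free_energies <- function(populations, temperature_K = 310) {
  if (inherits(populations, "msm_pcca")) populations <- populations$populations
  if (any(populations <= 0)) stop("populations must be > 0")
  ref <- max(populations)
  dG <- -GAS_CONSTANT_KJ * temperature_K * log(populations / ref)
  data.frame(state = seq_along(populations), population = populations,
             dG_kJ_mol = dG)
}

#' Free-energy difference implied by a population fold-change
#'
#' `ddG = R T log(fold)`: the relative stabilization of a state whose
#' population increases `fold`-fold between two conditions.
#'
#' @param fold population ratio (condition B over condition A).
#' @param temperature_K absolute temperature (K).
#' @return ddG in kJ/mol.
#' @export
ddg_from_fold <- function(fold, temperature_K = 310) {
  if (any(fold <= 0)) stop("fold must be > 0")
  GAS_CONSTANT_KJ * temperature_K * log(fold)
}

#' Compare metastable states across two conditions
#'
#' Both decompositions must come from the same shared microstate centers.
#' Metastable states are matched by maximal Jaccard overlap of their crisp
#' microstate sets; for each matched pair the population fold-change and
#' the corresponding `ddG = R T log(fold)` are reported.  States with best
#' overlap below `min_overlap` are reported unmatched (NA values).
#'
#' @param decompA,decompB `msm_pcca` objects for the two conditions.
#' @param temperature_K absolute temperature (K).
#' @param bootA,bootB optional bootstrap population matrices
#'   (replicates x n_meta, from [msm_bootstrap()]) used for 1-sigma
#'   percentile bounds on fold and ddG.
#' @param min_overlap minimum Jaccard overlap for a match.
#' @return data frame with `state_A`, `state_B`, `overlap`, `pop_A`,
#'   `pop_B`, `fold`, `ddG_kJ_mol` (+ bounds when bootstraps given).
#' @export
compare_conditions <- function(decompA, decompB, temperature_K = 310,
                               bootA = NULL, bootB = NULL,
                               min_overlap = 0.2) {
  nA <- decompA$n_meta
  jac <- matrix(0, nA, decompB$n_meta)
  for (i in seq_len(nA)) for (j in seq_len(decompB$n_meta)) {
    a <- decompA$sets[[i]]; b <- decompB$sets[[j]]
    jac[i, j] <- length(intersect(a, b)) / length(union(a, b))
  }
  rows <- lapply(seq_len(nA), function(i) {
    best <- max(jac[i, ])
    if (best < min_overlap)
      return(data.frame(state_A = i, state_B = NA_integer_, overlap = best,
                        pop_A = decompA$populations[i], pop_B = NA_real_,
                        fold = NA_real_, ddG_kJ_mol = NA_real_))
    js <- which(jac[i, ] == best)
    if (length(js) > 1) stop("ambiguous metastable matching (tied overlap)")
    j <- js[1]
    fold <- decompB$populations[j] / decompA$populations[i]
    data.frame(state_A = i, state_B = j, overlap = best,
               pop_A = decompA$populations[i],
               pop_B = decompB$populations[j],
               fold = fold, ddG_kJ_mol = ddg_from_fold(fold, temperature_K))
  })
  out <- do.call(rbind, rows)
  if (!is.null(bootA) && !is.null(bootB)) {
    nb <- min(nrow(bootA), nrow(bootB))
    lo <- up <- rep(NA_real_, nrow(out))
    dlo <- dup <- rep(NA_real_, nrow(out))
    for (r in seq_len(nrow(out))) {
      if (is.na(out$state_B[r])) next
      f <- bootB[seq_len(nb), out$state_B[r]] / bootA[seq_len(nb), out$state_A[r]]
      f <- f[is.finite(f) & f > 0]
      q <- quantile(f, c(0.1587, 0.8413), names = FALSE)
      lo[r] <- q[1]; up[r] <- q[2]
      dq <- quantile(ddg_from_fold(f, temperature_K), c(0.1587, 0.8413),
                     names = FALSE)
      dlo[r] <- dq[1]; dup[r] <- dq[2]
    }
    out$fold_lo <- lo; out$fold_up <- up
    out$ddG_lo <- dlo; out$ddG_up <- dup
  }
  out
}

# mean first-passage time (in lag steps) from every state to target set
.mfpt_to_set <- function(Tm, target) {
  n <- nrow(Tm)
  rest <- setdiff(seq_len(n), target)
  m <- numeric(n)
  if (length(rest)) {
    A <- diag(length(rest)) - Tm[rest, rest, drop = FALSE]
    m[rest] <- solve(A, rep(1, length(rest)))
  }
  m
}

#' Coarse inter-metastable transition rates
#'
#' `rate(m -> n) = 1 / MFPT(m -> n)` with the mean first-passage time from
#' the stationary-weighted states of the source set to the target set,
#' converted to 1/us via the lag time.
#'
#' @param model `msm_model`.
#' @param decomp `msm_pcca` on the same model.
#' @return data frame `from`, `to`, `mfpt_us`, `rate_per_us`.
#' @export
coarse_rates <- function(model, decomp) {
  tau_us <- model$lag_frames * model$dt_ns / 1000
  nm <- decomp$n_meta
  rows <- list()
  for (to in seq_len(nm)) {
    target <- which(decomp$crisp == to)
    m <- .mfpt_to_set(model$T, target)
    for (from in seq_len(nm)) {
      if (from == to) next
      src <- which(decomp$crisp == from)
      w <- model$pi[src] / sum(model$pi[src])
      mf <- sum(w * m[src]) * tau_us
      rate <- if (is.finite(mf) && mf > 0) 1 / mf else {
        warning("target set unreachable from state ", from)
        0
      }
      rows[[length(rows) + 1]] <- data.frame(from = from, to = to,
                                             mfpt_us = mf,
                                             rate_per_us = rate)
    }
  }
  do.call(rbind, rows)
}

#' Trajectory-level bootstrap of MSM thermodynamics and kinetics
#'
#' Resamples entire trajectories with replacement while holding the
#' k-means centers and the microstate-to-metastable map fixed, re-estimates
#' counts and the reversible transition matrix per replicate, and reports
#' 15.87/84.13 bootstrap percentiles as asymmetric 1-sigma bounds.
#' Replicates in which a metastable state vanishes from the active set are
#' dropped and counted.
#'
#' @param dtrajs list of integer state sequences (>= 2 recommended).
#' @param lag lag in frames.
#' @param decomp `msm_pcca` defining the fixed microstate-to-metastable
#'   map.
#' @param n_boot number of replicates (a warning is issued below 10).
#' @param seed integer seed.
#' @param temperature_K temperature for the free energies.
#' @param dt_ns frame interval (ns).
#' @param rates also bootstrap coarse rates (slower).
#' @return Object of class `msm_bootstrap`: matrices `populations`,
#'   `dG` (replicates x n_meta), optional `rates`, summary data frame
#'   `summary` with 1-sigma bounds, and `n_dropped`.
#' @export
msm_bootstrap <- function(dtrajs, lag, decomp, n_boot = 50, seed = 1,
                          temperature_K = 310, dt_ns = 1, rates = FALSE) {
  if (n_boot < 10) warning("fewer than 10 bootstrap replicates")
  set.seed(seed)
  k <- max(unlist(dtrajs))
  # fixed crisp map on original microstate indices
  crisp_full <- rep(NA_integer_, k)
  crisp_full[decomp$active] <- decomp$crisp
  nm <- decomp$n_meta
  pops <- matrix(NA_real_, n_boot, nm)
  ratemat <- if (rates) matrix(NA_real_, n_boot, nm * (nm - 1)) else NULL
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(dtrajs), replace = TRUE)
    m <- tryCatch(
      estimate_reversible_msm(count_transitions(dtrajs[idx], lag,
                                                n_states = k),
                              lag_frames = lag, dt_ns = dt_ns),
      error = function(e) NULL)
    if (is.null(m)) { dropped <- dropped + 1L; next }
    meta <- crisp_full[m$active]
    p <- vapply(seq_len(nm), function(s) sum(m$pi[!is.na(meta) & meta == s]),
                numeric(1))
    if (any(p == 0)) { dropped <- dropped + 1L; next }
    pops[b, ] <- p / sum(p)
    if (rates) {
      dres <- list(crisp = meta, n_meta = nm)
      cr <- tryCatch({
        d2 <- decomp; d2$crisp <- meta; d2$active <- m$active
        coarse_rates(m, d2)$rate_per_us
      }, error = function(e) rep(NA_real_, nm * (nm - 1)))
      ratemat[b, ] <- cr
    }
  }
  ok <- !is.na(pops[, 1])
  pops <- pops[ok, , drop = FALSE]
  dG <- t(apply(pops, 1, function(p)
    -GAS_CONSTANT_KJ * temperature_K * log(p / max(p))))
  qs <- function(m) apply(m, 2, quantile, probs = c(0.1587, 0.8413),
                          names = FALSE, na.rm = TRUE)
  qp <- qs(pops); qd <- qs(dG)
  summary <- data.frame(state = seq_len(nm),
                        pop_lo = qp[1, ], pop_up = qp[2, ],
                        pop_sd = apply(pops, 2, sd),
                        dG_lo = qd[1, ], dG_up = qd[2, ],
                        dG_sd = apply(dG, 2, sd))
  structure(list(populations = pops, dG = dG, rates = ratemat,
                 summary = summary, n_dropped = dropped,
                 seed = as.integer(seed)),
            class = "msm_bootstrap")
}

#' Sample seed conformations for adaptive simulation starts
#'
#' Projects the active microstates onto the first three non-stationary
#' right eigenvectors, clusters that space with k-means
#' (`k ~ sqrt(number of active microstates)` by default), and draws
#' `n_out` frames uniformly across clusters (quotas differing by at most
#' one) and uniformly within each cluster.
#'
#' @param model `msm_model` with at least 4 eigenvectors.
#' @param dtrajs discrete trajectories (original microstate indices).
#' @param n_out number of frames to draw.
#' @param k_clusters number of clusters; default
#'   `round(sqrt(length(model$active)))`.
#' @param seed integer seed.
#' @return data frame with `traj`, `frame`, `microstate`, `cluster`.
#' @export
sample_seed_conformations <- function(model, dtrajs, n_out,
                                      k_clusters = NULL, seed = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  nact <- length(model$active)
  if (ncol(model$right_eigenvectors) < 4)
    stop("model needs at least 3 non-stationary eigenvectors")
  if (is.null(k_clusters)) k_clusters <- round(sqrt(nact))
  if (k_clusters > nact) stop("k_clusters exceeds the number of microstates")
  set.seed(seed)
  Y <- model$right_eigenvectors[, 2:4, drop = FALSE]
  km <- suppressWarnings(stats::kmeans(Y, centers = min(k_clusters, nact),
                                       nstart = 5))
  micro_cluster <- km$cluster          # per active microstate
  # frame lookup: original microstate of every frame
  frames <- do.call(rbind, lapply(seq_along(dtrajs), function(ti)
    data.frame(traj = ti, frame = seq_along(dtrajs[[ti]]),
               microstate = dtrajs[[ti]])))
  frames <- frames[frames$microstate %in% model$active, ]
  frames$cluster <- micro_cluster[match(frames$microstate, model$active)]
  quota <- rep(n_out %/% k_clusters, k_clusters)
  extra <- n_out %% k_clusters
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  out <- list()
  for (cl in seq_len(k_clusters)) {
    pool <- frames[frames$cluster == cl, ]
    if (!nrow(pool)) next
    pick <- pool[sample.int(nrow(pool), quota[cl],
                            replace = quota[cl] > nrow(pool)), ]
    out[[cl]] <- pick
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
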