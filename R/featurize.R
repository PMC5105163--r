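# Featurization: pairwise C-alpha distances over a residue selection, and
# time-lagged independent component analysis (TICA) to extract the slow
# collective coordinates.

#' Pairwise C-alpha distance features
#'
#' For a selection of `n` residues returns the `n(n-1)/2` pairwise
#' C-alpha--C-alpha distances per frame, columns ordered lexicographically
#' in the pair index `(i < j)`, values in Angstrom.
#'
#' @param ens `msm_ensemble`.
#' @param sel `msm_selection` (every residue must have exactly one CA).
#' @return Object of class `msm_features`: `mats` (list of
#'   `frames x d` matrices per trajectory), `labels` (residue-pair
#'   descriptors), `condition`, `dt_ns`.
#' @export
pairwise_ca_distances <- function(ens, sel) {
  top <- ens$top
  ca <- integer(nrow(sel))
  for (i in seq_len(nrow(sel)))
    ca[i] <- .ca_index(top, sel$chain[i], sel$resno[i])
  n <- length(ca)
  if (n < 2) stop("selection must contain at least 2 residues")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  labels <- paste0(sel$chain[pairs[, 1]], sel$resno[pairs[, 1]], "-",
                   sel$chain[pairs[, 2]], sel$resno[pairs[, 2]])
  mats <- lapply(ens$trajs, function(arr) {
    X <- arr[, ca, , drop = FALSE]
    d <- matrix(NA_real_, dim(arr)[1], nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      d[, p] <- sqrt((X[, i, 1] - X[, j, 1])^2 +
                     (X[, i, 2] - X[, j, 2])^2 +
                     (X[, i, 3] - X[, j, 3])^2)
    }
    d
  })
  structure(list(mats = mats, labels = labels, condition = ens$condition,
                 dt_ns = ens$dt_ns),
            class = "msm_features")
}

#' Wrap raw matrices as a feature object
#'
#' For workflows whose features are produced outside
#' [pairwise_ca_distances()] (tests, custom featurizers).
#'
#' @param mats matrix or list of `frames x d` matrices.
#' @param labels optional column descriptors.
#' @param condition condition id.
#' @param dt_ns frame interval (ns).
#' @return `msm_features`.
#' @export
as_features <- function(mats, labels = NULL, condition = "default",
                        dt_ns = 1) {
  if (!is.list(mats)) mats <- list(mats)
  mats <- lapply(mats, as.matrix)
  if (is.null(labels)) labels <- paste0("f", seq_len(ncol(mats[[1]])))
  structure(list(mats = mats, labels = labels, condition = condition,
                 dt_ns = dt_ns),
            class = "msm_features")
}

#' Fit time-lagged independent component analysis
#'
#' Solves the generalized symmetric eigenproblem
#' `sym(C_tau) v = lambda (C_0 + reg I) v` with mean-free covariances
#' accumulated over trajectories (time-lagged pairs never cross trajectory
#' boundaries; sliding window).  Components are ordered by `|lambda|`
#' descending; eigenvector signs are fixed by forcing the
#' largest-magnitude loading positive.
#'
#' @param features `msm_features` or a list of them (covariances are
#'   pooled, e.g. over conditions).
#' @param lag TICA lag in frames.
#' @param n_components components to retain (default 3).
#' @param reg ridge regularization added to `C_0`; default
#'   `1e-6 * trace(C_0)/d`, needed for rank-deficient distance sets.
#' @return Object of class `msm_tica`: `lag`, `mean`, `C0`, `Ct`,
#'   `eigenvalues`, `eigenvectors` (`d x n_components`,
#'   `(C0+regI)`-orthonormal), `reg`, `dt_ns`.
#' @export
fit_tica <- function(features, lag, n_components = 3, reg = NULL) {
  if (inherits(features, "msm_features")) features <- list(features)
  mats <- unlist(lapply(features, `[[`, "mats"), recursive = FALSE)
  d <- ncol(mats[[1]])
  if (n_components > d) stop("n_components exceeds feature dimension")
  if (all(vapply(mats, nrow, 1L) <= lag))
    stop("every trajectory is shorter than the lag")
  # accumulate first and second moments over lagged frame pairs
  s <- numeric(d); n_tot <- 0
  S00 <- matrix(0, d, d); Stt <- matrix(0, d, d); S0t <- matrix(0, d, d)
  for (m in mats) {
    nf <- nrow(m)
    if (nf <= lag) next
    X0 <- m[1:(nf - lag), , drop = FALSE]
    Xt <- m[(lag + 1):nf, , drop = FALSE]
    s <- s + colSums(X0) + colSums(Xt)
    n_tot <- n_tot + nrow(X0)
    S00 <- S00 + crossprod(X0)
    Stt <- Stt + crossprod(Xt)
    S0t <- S0t + crossprod(X0, Xt)
  }
  mu <- s / (2 * n_tot)
  C0 <- (S00 + Stt) / (2 * n_tot) - outer(mu, mu)
  Ct <- S0t / n_tot - outer(mu, mu)
  Ct <- (Ct + t(Ct)) / 2
  if (is.null(reg)) reg <- 1e-6 * sum(diag(C0)) / d
  M <- C0 + diag(reg, d)
  R <- tryCatch(chol(M), error = function(e)
    stop("instantaneous covariance is singular; set reg > 0"))
  # whiten: (R^-T Ct R^-1) y = lambda y, v = R^-1 y
  Rinv <- backsolve(R, diag(d))
  B <- t(Rinv) %*% Ct %*% Rinv
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ord <- order(abs(es$values), decreasing = TRUE)[seq_len(n_components)]
  lam <- es$values[ord]
  V <- Rinv %*% es$vectors[, ord, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(lag = lag, mean = mu, C0 = C0, Ct = Ct,
                 eigenvalues = lam, eigenvectors = V, reg = reg,
                 dt_ns = features[[1]]$dt_ns),
            class = "msm_tica")
}

#' @export
print.msm_tica <- function(x, ...) {
  cat("msm_tica: lag", x$lag, "frames,", ncol(x$eigenvectors),
      "components, eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Slowest TICA relaxation timescales
#' @param model `msm_tica`.
#' @return timescales `-lag/log(lambda)` in ns.
#' @export
tica_timescales <- function(model) {
  lam <- model$eigenvalues
  ts <- rep(NA_real_, length(lam))
  pos <- lam > 0 & lam < 1
  ts[pos] <- -model$lag * model$dt_ns / log(lam[pos])
  ts
}

#' Project features onto TICA components
#'
#' Deterministic projection of the mean-free features onto the model
#' eigenvectors.
#'
#' @param model `msm_tica`.
#' @param features `msm_features` with matching dimension.
#' @return Object of class `msm_reduced`: `mats` (list of
#'   `frames x n_components` matrices), `condition`, `dt_ns`.
#' @export
transform_tica <- function(model, features) {
  d <- length(model$mean)
  mats <- lapply(features$mats, function(m) {
    if (ncol(m) != d)
      stop("feature dimension ", ncol(m), " does not match model (", d, ")")
    sweep(m, 2, model$mean) %*% model$eigenvectors
  })
  structure(list(mats = mats, condition = features$condition,
                 dt_ns = features$dt_ns),
            class = "msm_reduced")
}
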