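#' Full conformational-plasticity analysis pipeline
#'
#' Runs the complete chain on one or more simulation conditions sharing a
#' feature definition: TICA fitted on the pooled features, projection,
#' one shared k-means discretization, and per condition a reversible MSM,
#' PCCA+ decomposition, free energies and a trajectory bootstrap.
#'
#' @param features `msm_features` or list of them (one per condition;
#'   conditions are compared on the shared discretization).
#' @param tica_lag TICA lag (frames).
#' @param msm_lag MSM lag (frames).
#' @param k number of microstates (default 100).
#' @param n_components TICA components kept (default 3).
#' @param n_meta metastable states (default 3).
#' @param seed integer seed (clustering and bootstrap).
#' @param n_boot bootstrap replicates per condition.
#' @param temperature_K temperature for free energies (default 310 K).
#' @return Object of class `msm_pipeline`: `tica`, `disc`, and per
#'   condition a list with `model`, `decomp`, `energies`, `boot`.
#' @export
msm_pipeline <- function(features, tica_lag, msm_lag, k = 100,
                         n_components = 3, n_meta = 3, seed = 1,
                         n_boot = 50, temperature_K = 310) {
  if (inherits(features, "msm_features")) features <- list(features)
  tica <- fit_tica(features, lag = tica_lag, n_components = n_components)
  reduced <- lapply(features, function(f) transform_tica(tica, f))
  disc <- kmeans_discretize(reduced, k = k, seed = seed)
  conditions <- names(disc$dtrajs)
  out <- list(tica = tica, disc = disc, conditions = list())
  for (ci in seq_along(conditions)) {
    dtr <- disc$dtrajs[[ci]]
    C <- count_transitions(dtr, msm_lag, n_states = k)
    model <- estimate_reversible_msm(C, lag_frames = msm_lag,
                                     dt_ns = features[[ci]]$dt_ns)
    decomp <- pcca(model, n_meta)
    boot <- msm_bootstrap(dtr, msm_lag, decomp, n_boot = n_boot,
                          seed = seed + ci,
                          temperature_K = temperature_K,
                          dt_ns = features[[ci]]$dt_ns)
    out$conditions[[conditions[ci]]] <-
      list(model = model, decomp = decomp,
           energies = free_energies(decomp, temperature_K),
           boot = boot, dtrajs = dtr)
  }
  class(out) <- "msm_pipeline"
  out
}

#' @export
print.msm_pipeline <- function(x, ...) {
  cat("msm_pipeline:", length(x$conditions), "condition(s),",
      x$disc$k, "microstates\n")
  for (nm in names(x$conditions)) {
    d <- x$conditions[[nm]]$decomp
    cat("  ", nm, ": populations ",
        paste(signif(d$populations, 3), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
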