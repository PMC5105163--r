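# NMR-detected H/D exchange in the EX2 limit: first-order decay fitting
# with half-life classification, intrinsic-rate averaging, protection
# factors, open/closed free energies, and chemical shift perturbation.

#' Fit or classify an HDX signal decay
#'
#' Classification rules precede fitting: amides whose signal is already
#' at the noise floor at the first measurements (mean of the first three
#' points within three times the noise level) have exchanged within the
#' dead time (class `"fast"`, half-life reported as `< 15` min); series
#' decaying by
#' less than 5% over the horizon are `"stable"` (`> 4000` min).
#' Otherwise `S/N(t) = A exp(-k_obs t)` is least-squares fitted (no
#' baseline offset: the fully exchanged signal falls into the noise).
#' Series whose fitted rate is non-positive or whose fit fails are
#' `"excluded"`.
#'
#' @param time_min increasing time points (minutes).
#' @param sn signal-to-noise values.
#' @param noise_sd noise level (same units as `sn`).
#' @param dead_min dead time of the measurement (min, default 35).
#' @param horizon_min measurement horizon (min, default 3600).
#' @return Object of class `hdx_fit`: list with `class` (`"fast"`,
#'   `"fitted"`, `"stable"`, `"excluded"`), and for fitted series
#'   `k_obs` (1/min), `amplitude`, `t_half_min`, `residual_sd`; for
#'   classified series `t_half_label` (`"<15"` / `">4000"`).
#' @export
fit_decay <- function(time_min, sn, noise_sd, dead_min = 35,
                      horizon_min = 3600) {
  if (is.unsorted(time_min, strictly = TRUE)) stop("times must increase")
  if (length(time_min) < 1) stop("need at least one observation")
  res <- list(class = NA_character_, k_obs = NA_real_,
              amplitude = NA_real_, t_half_min = NA_real_,
              t_half_label = NA_character_, residual_sd = NA_real_)
  # undetectable from the first measurements on: the mean of the first
  # three points is a noise-robust read of the post-dead-time level
  head_mean <- mean(sn[seq_len(min(3L, length(sn)))])
  if (head_mean <= 3 * noise_sd) {
    res$class <- "fast"; res$t_half_label <- "<15"
    return(structure(res, class = "hdx_fit"))
  }
  # total relative decay over the horizon, from the first/last thirds
  nt <- length(sn)
  third <- max(1L, nt %/% 3)
  early <- mean(sn[seq_len(third)])
  late <- mean(sn[seq(nt - third + 1L, nt)])
  decay <- if (early > 0) (early - late) / early else NA_real_
  if (!is.na(decay) && abs(decay) < 0.05) {
    res$class <- "stable"; res$t_half_label <- ">4000"
    return(structure(res, class = "hdx_fit"))
  }
  if (!is.na(decay) && decay <= -0.05) {
    # grossly increasing signal: overlapping peaks or artefacts
    res$class <- "excluded"
    attr(res, "reason") <- "signal increases over time"
    return(structure(res, class = "hdx_fit"))
  }
  k0 <- {
    pos <- sn > 3 * noise_sd
    if (sum(pos) >= 2) {
      fitl <- stats::lm(log(sn[pos]) ~ time_min[pos])
      max(-coef(fitl)[2], 1e-6)
    } else log(2) / stats::median(time_min)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(sn ~ A * exp(-k * time_min),
                      start = list(A = max(sn), k = k0),
                      lower = c(A = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || coef(fit)[["k"]] <= 0) {
    res$class <- "excluded"
    attr(res, "reason") <- "fit failed or non-decaying series"
    return(structure(res, class = "hdx_fit"))
  }
  res$class <- "fitted"
  res$k_obs <- coef(fit)[["k"]]
  res$amplitude <- coef(fit)[["A"]]
  res$t_half_min <- log(2) / res$k_obs
  res$residual_sd <- sd(residuals(fit))
  structure(res, class = "hdx_fit")
}

#' @export
print.hdx_fit <- function(x, ...) {
  cat("hdx_fit:", x$class)
  if (x$class == "fitted")
    cat(sprintf("  k_obs = %.4g /min, t1/2 = %.4g min", x$k_obs,
                x$t_half_min))
  else if (!is.na(x$t_half_label)) cat("  t1/2", x$t_half_label, "min")
  cat("\n")
  invisible(x)
}

#' Intrinsic exchange rate with i +/- 1 averaging
#'
#' The intrinsic rate assigned to residue `i` is the arithmetic mean of
#' the tabulated rates at positions `i-1`, `i`, `i+1` where available
#' (sequence-context tables are position-shifted by construction, so the
#' local average is the robust choice at chain termini and gaps).
#'
#' @param table data frame with columns `position`, `k_int_per_min`.
#' @param position residue position.
#' @return intrinsic rate (1/min).
#' @export
intrinsic_rate <- function(table, position) {
  vals <- table$k_int_per_min[table$position %in%
                                (position + c(-1L, 0L, 1L))]
  if (!length(vals))
    stop("no intrinsic rate tabulated near position ", position)
  mean(vals)
}

#' Exchange equilibrium constant and protection factor
#'
#' In the EX2 limit `K_ex = k_obs / k_int` and the protection factor is
#' `P = K_ex^-1 = k_int / k_obs`.
#'
#' @param k_obs observed exchange rate (1/min).
#' @param k_int intrinsic exchange rate (1/min).
#' @return list with `K_ex`, `P`, and `unprotected` (TRUE when
#'   `k_obs > k_int`, i.e. P < 1).
#' @export
protection <- function(k_obs, k_int) {
  if (k_obs <= 0 || k_int <= 0) stop("rates must be > 0")
  K_ex <- k_obs / k_int
  list(K_ex = K_ex, P = 1 / K_ex, unprotected = K_ex > 1)
}

#' Free-energy difference between open and closed amide states
#'
#' `dG_op/cl = -R T log(K_ex)`, positive for protected amides
#' (`K_ex < 1`); `R = 0.00831462` kJ/K/mol.
#'
#' @param K_ex exchange equilibrium constant (> 0).
#' @param temperature_K absolute temperature (K), default 310.
#' @return dG in kJ/mol.
#' @export
open_close_energy <- function(K_ex, temperature_K = 310) {
  if (any(K_ex <= 0)) stop("K_ex must be > 0")
  -GAS_CONSTANT_KJ * temperature_K * log(K_ex)
}

#' Analyse a full HDX decay table
#'
#' Runs [fit_decay()] per residue and, where an intrinsic-rate table is
#' given, derives `K_ex`, the protection factor and the opening free
#' energy.
#'
#' @param decays data frame with columns `residue`, `time_min`, `sn`
#'   (e.g. from [generate_hdx_table()] or read from TSV).
#' @param noise_sd noise level.
#' @param intrinsic optional data frame `position`, `k_int_per_min`;
#'   residue labels must then be coercible to integer positions.
#' @param temperature_K temperature for the free energies.
#' @param ... passed to [fit_decay()].
#' @return data frame with one row per residue: `residue`, `class`,
#'   `k_obs`, `t_half_min`, `t_half_label`, and (with intrinsic rates)
#'   `k_int`, `K_ex`, `P`, `dG_kJ_mol`.
#' @export
hdx_analyze <- function(decays, noise_sd, intrinsic = NULL,
                        temperature_K = 310, ...) {
  out <- lapply(split(decays, decays$residue), function(d) {
    d <- d[order(d$time_min), ]
    f <- fit_decay(d$time_min, d$sn, noise_sd, ...)
    row <- data.frame(residue = d$residue[1], class = f$class,
                      k_obs = f$k_obs, t_half_min = f$t_half_min,
                      t_half_label = f$t_half_label)
    if (!is.null(intrinsic) && f$class == "fitted") {
      pos <- suppressWarnings(as.integer(as.character(d$residue[1])))
      if (!is.na(pos)) {
        ki <- intrinsic_rate(intrinsic, pos)
        pr <- protection(f$k_obs, ki)
        row$k_int <- ki; row$K_ex <- pr$K_ex; row$P <- pr$P
        row$dG_kJ_mol <- open_close_energy(pr$K_ex, temperature_K)
      }
    }
    row
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(match(res$residue, unique(decays$residue))), , drop = FALSE]
}

#' Summary counts per HDX class
#'
#' @param records data frame with a `class` column (from
#'   [hdx_analyze()]), optionally a `condition` column.
#' @return data frame of counts for fast/fitted/stable/excluded (per
#'   condition when present).
#' @export
classify_dataset <- function(records) {
  classes <- c("fast", "fitted", "stable", "excluded")
  count1 <- function(df) {
    n <- vapply(classes, function(cl) sum(df$class == cl, na.rm = TRUE),
                integer(1))
    as.data.frame(as.list(n))
  }
  if (!is.null(records$condition) && nrow(records)) {
    out <- do.call(rbind, lapply(split(records, records$condition), count1))
    out <- cbind(condition = rownames(out), out)
    rownames(out) <- NULL
    out
  } else {
    if (!nrow(records))
      return(as.data.frame(as.list(setNames(rep(0L, 4), classes))))
    count1(records)
  }
}

#' Combined chemical shift perturbation
#'
#' `d_comb = sqrt(ddH^2 + (w * ddN)^2)` with the conventional nitrogen
#' weight `w = 0.14`.
#'
#' @param delta_H proton shift difference (ppm).
#' @param delta_N nitrogen shift difference (ppm).
#' @param w nitrogen weight (> 0).
#' @return combined shift (ppm), vectorized.
#' @export
csp <- function(delta_H, delta_N, w = 0.14) {
  if (w <= 0) stop("weight must be > 0")
  sqrt(delta_H^2 + (w * delta_N)^2)
}
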