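# EX2-limit H/D exchange quantitation

test_that("noiseless exponential decays are fitted exactly", {
  t <- 35 * (1:60)
  f <- fit_decay(t, 100 * exp(-0.01 * t), noise_sd = 1e-9)
  expect_equal(f$class, "fitted")
  expect_equal(f$k_obs, 0.01, tolerance = 1e-6)
  expect_equal(f$amplitude, 100, tolerance = 1e-4)
  expect_equal(f$t_half_min, log(2) / 0.01, tolerance = 1e-4)
  expect_equal(f$t_half_min, 69.31, tolerance = 1e-3)
})

test_that("half-life classification follows the dead-time and stability rules", {
  t <- 35 * (1:90)
  set.seed(1)
  # everything at the noise floor: exchanged within the dead time
  fast <- fit_decay(t, rnorm(90, 0, 2), noise_sd = 2)
  expect_equal(fast$class, "fast")
  expect_equal(fast$t_half_label, "<15")
  # flat high signal over 60 h: stable
  stable <- fit_decay(t, 100 + rnorm(90, 0, 1), noise_sd = 1)
  expect_equal(stable$class, "stable")
  expect_equal(stable$t_half_label, ">4000")
  # a gross non-decaying series with signal is excluded, not mis-fitted
  grow <- fit_decay(t[1:20], seq(50, 150, length.out = 20), noise_sd = 1)
  expect_equal(grow$class, "excluded")
})

test_that("rate recovery within 5% at SNR 50 across two decades", {
  # two decades spanning the fittable window between dead time and
  # horizon; 10 seeds per rate, 100 fits in total
  t <- 35 * (1:90)
  rates <- 10^seq(-4, -2, length.out = 10)
  set.seed(42)
  for (k in rates) {
    err <- vapply(1:10, function(r) {
      sn <- 100 * exp(-k * t) + rnorm(length(t), 0, 2)  # SNR 50
      f <- fit_decay(t, sn, noise_sd = 2)
      expect_equal(f$class, "fitted")
      abs(f$k_obs - k) / k
    }, numeric(1))
    expect_lt(mean(err), 0.05)
  }
})

test_that("intrinsic rates average over the i +/- 1 window", {
  tab <- data.frame(position = 1:10, k_int_per_min = 1:10)
  tab$k_int_per_min[4:6] <- c(2, 3, 4)
  expect_equal(intrinsic_rate(tab, 5), 3)
  # terminal residue: mean of the two available positions
  expect_equal(intrinsic_rate(tab, 1), mean(c(1, 2)))
  # uniform table returns the constant
  uni <- data.frame(position = 1:5, k_int_per_min = 7)
  expect_equal(intrinsic_rate(uni, 3), 7)
  expect_error(intrinsic_rate(tab, 100), "intrinsic")
})

test_that("protection factors and opening energies follow the EX2 identities", {
  p <- protection(0.01, 1)
  expect_equal(p$K_ex, 0.01)
  expect_equal(p$P, 100)
  expect_false(p$unprotected)
  expect_equal(protection(1, 1)$P, 1)
  expect_true(protection(2, 1)$unprotected)
  expect_equal(open_close_energy(1), 0)
  expect_equal(open_close_energy(0.01, 310),
               -0.00831462 * 310 * log(0.01), tolerance = 1e-12)
  expect_equal(open_close_energy(0.01, 310), 11.87, tolerance = 1e-3)
  expect_equal(open_close_energy(exp(-1), 310), 2.5775, tolerance = 1e-4)
  # identity: dG(protection(k, k)) = 0 for any k
  for (k in c(1e-4, 0.3, 12))
    expect_equal(open_close_energy(protection(k, k)$K_ex), 0)
  # consistency: dG = RT log(P) exactly
  pr <- protection(0.004, 0.9)
  expect_equal(open_close_energy(pr$K_ex, 310),
               0.00831462 * 310 * log(pr$P), tolerance = 1e-12)
})

test_that("dataset classification counts classes, including empty input", {
  rec <- data.frame(class = c("fast", "fast", "fast", "fitted", "fitted",
                              "stable"))
  cts <- classify_dataset(rec)
  expect_equal(unlist(cts, use.names = FALSE), c(3L, 2L, 1L, 0L))
  empty <- classify_dataset(data.frame(class = character(0)))
  expect_equal(sum(unlist(empty)), 0)
  # per-condition split
  rec2 <- rbind(cbind(rec, condition = "wt"),
                cbind(rec[1:2, , drop = FALSE], condition = "mut"))
  cc <- classify_dataset(rec2)
  expect_equal(cc$fast[cc$condition == "mut"], 2L)
})

test_that("planted classes are recovered exactly at 2% noise", {
  residues <- data.frame(
    residue = as.character(1:12),
    class = rep(c("fitted", "fast", "stable"), 4),
    k_obs = rep(c(0.005, NA, NA), 4))
  spec <- hdx_decay_spec(residues, times_min = 35 * (1:90), sn0 = 100,
                         noise_sd = 2)
  tab <- generate_hdx_table(spec, seed = 8)
  res <- hdx_analyze(tab, noise_sd = 2)
  truth <- attr(tab, "truth")
  expect_equal(res$class[match(truth$residue, res$residue)], truth$class)
  # fitted rates recovered within 5%
  fitted <- res[res$class == "fitted", ]
  expect_true(all(abs(fitted$k_obs - 0.005) / 0.005 < 0.05))
})

test_that("full analysis derives protection and energies from intrinsic rates", {
  residues <- data.frame(residue = "20", class = "fitted", k_obs = 0.01)
  spec <- hdx_decay_spec(residues, times_min = 35 * (1:60), sn0 = 100,
                         noise_sd = 1e-6)
  tab <- generate_hdx_table(spec, seed = 1)
  intr <- data.frame(position = 19:21, k_int_per_min = c(0.9, 1.0, 1.1))
  res <- hdx_analyze(tab, noise_sd = 1e-6, intrinsic = intr)
  expect_equal(res$k_int, 1.0)
  expect_equal(res$P, 100, tolerance = 1e-3)
  expect_equal(res$dG_kJ_mol, -0.00831462 * 310 * log(0.01),
               tolerance = 1e-3)
})

test_that("chemical shift perturbation combines H and N shifts", {
  expect_equal(csp(0.1, 0), 0.1)
  expect_equal(csp(0, 1, w = 0.14), 0.14)
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.3, 2, w = 0.14), sqrt(0.3^2 + 0.28^2))
  expect_error(csp(0.1, 0.1, w = -1), "weight")
})
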