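# Per-state structural observables

# small labelled ensemble straight from the generator, with a matched
# perfect decomposition: microstates == latent states
synthetic_labelled <- function(n_traj = 4, frames = 500, seed = 40,
                               detail = "backbone") {
  chain <- chain_from_populations(c(0.5, 0.35, 0.15), 20)
  arch <- default_archetypes(3, detail = detail, sigma = 0.2,
                             tau_frames = 1)
  syn <- synth_ensemble(chain, arch, n_traj, frames, seed)
  decomp <- structure(list(crisp = 1:3, n_meta = 3, active = 1:3,
                           populations = chain$pi),
                      class = "msm_pcca")
  labels <- assign_frames(decomp, syn$latent)
  list(ens = syn$ens, labels = labels, latent = syn$latent, arch = arch,
       decomp = decomp)
}

test_that("frame assignment follows the crisp map and flags pruned frames", {
  decomp <- structure(list(crisp = c(1L, 1L, 2L), n_meta = 2,
                           active = c(1L, 2L, 4L)),
                      class = "msm_pcca")
  lab <- assign_frames(decomp, list(c(1, 2, 3, 4, 1)))
  expect_equal(lab$labels[[1]], c(1L, 1L, NA, 2L, 1L))
  expect_equal(lab$unassigned_fraction, 0.2)
  # single-block toy: all frames land in the only metastable state
  d1 <- structure(list(crisp = c(1L, 1L), n_meta = 1, active = 1:2),
                  class = "msm_pcca")
  l1 <- assign_frames(d1, list(c(1, 2, 2, 1)))
  expect_true(all(unlist(l1$labels) == 1))
})

test_that("assigned label fractions match the latent populations", {
  s <- synthetic_labelled(n_traj = 6, frames = 2000, detail = "calpha")
  lab <- unlist(s$labels$labels)
  fr <- tabulate(lab, 3) / length(lab)
  ess <- 6 * 2000 / (2 * 20)
  for (k in 1:3)
    expect_lt(abs(fr[k] - c(0.5, 0.35, 0.15)[k]),
              3 * sqrt(0.5 * 0.5 / ess))
})

test_that("flip probability equals the per-state flipped fraction", {
  s <- synthetic_labelled(frames = 400)
  fp <- flip_probability(s$ens, s$labels, s$arch$flip_atoms,
                         interval = s$arch$flip_interval, n_boot = 50,
                         seed = 2)
  # archetypes: states 1,2 flipped-in, state 3 flipped-out
  expect_lt(fp$frequency[1], 0.02)
  expect_lt(fp$frequency[2], 0.02)
  expect_gt(fp$frequency[3], 0.98)
  # direct-fraction identity on a hand-made case: 16 of 100 frames flipped
  ens1 <- s$ens; lab1 <- s$labels
  ang <- msmex:::.dihedral_series(ens1$trajs[[1]], s$arch$flip_atoms)
  flipped <- ang >= s$arch$flip_interval[1] & ang <= s$arch$flip_interval[2]
  lab_t1 <- s$labels$labels[[1]]
  manual <- mean(flipped[lab_t1 == 3])
  one <- flip_probability(
    trajectory_ensemble(s$ens$top, s$ens$trajs[1], 1),
    structure(list(labels = s$labels$labels[1], n_meta = 3),
              class = "msm_labels"),
    s$arch$flip_atoms, interval = s$arch$flip_interval, n_boot = 5, seed = 1)
  expect_equal(one$frequency[3], manual)
  # all frames flipped in a state: p = 1, sd = 0
  expect_equal(fp$sd[3] <= 0.02, TRUE)
})

test_that("contact frequency equals brute-force frame enumeration", {
  s <- synthetic_labelled(frames = 250)
  pept <- data.frame(chain = "P", resno = 1:2)
  recB <- data.frame(chain = "B", resno = 1:12)
  cf <- contact_frequency(s$ens, s$labels, pept, recB, cutoff = 6,
                          n_boot = 20, seed = 3)
  # brute force for residue P1, every state
  atomsA <- msmex:::.residue_atoms(s$ens$top, pept)[[1]]
  atomsB <- unlist(msmex:::.residue_atoms(s$ens$top, recB))
  vals <- lapply(s$ens$trajs, function(arr)
    msmex:::.min_dist_series(arr, atomsA, atomsB) <= 6)
  for (st in 1:3) {
    manual <- exhaustive_state_fraction(vals, s$labels$labels, st)
    got <- cf$frequency[cf$resno == 1 & cf$chain == "P" & cf$state == st]
    expect_equal(got, manual)
  }
  expect_true(all(cf$frequency >= 0 & cf$frequency <= 1, na.rm = TRUE))
})

test_that("always/never in contact give frequencies 1 and 0", {
  lt <- line_topology(c(0, 2, 50))
  arr <- array(rep(lt$coords, each = 10), c(10, 3, 3))
  ens <- trajectory_ensemble(lt$top, list(arr), 1)
  lab <- structure(list(labels = list(rep(1L, 10)), n_meta = 1),
                   class = "msm_labels")
  near <- contact_frequency(ens, lab, data.frame(chain = "A", resno = 1),
                            data.frame(chain = "A", resno = 2),
                            cutoff = 4, n_boot = 5, seed = 1)
  expect_equal(near$frequency, 1)
  far <- contact_frequency(ens, lab, data.frame(chain = "A", resno = 1),
                           data.frame(chain = "A", resno = 3),
                           cutoff = 4, n_boot = 5, seed = 1)
  expect_equal(far$frequency, 0)
})

test_that("solvent contacts use water oxygens, or a flagged proxy without them", {
  # box with a water shell present in half the frames
  atoms <- data.frame(name = c("CA", "O", "O"), elem = c("C", "O", "O"),
                      resno = c(1, 1, 2), resname = c("GLY", "HOH", "HOH"),
                      chain = c("A", "W", "W"))
  top <- topology(atoms, chain_roles = c(A = "receptor-alpha",
                                         W = "solvent"))
  arr <- array(0, c(10, 3, 3))
  arr[, 2, 1] <- c(rep(2, 5), rep(50, 5))   # water near in frames 1..5
  arr[, 3, 1] <- 60
  ens <- trajectory_ensemble(top, list(arr), 1)
  lab <- structure(list(labels = list(rep(1L, 10)), n_meta = 1),
                   class = "msm_labels")
  sc <- solvent_contact_frequency(ens, lab,
                                  data.frame(chain = "A", resno = 1),
                                  cutoff = 3.5, n_boot = 5, seed = 1)
  expect_equal(sc$frequency, 0.5)
  expect_false(attr(sc, "proxy"))
  # no solvent: proxy path, flagged
  s <- synthetic_labelled(frames = 50)
  expect_message(
    scp <- solvent_contact_frequency(s$ens, s$labels,
                                     data.frame(chain = "P", resno = 1),
                                     n_boot = 5, seed = 1),
    "proxy")
  expect_true(attr(scp, "proxy"))
})

test_that("helicity is 1 for ideal helices, 0 for extended chains, 0.5 mixed", {
  nres <- 10
  hel <- build_backbone(nres, -57, -47)
  ext <- build_backbone(nres, 180, 180)
  atoms <- data.frame(name = hel$atoms$name, elem = substr(hel$atoms$name, 1, 1),
                      resno = hel$atoms$resno, resname = "ALA", chain = "B")
  top <- topology(atoms, chain_roles = c(B = "receptor-beta"))
  arr <- array(NA_real_, c(10, nrow(atoms), 3))
  for (t in 1:5) arr[t, , ] <- hel$coords
  for (t in 6:10) arr[t, , ] <- ext$coords
  ens <- trajectory_ensemble(top, list(arr), 1)
  lab_split <- structure(list(labels = list(c(rep(1L, 5), rep(2L, 5))),
                              n_meta = 2), class = "msm_labels")
  hp <- helicity_profile(ens, lab_split, "B", 1, 6)
  expect_true(all(hp$helicity[hp$state == 1] == 1))
  expect_true(all(hp$helicity[hp$state == 2] == 0))
  lab_all <- structure(list(labels = list(rep(1L, 10)), n_meta = 1),
                       class = "msm_labels")
  hm <- helicity_profile(ens, lab_all, "B", 1, 6)
  expect_true(all(hm$helicity == 0.5))
  expect_warning(helicity_profile(ens, lab_all, "B", 1, 10), "truncated")
})

test_that("bootstrap sd shrinks with the number of trajectories", {
  sd_for <- function(n_traj) {
    s <- synthetic_labelled(n_traj = n_traj, frames = 300, seed = 77,
                            detail = "calpha")
    pept <- data.frame(chain = "P", resno = 1)
    cf <- contact_frequency(s$ens, s$labels, pept,
                            data.frame(chain = "B", resno = 1:12),
                            cutoff = 8, n_boot = 60, seed = 5)
    mean(cf$sd, na.rm = TRUE)
  }
  expect_gt(sd_for(4), sd_for(16))
})
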