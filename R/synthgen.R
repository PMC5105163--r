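# Synthetic trajectory and HDX-decay generator.  A hidden metastable Markov
# chain with user-set stationary populations drives state-dependent
# structural archetypes (helix fold, side-chain flip, peptide contacts)
# plus time-correlated Gaussian positional noise, so that every downstream
# estimator can be validated against analytic ground truth.

#' Latent metastable Markov chain
#'
#' @param P row-stochastic transition matrix at the frame interval.
#' @param dt_ns frame interval (ns).
#' @return Object of class `msm_latent_chain` with elements `P`, `pi`
#'   (stationary distribution), `dt_ns`, `timescales_frames` (relaxation
#'   times `-1/log |lambda_i|`, slowest first, excluding the stationary
#'   eigenvalue).
#' @export
latent_chain <- function(P, dt_ns = 1) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-10))
    stop("P must be row-stochastic")
  if (n > 1) {
    comp <- .strong_components(P > 0)
    if (length(unique(comp)) != 1) stop("chain is reducible")
  }
  e <- eigen(t(P))
  i1 <- which.min(abs(e$values - 1))
  pi <- Re(e$vectors[, i1]); pi <- pi / sum(pi)
  if (any(pi <= 0)) stop("stationary distribution not strictly positive")
  lam <- sort(abs(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
  ts <- if (n > 1) -1 / log(pmin(lam[-1], 1 - 1e-15)) else numeric(0)
  structure(list(P = P, pi = pi, dt_ns = dt_ns,
                 timescales_frames = ts),
            class = "msm_latent_chain")
}

#' Design a detailed-balance chain from target populations
#'
#' Builds the transition matrix `T = (1-a) I + a 1 pi'`, which has the
#' requested stationary distribution exactly, satisfies detailed balance,
#' and relaxes with a single timescale: all non-stationary eigenvalues
#' equal `1-a = exp(-1/t_ex)`.  This makes rare-state targets such as a
#' 1-2% population plantable with analytic ground truth.
#'
#' @param populations strictly positive probability vector (sums to 1).
#' @param exchange_frames slowest relaxation time in frames (>= 1).
#' @param dt_ns frame interval (ns).
#' @return `msm_latent_chain`.
#' @export
chain_from_populations <- function(populations, exchange_frames, dt_ns = 1) {
  p <- populations
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-9)
    stop("populations must be > 0 and sum to 1")
  n <- length(p)
  if (n == 1) return(latent_chain(matrix(1, 1, 1), dt_ns))
  if (exchange_frames < 1) stop("exchange time must be >= 1 frame")
  a <- 1 - exp(-1 / exchange_frames)
  P <- (1 - a) * diag(n) + a * matrix(p, n, n, byrow = TRUE)
  latent_chain(P, dt_ns)
}

#' Sample a latent state path
#'
#' The first state is drawn from the stationary distribution; subsequent
#' states follow the transition matrix.  Bit-reproducible for a fixed seed.
#'
#' @param chain `msm_latent_chain`.
#' @param n_frames path length (>= 2).
#' @param seed integer seed.
#' @return integer vector of state indices (1-based).
#' @export
sample_latent_path <- function(chain, n_frames, seed) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  set.seed(seed)
  n <- nrow(chain$P)
  cum <- t(apply(chain$P, 1, cumsum))
  s <- integer(n_frames)
  u <- runif(n_frames)
  s[1] <- findInterval(u[1], cumsum(chain$pi)) + 1L
  if (n == 1) return(rep(1L, n_frames))
  for (t in 2:n_frames)
    s[t] <- findInterval(u[t], cum[s[t - 1], ]) + 1L
  s
}

# -- archetypes ---------------------------------------------------------

.offset <- function(coords, v) sweep(coords, 2, v, "+")

#' Structural archetypes for the synthetic pseudo-protein
#'
#' Builds one reference structure per latent state.  The pseudo-protein has
#' a receptor alpha chain (A) carrying a side-chain "flip" reporter
#' dihedral (N-CA-CB-CG of residue A3), a receptor beta chain (B) whose
#' C-terminal half is an alpha-helix that unfolds in the last state, and a
#' short peptide chain (P) that partially dissociates in the last state.
#' State 1 is the folded, bound, flipped-in ground state; intermediate
#' states shift the peptide; the last state unfolds the helix, flips the
#' reporter out and displaces the peptide.
#'
#' @param n_states number of latent states (2 or 3).
#' @param detail `"backbone"` (N/CA/C/O atoms plus the flip side chain;
#'   needed for helicity and flip observables) or `"calpha"` (C-alpha
#'   trace only; lean, for large-scale estimator tests).
#' @param sigma positional noise standard deviation (Angstrom).
#' @param tau_frames autocorrelation time of the emission noise (frames);
#'   0 gives white noise.
#' @return Object of class `msm_archetypes`: list with `top`
#'   (`msm_topology`), `coords` (list of `natom x 3` matrices, one per
#'   state), `sigma`, `tau_frames`, `flip` (logical per state),
#'   `flip_atoms` (4 atom indices, `"backbone"` only), `flip_interval`
#'   (dihedral interval in degrees counted as flipped-out), `helix`
#'   (chain/residue range of the fold reporter).
#' @export
default_archetypes <- function(n_states = 3,
                               detail = c("backbone", "calpha"),
                               sigma = 0.25, tau_frames = 2) {
  detail <- match.arg(detail)
  if (!n_states %in% 2:3) stop("n_states must be 2 or 3")
  if (sigma <= 0) stop("sigma must be > 0")

  nA <- 8; nB <- 12; nP <- 4
  helixB <- build_backbone(nB, phi = -57, psi = -47)
  # unfolded variant: residues 6..12 extended
  unf <- build_backbone(nB, phi = c(rep(-57, 5), rep(-150, nB - 5)),
                        psi = c(rep(-47, 5), rep(150, nB - 5)))
  chainA <- build_backbone(nA, phi = -57, psi = -47)
  pept <- build_backbone(nP, phi = -120, psi = 120)

  assemble <- function(helix_folded, flip_out, pept_shift) {
    b <- if (helix_folded) helixB else unf
    partsA <- chainA$coords
    atomsA <- data.frame(name = chainA$atoms$name, elem = substr(chainA$atoms$name, 1, 1),
                         resno = chainA$atoms$resno, resname = "ALA", chain = "A")
    if (detail == "backbone") {
      # flip reporter side chain on residue A3: CB + CG with chi1
      i <- function(nm) which(chainA$atoms$resno == 3 & chainA$atoms$name == nm)
      N <- chainA$coords[i("N"), ]; CA <- chainA$coords[i("CA"), ]
      C <- chainA$coords[i("C"), ]
      # elongated reporter arm: small positional noise then maps to small
      # dihedral noise, so the flip state is read off reliably
      CB <- .place_atom(C, N, CA, 2.0, 110.5, -122)
      chi1 <- if (flip_out) 90 else -90
      CG <- .place_atom(N, CA, CB, 2.5, 114, chi1)
      partsA <- rbind(partsA, CB, CG)
      atomsA <- rbind(atomsA,
                      data.frame(name = c("CB", "CG"), elem = "C", resno = 3,
                                 resname = "ALA", chain = "A"))
      ord <- order(atomsA$resno)           # stable: side chain after backbone
      partsA <- partsA[ord, , drop = FALSE]
      atomsA <- atomsA[ord, , drop = FALSE]
    }
    coords <- rbind(partsA,
                    .offset(b$coords, c(14, 0, 0)),
                    .offset(pept$coords, c(7, 7, 0) + pept_shift))
    atoms <- rbind(atomsA,
                   data.frame(name = b$atoms$name,
                              elem = substr(b$atoms$name, 1, 1),
                              resno = b$atoms$resno, resname = "ALA",
                              chain = "B"),
                   data.frame(name = pept$atoms$name,
                              elem = substr(pept$atoms$name, 1, 1),
                              resno = pept$atoms$resno, resname = "ALA",
                              chain = "P"))
    if (detail == "calpha") {
      keep <- atoms$name == "CA"
      coords <- coords[keep, , drop = FALSE]
      atoms <- atoms[keep, , drop = FALSE]
    }
    rownames(atoms) <- NULL
    list(coords = coords, atoms = atoms)
  }

  # reorder atoms so the flip side chain comes last in chain A residue 3?
  # keep assembly order identical across states (same atoms data frame).
  states <- list()
  flips <- logical(n_states)
  for (s in seq_len(n_states)) {
    if (s < n_states) {
      states[[s]] <- assemble(helix_folded = TRUE, flip_out = FALSE,
                              pept_shift = c(0, 1.5, 0) * (s - 1))
      flips[s] <- FALSE
    } else {
      states[[s]] <- assemble(helix_folded = FALSE, flip_out = TRUE,
                              pept_shift = c(0, 5, 0))
      flips[s] <- TRUE
    }
  }
  atoms <- states[[1]]$atoms
  top <- topology(atoms,
                  chain_roles = c(A = "receptor-alpha", B = "receptor-beta",
                                  P = "peptide"))
  flip_atoms <- if (detail == "backbone") {
    a <- top$atoms
    c(which(a$chain == "A" & a$resno == 3 & a$name == "N"),
      which(a$chain == "A" & a$resno == 3 & a$name == "CA"),
      which(a$chain == "A" & a$resno == 3 & a$name == "CB"),
      which(a$chain == "A" & a$resno == 3 & a$name == "CG"))
  } else NULL
  structure(list(top = top,
                 coords = lapply(states, `[[`, "coords"),
                 sigma = sigma, tau_frames = tau_frames,
                 flip = flips, flip_atoms = flip_atoms,
                 flip_interval = c(0, 180),
                 helix = list(chain = "B", from = 6, to = 12)),
            class = "msm_archetypes")
}

#' Emit structures along a latent state path
#'
#' Frame `t` equals the archetype of `state[t]` plus first-order
#' autoregressive Gaussian displacement (per atom and coordinate
#' independent, stationary sd `sigma`, lag-1 correlation
#' `exp(-1/tau_frames)`).
#'
#' @param path integer state path (from [sample_latent_path()]).
#' @param arch `msm_archetypes`.
#' @param seed integer seed.
#' @param dt_ns frame interval (ns).
#' @param condition condition id for the resulting ensemble.
#' @return `msm_ensemble` with one trajectory; the latent path is attached
#'   as attribute `"latent"`.
#' @export
emit_structures <- function(path, arch, seed, dt_ns = 1,
                            condition = "synthetic") {
  ns <- length(arch$coords)
  if (any(path < 1 | path > ns)) stop("path contains unknown states")
  natom <- nrow(arch$coords[[1]])
  if (any(vapply(arch$coords, nrow, 1L) != natom))
    stop("archetypes disagree in atom count")
  nf <- length(path)
  set.seed(seed)
  a <- if (arch$tau_frames > 0) exp(-1 / arch$tau_frames) else 0
  burn <- if (a > 0) ceiling(10 * arch$tau_frames) else 0
  z <- matrix(rnorm((nf + burn) * natom * 3), nf + burn, natom * 3)
  if (a > 0) {
    e <- stats::filter(z * sqrt(1 - a^2), a, method = "recursive")
    e <- unclass(e)[(burn + 1):(burn + nf), , drop = FALSE]
  } else {
    e <- z
  }
  e <- e * arch$sigma
  arr <- array(NA_real_, c(nf, natom, 3))
  for (s in unique(path)) {
    idx <- which(path == s)
    base <- arch$coords[[s]]
    for (d in 1:3)
      arr[idx, , d] <- matrix(base[, d], length(idx), natom, byrow = TRUE) +
        e[idx, ((d - 1) * natom + 1):(d * natom)]
  }
  ens <- trajectory_ensemble(arch$top, list(arr), dt_ns, condition)
  attr(ens, "latent") <- path
  ens
}

#' Generate a multi-trajectory synthetic ensemble with ground truth
#'
#' Samples `n_traj` independent latent paths from the chain and emits
#' structures for each.
#'
#' @param chain `msm_latent_chain`.
#' @param arch `msm_archetypes`.
#' @param n_traj number of trajectories.
#' @param traj_frames frames per trajectory.
#' @param seed integer seed (per-trajectory seeds are derived from it).
#' @param condition condition id.
#' @return list with `ens` (`msm_ensemble`) and `latent` (list of integer
#'   paths, the ground truth).
#' @export
synth_ensemble <- function(chain, arch, n_traj, traj_frames, seed,
                           condition = "synthetic") {
  seeds <- seed + seq_len(n_traj) * 1000L
  trajs <- vector("list", n_traj)
  latent <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    p <- sample_latent_path(chain, traj_frames, seeds[i])
    ei <- emit_structures(p, arch, seeds[i] + 1L, dt_ns = chain$dt_ns,
                          condition = condition)
    trajs[[i]] <- ei$trajs[[1]]
    latent[[i]] <- p
  }
  list(ens = trajectory_ensemble(arch$top, trajs, chain$dt_ns, condition),
       latent = latent)
}

# -- HDX decay tables ---------------------------------------------------

#' Specification of synthetic HDX decay curves
#'
#' @param residues data frame with columns `residue` (label), `class`
#'   (`"fitted"`, `"fast"` or `"stable"`), and `k_obs` (1/min; used for
#'   class `"fitted"`, ignored otherwise).
#' @param times_min increasing acquisition time grid in minutes; defaults
#'   to 90 experiments of ~35 min starting after the dead time.
#' @param sn0 initial signal-to-noise.
#' @param noise_sd additive noise standard deviation (same units as S/N).
#' @param dead_min spectrometer dead time (min).
#' @param horizon_min last usable time point (min).
#' @return Object of class `msm_hdx_spec`.
#' @export
hdx_decay_spec <- function(residues, times_min = 35 * (1:90), sn0 = 100,
                           noise_sd = 2, dead_min = 35, horizon_min = 3600) {
  if (is.unsorted(times_min, strictly = TRUE)) stop("time grid must increase")
  if (times_min[1] < dead_min)
    stop("first time point must be >= dead time")
  stopifnot(all(residues$class %in% c("fitted", "fast", "stable")))
  structure(list(residues = residues, times_min = times_min, sn0 = sn0,
                 noise_sd = noise_sd, dead_min = dead_min,
                 horizon_min = horizon_min),
            class = "msm_hdx_spec")
}

#' Generate synthetic HDX decay tables
#'
#' Emits `S/N(t) = S/N(0) exp(-k_obs t) + noise` per residue.  `"fast"`
#' residues exchange within the dead time and are emitted at the noise
#' floor from the first point; `"stable"` residues decay by less than 5%
#' over the horizon.
#'
#' @param spec `msm_hdx_spec`.
#' @param seed integer seed.
#' @return data frame with columns `residue`, `time_min`, `sn`; the true
#'   per-residue class and rate are attached as attribute `"truth"`.
#' @export
generate_hdx_table <- function(spec, seed) {
  set.seed(seed)
  t <- spec$times_min
  k_stable <- -log(0.98) / max(t)   # 2% decay over the grid, safely < 5%
  out <- vector("list", nrow(spec$residues))
  truth <- spec$residues
  truth$k_true <- NA_real_
  for (i in seq_len(nrow(spec$residues))) {
    cls <- spec$residues$class[i]
    mu <- switch(cls,
      fast = rep(0, length(t)),
      stable = spec$sn0 * exp(-k_stable * t),
      fitted = spec$sn0 * exp(-spec$residues$k_obs[i] * t))
    truth$k_true[i] <- switch(cls, fast = NA_real_, stable = k_stable,
                              fitted = spec$residues$k_obs[i])
    out[[i]] <- data.frame(residue = spec$residues$residue[i],
                           time_min = t,
                           sn = mu + rnorm(length(t), sd = spec$noise_sd))
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- truth
  res
}
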