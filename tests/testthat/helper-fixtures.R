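# Shared fixtures and independent oracles, all built in code.

# 3-residue toy PDB (24 atoms: 8 atoms x 3 residues over chains A, B, C)
toy_pdb_file <- function(path = tempfile(fileext = ".pdb")) {
  atom_line <- function(serial, name, resname, chain, resno, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, substr(paste0(" ", name), 1, 4), resname, chain, resno,
            x, y, z, elem)
  }
  lines <- character(0)
  serial <- 0
  names <- c("N", "CA", "C", "O", "CB", "CG", "CD", "NE")
  elems <- c("N", "C", "C", "O", "C", "C", "C", "N")
  for (r in 1:3) {
    ch <- c("A", "B", "C")[r]
    for (k in 1:8) {
      serial <- serial + 1
      lines <- c(lines, atom_line(serial, names[k], "ARG", ch, r,
                                  r * 10 + k * 0.5, r * 2, k * 0.3,
                                  elems[k]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# linear chain of CA-only residues on chain A at given x positions
line_topology <- function(x_positions) {
  n <- length(x_positions)
  top <- topology(data.frame(name = "CA", elem = "C",
                             resno = seq_len(n), resname = "GLY",
                             chain = "A"),
                  chain_roles = c(A = "receptor-alpha"))
  coords <- cbind(x_positions, 0, 0)
  list(top = top, coords = coords)
}

# the published residue selection: alpha H5-A10, M23-D27, E30-F32,
# F48-E55 (not R50), beta R13-L27 (not N19), beta R71-R93 (not R72, N82)
published_selection <- function() {
  selection_from_ranges(
    data.frame(chain = c("A", "A", "A", "A", "B", "B"),
               from = c(5, 23, 30, 48, 13, 71),
               to = c(10, 27, 32, 55, 27, 93)),
    exclude = data.frame(chain = c("A", "B", "B", "B"),
                         resno = c(50, 19, 72, 82)))
}

# independent reversible-MLE oracle: numerical likelihood maximization
# over the upper triangle of the symmetric edge-weight matrix (log
# parametrization, analytic gradient, BFGS).
reversible_mle_oracle <- function(C) {
  n <- nrow(C)
  ut <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  ci <- rowSums(C)
  Csym <- C + t(C)
  unpack <- function(theta) {
    x <- matrix(0, n, n)
    x[ut] <- exp(theta)
    x <- x + t(x) - diag(diag(x))
    x
  }
  negll <- function(theta) {
    x <- unpack(theta)
    xi <- rowSums(x)
    -(sum(C[C > 0] * log(x[C > 0])) - sum(ci * log(xi)))
  }
  grad <- function(theta) {
    x <- unpack(theta)
    xi <- rowSums(x)
    G <- Csym / pmax(x, 1e-300) - outer(ci / xi, ci / xi, "+")
    diag(G) <- diag(C) / pmax(diag(x), 1e-300) - ci / xi
    -(G[ut] * x[ut])           # chain rule for log parametrization
  }
  init <- log(pmax(Csym[ut] / sum(Csym), 1e-8))
  opt <- stats::optim(init, negll, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  x <- unpack(opt$par)
  Tm <- x / rowSums(x)
  list(T = Tm, pi = rowSums(x) / sum(x), value = -opt$value)
}

# exhaustive state-conditional presence fraction (brute-force oracle)
exhaustive_state_fraction <- function(values, labels, state) {
  v <- unlist(values); l <- unlist(labels)
  mean(v[!is.na(l) & l == state])
}

# random connected count matrix on n states
random_count_matrix <- function(n, seed) {
  set.seed(seed)
  C <- matrix(rpois(n * n, lambda = 8), n, n) + 1  # +1 ensures connectivity
  C
}

# central finite-difference gradient of a scalar coordinate function
fd_gradient <- function(f, coords, h = 1e-5) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) for (d in 1:3) {
    cp <- coords; cp[i, d] <- cp[i, d] + h
    cm <- coords; cm[i, d] <- cm[i, d] - h
    g[i, d] <- (f(cp) - f(cm)) / (2 * h)
  }
  g
}

# toy ensemble where one atom pair is within the cutoff in a set fraction
# of the frames of each latent state
pia_toy <- function(frac_by_state = c(0.7, 0.2), frames = 1000,
                    n_traj = 1, seed = 1) {
  lt <- line_topology(c(0, 3, 30))
  set.seed(seed)
  trajs <- list(); dtrajs <- list()
  for (tr in seq_len(n_traj)) {
    st <- sample(seq_along(frac_by_state), frames, replace = TRUE)
    arr <- array(0, c(frames, 3, 3))
    arr[, 2, 1] <- ifelse(runif(frames) < frac_by_state[st], 3, 10)
    arr[, 3, 1] <- 30
    trajs[[tr]] <- arr
    dtrajs[[tr]] <- st
  }
  ens <- trajectory_ensemble(lt$top, trajs, 1)
  decomp <- structure(list(crisp = seq_along(frac_by_state),
                           n_meta = length(frac_by_state),
                           active = seq_along(frac_by_state)),
                      class = "msm_pcca")
  list(ens = ens, dtrajs = dtrajs, decomp = decomp)
}
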