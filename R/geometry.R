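# Internal-coordinate geometry: atom placement from bond length/angle/
# torsion (NeRF), dihedral measurement, and an ideal peptide-backbone
# builder used by the synthetic generator and by the helicity tests.

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom).
#' @return signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D given atoms A-B-C, bond length |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg).
.place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal-geometry backbone builder: one row per atom, atoms N, CA, C, O per
# residue, chain built from per-residue (phi, psi) with omega = 180.
# Standard bond lengths/angles: N-CA 1.458, CA-C 1.525, C-N 1.329, C-O
# 1.231 A; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.5.
# Returns list(coords = (4*nres) x 3, atoms = data.frame(name, resno)).
.build_backbone <- function(phi, psi) {
  nres <- length(phi)
  stopifnot(length(psi) == nres)
  coords <- matrix(NA_real_, 4 * nres, 3)
  atoms <- data.frame(name = rep(c("N", "CA", "C", "O"), nres),
                      resno = rep(seq_len(nres), each = 4))
  idx <- function(i, nm) (i - 1) * 4 + match(nm, c("N", "CA", "C", "O"))
  # seed first residue
  coords[idx(1, "N"), ] <- c(0, 0, 0)
  coords[idx(1, "CA"), ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  coords[idx(1, "C"), ] <- coords[idx(1, "CA"), ] +
    1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(nres)) {
    N <- coords[idx(i, "N"), ]; CA <- coords[idx(i, "CA"), ]
    C <- coords[idx(i, "C"), ]
    if (i < nres) {
      Nn <- .place_atom(N, CA, C, 1.329, 116.2, psi[i])
      coords[idx(i + 1, "N"), ] <- Nn
      CAn <- .place_atom(CA, C, Nn, 1.458, 121.7, 180)   # omega = 180
      coords[idx(i + 1, "CA"), ] <- CAn
      coords[idx(i + 1, "C"), ] <- .place_atom(C, Nn, CAn, 1.525, 111.2,
                                               phi[i + 1])
      # carbonyl O in the peptide plane, anti to the next N
      coords[idx(i, "O"), ] <- .place_atom(Nn, CA, C, 1.231, 120.5, 180)
    } else {
      # terminal O: plane defined by N, CA, C with psi-like torsion
      coords[idx(i, "O"), ] <- .place_atom(N, CA, C, 1.231, 120.5,
                                           psi[i] + 180)
    }
  }
  list(coords = coords, atoms = atoms)
}

#' Build an ideal peptide backbone
#'
#' Constructs N/CA/C/O coordinates for a chain with the given backbone
#' dihedrals and ideal bond geometry.  `phi[1]` is unused (no preceding
#' residue).  An ideal alpha-helix is `phi = -57`, `psi = -47`; a fully
#' extended chain is `phi = psi = 180`.
#'
#' @param nres number of residues.
#' @param phi,psi backbone dihedrals in degrees, recycled to `nres`.
#' @return list with `coords` (`4*nres x 3` matrix, Angstrom) and `atoms`
#'   (data frame `name`, `resno`).
#' @export
build_backbone <- function(nres, phi = -57, psi = -47) {
  .build_backbone(rep_len(phi, nres), rep_len(psi, nres))
}
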