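#' @importFrom stats rnorm runif sd quantile setNames var aggregate
#' @importFrom utils read.delim write.table head tail
NULL

# Standard atomic masses (amu) for the elements that occur in protein/solvent
# topologies.  Unknown elements fall back to carbon with a warning.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, NA. = 22.990, CL = 35.45, K = 39.098,
  MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845
)

.chain_roles <- c("receptor-alpha", "receptor-beta", "peptide", "solvent", "other")

#' Molecular topology
#'
#' An atom table plus a mapping of chain identifiers to biological roles
#' (receptor alpha chain, receptor beta chain, peptide, solvent, other).
#' Residue labels follow the convention used for MHC class II work, e.g.
#' residue 82 of the receptor beta chain is "beta-N82".
#'
#' @param atoms data frame with columns `name`, `elem`, `resno` (1-based),
#'   `resname`, `chain`, and optionally `mass`; heavy-atom flags and missing
#'   masses are derived from the element.
#' @param chain_roles named character vector mapping chain id to one of
#'   `"receptor-alpha"`, `"receptor-beta"`, `"peptide"`, `"solvent"`,
#'   `"other"`. Chains not named here get role `"other"`.
#' @return An object of class `msm_topology`: a list with elements `atoms`
#'   (data frame, plus `heavy` and `mass` columns) and `chain_roles`.
#' @export
topology <- function(atoms, chain_roles = NULL) {
  req <- c("name", "elem", "resno", "resname", "chain")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  atoms$name <- as.character(atoms$name)
  atoms$elem <- toupper(as.character(atoms$elem))
  atoms$chain <- as.character(atoms$chain)
  # one chain per atom, residue numbers ordered within each chain
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn))
      stop("residue numbers not ordered within chain ", ch)
  }
  dup <- duplicated(atoms[, c("chain", "resno", "name")])
  if (any(dup))
    stop("duplicate atom within residue: ",
         paste(atoms$name[dup][1], atoms$resno[dup][1], sep = "/"))
  if (is.null(atoms$mass)) {
    m <- .element_masses[atoms$elem]
    if (anyNA(m)) {
      warning("unknown element(s) ",
              paste(unique(atoms$elem[is.na(m)]), collapse = ","),
              "; assigning carbon mass")
      m[is.na(m)] <- .element_masses[["C"]]
    }
    atoms$mass <- unname(m)
  }
  if (any(atoms$mass <= 0)) stop("atom masses must be > 0")
  atoms$heavy <- atoms$elem != "H"
  roles <- setNames(rep("other", length(unique(atoms$chain))),
                    unique(atoms$chain))
  if (!is.null(chain_roles)) {
    bad <- setdiff(chain_roles, .chain_roles)
    if (length(bad)) stop("unknown chain role(s): ", paste(bad, collapse = ","))
    roles[names(chain_roles)] <- chain_roles
  }
  structure(list(atoms = atoms, chain_roles = roles),
            class = "msm_topology")
}

#' @export
print.msm_topology <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno")]))
  cat("msm_topology:", nrow(x$atoms), "atoms,", nres, "residues,",
      length(x$chain_roles), "chain(s)\n")
  for (ch in names(x$chain_roles))
    cat("  chain", ch, "->", x$chain_roles[[ch]], "\n")
  invisible(x)
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) and assigns chain roles from the
#' supplied mapping; roles are configuration, never guessed from chain
#' letters.
#'
#' @param path PDB file.
#' @param chain_roles named character vector, chain id -> role (see
#'   [topology()]).
#' @return `msm_topology`.
#' @export
read_topology <- function(path, chain_roles = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <- substr(trimws(a$elety[is.na(elem) | elem == ""]), 1, 1)
  topology(data.frame(name = trimws(a$elety), elem = trimws(elem),
                      resno = a$resno, resname = trimws(a$resid),
                      chain = ifelse(is.na(a$chain), " ", a$chain),
                      stringsAsFactors = FALSE),
           chain_roles = chain_roles)
}

#' Trajectory ensemble
#'
#' One or more coordinate trajectories sharing a topology under a named
#' simulation condition (e.g. wild type vs a point mutant).
#'
#' @param top `msm_topology`.
#' @param trajs list of coordinate arrays, each `frames x atoms x 3` in
#'   Angstrom.
#' @param dt_ns frame interval in nanoseconds (> 0).
#' @param condition condition identifier.
#' @return Object of class `msm_ensemble`.
#' @export
trajectory_ensemble <- function(top, trajs, dt_ns, condition = "default") {
  stopifnot(inherits(top, "msm_topology"))
  if (!is.list(trajs)) trajs <- list(trajs)
  if (!(is.numeric(dt_ns) && length(dt_ns) == 1 && dt_ns > 0))
    stop("frame interval must be a single value > 0 ns")
  natom <- nrow(top$atoms)
  for (i in seq_along(trajs)) {
    x <- trajs[[i]]
    if (length(dim(x)) != 3 || dim(x)[3] != 3)
      stop("trajectory ", i, " must be a frames x atoms x 3 array")
    if (dim(x)[2] != natom)
      stop("trajectory ", i, ": expected ", natom, " atoms, found ", dim(x)[2])
    if (dim(x)[1] < 2)
      stop("trajectory ", i, " has fewer than 2 frames")
  }
  structure(list(top = top, trajs = trajs, dt_ns = dt_ns,
                 condition = condition),
            class = "msm_ensemble")
}

#' @export
print.msm_ensemble <- function(x, ...) {
  nf <- vapply(x$trajs, function(t) dim(t)[1], integer(1))
  cat("msm_ensemble [", x$condition, "]: ", length(x$trajs),
      " trajectories, ", sum(nf), " frames total, dt = ", x$dt_ns,
      " ns\n", sep = "")
  invisible(x)
}

#' Total number of frames in an ensemble
#' @param ens `msm_ensemble`.
#' @return integer frame count summed over trajectories.
#' @export
n_frames <- function(ens) {
  sum(vapply(ens$trajs, function(t) dim(t)[1], integer(1)))
}

.xyz_to_array <- function(xyz, natom) {
  xyz <- as.matrix(xyz)
  nf <- nrow(xyz)
  if (ncol(xyz) != 3 * natom)
    stop("frame atom count mismatch: expected ", natom,
         " atoms, found ", ncol(xyz) / 3)
  arr <- array(NA_real_, c(nf, natom, 3))
  arr[, , 1] <- xyz[, seq(1, 3 * natom, by = 3)]
  arr[, , 2] <- xyz[, seq(2, 3 * natom, by = 3)]
  arr[, , 3] <- xyz[, seq(3, 3 * natom, by = 3)]
  arr
}

.array_to_xyz <- function(arr) {
  nf <- dim(arr)[1]; natom <- dim(arr)[2]
  xyz <- matrix(NA_real_, nf, 3 * natom)
  xyz[, seq(1, 3 * natom, by = 3)] <- arr[, , 1]
  xyz[, seq(2, 3 * natom, by = 3)] <- arr[, , 2]
  xyz[, seq(3, 3 * natom, by = 3)] <- arr[, , 3]
  xyz
}

#' Read trajectory coordinates
#'
#' Reads one or more multi-model PDB or DCD files into an ensemble under a
#' single condition.  Units are Angstrom throughout; frames keep file order.
#' XTC is not supported.
#'
#' @param top `msm_topology`; frame atom counts must match.
#' @param paths character vector of files.
#' @param dt_ns frame interval in nanoseconds.
#' @param condition condition id.
#' @return `msm_ensemble` with one trajectory per file.
#' @export
read_trajectory <- function(top, paths, dt_ns, condition = "default") {
  natom <- nrow(top$atoms)
  trajs <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    xyz <- if (ext == "dcd") {
      bio3d::read.dcd(p, verbose = FALSE)
    } else if (ext %in% c("pdb", "ent")) {
      bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz
    } else {
      stop("unsupported trajectory format '", ext, "' (PDB or DCD)")
    }
    .xyz_to_array(xyz, natom)
  })
  trajectory_ensemble(top, trajs, dt_ns, condition)
}

#' Write an ensemble as multi-model PDB files
#'
#' One file per trajectory (suffix `_<i>` when several). Coordinates are
#' written at PDB precision (1e-3 Angstrom).
#'
#' @param ens `msm_ensemble`.
#' @param path output file name; for multiple trajectories the index is
#'   inserted before the extension.
#' @return invisibly, the vector of files written.
#' @export
write_trajectory <- function(ens, path) {
  a <- ens$top$atoms
  nt <- length(ens$trajs)
  files <- character(nt)
  for (i in seq_len(nt)) {
    f <- if (nt == 1) path else {
      root <- tools::file_path_sans_ext(path)
      paste0(root, "_", i, ".", tools::file_ext(path))
    }
    bio3d::write.pdb(file = f, xyz = .array_to_xyz(ens$trajs[[i]]),
                     type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resname,
                     chain = a$chain, elety = a$name,
                     elesy = a$elem)
    files[i] <- f
  }
  invisible(files)
}

.resolve_residue <- function(top, chain, resno) {
  idx <- which(top$atoms$chain == chain & top$atoms$resno == resno)
  if (!length(idx)) stop("residue ", chain, "/", resno, " not in topology")
  idx
}

.ca_index <- function(top, chain, resno) {
  idx <- .resolve_residue(top, chain, resno)
  ca <- idx[top$atoms$name[idx] == "CA"]
  if (!length(ca)) stop("residue ", chain, "/", resno, " lacks a CA atom")
  ca[1]
}

#' Select residues within a distance cutoff of a center residue
#'
#' A residue is included iff its C-alpha lies within `cutoff` Angstrom of
#' the center residue's C-alpha in the given reference frame.  Explicit
#' include/exclude overrides are applied afterwards, so a published residue
#' list can be reproduced exactly.
#'
#' @param top `msm_topology`.
#' @param coords one frame, `atoms x 3` matrix (Angstrom).
#' @param center list/vector `c(chain=, resno=)` identifying the center
#'   residue.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param include,exclude optional data frames with columns `chain`,
#'   `resno` forced in/out after the distance rule.
#' @return Object of class `msm_selection`: data frame of (`chain`,
#'   `resno`) ordered as in the topology, with the provenance stored in
#'   attributes.
#' @export
select_within <- function(top, coords, center, cutoff,
                          include = NULL, exclude = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  center <- as.list(center)
  cca <- .ca_index(top, center$chain, as.integer(center$resno))
  res <- unique(top$atoms[top$atoms$heavy, c("chain", "resno")])
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ca <- tryCatch(.ca_index(top, res$chain[i], res$resno[i]),
                   error = function(e) NA_integer_)
    if (is.na(ca)) next
    keep[i] <- sqrt(sum((coords[ca, ] - coords[cca, ])^2)) <= cutoff
  }
  sel <- res[keep, , drop = FALSE]
  key <- function(d) paste(d$chain, d$resno)
  if (!is.null(include))
    sel <- rbind(sel, include[!key(include) %in% key(sel), c("chain", "resno")])
  if (!is.null(exclude))
    sel <- sel[!key(sel) %in% key(exclude), , drop = FALSE]
  # restore topology order, drop duplicates
  sel <- sel[!duplicated(key(sel)), , drop = FALSE]
  ord <- match(key(sel), key(res))
  sel <- sel[order(ord), , drop = FALSE]
  rownames(sel) <- NULL
  structure(sel, class = c("msm_selection", "data.frame"),
            center = center, cutoff = cutoff)
}

#' Build a residue selection from explicit ranges
#'
#' Convenience for encoding published residue lists such as
#' "alpha H5-A10, ..., beta R71-R93 excluding R72 and N82".
#'
#' @param ranges data frame with columns `chain`, `from`, `to` (inclusive
#'   residue-number ranges).
#' @param exclude optional data frame with columns `chain`, `resno`.
#' @return `msm_selection` (no topology check is performed here).
#' @export
selection_from_ranges <- function(ranges, exclude = NULL) {
  sel <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(i)
    data.frame(chain = ranges$chain[i],
               resno = seq(ranges$from[i], ranges$to[i]))))
  if (!is.null(exclude)) {
    key <- function(d) paste(d$chain, d$resno)
    sel <- sel[!key(sel) %in% key(exclude), , drop = FALSE]
  }
  rownames(sel) <- NULL
  structure(sel, class = c("msm_selection", "data.frame"),
            center = NULL, cutoff = NULL)
}

#' Run configuration
#'
#' Bundles the stage parameters of a full analysis run so that every output
#' can record them.  Temperature defaults to 310 K, the condition of the
#' underlying NMR experiments.
#'
#' @param seed integer random seed, recorded in every output.
#' @param temperature_K absolute temperature (K).
#' @param ... further stage parameters (lags, k, component counts, cutoffs,
#'   bootstrap counts, ...), stored as given.
#' @return Object of class `msm_config` (a named list).
#' @export
run_config <- function(seed, temperature_K = 310, ...) {
  if (temperature_K <= 0) stop("temperature must be > 0 K")
  structure(c(list(seed = as.integer(seed), temperature_K = temperature_K),
              list(...)),
            class = "msm_config")
}
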