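# Shrake-Rupley solvent-accessible surface area.
#
# Deterministic by construction: test points are a Fibonacci lattice (no RNG),
# and the van der Waals radii and per-residue maxima are fixed bundled tables.

# van der Waals radii (Angstrom), one bundled table
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Theoretical maximal accessible areas of residue X in a Gly-X-Gly tripeptide
# (Tien et al. 2013, "theoretical" column), Angstrom^2.  Used to normalise
# per-residue SASA into relative SASA.
MAX_SASA_GXG <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

# quasi-uniform unit sphere: Fibonacci lattice with n points
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For every atom a quasi-uniform lattice of `n_points` test points is placed
#' on the sphere of radius `r_vdw + probe`; a point is exposed iff it lies
#' outside every other atom's probe-inflated sphere.  Atom SASA is the exposed
#' fraction of `4*pi*(r_vdw+probe)^2`; residue SASA sums its atoms; relative
#' SASA divides by the residue type's maximal Gly-X-Gly exposure.
#'
#' @param model a `structure_model`.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points number of lattice points per atom sphere.
#' @return a `sasa_profile`: data.frame (chain, resnum, icode, resname, sasa,
#'   rel_sasa) with attributes `probe`, `n_points`, `atom_sasa` (per-atom
#'   values) and `total` (total SASA).
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(model, "structure_model"))
  rad <- unname(VDW_RADII[model$element])
  if (anyNA(rad)) {
    bad <- unique(model$element[is.na(rad)])
    stopf("no van der Waals radius for element(s): %s (atoms: %s)",
          paste(bad, collapse = ", "),
          paste(utils::head(model$atom[is.na(rad)], 5L), collapse = ", "))
  }
  xyz <- as.matrix(model[, c("x", "y", "z")])
  n <- nrow(xyz)
  sphere <- fibonacci_sphere(n_points)
  inflated <- rad + probe
  # neighbour candidates: pairwise centre distances under r_i + r_j + 2*probe
  d2 <- as.matrix(stats::dist(xyz))^2
  atom_area <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- inflated[i]
    cutoff2 <- (Ri + inflated)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    pts <- sweep(sphere * Ri, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dd <- (pts[, 1L] - xyz[j, 1L])^2 + (pts[, 2L] - xyz[j, 2L])^2 +
        (pts[, 3L] - xyz[j, 3L])^2
      exposed <- exposed & dd >= inflated[j]^2
    }
    atom_area[i] <- 4 * pi * Ri^2 * sum(exposed) / n_points
  }
  key <- paste(model$chain, model$resnum, model$icode, sep = "|")
  res <- chain_residues(model)
  res_key <- paste(res$chain, res$resnum, res$icode, sep = "|")
  res$sasa <- as.numeric(tapply(atom_area, factor(key, levels = res_key), sum))
  mx <- unname(MAX_SASA_GXG[res$resname])
  if (anyNA(mx))
    warning("no maximal SASA for residue type(s): ",
            paste(unique(res$resname[is.na(mx)]), collapse = ", "),
            "; relative SASA set to NA")
  res$rel_sasa <- res$sasa / mx
  structure(res, class = c("sasa_profile", "data.frame"),
            probe = probe, n_points = as.integer(n_points),
            atom_sasa = data.frame(model[, c("chain", "resnum", "icode",
                                             "atom", "element")],
                                   sasa = atom_area),
            total = sum(atom_area))
}

#' @export
print.sasa_profile <- function(x, ...) {
  cat(sprintf("<sasa_profile> %d residues, total %.1f A^2 (probe %.2f, %d points)\n",
              nrow(x), attr(x, "total"), attr(x, "probe"), attr(x, "n_points")))
  invisible(x)
}

#' Write a per-residue profile as TSV
#' @param profile a `sasa_profile` or `ensemble_rmsd_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
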