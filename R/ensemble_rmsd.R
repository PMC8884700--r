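# Per-residue RMSD over a structural ensemble (RMSF-style, about the
# per-atom ensemble mean after rigid alignment to the first frame).

#' Per-residue RMSD profile of a structural ensemble
#'
#' Frames are strided, then each frame is Kabsch-aligned to the *first* frame
#' on the CA atoms of `align_on`.  For every residue the profile reports
#' `sqrt(mean over frames and named atoms of |x - xbar|^2)` where `xbar` is
#' the per-atom mean over the aligned ensemble.
#'
#' @param frames list of `structure_model` frames with identical topology.
#' @param align_on residue selection string (author numbering, e.g.
#'   `"B:1-121"`) whose CA atoms define the alignment.
#' @param atoms backbone atom names entering the profile.
#' @param stride keep every `stride`-th frame, starting from the first.
#' @return an `ensemble_rmsd_profile`: data.frame (chain, resnum, icode,
#'   resname, rmsd) with attributes `n_frames`, `align_on`, `atoms`.
#' @export
ensemble_per_residue_rmsd <- function(frames, align_on,
                                      atoms = c("N", "CA", "C"),
                                      stride = 1L) {
  stopifnot(length(frames) >= 1L, stride >= 1L)
  frames <- frames[seq(1L, length(frames), by = as.integer(stride))]
  if (length(frames) < 2L)
    stopf("need at least 2 frames after striding, got %d", length(frames))
  ref <- frames[[1L]]
  sel <- select_atoms(ref, align_on, atoms = "CA")
  if (length(sel) < 3L) stopf("alignment selection resolves to <3 CA atoms")
  sel_key <- paste(ref$chain[sel], ref$resnum[sel], ref$icode[sel], sep = "|")

  res <- chain_residues(ref)
  res_key <- paste(res$chain, res$resnum, res$icode, sep = "|")
  nres <- nrow(res); natom <- length(atoms); nfr <- length(frames)

  # coords[frame, residue, atom, xyz]
  coords <- array(NA_real_, c(nfr, nres, natom, 3L))
  for (k in seq_len(nfr)) {
    fr <- frames[[k]]
    fsel <- select_atoms(fr, align_on, atoms = "CA")
    fkey <- paste(fr$chain[fsel], fr$resnum[fsel], fr$icode[fsel], sep = "|")
    if (!identical(fkey, sel_key))
      stopf("frame %d: alignment selection does not resolve identically", k)
    tr <- kabsch(as.matrix(fr[fsel, c("x", "y", "z")]),
                 as.matrix(ref[sel, c("x", "y", "z")]))
    fr_aligned <- apply_transform(fr, tr)
    akey <- paste(fr_aligned$chain, fr_aligned$resnum, fr_aligned$icode,
                  sep = "|")
    for (a in seq_len(natom)) {
      idx <- which(fr_aligned$atom == atoms[a])
      m <- match(res_key, akey[idx])
      if (anyNA(m)) {
        missing_res <- res_key[which(is.na(m))[1L]]
        stopf("frame %d is missing atom %s of residue %s",
              k, atoms[a], missing_res)
      }
      coords[k, , a, ] <- as.matrix(
        fr_aligned[idx[m], c("x", "y", "z")])
    }
  }
  xbar <- apply(coords, c(2L, 3L, 4L), mean)
  dev2 <- sweep(coords, c(2L, 3L, 4L), xbar)^2
  # per residue: mean over frames and atoms of the squared deviation norm
  res$rmsd <- vapply(seq_len(nres), function(r) {
    d <- dev2[, r, , , drop = FALSE]
    sqrt(mean(apply(d, c(1L, 3L), sum)))
  }, numeric(1))
  structure(res, class = c("ensemble_rmsd_profile", "data.frame"),
            n_frames = nfr, align_on = align_on, atoms = atoms)
}

#' @export
print.ensemble_rmsd_profile <- function(x, ...) {
  cat(sprintf("<ensemble_rmsd_profile> %d residues over %d frames (align %s; atoms %s)\n",
              nrow(x), attr(x, "n_frames"), attr(x, "align_on"),
              paste(attr(x, "atoms"), collapse = ",")))
  invisible(x)
}
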