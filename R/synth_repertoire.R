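# Synthetic VHH sequencing libraries with known ground truth.
#
# Read counts per unique sequence follow a zero-truncated negative binomial;
# translated lengths of intact sequences follow a rounded Gaussian; a
# controlled fraction of sequences carries a premature stop codon or a
# 1-2 nt deletion (frameshift).

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Specification of a synthetic VHH repertoire
#'
#' Defaults state the emulated world: read counts with mean ~5.4 per unique
#' sequence (the published library's ~6.3e6 reads over ~1.15e6 unique
#' sequences), translated lengths Gaussian with mean 120.7725 aa and SD
#' 4.8723 aa, and a 7% defective minority (premature stop or frameshift),
#' i.e. 93% full-length.
#'
#' @param n_unique number of distinct nucleotide sequences.
#' @param nb_r negative-binomial dispersion (size), > 0.
#' @param nb_p negative-binomial success probability, strictly in (0, 1);
#'   counts are NB(r, p) conditioned on being >= 1, with mean r(1-p)/p
#'   before truncation.
#' @param length_mean,length_sd Gaussian of translated lengths, amino acids.
#' @param defect_fraction fraction of sequences made defective, in [0, 1].
#' @param seed integer seed (mandatory); generation is bit-identical for a
#'   given spec.
#' @return a `repertoire_spec`.
#' @export
repertoire_spec <- function(n_unique, nb_r = 2, nb_p = 0.27,
                            length_mean = 120.7725, length_sd = 4.8723,
                            defect_fraction = 0.07, seed) {
  if (missing(seed)) stopf("repertoire_spec: seed is mandatory")
  n_unique <- as.integer(n_unique)
  if (n_unique < 1L) stopf("n_unique must be a positive integer")
  if (nb_r <= 0) stopf("nb_r must be > 0")
  if (nb_p <= 0 || nb_p >= 1) stopf("nb_p must lie strictly inside (0, 1)")
  if (length_sd < 0) stopf("length_sd must be nonnegative")
  if (defect_fraction < 0 || defect_fraction > 1)
    stopf("defect_fraction must lie in [0, 1]")
  structure(list(n_unique = n_unique, nb_r = nb_r, nb_p = nb_p,
                 length_mean = length_mean, length_sd = length_sd,
                 defect_fraction = defect_fraction, seed = as.integer(seed)),
            class = "repertoire_spec")
}

#' Draw zero-truncated negative binomial counts
#'
#' Inverse-CDF sampling of NB(size = r, prob = p) conditioned on counts >= 1.
#'
#' @param n number of draws.
#' @param r,p negative-binomial size and success probability.
#' @return integer vector of counts >= 1.
#' @export
rztnb <- function(n, r, p) {
  p0 <- stats::pnbinom(0L, size = r, prob = p)
  u <- stats::runif(n, p0, 1)
  u <- pmin(u, 1 - 1e-14)
  as.integer(stats::qnbinom(u, size = r, prob = p))
}

#' Zero-truncated negative binomial pmf
#' @param k counts (>= 1).
#' @param r,p negative-binomial size and success probability.
#' @param log return the log pmf.
#' @export
dztnb <- function(k, r, p, log = FALSE) {
  lp <- stats::dnbinom(k, size = r, prob = p, log = TRUE) -
    log1p(-exp(r * log(p)))
  lp[k < 1L] <- -Inf
  if (log) lp else exp(lp)
}

# encode integers as base-61 sense-codon barcodes of fixed width
index_barcode <- function(idx, width) {
  out <- character(length(idx))
  rem <- idx - 1L
  mat <- matrix("", nrow = length(idx), ncol = width)
  for (d in seq_len(width)) {
    mat[, d] <- SENSE_CODONS[(rem %% 61L) + 1L]
    rem <- rem %/% 61L
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Generate a synthetic VHH repertoire
#'
#' Produces `n_unique` distinct nucleotide sequences (uniqueness guaranteed
#' by a short sense-codon barcode encoding the sequence index), read counts
#' from the zero-truncated negative binomial, translated lengths from
#' `round(Normal(length_mean, length_sd))` (redrawn while < 1, capped), and
#' exactly `round(defect_fraction * n_unique)` defective sequences: half get
#' one internal stop codon, half a 1-2 nt deletion (choices seeded).
#'
#' @param spec a [repertoire_spec()].
#' @return list with `records` (data.frame id, nt_seq, count) and `truth`
#'   (data.frame id, defect in none/stop/frameshift, length in aa).
#' @export
generate_repertoire <- function(spec) {
  stopifnot(inherits(spec, "repertoire_spec"))
  n <- spec$n_unique
  with_seed(spec$seed, {
    counts <- rztnb(n, spec$nb_r, spec$nb_p)
    lens <- as.integer(round(stats::rnorm(n, spec$length_mean, spec$length_sd)))
    for (pass in seq_len(100L)) {
      bad <- which(lens < 1L)
      if (!length(bad)) break
      if (pass == 100L)
        stopf("length model mis-specified: lengths < 1 keep being drawn")
      lens[bad] <- as.integer(round(stats::rnorm(length(bad), spec$length_mean,
                                                 spec$length_sd)))
    }
    width <- max(1L, ceiling(log(n + 1) / log(61)))
    if (any(lens <= width + 2L))
      stopf("length model mis-specified: sequences too short for generation")
    bc <- index_barcode(seq_len(n), width)
    n_rand <- lens - width
    total <- sum(n_rand)
    big <- paste(SENSE_CODONS[sample.int(61L, total, replace = TRUE)],
                 collapse = "")
    ends <- cumsum(3L * n_rand)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    seqs <- paste0(bc, substring(big, starts, ends))

    n_def <- as.integer(round(spec$defect_fraction * n))
    defect <- rep("none", n)
    if (n_def > 0L) {
      def_idx <- sample.int(n, n_def)
      kinds <- sample(c("stop", "frameshift"), n_def, replace = TRUE)
      for (i in seq_len(n_def)) {
        j <- def_idx[i]
        if (kinds[i] == "stop") {
          # replace one internal codon (outside the barcode, not the last)
          pos <- sample((width + 1L):(lens[j] - 1L), 1L)
          stopc <- sample(STOP_CODONS, 1L)
          substr(seqs[j], 3L * pos - 2L, 3L * pos) <- stopc
        } else {
          k <- sample(1:2, 1L)               # delete 1-2 nt
          pos <- sample((3L * width + 1L):(3L * lens[j] - k), 1L)
          seqs[j] <- paste0(substr(seqs[j], 1L, pos - 1L),
                            substr(seqs[j], pos + k, 3L * lens[j]))
        }
      }
      defect[def_idx] <- kinds
    }
    if (anyDuplicated(seqs))
      stopf("internal error: generated sequences are not unique")
    ids <- sprintf("seq_%06d", seq_len(n))
    list(records = data.frame(id = ids, nt_seq = seqs, count = counts,
                              stringsAsFactors = FALSE),
         truth = data.frame(id = ids, defect = defect, length = lens,
                            stringsAsFactors = FALSE))
  })
}

#' Write repertoire records as FASTA or FASTQ
#'
#' With `expand = TRUE` every read is written as its own record
#' (`id_r1 ... id_rk` for a count of k), so reading the file back and
#' collapsing identical sequences recovers the same (sequence, count)
#' multiset.  FASTQ output uses a constant quality of `I`.
#'
#' @param records data.frame with id, nt_seq, count.
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @param expand write one record per read (default) or one per unique
#'   sequence.
#' @export
write_repertoire <- function(records, path, format = c("fasta", "fastq"),
                             expand = TRUE) {
  format <- match.arg(format)
  if (expand) {
    idx <- rep(seq_len(nrow(records)), records$count)
    rep_n <- unlist(lapply(records$count, seq_len))
    ids <- paste0(records$id[idx], "_r", rep_n)
    seqs <- records$nt_seq[idx]
  } else {
    ids <- records$id
    seqs <- records$nt_seq
  }
  if (format == "fasta") {
    writeLines(paste0(">", ids, "\n", seqs), path)
  } else {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  invisible(path)
}

#' Binomially subsample the reads of a repertoire
#'
#' Each unique sequence's count is thinned as Binomial(count, fraction);
#' sequences losing all reads drop out.
#'
#' @param records data.frame with id, nt_seq, count.
#' @param fraction retention probability per read.
#' @param seed integer seed.
#' @return records data.frame with thinned counts (only counts >= 1).
#' @export
subsample_reads <- function(records, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  with_seed(seed, {
    thin <- stats::rbinom(nrow(records), records$count, fraction)
    out <- records[thin > 0L, , drop = FALSE]
    out$count <- thin[thin > 0L]
    rownames(out) <- NULL
    out
  })
}
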