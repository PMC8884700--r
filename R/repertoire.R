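# Characterisation of a VHH library: reading and collapsing sequences,
# full-length filtering, the cardinality (counts-of-counts) spectrum,
# zero-truncated negative-binomial diversity estimation, and the Gaussian
# length fit.

#' Read and collapse a sequence collection
#'
#' Identical sequences are collapsed into one record with their occurrence
#' count; the id of the first occurrence is kept.
#'
#' @param path FASTA or FASTQ file.
#' @param format `"auto"` (by first character), `"fasta"` or `"fastq"`.
#' @return data.frame with id, nt_seq, count (0 rows, with a warning, for an
#'   empty file).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) {
    warning("empty sequence file: ", path)
    return(data.frame(id = character(0), nt_seq = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  first <- substr(lines[nonempty[1L]], 1L, 1L)
  if (format == "auto")
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stopf("cannot determine format of %s (line %d does not start a record)",
                           path, nonempty[1L]))
  if (format == "fasta") {
    # light validation so malformed records are reported with a line number
    if (first != ">")
      stopf("malformed FASTA: line %d does not start with '>'", nonempty[1L])
    is_hdr <- startsWith(lines, ">")
    bad <- which(!is_hdr & nzchar(lines) &
                   !grepl("^[A-Za-z*.-]+$", lines))
    if (length(bad))
      stopf("malformed FASTA record at line %d: %s", bad[1L],
            substr(lines[bad[1L]], 1L, 40L))
    xs <- Biostrings::readDNAStringSet(path, format = "fasta")
  } else {
    if (length(nonempty) %% 4L != 0L)
      stopf("malformed FASTQ: %s does not contain a multiple of 4 lines",
            path)
    xs <- Biostrings::readDNAStringSet(path, format = "fastq")
  }
  seqs <- as.character(xs)
  ids <- sub("\\s.*$", "", names(xs))
  f <- factor(seqs, levels = unique(seqs))
  data.frame(id = ids[!duplicated(seqs)],
             nt_seq = levels(f),
             count = as.integer(table(f)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full-length filter
#'
#' A record is kept iff `(nchar(nt_seq) - frame_offset) %% 3 == 0` (the
#' frameshift proxy), its translation in that frame carries no internal stop
#' codon (a single trailing stop is tolerated and trimmed), and the
#' translated length lies in `[min_aa, max_aa]`.  Records with non-ACGT
#' characters are rejected with reason `"ambiguous"`.
#'
#' @param records data.frame with id, nt_seq, count.
#' @param frame_offset 5' offset of the reading frame, nucleotides.
#' @param min_aa,max_aa translated-length window, amino acids.
#' @return list with `kept` (records plus an aa_seq column), `reasons`
#'   (per-record: kept / ambiguous / frameshift / premature_stop / length)
#'   and `report` (counts per reason).
#' @export
filter_full_length <- function(records, frame_offset = 0L, min_aa = 90L,
                               max_aa = 150L) {
  n <- nrow(records)
  reason <- rep("kept", n)
  nt <- toupper(records$nt_seq)
  reason[grepl("[^ACGT]", nt)] <- "ambiguous"
  ok <- reason == "kept"
  frame_bad <- ok & ((nchar(nt) - frame_offset) %% 3L != 0L)
  reason[frame_bad] <- "frameshift"
  ok <- reason == "kept"
  aa <- rep(NA_character_, n)
  if (any(ok)) {
    sub <- substr(nt[ok], frame_offset + 1L, nchar(nt[ok]))
    tr <- as.character(Biostrings::translate(Biostrings::DNAStringSet(sub)))
    tr_trim <- sub("\\*$", "", tr)          # tolerate one trailing stop
    premature <- grepl("*", tr_trim, fixed = TRUE)
    idx <- which(ok)
    reason[idx[premature]] <- "premature_stop"
    aa[idx[!premature]] <- tr_trim[!premature]
  }
  ok <- reason == "kept"
  len_bad <- ok & (nchar(aa) < min_aa | nchar(aa) > max_aa)
  reason[len_bad] <- "length"
  kept <- records[reason == "kept", , drop = FALSE]
  kept$aa_seq <- aa[reason == "kept"]
  rownames(kept) <- NULL
  lv <- c("kept", "ambiguous", "frameshift", "premature_stop", "length")
  list(kept = kept, reasons = reason,
       report = as.data.frame(table(reason = factor(reason, levels = lv)),
                              responseName = "n"))
}

#' Cardinality (counts-of-counts) spectrum
#'
#' For each read count k, the number of distinct sequences observed exactly
#' k times - the sufficient statistic for abundance-based diversity fits.
#'
#' @param records data.frame with a `count` column (all >= 1), or an integer
#'   vector of counts.
#' @return a `cardinality_spectrum`: data.frame (k, f) satisfying
#'   `sum(f) == number of unique sequences` and `sum(k*f) == total reads`.
#' @export
cardinality_spectrum <- function(records) {
  counts <- if (is.data.frame(records)) records$count else as.integer(records)
  if (!length(counts)) stopf("no counts supplied")
  if (any(counts < 1L)) stopf("counts must all be >= 1")
  tab <- table(counts)
  out <- data.frame(k = as.integer(names(tab)), f = as.integer(tab))
  stopifnot(sum(out$f) == length(counts),
            sum(as.numeric(out$k) * out$f) == sum(as.numeric(counts)))
  structure(out, class = c("cardinality_spectrum", "data.frame"),
            total_reads = sum(as.numeric(counts)),
            observed_unique = length(counts))
}

ztnb_negloglik <- function(par, k, f) {
  r <- exp(par[1L]); p <- stats::plogis(par[2L])
  lp0 <- r * log(p)
  if (!is.finite(lp0) || lp0 > -1e-12) return(1e10)
  ll <- sum(f * (stats::dnbinom(k, size = r, prob = p, log = TRUE) -
                   log1p(-exp(lp0))))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a zero-truncated negative binomial to a cardinality spectrum
#'
#' Maximises the zero-truncated NB log-likelihood
#' `sum_k f(k) * log[ NB(k; r, p) / (1 - NB(0; r, p)) ]` over (log r,
#' logit p) by quasi-Newton from five deterministic starts (best likelihood
#' wins, ties by smallest r).  The unseen-species extrapolation is
#' `estimated_total = U / (1 - p0)` with `p0 = NB(0; r_hat, p_hat) =
#' p_hat^r_hat`.
#'
#' @param spectrum a [cardinality_spectrum()] with at least two distinct
#'   cardinalities (a single cardinality is unidentifiable and errors).
#' @return a `diversity_estimate`: list with observed_unique, nb_r, nb_p,
#'   p0, estimated_total, loglik, converged.
#' @export
fit_truncated_nb <- function(spectrum) {
  k <- spectrum$k; f <- spectrum$f
  if (length(k) < 2L)
    stopf("spectrum with a single cardinality is unidentifiable; refusing to fit")
  U <- sum(f)
  m <- sum(as.numeric(k) * f) / U          # mean observed count
  starts <- lapply(c(0.2, 0.5, 1, 2, 5), function(r0) {
    p0 <- r0 / (r0 + max(m - 1, 0.1))      # moment-flavoured start
    c(log(r0), stats::qlogis(min(max(p0, 1e-3), 1 - 1e-3)))
  })
  nll <- function(par) ztnb_negloglik(par, k = k, f = f)
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, nll, method = "BFGS",
                          control = list(maxit = 500L)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stopf("all optimiser starts failed")
  vals <- vapply(fits, `[[`, numeric(1), "value")
  rs <- vapply(fits, function(ft) exp(ft$par[1L]), numeric(1))
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-8)
  best <- cand[which.min(rs[cand])]        # ties by smallest r
  ft <- fits[[best]]
  r_hat <- exp(ft$par[1L]); p_hat <- stats::plogis(ft$par[2L])
  p0 <- p_hat^r_hat
  structure(list(observed_unique = U,
                 nb_r = r_hat, nb_p = p_hat, p0 = p0,
                 estimated_total = U / (1 - p0),
                 loglik = -ft$value,
                 converged = ft$convergence == 0L,
                 diagnostics = list(convergence_code = ft$convergence,
                                    n_starts = length(fits))),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf(paste0("<diversity_estimate> U = %d observed unique\n",
                     "  ZTNB fit: r = %.4f, p = %.4f (p0 = %.4f, loglik = %.2f, converged: %s)\n",
                     "  estimated total diversity: %.0f\n"),
              x$observed_unique, x$nb_r, x$nb_p, x$p0, x$loglik,
              x$converged, x$estimated_total))
  invisible(x)
}

#' Gaussian fit of translated sequence lengths
#'
#' Maximum-likelihood Gaussian (sample mean, population standard deviation)
#' over amino-acid lengths; `"unique"` weighting counts every distinct
#' sequence once, `"read"` weights by read count.
#'
#' @param records data.frame with aa_seq (and count for read weighting).
#' @param weighting `"unique"` or `"read"`.
#' @return a `length_fit`: list with mean, sd, n.
#' @export
fit_length_gaussian <- function(records, weighting = c("unique", "read")) {
  weighting <- match.arg(weighting)
  has <- !is.na(records$aa_seq)
  if (sum(has) < 2L) stopf("need at least 2 sequences with aa_seq")
  x <- nchar(records$aa_seq[has])
  w <- if (weighting == "read") records$count[has] else rep(1L, sum(has))
  mu <- sum(w * x) / sum(w)
  sdv <- sqrt(sum(w * (x - mu)^2) / sum(w))
  structure(list(mean = mu, sd = sdv, n = sum(has), weighting = weighting),
            class = "length_fit")
}

#' @export
print.length_fit <- function(x, ...) {
  cat(sprintf("<length_fit> mean %.4f aa, sd %.4f aa (%d sequences, %s weighting)\n",
              x$mean, x$sd, x$n, x$weighting))
  invisible(x)
}

#' Write spectrum / fit reports
#' @param spectrum a `cardinality_spectrum`.
#' @param path output TSV path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(as.data.frame(spectrum), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param diversity a `diversity_estimate` (or NULL).
#' @param length_fit a `length_fit` (or NULL).
#' @param path output JSON path.
#' @rdname write_spectrum_tsv
#' @export
write_fit_json <- function(diversity = NULL, length_fit = NULL, path) {
  obj <- list()
  if (!is.null(diversity))
    obj$diversity <- diversity[c("observed_unique", "nb_r", "nb_p", "p0",
                                 "estimated_total", "loglik", "converged")]
  if (!is.null(length_fit))
    obj$length_fit <- length_fit[c("mean", "sd", "n", "weighting")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
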