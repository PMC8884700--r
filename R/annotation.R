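# CDR annotation of VHH amino-acid sequences by framework anchor motifs
# (a deliberately simplified Chothia-flavoured heuristic), or manual spans.
#
# Spans are 0-based half-open [start, end) internally; print methods also
# show 1-based inclusive coordinates for human reading.

default_cdr_rules <- function() {
  list(
    first_cys_window = c(15L, 30L),   # 1-based window for the first Cys
    trp_offset = c(10L, 16L),         # conserved Trp this far after the Cys
    cdr1_start_offset = 4L,           # CDR1 starts 4 residues after the Cys
    cdr2_start_offset = 14L,          # CDR2 starts 14 residues after the Trp
    cdr2_len_range = c(4L, 10L),
    fr3_motif = "[RK].{5}T[AV]Y",     # framework-3 start motif ends CDR2
    cdr2_fallback_len = 6L,
    second_cys_window = c(85L, 104L), # 1-based window for the second Cys
    cdr3_start_offset = 3L,           # CDR3 starts 3 residues after the Cys
    j_motif = "WG.G"                  # J-region WGxG; CDR3 ends before its W
  )
}

new_annotation <- function(aa_seq, cdr1, cdr2, cdr3, anchors, source) {
  n <- nchar(aa_seq)
  spans <- list(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3)
  for (nm in names(spans)) {
    s <- spans[[nm]]
    if (length(s) != 2L || s[1L] < 0L || s[2L] <= s[1L] || s[2L] > n)
      stopf("invalid %s span [%s) on a %d-aa sequence", nm,
            paste(s, collapse = ", "), n)
  }
  if (!(cdr1[2L] <= cdr2[1L] && cdr2[2L] <= cdr3[1L]))
    stopf("CDR spans must be pairwise disjoint and ordered cdr1 < cdr2 < cdr3")
  structure(list(aa_seq = aa_seq, cdr1 = as.integer(cdr1),
                 cdr2 = as.integer(cdr2), cdr3 = as.integer(cdr3),
                 anchors = anchors, source = source),
            class = "antibody_annotation")
}

#' Annotate CDR1/2/3 on a VHH amino-acid sequence
#'
#' In `motif` mode the three loops are located from framework anchors: the
#' first conserved Cys (window positions 15-30), the conserved Trp 10-16
#' residues after it, the second conserved Cys (window 85-104) and the
#' J-region `WGxG` motif.  CDR1 runs from 4 residues after the first Cys to 2
#' before the Trp; CDR2 is a window starting 14 residues after the Trp,
#' closed by the framework-3 start motif (`[RK]x{5}T[AV]Y`) or a fixed
#' fallback length; CDR3 runs from 3 residues after the second Cys to the
#' residue before the `WGxG` Trp.  A missing anchor raises an error naming
#' it - there is no silent guessing.  `manual` mode validates and returns
#' user spans verbatim.
#'
#' @param aa_seq amino-acid sequence (80-160 residues in motif mode).
#' @param mode `"motif"` or `"manual"`.
#' @param manual_spans list with elements cdr1, cdr2, cdr3, each a 0-based
#'   half-open `c(start, end)` (manual mode only).
#' @param rules motif rule list; see `vhhforge:::default_cdr_rules()`.
#' @return an `antibody_annotation` with 0-based half-open spans, the anchor
#'   positions found, and the source mode.
#' @export
annotate_cdrs <- function(aa_seq, mode = c("motif", "manual"),
                          manual_spans = NULL, rules = default_cdr_rules()) {
  mode <- match.arg(mode)
  aa_seq <- toupper(as.character(aa_seq))
  n <- nchar(aa_seq)
  if (mode == "manual") {
    if (is.null(manual_spans) ||
        !all(c("cdr1", "cdr2", "cdr3") %in% names(manual_spans)))
      stopf("manual mode requires manual_spans with cdr1, cdr2, cdr3")
    return(new_annotation(aa_seq, manual_spans$cdr1, manual_spans$cdr2,
                          manual_spans$cdr3, anchors = list(),
                          source = "manual"))
  }
  if (n < 80L || n > 160L)
    stopf("motif mode expects a VHH-like sequence of 80-160 aa, got %d", n)
  ch <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]

  w <- rules$first_cys_window
  cys1 <- which(ch == "C" & seq_len(n) >= w[1L] & seq_len(n) <= w[2L])
  if (!length(cys1)) stopf("first conserved Cys not found (positions %d-%d)",
                           w[1L], w[2L])
  cys1 <- cys1[1L]                       # 1-based

  to <- rules$trp_offset
  trp <- which(ch == "W" & seq_len(n) >= cys1 + to[1L] &
                 seq_len(n) <= cys1 + to[2L])
  if (!length(trp))
    stopf("conserved Trp after CDR1 not found (%d-%d residues after Cys%d)",
          to[1L], to[2L], cys1)
  trp <- trp[1L]

  cdr1 <- c(cys1 - 1L + rules$cdr1_start_offset, trp - 2L)  # 0-based [s, e)
  cdr2_start <- trp - 1L + rules$cdr2_start_offset          # 0-based
  lr <- rules$cdr2_len_range
  m <- regexpr(rules$fr3_motif, substr(aa_seq, cdr2_start + 1L + lr[1L],
                                       min(n, cdr2_start + lr[2L] + 9L)))
  if (m > 0L && (m - 1L + lr[1L]) <= lr[2L]) {
    cdr2 <- c(cdr2_start, cdr2_start + lr[1L] + m - 1L)
  } else {
    cdr2 <- c(cdr2_start, cdr2_start + rules$cdr2_fallback_len)
  }

  w2 <- rules$second_cys_window
  cys2 <- which(ch == "C" & seq_len(n) >= w2[1L] & seq_len(n) <= w2[2L] &
                  seq_len(n) > cdr2[2L])
  if (!length(cys2)) stopf("second conserved Cys not found (positions %d-%d)",
                           w2[1L], w2[2L])
  cys2 <- cys2[1L]

  jm <- regexpr(rules$j_motif, substr(aa_seq, cys2 + 1L, n))
  if (jm < 0L) stopf("J-region WGxG motif not found after Cys%d", cys2)
  jtrp <- cys2 + jm                       # 1-based position of the W

  cdr3 <- c(cys2 - 1L + rules$cdr3_start_offset, jtrp - 1L)  # 0-based [s, e)
  new_annotation(aa_seq, cdr1, cdr2, cdr3,
                 anchors = list(first_cys = cys1 - 1L, cdr1_trp = trp - 1L,
                                second_cys = cys2 - 1L, j_trp = jtrp - 1L),
                 source = "motif")
}

#' @export
print.antibody_annotation <- function(x, ...) {
  span_str <- function(s) sprintf("[%d,%d) (1-based %d-%d, len %d)",
                                  s[1L], s[2L], s[1L] + 1L, s[2L], diff(s))
  cat(sprintf("<antibody_annotation> %d aa, source=%s\n", nchar(x$aa_seq),
              x$source))
  cat("  CDR1 ", span_str(x$cdr1), "\n  CDR2 ", span_str(x$cdr2),
      "\n  CDR3 ", span_str(x$cdr3), "\n", sep = "")
  invisible(x)
}

#' CDR span lengths of an annotation
#' @param annotation an `antibody_annotation`.
#' @return named integer vector (cdr1, cdr2, cdr3).
#' @export
cdr_lengths <- function(annotation) {
  c(cdr1 = diff(annotation$cdr1), cdr2 = diff(annotation$cdr2),
    cdr3 = diff(annotation$cdr3))
}

# 0-based sequence indices covered by the three CDR spans
cdr_indices <- function(annotation) {
  sort(unique(c(annotation$cdr1[1L]:(annotation$cdr1[2L] - 1L),
                annotation$cdr2[1L]:(annotation$cdr2[2L] - 1L),
                annotation$cdr3[1L]:(annotation$cdr3[2L] - 1L))))
}

#' Write an annotation as JSON (and optionally a BED-like TSV)
#' @param annotation an `antibody_annotation`.
#' @param path output JSON path.
#' @param id sequence id used in the TSV.
#' @param tsv optional TSV path (id, 0-based start, end, label).
#' @export
write_annotation <- function(annotation, path, id = "query", tsv = NULL) {
  obj <- list(cdr1 = annotation$cdr1, cdr2 = annotation$cdr2,
              cdr3 = annotation$cdr3, anchors = annotation$anchors,
              source = annotation$source)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  if (!is.null(tsv)) {
    df <- data.frame(id = id,
                     start = c(annotation$cdr1[1L], annotation$cdr2[1L],
                               annotation$cdr3[1L]),
                     end = c(annotation$cdr1[2L], annotation$cdr2[2L],
                             annotation$cdr3[2L]),
                     label = c("CDR1", "CDR2", "CDR3"))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
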