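# PDB input/output and the structure container shared by every stage.
#
# A structure model is a data.frame with one row per atom and columns
#   record, serial, atom, altloc, resname, chain, resnum, icode,
#   x, y, z, occ, bfac, element
# plus class "structure_model" and attribute "model_id".  Atom order is file
# order; (chain, resnum, icode, atom) is unique within a model.

new_structure_model <- function(df, model_id = 1L) {
  need <- c("record", "atom", "resname", "chain", "resnum", "icode",
            "x", "y", "z", "element")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("structure model missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stopf("structure model has non-finite coordinates")
  key <- paste(df$chain, df$resnum, df$icode, df$atom, sep = "|")
  if (anyDuplicated(key))
    stopf("duplicate atom key (chain/resnum/icode/atom): %s",
          key[duplicated(key)][1L])
  if (is.null(df$serial)) df$serial <- seq_len(nrow(df))
  if (is.null(df$altloc)) df$altloc <- ""
  if (is.null(df$occ)) df$occ <- 1
  if (is.null(df$bfac)) df$bfac <- 0
  structure(df, class = c("structure_model", "data.frame"),
            model_id = as.integer(model_id))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, chains: %s\n", nrow(x),
              paste(unique(x$chain), collapse = ", ")))
  invisible(x)
}

infer_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  # two-letter elements occurring in standard residues
  up <- toupper(nm)
  ifelse(substr(up, 1, 2) %in% c("SE", "FE", "ZN", "MG", "CL", "BR"),
         substr(up, 1, 2), substr(up, 1, 1))
}

parse_atom_lines <- function(lines, lineno, model_id) {
  sub2 <- function(a, b) substr(lines, a, b)
  xs <- suppressWarnings(as.numeric(sub2(31, 38)))
  ys <- suppressWarnings(as.numeric(sub2(39, 46)))
  zs <- suppressWarnings(as.numeric(sub2(47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stopf("unparseable ATOM/HETATM record at line %d: %s",
          lineno[bad[1L]], lines[bad[1L]])
  resnum <- suppressWarnings(as.integer(sub2(23, 26)))
  if (anyNA(resnum))
    stopf("unparseable residue number at line %d", lineno[which(is.na(resnum))[1L]])
  occ <- suppressWarnings(as.numeric(sub2(55, 60)))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(sub2(61, 66)))
  bfac[is.na(bfac)] <- 0
  elem <- trimws(sub2(77, 78))
  atom <- trimws(sub2(13, 16))
  elem[elem == ""] <- infer_element(atom[elem == ""])
  df <- data.frame(
    record = trimws(sub2(1, 6)),
    serial = suppressWarnings(as.integer(sub2(7, 11))),
    atom = atom,
    altloc = trimws(sub2(17, 17)),
    resname = trimws(sub2(18, 20)),
    chain = trimws(sub2(22, 22)),
    resnum = resnum,
    icode = trimws(sub2(27, 27)),
    x = xs, y = ys, z = zs, occ = occ, bfac = bfac,
    element = toupper(elem),
    stringsAsFactors = FALSE
  )
  # altloc resolution: keep the highest-occupancy altloc per atom key
  # (first wins on ties); blank altloc is always kept.
  key <- paste(df$chain, df$resnum, df$icode, df$atom, sep = "|")
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
      if (length(i) == 1L) return(i)
      alt <- df$altloc[i]
      if (all(alt == "")) return(i)  # genuine duplicate; caught below
      i[which.max(df$occ[i])]
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
    rownames(df) <- NULL
  }
  new_structure_model(df, model_id)
}

#' Read a PDB file
#'
#' Parses `ATOM`/`HETATM` records (fixed PDB columns). `MODEL`/`ENDMDL`
#' blocks yield one structure model each.  When several alternate locations
#' are present for the same atom, the highest-occupancy one is kept (first on
#' ties).  The element is taken from columns 77-78 and inferred from the atom
#' name when blank.
#'
#' @param path path to a PDB file.
#' @return a list of `structure_model` data.frames (length 1 for single-model
#'   files).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | trimws(rec) %in% c("ATOM", "HETATM")
  model_id <- cumsum(trimws(rec) == "MODEL")
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
  models <- list()
  for (m in sort(unique(model_id[is_atom]))) {
    sel <- is_atom & model_id == m
    models[[length(models) + 1L]] <-
      parse_atom_lines(lines[sel], which(sel), length(models) + 1L)
  }
  if (!length(models)) stopf("no ATOM/HETATM records in %s", path)
  models
}

format_atom_line <- function(df) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          df$record,
          df$serial %% 100000L,
          ifelse(nchar(df$atom) < 4, paste0(" ", df$atom), df$atom),
          df$altloc, df$resname, df$chain, df$resnum,
          ifelse(df$icode == "", " ", df$icode),
          df$x, df$y, df$z, df$occ, df$bfac, df$element)
}

#' Write one or more structure models as a PDB file
#'
#' Coordinates are written with three decimals, so a write/read round trip
#' preserves them to 0.001 Angstrom.  Multiple models are wrapped in
#' `MODEL`/`ENDMDL`; a `TER` record closes each chain.
#'
#' @param model a `structure_model` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  models <- if (inherits(model, "structure_model")) list(model) else model
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    df <- models[[m]]
    df$serial <- seq_len(nrow(df))
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    for (ch in unique(df$chain)) {
      writeLines(format_atom_line(df[df$chain == ch, , drop = FALSE]), con)
      writeLines("TER", con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ordered unique residues of a chain: data.frame(chain, resnum, icode, resname)
chain_residues <- function(model, chain = NULL) {
  df <- if (is.null(chain)) model else model[model$chain == chain, , drop = FALSE]
  key <- paste(df$chain, df$resnum, df$icode, sep = "|")
  idx <- !duplicated(key)
  out <- df[idx, c("chain", "resnum", "icode", "resname"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# coordinate matrix for named atoms of a chain, ordered by residue occurrence
atom_coords <- function(model, chain, atom = "CA") {
  df <- model[model$chain == chain & model$atom %in% atom, , drop = FALSE]
  as.matrix(df[, c("x", "y", "z")])
}

#' Parse a residue selection string
#'
#' Selections use author numbering with a chain id and 1-based inclusive
#' ranges, e.g. `"B:1-121"` or `"A:101-154,A:201-254"`; a bare chain id
#' selects the whole chain.
#'
#' @param sel selection string.
#' @return a data.frame with columns chain, start, end (NA = whole chain).
#' @export
parse_selection <- function(sel) {
  parts <- trimws(strsplit(sel, ",", fixed = TRUE)[[1L]])
  out <- lapply(parts, function(p) {
    if (!grepl(":", p, fixed = TRUE))
      return(data.frame(chain = p, start = NA_integer_, end = NA_integer_))
    bits <- strsplit(p, ":", fixed = TRUE)[[1L]]
    rng <- strsplit(bits[2L], "-", fixed = TRUE)[[1L]]
    if (length(rng) != 2L) stopf("bad selection range: %s", p)
    data.frame(chain = bits[1L], start = as.integer(rng[1L]),
               end = as.integer(rng[2L]))
  })
  do.call(rbind, out)
}

# row indices of `model` matching a parsed selection (optionally one atom set)
select_atoms <- function(model, sel, atoms = NULL) {
  seldf <- if (is.character(sel)) parse_selection(sel) else sel
  hit <- rep(FALSE, nrow(model))
  for (i in seq_len(nrow(seldf))) {
    h <- model$chain == seldf$chain[i]
    if (!is.na(seldf$start[i]))
      h <- h & model$resnum >= seldf$start[i] & model$resnum <= seldf$end[i]
    hit <- hit | h
  }
  if (!is.null(atoms)) hit <- hit & model$atom %in% atoms
  which(hit)
}
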