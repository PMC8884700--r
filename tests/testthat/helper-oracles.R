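# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (triple loops, brute force) and never call
# the code paths they check.

# ---- brute-force contact oracle -------------------------------------------
# all-atom-pair residue contact sets, strict < cutoff
oracle_contacts <- function(model, ab_chain, ag_chain, cutoff = 4.0) {
  ab <- model[model$chain == ab_chain, , drop = FALSE]
  ag <- model[model$chain == ag_chain, , drop = FALSE]
  ab_res <- unique(ab$resnum)
  ag_res <- unique(ag$resnum)
  ab_hit <- logical(length(ab_res)); ag_hit <- logical(length(ag_res))
  for (i in seq_len(nrow(ab))) for (j in seq_len(nrow(ag))) {
    d <- sqrt((ab$x[i] - ag$x[j])^2 + (ab$y[i] - ag$y[j])^2 +
                (ab$z[i] - ag$z[j])^2)
    if (d < cutoff) {
      ab_hit[match(ab$resnum[i], ab_res)] <- TRUE
      ag_hit[match(ag$resnum[j], ag_res)] <- TRUE
    }
  }
  list(ab = ab_res[ab_hit], ag = ag_res[ag_hit])
}

# ---- brute-force SASA oracle ----------------------------------------------
# independent Shrake-Rupley: plain loops, golden-spiral points
oracle_sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 10000L) {
  n <- nrow(xyz)
  golden <- pi * (3 - sqrt(5))
  area <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    exposed <- 0L
    for (p in seq_len(n_points)) {
      zz <- 1 - 2 * (p - 0.5) / n_points
      rr <- sqrt(max(0, 1 - zz^2))
      ph <- golden * (p - 1)
      pt <- xyz[i, ] + R * c(rr * cos(ph), rr * sin(ph), zz)
      ok <- TRUE
      for (j in seq_len(n)) {
        if (j == i) next
        if (sum((pt - xyz[j, ])^2) < (radii[j] + probe)^2) { ok <- FALSE; break }
      }
      if (ok) exposed <- exposed + 1L
    }
    area[i] <- 4 * pi * R^2 * exposed / n_points
  }
  area
}

# ---- reference DBSCAN (python scikit-learn) -------------------------------
has_python_sklearn <- function() {
  out <- tryCatch(
    suppressWarnings(system2("python", c("-c", shQuote("import sklearn")),
                             stdout = TRUE, stderr = TRUE)),
    error = function(e) structure("", status = 1L))
  is.null(attr(out, "status")) || attr(out, "status") == 0L
}

# run sklearn DBSCAN(metric="precomputed") on a list of matrices in one call
sklearn_dbscan <- function(mats, eps, min_samples) {
  dirn <- tempfile("dbscan_oracle_")
  dir.create(dirn)
  on.exit(unlink(dirn, recursive = TRUE))
  for (i in seq_along(mats))
    write.table(mats[[i]], file.path(dirn, sprintf("m%03d.csv", i)),
                sep = ",", row.names = FALSE, col.names = FALSE)
  script <- file.path(dirn, "run.py")
  writeLines(c(
    "import sys, glob, numpy as np",
    "from sklearn.cluster import DBSCAN",
    "eps, ms = float(sys.argv[1]), int(sys.argv[2])",
    "for f in sorted(glob.glob(sys.argv[3] + '/m*.csv')):",
    "    D = np.loadtxt(f, delimiter=',')",
    "    lab = DBSCAN(eps=eps, min_samples=ms, metric='precomputed').fit(D).labels_",
    "    print(' '.join(map(str, lab)))"), script)
  out <- system2("python", c(script, eps, min_samples, dirn), stdout = TRUE)
  lapply(strsplit(out, " "), as.integer)
}

# ---- adjusted Rand index ---------------------------------------------------
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# same partition, labels possibly permuted (outlier label -1 must match)
same_partition <- function(a, b) {
  if (!all((a == -1L) == (b == -1L))) return(FALSE)
  keep <- a != -1L
  if (!any(keep)) return(TRUE)
  adjusted_rand_index(a[keep], b[keep]) == 1 &&
    length(unique(a[keep])) == length(unique(b[keep]))
}

# ---- synthetic VHH framework assembly -------------------------------------
# fixed framework segments + planted CDR loops; annotate_cdrs must recover
# the planted lengths (l1 in 5-11, l2 in 4-10, l3 in 3-24).
build_vhh <- function(l1 = 9L, l2 = 6L, l3 = 17L) {
  fw_alpha <- c("G", "S", "T", "E", "Q", "A", "D", "N", "V", "L")
  cdr_alpha <- c("S", "D", "N", "H", "P", "G")
  seg <- function(n, off = 0) if (n == 0) "" else
    paste(fw_alpha[(seq_len(n) + off - 1) %% 10 + 1], collapse = "")
  loop <- function(n, off = 0) if (n == 0) "" else
    paste(cdr_alpha[(seq_len(n) + off - 1) %% 6 + 1], collapse = "")
  pad <- 95 - (49 + l1 + l2)             # second Cys lands at 1-based 96
  stopifnot(pad >= 0)
  paste0(seg(21, 3), "C",                # first Cys at 1-based 22
         seg(3, 5), loop(l1, 1),         # 3 linker residues, CDR1
         "E", "W", seg(13, 7),           # one residue, conserved Trp, FR2
         loop(l2, 2), "RFTISRTAY",       # CDR2 closed by the FR3 motif
         seg(pad, 9), "C",               # second Cys
         substr(seg(2, 1), 1, 2),        # 2 residues before CDR3
         loop(l3, 4), "WGQGTQVTVSS")     # CDR3, J-region WGxG, tail
}

# ---- tiny structure fixtures ----------------------------------------------
# a minimal structure_model from a coordinate table
make_model <- function(chain, resnum, atom, xyz, resname = "GLY",
                       element = NULL) {
  df <- data.frame(record = "ATOM", atom = atom, resname = resname,
                   chain = chain, resnum = resnum, icode = "",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   element = element %||% vhhforge:::infer_element(atom),
                   stringsAsFactors = FALSE)
  vhhforge:::new_structure_model(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a rod-like chain: one CA per residue plus offset N, C, O.  A small
# deterministic lateral wiggle keeps CA sets non-collinear (Kabsch-fittable).
make_rod_chain <- function(chain, n, origin = c(0, 0, 0), spacing = 3.8,
                           resname = "GLY", start_resnum = 1L) {
  rows <- lapply(seq_len(n), function(i) {
    ca <- origin + c(0.6 * sin(1.9 * i), 0.6 * cos(1.3 * i),
                     (i - 1) * spacing)
    data.frame(record = "ATOM",
               atom = c("N", "CA", "C", "O"),
               resname = if (length(resname) > 1L) resname[i] else resname,
               chain = chain,
               resnum = start_resnum + i - 1L, icode = "",
               x = ca[1] + c(1.55, 0, -1.55, -1.55),
               y = ca[2] + c(0, 0, 0, 1.55),
               z = ca[3],
               element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
  })
  vhhforge:::new_structure_model(do.call(rbind, rows))
}
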