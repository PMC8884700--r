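# Epitope-inference pipeline over ensembles of docked antibody-antigen poses:
# per-pose interface extraction, two-stage contact filtering, pairwise
# interface-RMSD matrix, DBSCAN on the precomputed matrix, and cluster
# composition summaries.

#' Construct a complex pose
#'
#' @param pose_id identifier.
#' @param model a `structure_model` containing both chains.
#' @param antibody_chain,antigen_chain distinct chain ids.
#' @return a `complex_pose`.
#' @export
complex_pose <- function(pose_id, model, antibody_chain, antigen_chain) {
  stopifnot(inherits(model, "structure_model"))
  if (antibody_chain == antigen_chain)
    stopf("antibody and antigen chains must be distinct")
  chains <- unique(model$chain)
  if (!all(c(antibody_chain, antigen_chain) %in% chains))
    stopf("pose %s: chains %s/%s not both present", pose_id,
          antibody_chain, antigen_chain)
  structure(list(pose_id = pose_id, model = model,
                 antibody_chain = antibody_chain,
                 antigen_chain = antigen_chain),
            class = "complex_pose")
}

# per-residue minimum cross distances between two chains:
# returns list(ab = min distance per antibody residue,
#              ag = min distance per antigen residue), residues in chain order
residue_min_dists <- function(model, ab_chain, ag_chain) {
  ab <- model[model$chain == ab_chain, , drop = FALSE]
  ag <- model[model$chain == ag_chain, , drop = FALSE]
  if (!nrow(ab) || !nrow(ag)) stopf("empty antibody or antigen chain")
  A <- as.matrix(ab[, c("x", "y", "z")])
  B <- as.matrix(ag[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  ab_key <- paste(ab$resnum, ab$icode)
  ag_key <- paste(ag$resnum, ag$icode)
  ab_f <- factor(ab_key, levels = unique(ab_key))
  ag_f <- factor(ag_key, levels = unique(ag_key))
  atom_min_ab <- apply(d2, 1L, min)
  atom_min_ag <- apply(d2, 2L, min)
  list(ab = sqrt(as.numeric(tapply(atom_min_ab, ab_f, min))),
       ag = sqrt(as.numeric(tapply(atom_min_ag, ag_f, min))))
}

#' Interface description of a docked pose
#'
#' A residue is interacting iff any of its atoms lies at *strictly less than*
#' `cutoff` Angstrom from any atom of the partner chain (all atoms present in
#' the file are used, hydrogens included).  Antibody CDR membership comes
#' from the annotation spans, mapped positionally (span index i is the i-th
#' residue of the antibody chain).  Interacting antigen residues are tallied
#' per annotated domain and the pose is classed as contacting the `first`,
#' `second`, `both` or `none` of the domains.
#'
#' @param pose a `complex_pose`.
#' @param annotation an `antibody_annotation` for the antibody chain.
#' @param domains data.frame with columns label, start, end (author-numbered
#'   inclusive ranges on the antigen chain, non-overlapping).
#' @param cutoff contact cutoff, Angstrom (strict `<`).
#' @return an `interaction_summary`.
#' @export
interacting_residues <- function(pose, annotation, domains, cutoff = 4.0) {
  stopifnot(inherits(pose, "complex_pose"))
  model <- pose$model
  ab_res <- chain_residues(model, pose$antibody_chain)
  ag_res <- chain_residues(model, pose$antigen_chain)
  if (!nrow(ab_res) || !nrow(ag_res)) stopf("empty antibody or antigen chain")
  if (max(annotation$cdr3[2L], annotation$cdr2[2L], annotation$cdr1[2L]) >
      nrow(ab_res))
    stopf("annotation spans do not fit the %d-residue antibody chain",
          nrow(ab_res))
  if (any(domains$end < domains$start)) stopf("invalid domain ranges")

  md <- residue_min_dists(model, pose$antibody_chain, pose$antigen_chain)
  ab_hit <- which(md$ab < cutoff)            # 1-based chain residue indices
  ag_hit <- which(md$ag < cutoff)
  cdr_idx0 <- cdr_indices(annotation)        # 0-based
  cdr_hit <- intersect(ab_hit, cdr_idx0 + 1L)

  ag_nums <- ag_res$resnum[ag_hit]
  counts <- vapply(seq_len(nrow(domains)), function(i) {
    sum(ag_nums >= domains$start[i] & ag_nums <= domains$end[i])
  }, integer(1))
  names(counts) <- domains$label
  hitdom <- counts >= 1L
  klass <- if (!any(hitdom)) "none"
  else if (all(hitdom)) "both"
  else if (sum(hitdom) == 1L) {
    i <- which(hitdom)[1L]
    if (i == 1L) "first" else if (i == 2L) "second" else domains$label[i]
  } else "multiple"

  structure(list(pose_id = pose$pose_id,
                 ab_residues = ab_res$resnum[ab_hit],
                 ab_indices = ab_hit - 1L,
                 cdr_residues = ab_res$resnum[cdr_hit],
                 cdr_indices = cdr_hit - 1L,
                 ag_residues = ag_res$resnum[ag_hit],
                 domain_counts = counts,
                 class = klass,
                 cutoff = cutoff),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("<interaction_summary> %s: %d ab / %d CDR / %d ag residues (< %.2f A), class %s\n",
              x$pose_id, length(x$ab_residues), length(x$cdr_residues),
              length(x$ag_residues), x$cutoff, x$class))
  invisible(x)
}

#' Two-stage contact filter over pose interaction summaries
#'
#' Stage 1 drops poses whose CDR loops make no contact with the antigen at
#' all; stage 2 drops poses in which fewer than `min_cdr_contacts` CDR
#' residues are involved in interactions.
#'
#' @param summaries list of `interaction_summary`.
#' @param min_cdr_contacts stage-2 threshold (default 10: "fewer than ten
#'   interacting CDR residues" fails).
#' @return list with `kept` (pose ids), `report` (per-pose data.frame
#'   pose_id, n_cdr, stage: kept / stage1 / stage2) and `tallies`.
#' @export
filter_poses <- function(summaries, min_cdr_contacts = 10L) {
  n_cdr <- vapply(summaries, function(s) length(s$cdr_residues), integer(1))
  ids <- vapply(summaries, `[[`, "", "pose_id")
  stage <- ifelse(n_cdr == 0L, "stage1",
                  ifelse(n_cdr < min_cdr_contacts, "stage2", "kept"))
  list(kept = ids[stage == "kept"],
       report = data.frame(pose_id = ids, n_cdr = n_cdr, stage = stage,
                           stringsAsFactors = FALSE),
       tallies = c(input = length(ids),
                   stage1_dropped = sum(stage == "stage1"),
                   stage2_dropped = sum(stage == "stage2"),
                   kept = sum(stage == "kept")))
}

#' Pairwise interface-RMSD matrix of a pose ensemble
#'
#' For each pose pair the antigen CA sets are Kabsch-superposed (pose j onto
#' pose i), the fitted transform is applied to pose j's antibody, and the
#' entry is the RMSD over the CA atoms of all CDR residues (the union of the
#' three spans; set `cdr_only = FALSE` to use every antibody CA).
#'
#' @param poses list of `complex_pose` sharing atom naming and residue order.
#' @param annotation an `antibody_annotation` (positional mapping onto the
#'   antibody chain).
#' @param cdr_only use only CDR CA atoms (default) or all antibody CAs.
#' @return a `distance_matrix` (symmetric, zero diagonal, pose ids as
#'   dimnames).
#' @export
irmsd_matrix <- function(poses, annotation, cdr_only = TRUE) {
  n <- length(poses)
  ids <- vapply(poses, `[[`, "", "pose_id")
  ag_ca <- vector("list", n); ab_ca <- vector("list", n)
  ref_key <- NULL
  for (i in seq_len(n)) {
    p <- poses[[i]]
    m <- p$model
    ag <- m[m$chain == p$antigen_chain & m$atom == "CA", , drop = FALSE]
    ab <- m[m$chain == p$antibody_chain & m$atom == "CA", , drop = FALSE]
    # every antibody residue must carry exactly one CA
    ab_res <- chain_residues(m, p$antibody_chain)
    if (nrow(ab) != nrow(ab_res)) {
      miss <- setdiff(paste(ab_res$resnum, ab_res$icode),
                      paste(ab$resnum, ab$icode))
      stopf("pose %s: missing CA in residue %s of the antibody chain",
            p$pose_id, miss[1L] %||% "(duplicated CA)")
    }
    if (cdr_only) {
      idx <- cdr_indices(annotation) + 1L
      if (max(idx) > nrow(ab))
        stopf("pose %s: CDR spans exceed the antibody chain", p$pose_id)
      ab <- ab[idx, , drop = FALSE]
    }
    key <- c(paste(ag$resnum, ag$icode), "|", paste(ab$resnum, ab$icode))
    if (is.null(ref_key)) ref_key <- key
    else if (!identical(ref_key, key))
      stopf("pose %s: chains do not match the other poses", p$pose_id)
    ag_ca[[i]] <- as.matrix(ag[, c("x", "y", "z")])
    ab_ca[[i]] <- as.matrix(ab[, c("x", "y", "z")])
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    tr <- kabsch(ag_ca[[j]], ag_ca[[i]])
    abj <- apply_transform(ab_ca[[j]], tr)
    D[i, j] <- D[j, i] <- sqrt(mean(rowSums((abj - ab_ca[[i]])^2)))
  }
  structure(D, class = c("distance_matrix", "matrix"))
}

#' DBSCAN on a precomputed distance matrix
#'
#' A pose is a core point iff at least `min_samples` poses (itself included)
#' lie within `eps`; clusters are the connected components of core points
#' under mutual eps-reachability; non-core poses within `eps` of a core join
#' its cluster as "reachable" (ambiguous cases go to the cluster whose
#' lowest-indexed core neighbour comes first in input order); everything
#' else is an outlier (label -1).  Cluster labels are renumbered 0..K-1 by
#' decreasing size, ties broken by smallest member index.
#'
#' @param matrix a symmetric distance matrix (`distance_matrix` or plain).
#' @param eps neighbourhood radius, Angstrom (default 9, the shipped
#'   clustering default).
#' @param min_samples minimum neighbourhood size for a core point, the point
#'   itself included (default 3).
#' @return a `dbscan_result`: data.frame (pose_id, label, status) with
#'   attributes `eps`, `min_samples`.
#' @export
dbscan_precomputed <- function(matrix, eps = 9.0, min_samples = 3L) {
  D <- unclass(as.matrix(matrix))
  n <- nrow(D)
  if (n == 0L) stopf("empty distance matrix")
  if (max(abs(D - t(D))) > 1e-6) stopf("distance matrix is not symmetric")
  ids <- rownames(D) %||% sprintf("pose_%03d", seq_len(n))
  A <- D <= eps
  core <- rowSums(A) >= min_samples
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in which(core)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(A[v, ] & core & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  status <- rep("outlier", n)
  status[core] <- "core"
  for (v in which(!core)) {
    nb_core <- which(A[v, ] & core)
    if (length(nb_core)) {
      comp[v] <- comp[nb_core[1L]]   # lowest-indexed core neighbour
      status[v] <- "reachable"
    }
  }
  # renumber by decreasing cluster size, ties by smallest member index
  if (cid > 0L) {
    size <- tabulate(comp, nbins = cid)
    first <- vapply(seq_len(cid), function(k) min(which(comp == k)), integer(1))
    ord <- order(-size, first)
    relabel <- integer(cid); relabel[ord] <- seq_len(cid) - 1L
    label <- ifelse(is.na(comp), -1L, relabel[comp])
  } else label <- rep(-1L, n)
  structure(data.frame(pose_id = ids, label = as.integer(label),
                       status = status, stringsAsFactors = FALSE),
            class = c("dbscan_result", "data.frame"),
            eps = eps, min_samples = as.integer(min_samples))
}

#' Cluster composition summary
#'
#' Per cluster: size, number of core poses, and how many member poses
#' contact the first, second, both or neither antigen domain; plus an
#' overall row (outliers included) and the headline ratio of both-domain
#' poses among clustered poses outside the largest cluster.
#'
#' @param clustering a `dbscan_result` (or a pipeline pose table with
#'   pose_id, label, status).
#' @param summaries list of `interaction_summary` covering the clustered
#'   poses.
#' @return a `cluster_summary`: list with `table` (per-cluster data.frame),
#'   `both_domain_ratio`, `both_domain_counts` (c(both, total)) and
#'   `n_outliers`.
#' @export
summarize_clusters <- function(clustering, summaries) {
  sm_ids <- vapply(summaries, `[[`, "", "pose_id")
  klass <- vapply(summaries, `[[`, "", "class")[match(clustering$pose_id,
                                                      sm_ids)]
  classes <- c("first", "second", "both", "none")
  row_for <- function(sel, label) {
    cnt <- vapply(classes, function(k) sum(klass[sel] == k, na.rm = TRUE),
                  integer(1))
    data.frame(cluster = label, size = sum(sel),
               n_core = sum(clustering$status[sel] == "core"),
               t(cnt), stringsAsFactors = FALSE)
  }
  labs <- sort(unique(clustering$label[clustering$label >= 0L]))
  tab <- do.call(rbind, c(
    lapply(labs, function(l) row_for(clustering$label == l, as.character(l))),
    list(row_for(rep(TRUE, nrow(clustering)), "overall"))))
  n_out <- sum(clustering$label == -1L)
  # headline: both-domain fraction among clustered poses outside the largest
  # cluster (the statistic the 51/61 report line is built from)
  if (length(labs)) {
    sizes <- vapply(labs, function(l) sum(clustering$label == l), integer(1))
    largest <- labs[which.max(sizes)]
    denom_sel <- clustering$label >= 0L & clustering$label != largest
    both <- sum(klass[denom_sel] == "both", na.rm = TRUE)
    denom <- sum(denom_sel)
  } else { both <- 0L; denom <- 0L }
  structure(list(table = tab,
                 both_domain_ratio = if (denom > 0L) both / denom else NA_real_,
                 both_domain_counts = c(both = both, total = denom),
                 n_outliers = n_out),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  print(x$table)
  cat(sprintf("outliers: %d; both-domain outside largest cluster: %d/%d\n",
              x$n_outliers, x$both_domain_counts[["both"]],
              x$both_domain_counts[["total"]]))
  invisible(x)
}

#' 2D embedding of a distance matrix (plotting aid)
#'
#' Delegates to classical multidimensional scaling; deterministic, and no
#' downstream computation depends on it.
#'
#' @param matrix a `distance_matrix`.
#' @param seed kept for interface stability; the embedding is deterministic.
#' @return data.frame (pose_id, x, y).
#' @export
embed_2d <- function(matrix, seed = 1L) {
  D <- unclass(as.matrix(matrix))
  n <- nrow(D)
  k <- min(2L, n - 1L)
  xy <- stats::cmdscale(D, k = k)
  if (ncol(xy) < 2L) xy <- cbind(xy, 0)
  # fix the sign indeterminacy so repeated runs agree bit-for-bit
  for (j in 1:2) if (xy[which.max(abs(xy[, j])), j] < 0) xy[, j] <- -xy[, j]
  data.frame(pose_id = rownames(D) %||% sprintf("pose_%03d", seq_len(n)),
             x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
}

#' Full docking-ensemble analysis pipeline
#'
#' Contacts -> two-stage CDR filter -> interface-RMSD matrix -> DBSCAN ->
#' cluster summary.  Poses removed by the contact filter never enter the
#' matrix; in the combined per-pose table they carry label -1 and status
#' `"excluded"`.
#'
#' @param poses list of `complex_pose`.
#' @param annotation an `antibody_annotation`.
#' @param domains domain definition data.frame (label, start, end).
#' @param cutoff contact cutoff, Angstrom.
#' @param min_cdr_contacts stage-2 filter threshold.
#' @param eps,min_samples DBSCAN parameters (defaults 9 Angstrom / 3).
#' @param embed also compute the 2D embedding.
#' @return list with `summaries`, `filter`, `matrix`, `clustering`,
#'   `cluster_summary`, `pose_table` (every input pose with final label and
#'   status) and optionally `embedding`.
#' @export
analyze_pose_ensemble <- function(poses, annotation, domains, cutoff = 4.0,
                                  min_cdr_contacts = 10L, eps = 9.0,
                                  min_samples = 3L, embed = FALSE) {
  summaries <- lapply(poses, interacting_residues, annotation = annotation,
                      domains = domains, cutoff = cutoff)
  flt <- filter_poses(summaries, min_cdr_contacts = min_cdr_contacts)
  ids <- vapply(poses, `[[`, "", "pose_id")
  kept <- poses[ids %in% flt$kept]
  clustering <- NULL
  if (length(kept) >= 1L) {
    D <- irmsd_matrix(kept, annotation)
    clustering <- dbscan_precomputed(D, eps = eps, min_samples = min_samples)
  } else D <- NULL
  pose_table <- data.frame(pose_id = ids, label = -1L, status = "excluded",
                           stringsAsFactors = FALSE)
  if (!is.null(clustering)) {
    m <- match(clustering$pose_id, pose_table$pose_id)
    pose_table$label[m] <- clustering$label
    pose_table$status[m] <- clustering$status
  }
  out <- list(summaries = summaries, filter = flt, matrix = D,
              clustering = clustering,
              cluster_summary = if (!is.null(clustering))
                summarize_clusters(clustering, summaries) else NULL,
              pose_table = pose_table)
  if (embed && !is.null(D)) out$embedding <- embed_2d(D)
  out
}

#' Write a distance matrix as TSV (pose ids as header)
#' @param matrix a `distance_matrix`.
#' @param path output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  utils::write.table(as.data.frame(unclass(as.matrix(matrix))), path,
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  invisible(path)
}
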