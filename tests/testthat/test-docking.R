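# Shared fixture: toy complex and a small pose ensemble (built once; the
# generators are themselves under test in test-synthetic-poses.R)
tc <- generate_toy_complex(1)

test_that("interacting_residues matches the brute-force all-pair oracle", {
  # 20 constructed poses: rigid placements of the antibody at graded offsets
  set.seed(6)
  m <- tc$model
  ab_rows <- m$chain == "B"
  for (i in 1:20) {
    m2 <- m
    shift <- c(runif(1, 0, 3), runif(1, -2, 2), runif(1, -10, 10))
    m2$x[ab_rows] <- m2$x[ab_rows] + shift[1]
    m2$y[ab_rows] <- m2$y[ab_rows] + shift[2]
    m2$z[ab_rows] <- m2$z[ab_rows] + shift[3]
    pose <- complex_pose(sprintf("t%02d", i), m2, "B", "A")
    s <- interacting_residues(pose, tc$annotation, tc$domains)
    orc <- oracle_contacts(m2, "B", "A")
    expect_identical(sort(s$ab_residues), sort(orc$ab))
    expect_identical(sort(s$ag_residues), sort(orc$ag))
    # contact symmetry: either both sides see the interface or neither does
    expect_identical(length(s$ab_residues) > 0, length(s$ag_residues) > 0)
  }
})

test_that("contact cutoff is strictly less-than at the boundary", {
  # a single-atom antigen against a 3-residue antibody at exact separations
  ab <- function(d) {
    xyz <- rbind(c(0, 0, 0),                       # antigen
                 c(d, 0, 0), c(d, 0, 10), c(d, 0, 20))
    make_model(c("A", "B", "B", "B"), c(1L, 1L, 2L, 3L),
               rep("CA", 4), xyz)
  }
  ann3 <- annotate_cdrs("AAA", mode = "manual",
                        manual_spans = list(cdr1 = c(0, 1), cdr2 = c(1, 2),
                                            cdr3 = c(2, 3)))
  doms <- data.frame(label = "domain1", start = 1L, end = 1L)
  for (case in list(c(3.99, 1), c(4.00, 0), c(4.01, 0))) {
    pose <- complex_pose("b", ab(case[1]), "B", "A")
    s <- interacting_residues(pose, ann3, doms, cutoff = 4.0)
    expect_equal(length(s$cdr_residues), case[2])
  }
  # far translation: everything empty, class none
  far <- complex_pose("far", ab(100), "B", "A")
  sf <- interacting_residues(far, ann3, doms)
  expect_length(sf$ab_residues, 0)
  expect_identical(sf$class, "none")
})

test_that("domain annotation classes follow the contact tallies", {
  ref <- complex_pose("ref", tc$model, "B", "A")
  s <- interacting_residues(ref, tc$annotation, tc$domains)
  expect_identical(s$class, "first")
  expect_gte(s$domain_counts[["domain1"]], 1L)
  expect_identical(s$domain_counts[["domain2"]], 0L)
  expect_true(all(s$cdr_residues %in% s$ab_residues))
  expect_lte(sum(s$domain_counts), length(s$ag_residues))
})

test_that("filter_poses implements the two-stage less-than-ten rule", {
  fake <- function(id, n) structure(list(pose_id = id,
                                         cdr_residues = seq_len(n),
                                         class = "first"),
                                    class = "interaction_summary")
  sm <- list(fake("zero", 0), fake("nine", 9), fake("ten", 10),
             fake("many", 15))
  flt <- filter_poses(sm)
  expect_identical(flt$kept, c("ten", "many"))
  expect_identical(flt$report$stage, c("stage1", "stage2", "kept", "kept"))
  expect_equal(unname(flt$tallies[c("stage1_dropped", "stage2_dropped")]),
               c(1L, 1L))
  # degenerate threshold: stage 2 drops nothing
  flt0 <- filter_poses(sm, min_cdr_contacts = 0L)
  expect_identical(flt0$kept, c("nine", "ten", "many"))
  # monotone: raising the threshold never grows the kept set
  kept_sets <- lapply(c(0, 5, 10, 12, 20),
                      function(th) filter_poses(sm, th)$kept)
  for (i in seq_len(length(kept_sets) - 1L))
    expect_true(all(kept_sets[[i + 1L]] %in% kept_sets[[i]]))
})

test_that("irmsd matrix: identity, rigid-motion invariance, exact translation", {
  ens <- generate_pose_ensemble(tc, pose_ensemble_spec(
    n_clusters = 1L, sizes = 3L, n_outliers = 0L, rot_sd_within = 0,
    trans_sd_within = 0, coord_noise_sd = 0, seed = 4L))
  poses <- ens$poses
  D <- irmsd_matrix(poses, tc$annotation)
  expect_true(all(abs(D) < 1e-9))          # identical members

  # pose with whole complex rigidly transformed: iRMSD stays 0
  p2 <- poses[[1L]]
  tr <- list(rotation = vhhforge:::random_rotation(), translation = c(9, 8, -7))
  p2$model <- apply_transform(p2$model, tr)
  p2$pose_id <- "moved"
  D2 <- irmsd_matrix(list(poses[[1L]], p2), tc$annotation)
  expect_lt(D2[1, 2], 1e-6)

  # pure 10 A antibody translation (antigen fixed): exactly 10
  p3 <- poses[[1L]]
  sel <- p3$model$chain == "B"
  p3$model$x[sel] <- p3$model$x[sel] + 10
  p3$pose_id <- "shifted"
  D3 <- irmsd_matrix(list(poses[[1L]], p3), tc$annotation)
  expect_equal(D3[1, 2], 10.0, tolerance = 1e-9)
  expect_equal(D3[2, 1], D3[1, 2])
  expect_true(all(diag(D3) == 0))
})

test_that("dbscan_precomputed handles hand-checkable cases", {
  # 5 poses all at distance 0: one cluster, all core
  Z <- matrix(0, 5, 5)
  r <- dbscan_precomputed(Z, eps = 9, min_samples = 3)
  expect_true(all(r$label == 0L))
  expect_true(all(r$status == "core"))

  # two groups of 4 (intra 1) plus one isolated pose (inter 100)
  D <- matrix(100, 9, 9); diag(D) <- 0
  D[1:4, 1:4] <- 1; D[5:8, 5:8] <- 1; diag(D) <- 0
  r2 <- dbscan_precomputed(D, eps = 9, min_samples = 3)
  expect_equal(r2$label, c(rep(0L, 4), rep(1L, 4), -1L))
  expect_identical(r2$status[9], "outlier")
  expect_true(all(r2$status[1:8] == "core"))

  # border point: within eps of one cluster's cores but not core itself
  B <- matrix(100, 5, 5); diag(B) <- 0
  B[1:3, 1:3] <- 1; diag(B) <- 0
  B[4, 1] <- B[1, 4] <- 8              # reachable from pose 1 only
  r3 <- dbscan_precomputed(B, eps = 9, min_samples = 3)
  expect_identical(r3$status, c("core", "core", "core", "reachable",
                                "outlier"))
  expect_equal(r3$label, c(0L, 0L, 0L, 0L, -1L))

  # every non-empty cluster contains at least one core pose
  expect_true(all(tapply(r3$status[r3$label >= 0], r3$label[r3$label >= 0],
                         function(s) any(s == "core"))))
})

test_that("dbscan matches the scikit-learn reference on random tie-free matrices", {
  skip_if(!has_python_sklearn(), "python/sklearn oracle unavailable")
  set.seed(77)
  mats <- list()
  while (length(mats) < 50L) {
    n <- sample(12:25, 1)
    pts <- matrix(rnorm(n * 5, sd = 3), ncol = 5)
    D <- as.matrix(dist(pts))
    eps <- 6
    # tie-free by construction: no distance near eps, no ambiguous border
    if (any(abs(D[upper.tri(D)] - eps) < 1e-3)) next
    ours <- dbscan_precomputed(D, eps = eps, min_samples = 3)
    A <- D <= eps; core <- rowSums(A) >= 3
    amb <- vapply(which(!core), function(v) {
      cl <- unique(ours$label[A[v, ] & core])
      length(cl) > 1L
    }, logical(1))
    if (any(amb)) next
    mats[[length(mats) + 1L]] <- D
  }
  ref <- sklearn_dbscan(mats, eps = 6, min_samples = 3)
  for (i in seq_along(mats)) {
    ours <- dbscan_precomputed(mats[[i]], eps = 6, min_samples = 3)
    expect_true(same_partition(ours$label, ref[[i]]),
                info = sprintf("matrix %d", i))
  }
})

test_that("permuting pose order permutes labels consistently", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(30, 0), ncol = 3),
               matrix(rnorm(30, 50), ncol = 3),
               matrix(rnorm(15, -60), ncol = 3))
  D <- as.matrix(dist(pts))
  a <- dbscan_precomputed(D, eps = 10, min_samples = 3)
  perm <- sample(nrow(D))
  b <- dbscan_precomputed(D[perm, perm], eps = 10, min_samples = 3)
  expect_true(same_partition(a$label[perm], b$label))
})

test_that("summarize_clusters reports composition and the both-domain ratio", {
  fake_sum <- function(id, klass) structure(
    list(pose_id = id, cdr_residues = 1:12, class = klass),
    class = "interaction_summary")
  fake_clust <- function(ids, labels, status) data.frame(
    pose_id = ids, label = labels, status = status, stringsAsFactors = FALSE)

  # single cluster, all members class both
  sm <- lapply(1:4, function(i) fake_sum(paste0("p", i), "both"))
  cl <- fake_clust(paste0("p", 1:4), rep(0L, 4), rep("core", 4))
  s <- summarize_clusters(cl, sm)
  expect_equal(s$table$both[s$table$cluster == "0"], 4L)

  # planted composition: cluster 0 (largest) only domain1; cluster 1 both;
  # cluster 2 mixed; one outlier
  ids <- sprintf("p%02d", 1:12)
  klass <- c(rep("first", 5), rep("both", 3), "both", "both", "first", "none")
  labels <- c(rep(0L, 5), rep(1L, 3), rep(2L, 3), -1L)
  status <- c(rep("core", 11), "outlier")
  sm2 <- lapply(seq_along(ids), function(i) fake_sum(ids[i], klass[i]))
  cl2 <- fake_clust(ids, labels, status)
  s2 <- summarize_clusters(cl2, sm2)
  tab <- s2$table
  expect_equal(tab$size[tab$cluster == "0"], 5L)
  expect_equal(tab$first[tab$cluster == "0"], 5L)
  expect_equal(tab$both[tab$cluster == "1"], 3L)
  expect_equal(s2$n_outliers, 1L)
  # poses outside the largest cluster and not outliers: 6, of which 5 both
  expect_equal(unname(s2$both_domain_counts), c(5L, 6L))
  expect_equal(s2$both_domain_ratio, 5 / 6)

  # all-outlier clustering: only the overall row
  cl3 <- fake_clust(ids[1:3], rep(-1L, 3), rep("outlier", 3))
  s3 <- summarize_clusters(cl3, sm2[1:3])
  expect_identical(s3$table$cluster, "overall")
  expect_true(is.na(s3$both_domain_ratio))
})

test_that("embed_2d is deterministic and separates planted far clusters", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(24, 0), ncol = 3), matrix(rnorm(24, 60), ncol = 3))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- sprintf("p%02d", 1:16)
  e1 <- embed_2d(D); e2 <- embed_2d(D)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 16L)
  lab <- rep(1:2, each = 8)
  intra <- mean(dist(e1[lab == 1, c("x", "y")]))
  inter <- mean(as.matrix(dist(e1[, c("x", "y")]))[lab == 1, lab == 2])
  expect_gt(inter, intra)
})

test_that("irmsd_matrix validates pose compatibility and CA presence", {
  ens <- generate_pose_ensemble(tc, pose_ensemble_spec(
    n_clusters = 1L, sizes = 2L, n_outliers = 0L, seed = 8L))
  poses <- ens$poses
  broken <- poses[[2L]]
  bm <- broken$model
  drop <- which(bm$chain == "B" & bm$atom == "CA")[16]   # a CDR residue CA
  broken$model <- vhhforge:::new_structure_model(as.data.frame(bm[-drop, ]))
  expect_error(irmsd_matrix(list(poses[[1L]], broken), tc$annotation))
})
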