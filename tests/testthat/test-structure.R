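test_that("PDB write/read round-trips coordinates to 0.001 A", {
  tc <- generate_toy_complex(2)
  f <- tempfile(fileext = ".pdb")
  write_pdb(tc$model, f)
  back <- read_pdb(f)
  expect_length(back, 1L)
  m <- back[[1L]]
  expect_equal(nrow(m), nrow(tc$model))
  expect_lt(max(abs(m$x - tc$model$x)), 5.1e-4)   # %8.3f: 0.0005 rounding
  expect_lt(max(abs(m$y - tc$model$y)), 5.1e-4)
  expect_lt(max(abs(m$z - tc$model$z)), 5.1e-4)
  expect_identical(m$chain, tc$model$chain)
  expect_identical(m$atom, tc$model$atom)
  expect_identical(m$resnum, tc$model$resnum)
})

test_that("multi-model files, altloc resolution and malformed lines", {
  rod <- make_rod_chain("A", 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb(list(rod, rod), f)
  expect_length(read_pdb(f), 2L)

  # altloc: highest occupancy kept
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.40  0.00           C")
  fa <- tempfile(fileext = ".pdb"); writeLines(lines, fa)
  m <- read_pdb(fa)[[1L]]
  expect_equal(nrow(m), 1L)
  expect_equal(m$x, 0)

  bad <- c("ATOM      1  CA  GLY A   1       xxx     0.000   0.000  1.00  0.00           C")
  fb <- tempfile(fileext = ".pdb"); writeLines(bad, fb)
  expect_error(read_pdb(fb), "line 1")

  dup <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   1       1.550   0.000   0.000  1.00  0.00           C")
  fd <- tempfile(fileext = ".pdb"); writeLines(dup, fd)
  expect_error(read_pdb(fd), "duplicate atom key")
})

test_that("kabsch: identity, construct-and-recover, symmetry, degenerate input", {
  set.seed(5)
  A <- matrix(rnorm(30), ncol = 3)
  id <- kabsch(A, A)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)
  expect_equal(id$translation, rep(0, 3), tolerance = 1e-8)

  R <- vhhforge:::random_rotation()
  t <- c(3, -2, 7)
  B <- sweep(A %*% t(R), 2, t, "+")
  fit <- kabsch(A, B)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation, R, tolerance = 1e-6)
  expect_equal(fit$translation, t, tolerance = 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)

  for (i in 1:20) {
    X <- matrix(rnorm(15), ncol = 3); Y <- matrix(rnorm(15), ncol = 3)
    expect_equal(kabsch(X, Y)$rmsd, kabsch(Y, X)$rmsd, tolerance = 1e-8)
  }

  expect_error(kabsch(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "degenerate")
})

test_that("kabsch RMSD is optimal against random rigid transforms", {
  set.seed(8)
  for (rep in 1:5) {
    A <- matrix(rnorm(18), ncol = 3)
    B <- matrix(rnorm(18), ncol = 3)
    best <- kabsch(A, B)$rmsd
    # brute-force lower-bound check over 1000 random rigid transforms
    worst_gap <- min(vapply(1:1000, function(i) {
      R <- vhhforge:::random_rotation()
      Ar <- A %*% t(R)
      tt <- colMeans(B) - colMeans(Ar)
      sqrt(mean(rowSums((sweep(Ar, 2, -tt) - B)^2)))
    }, numeric(1)))
    expect_lte(best, worst_gap + 1e-9)
  }
})

test_that("sasa matches closed forms and the dense brute-force oracle", {
  # isolated atom: full sphere
  one <- make_model("A", 1L, "CA", matrix(c(0, 0, 0), 1), resname = "GLY")
  p <- sasa(one, n_points = 960L)
  expect_equal(attr(p, "total"), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # two atoms beyond mutual occlusion range: both full spheres
  two <- make_model("A", 1:2, c("CA", "CA"),
                    rbind(c(0, 0, 0), c(10, 0, 0)))
  p2 <- sasa(two, n_points = 960L)
  expect_equal(attr(p2, "total"), 2 * 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)

  # 20-atom cluster at van der Waals contact packing vs the independent
  # 10k-point oracle (tighter packing buries atoms below the 960-point
  # quadrature granularity, where a 3% relative bound is meaningless)
  set.seed(7)
  xyz <- matrix(rnorm(60, sd = 4), ncol = 3)
  elements <- rep(c("C", "N", "O", "S"), 5)
  mdl <- make_model("A", 1:20, rep("CA", 20), xyz, element = elements)
  ours <- attr(sasa(mdl, n_points = 960L), "atom_sasa")$sasa
  radii <- unname(vhhforge:::VDW_RADII[elements])
  ref <- oracle_sasa_atoms(xyz, radii, n_points = 10000L)
  rel <- abs(ours - ref) / pmax(ref, 1)
  expect_lt(max(rel), 0.03)

  # unknown element errors
  bad <- make_model("A", 1L, "XX", matrix(0, 1, 3), element = "Q")
  expect_error(sasa(bad), "van der Waals")
})

test_that("sasa refinement and relative-SASA normalisation are sane", {
  tc <- generate_toy_complex(3)
  s1 <- sasa(tc$model, n_points = 960L)
  s2 <- sasa(tc$model, n_points = 3840L)
  expect_lt(abs(attr(s1, "total") - attr(s2, "total")) / attr(s2, "total"),
            0.02)
  expect_true(all(s1$sasa >= 0))
  expect_identical(attr(s1, "n_points"), 960L)
})

test_that("ensemble RMSD: zero for identical frames, closed form for displacement", {
  rod <- make_rod_chain("B", 6)
  frames <- replicate(4, rod, simplify = FALSE)
  prof <- ensemble_per_residue_rmsd(frames, "B:1-4")
  expect_true(all(prof$rmsd < 1e-9))

  # displace residue 6 by d along x in exactly half of 2k frames
  d <- 2.4
  moved <- rod
  sel <- moved$resnum == 6L
  moved$x[sel] <- moved$x[sel] + d
  frames2 <- c(replicate(5, rod, simplify = FALSE),
               replicate(5, moved, simplify = FALSE))
  prof2 <- ensemble_per_residue_rmsd(frames2, "B:1-4")
  expect_equal(prof2$rmsd[prof2$resnum == 6L], d / 2, tolerance = 1e-9)
  expect_true(all(prof2$rmsd[prof2$resnum != 6L] < 1e-9))
})

test_that("ensemble RMSD: striding, rigid-motion invariance, missing atoms", {
  rod <- make_rod_chain("B", 4)
  # stride semantics: every tenth frame, starting at the first
  frames <- replicate(50, rod, simplify = FALSE)
  prof <- ensemble_per_residue_rmsd(frames, "B:1-4", stride = 10L)
  expect_identical(attr(prof, "n_frames"), 5L)

  # invariance under one global rigid transform applied to every frame
  set.seed(3)
  moved <- rod; moved$x[moved$resnum == 4L] <- moved$x[moved$resnum == 4L] + 1
  fr <- list(rod, moved, rod, moved)
  base <- ensemble_per_residue_rmsd(fr, "B:1-3")
  R <- vhhforge:::random_rotation()
  tr <- list(rotation = R, translation = c(5, -3, 2))
  fr2 <- lapply(fr, apply_transform, transform = tr)
  moved_prof <- ensemble_per_residue_rmsd(fr2, "B:1-3")
  expect_equal(base$rmsd, moved_prof$rmsd, tolerance = 1e-6)

  # a frame missing a selected atom errors with frame and atom named
  broken <- rod[!(rod$resnum == 2L & rod$atom == "N"), ]
  broken <- vhhforge:::new_structure_model(as.data.frame(broken))
  expect_error(ensemble_per_residue_rmsd(list(rod, broken), "B:1-4"),
               "frame 2 is missing atom N")
})

test_that("selection parsing resolves chains and ranges", {
  sel <- parse_selection("B:1-121,A:5-10")
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$start, c(1L, 5L))
  rod <- make_rod_chain("B", 10)
  idx <- vhhforge:::select_atoms(rod, "B:2-4", atoms = "CA")
  expect_equal(rod$resnum[idx], 2:4)
  expect_error(parse_selection("B:1"), "bad selection")
})
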