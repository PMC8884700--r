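# Synthetic docked-pose ensembles with planted clusters.
#
# The toy antigen is two rigid rods ("domain1", "domain2") 28 Angstrom apart;
# the toy antibody carries a 15-residue CDR patch that wraps an antigen rod
# (so every docked placement has its whole paratope in atomic contact) plus
# two framework columns pointing away from the interface.  Pose clusters are
# rigid placements of the antibody (which rod, height along it, angle around
# it); members perturb their centre by small rotations/translations and
# per-atom noise.  All geometric constants live in .toy below.

.toy <- list(
  rod_x = c(0, 28),             # rod axis x-positions (y = 0)
  rod_len = 54L,                # residues per antigen domain
  rod_rise = 1.6,               # Angstrom per residue along z
  rod_offset = 1.8,             # radial offset of antigen N/C/O atoms
  rod_twist = 137.5 * pi / 180, # offset-atom twist per residue
  dom_start = c(101L, 201L),    # author numbering of the two domains
  cdr_radius = 6.5,             # CDR patch CA radius around the rod axis
  cdr_cb = 2.0,                 # CB points inward by this much
  cdr_cols = c(-45, 0, 45) * pi / 180,
  cdr_zs = c(-7.6, -3.8, 0, 3.8, 7.6),
  fw_radius = 12,               # framework column radius
  fw_phi = c(75, -75) * pi / 180,
  fw_len = 15L,
  fw_spacing = 3.8,
  bond = 1.55,                  # N/C/O offsets within antibody residues
  z0_margin = 10,               # placement z kept this far off the rod ends
  member_min_contacts = 12L     # cluster members must keep at least this
)                               # many CDR residues inside the 4 A band

toy_rod_z <- function() {
  n <- .toy$rod_len
  (seq_len(n) - (n + 1) / 2) * .toy$rod_rise
}

# antigen: both rods, chain A, author-numbered blocks
.toy_antigen <- function() {
  hydrophilic <- c("SER", "ASP", "LYS", "THR", "GLU", "ASN", "GLN", "GLY")
  rows <- list()
  z <- toy_rod_z()
  for (d in 1:2) {
    x0 <- .toy$rod_x[d]
    for (i in seq_len(.toy$rod_len)) {
      th <- .toy$rod_twist * i
      # four offset atoms 90 degrees apart: dense angular coverage of the
      # contact shell, so per-residue nearest-atom distances are uniform
      ang <- th + c(0, 1, 2, 3) * pi / 2
      off <- .toy$rod_offset
      resnum <- .toy$dom_start[d] + i - 1L
      resname <- hydrophilic[(i - 1L) %% length(hydrophilic) + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        atom = c("CA", "N", "C", "O", "CB"),
        resname = resname, chain = "A", resnum = resnum,
        x = x0 + c(0, off * cos(ang)),
        y = c(0, off * sin(ang)),
        z = z[i],
        element = c("C", "N", "C", "O", "C"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# antibody in its local frame: local z axis == the wrapped rod axis
.toy_antibody_local <- function() {
  b <- .toy$bond
  rows <- list()
  add_res <- function(resnum, resname, ca, tangent, radial, cb = FALSE) {
    atoms <- c("N", "CA", "C", "O", if (cb) "CB")
    elem <- c("N", "C", "C", "O", if (cb) "C")
    xyz <- rbind(ca + b * tangent, ca, ca - b * tangent, ca + b * radial,
                 if (cb) ca - .toy$cdr_cb * radial)
    rows[[length(rows) + 1L]] <<- data.frame(
      atom = atoms, resname = resname, chain = "B", resnum = resnum,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], element = elem,
      stringsAsFactors = FALSE)
  }
  fw_names <- c("GLN", "VAL", "GLN", "LEU", "GLU", "SER", "GLY", "GLY",
                "GLY", "SER", "VAL", "GLN", "ALA", "GLY", "GLY")
  cdr_names <- c("GLY", "SER", "TYR", "THR", "SER",   # cdr1
                 "SER", "ASN", "GLY", "SER", "THR",   # cdr2
                 "ASP", "SER", "TYR", "GLY", "SER")   # cdr3
  # FW1: residues 1-15, column parallel to the axis
  for (side in 1:2) {
    phi <- .toy$fw_phi[side]
    radial <- c(cos(phi), sin(phi), 0); tangent <- c(-sin(phi), cos(phi), 0)
    zs <- (seq_len(.toy$fw_len) - (.toy$fw_len + 1) / 2) * .toy$fw_spacing
    base <- if (side == 1L) 0L else 30L
    for (i in seq_len(.toy$fw_len)) {
      ca <- c(.toy$fw_radius * radial[1:2], zs[i])
      add_res(base + i, fw_names[i], ca, tangent, radial)
    }
  }
  # CDR patch: residues 16-30, serpentine over three columns on the cylinder
  k <- 0L
  for (col in 1:3) {
    phi <- .toy$cdr_cols[col]
    radial <- c(cos(phi), sin(phi), 0); tangent <- c(-sin(phi), cos(phi), 0)
    zs <- if (col == 2L) rev(.toy$cdr_zs) else .toy$cdr_zs
    for (i in seq_along(zs)) {
      k <- k + 1L
      ca <- c(.toy$cdr_radius * radial[1:2], zs[i])
      add_res(15L + k, cdr_names[k], ca, tangent, radial, cb = TRUE)
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$resnum), , drop = FALSE]
}

#' Generate the toy antibody-antigen reference complex
#'
#' Antigen chain A holds two spatially separated rigid residue blocks
#' (author-numbered 101-154 and 201-254, axes 28 Angstrom apart); antibody
#' chain B (45 residues) carries three annotated CDR spans forming a patch
#' that wraps the first antigen block.  Every residue has at least N, CA, C,
#' O atoms and no two atoms lie closer than 1.5 Angstrom.  The seed drives a
#' small (<= 0.04 Angstrom) coordinate jitter so distinct seeds give distinct
#' but equally valid geometries.
#'
#' @param seed integer seed.
#' @return a list with `model` (a `structure_model`), `annotation` (an
#'   `antibody_annotation` for chain B) and `domains` (a data.frame
#'   label/start/end usable with [interacting_residues()]).
#' @export
generate_toy_complex <- function(seed) {
  df <- rbind(.toy_antigen(), .toy_antibody_local())
  df <- with_seed(seed, {
    jit <- matrix(stats::rnorm(3L * nrow(df), sd = 0.01), ncol = 3L)
    jit <- pmin(pmax(jit, -0.04), 0.04)
    df$x <- df$x + jit[, 1L]; df$y <- df$y + jit[, 2L]; df$z <- df$z + jit[, 3L]
    df
  })
  df$record <- "ATOM"; df$icode <- ""
  model <- new_structure_model(df)
  aa <- paste(aa3to1(chain_residues(model, "B")$resname), collapse = "")
  ann <- annotate_cdrs(aa, mode = "manual",
                       manual_spans = list(cdr1 = c(15L, 20L),
                                           cdr2 = c(20L, 25L),
                                           cdr3 = c(25L, 30L)))
  domains <- data.frame(
    label = c("domain1", "domain2"),
    start = .toy$dom_start,
    end = .toy$dom_start + .toy$rod_len - 1L)
  list(model = model, annotation = ann, domains = domains)
}

#' Specification of a synthetic docked-pose ensemble
#'
#' Defaults describe the stated benchmark world: three planted clusters of
#' sizes 8/6/5, four planted outliers, within-cluster spread well under
#' 3 Angstrom (2 degrees / 1 Angstrom / 0.1 Angstrom noise) and cluster
#' centres at least 40 Angstrom apart in antibody-CA displacement.
#'
#' @param n_clusters number of planted clusters.
#' @param sizes integer vector of cluster sizes (length `n_clusters`).
#' @param n_outliers number of planted outlier poses.
#' @param rot_sd_within within-cluster rotational noise, degrees.  The
#'   defaults (1 degree / 0.5 Angstrom / 0.05 Angstrom) keep cluster members
#'   docked (a docking cluster is by definition a family of contacting
#'   solutions) while giving a within-cluster antibody-CA spread of roughly
#'   1-2 Angstrom, well below the 3 Angstrom the benchmark world states.
#' @param trans_sd_within within-cluster translational noise, Angstrom.
#' @param min_between_separation minimum antibody-CA RMSD between cluster
#'   centres, Angstrom; outliers are placed farther than three times this.
#' @param coord_noise_sd per-atom Gaussian noise, Angstrom.
#' @param seed integer seed (mandatory).
#' @return a `pose_ensemble_spec`.
#' @export
pose_ensemble_spec <- function(n_clusters = 3L, sizes = c(8L, 6L, 5L),
                               n_outliers = 4L, rot_sd_within = 1,
                               trans_sd_within = 0.5,
                               min_between_separation = 40,
                               coord_noise_sd = 0.05, seed) {
  if (missing(seed)) stopf("pose_ensemble_spec: seed is mandatory")
  n_clusters <- as.integer(n_clusters)
  sizes <- as.integer(sizes)
  if (n_clusters < 0L || n_outliers < 0L) stopf("negative counts")
  if (length(sizes) != n_clusters)
    stopf("length(sizes) == n_clusters violated (%d vs %d)",
          length(sizes), n_clusters)
  if (n_clusters > 0L && any(sizes < 1L)) stopf("cluster sizes must be >= 1")
  if (n_clusters > 1L && min_between_separation <= 0)
    stopf("min_between_separation must be > 0 with more than one cluster")
  if (rot_sd_within < 0 || trans_sd_within < 0 || coord_noise_sd < 0)
    stopf("noise parameters must be nonnegative")
  structure(list(n_clusters = n_clusters, sizes = sizes,
                 n_outliers = as.integer(n_outliers),
                 rot_sd_within = rot_sd_within,
                 trans_sd_within = trans_sd_within,
                 min_between_separation = min_between_separation,
                 coord_noise_sd = coord_noise_sd,
                 seed = as.integer(seed)),
            class = "pose_ensemble_spec")
}

# split antigen residues into domain blocks by gaps in author numbering
antigen_blocks <- function(ag_res) {
  brk <- c(0L, which(diff(ag_res$resnum) > 1L), nrow(ag_res))
  lapply(seq_len(length(brk) - 1L),
         function(i) (brk[i] + 1L):(brk[i + 1L]))
}

min_cross_dist <- function(A, B) {
  # minimum distance between two coordinate sets (n x 3, m x 3)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Generate a docked-pose ensemble with planted clusters and outliers
#'
#' Cluster centres are random rigid placements of the antibody around one of
#' the two antigen rods (rod choice, height, wrap angle), rejected until all
#' pairwise antibody-CA RMSDs reach `min_between_separation`; every docked
#' placement keeps the full CDR patch in contact with the antigen.  Members
#' perturb their centre by small rotations/translations plus per-atom
#' Gaussian noise; a member is redrawn (hard cap 50) when it clashes into
#' the antigen (minimum interatomic distance < 2 Angstrom) or loses its
#' docked interface (fewer than 12 of its 15 CDR residues left inside the
#' 4 Angstrom contact band) - planted cluster members are docked solutions
#' by construction.  Outliers are
#' detached placements farther than `3 * min_between_separation` from every
#' centre (and out of antigen contact).
#'
#' @param reference toy complex from [generate_toy_complex()] (the list or
#'   its `$model`).
#' @param spec a [pose_ensemble_spec()].
#' @param antibody_chain,antigen_chain chain ids in the reference.
#' @return a list with `poses` (list of `complex_pose`), `truth`
#'   (data.frame pose_id/label, label -1 for outliers) and `annotation`
#'   (CDR spans, when the reference carried them).
#' @export
generate_pose_ensemble <- function(reference, spec,
                                   antibody_chain = "B",
                                   antigen_chain = "A") {
  stopifnot(inherits(spec, "pose_ensemble_spec"))
  ann <- NULL
  if (is.list(reference) && !inherits(reference, "structure_model")) {
    ann <- reference$annotation
    reference <- reference$model
  }
  stopifnot(inherits(reference, "structure_model"))
  ab <- reference[reference$chain == antibody_chain, , drop = FALSE]
  ag <- reference[reference$chain == antigen_chain, , drop = FALSE]
  if (!nrow(ab) || !nrow(ag))
    stopf("reference must contain antibody chain %s and antigen chain %s",
          antibody_chain, antigen_chain)
  ag_res <- chain_residues(reference, antigen_chain)
  blocks <- antigen_blocks(ag_res)
  ag_ca <- reference[reference$chain == antigen_chain &
                       reference$atom == "CA", , drop = FALSE]
  rod_xy <- t(vapply(blocks, function(ix) {
    colMeans(as.matrix(ag_ca[ix, c("x", "y")]))
  }, numeric(2)))
  zr <- range(ag_ca$z)
  z_lo <- zr[1L] + .toy$z0_margin; z_hi <- zr[2L] - .toy$z0_margin

  ab_xyz <- as.matrix(ab[, c("x", "y", "z")])
  ab_ca_idx <- which(ab$atom == "CA")
  ag_xyz <- as.matrix(ag[, c("x", "y", "z")])
  # local frame: the reference antibody wraps rod 1, whose axis passes
  # through rod_xy[1, ] parallel to z
  origin <- c(rod_xy[1L, ], 0)

  place <- function(rod, z0, phi) {
    R <- rotation_about_axis(c(0, 0, 1), phi)
    shift <- c(rod_xy[rod, ], z0)
    xyz <- sweep(ab_xyz, 2, origin) %*% t(R)
    sweep(xyz, 2, shift, "+")
  }
  ca_rmsd <- function(A, B) sqrt(mean(rowSums((A[ab_ca_idx, , drop = FALSE] -
                                                 B[ab_ca_idx, , drop = FALSE])^2)))
  # CDR residues of the antibody chain (0-based spans -> atom rows), used to
  # keep cluster members genuinely docked; falls back to all residues
  ab_reskey <- paste(ab$resnum, ab$icode)
  ab_resf <- factor(ab_reskey, levels = unique(ab_reskey))
  cdr_rows <- if (!is.null(ann)) {
    as.integer(ab_resf) %in% (cdr_indices(ann) + 1L)
  } else rep(TRUE, nrow(ab))
  n_cdr_total <- length(unique(ab_resf[cdr_rows]))
  cdr_contacts <- function(xyz) {
    A <- xyz[cdr_rows, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(ag_xyz^2), "+") - 2 * A %*% t(ag_xyz)
    mind <- sqrt(pmax(0, tapply(apply(d2, 1L, min),
                                droplevels(ab_resf[cdr_rows]), min)))
    sum(mind < 4)
  }
  make_pose <- function(xyz, pose_id) {
    m <- reference
    abrow <- m$chain == antibody_chain
    m$x[abrow] <- xyz[, 1L]; m$y[abrow] <- xyz[, 2L]; m$z[abrow] <- xyz[, 3L]
    complex_pose(pose_id, m, antibody_chain, antigen_chain)
  }

  with_seed(spec$seed, {
    centres <- list()
    if (spec$n_clusters > 0L) {
      for (restart in seq_len(60L)) {
        centres <- list()
        for (ci in seq_len(spec$n_clusters)) {
          for (try in seq_len(300L)) {
            rod <- sample.int(nrow(rod_xy), 1L)
            z0 <- stats::runif(1L, z_lo, z_hi)
            phi <- stats::runif(1L, 0, 2 * pi)
            cand <- place(rod, z0, phi)
            if (length(centres) &&
                any(vapply(centres, function(cc) ca_rmsd(cc, cand),
                           numeric(1)) < spec$min_between_separation)) next
            if (min_cross_dist(cand, ag_xyz) < 2) next
            centres[[ci]] <- cand
            break
          }
          if (length(centres) < ci) break   # restart from scratch
        }
        if (length(centres) == spec$n_clusters) break
      }
      if (length(centres) < spec$n_clusters)
        stopf("could not place %d cluster centres with separation %.1f A (mis-specified ensemble?)",
              spec$n_clusters, spec$min_between_separation)
    }

    poses <- list(); labels <- integer(0)
    pid <- function(i) sprintf("pose_%03d", i)
    n_total <- 0L
    for (ci in seq_along(centres)) {
      for (m in seq_len(spec$sizes[ci])) {
        for (try in seq_len(50L)) {
          xyz <- centres[[ci]]
          if (spec$rot_sd_within > 0) {
            ang <- stats::rnorm(1L, 0, spec$rot_sd_within) * pi / 180
            axis <- stats::rnorm(3L)
            cen <- colMeans(xyz[ab_ca_idx, , drop = FALSE])
            R <- rotation_about_axis(axis, ang)
            xyz <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen, "+")
          }
          if (spec$trans_sd_within > 0)
            xyz <- sweep(xyz, 2, stats::rnorm(3L, 0, spec$trans_sd_within), "+")
          if (spec$coord_noise_sd > 0)
            xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$coord_noise_sd),
                                ncol = 3L)
          # members must stay docked: no clash, paratope still engaged
          need <- min(.toy$member_min_contacts, n_cdr_total)
          if (min_cross_dist(xyz, ag_xyz) >= 2 && cdr_contacts(xyz) >= need)
            break
          if (try == 50L)
            stopf("member redraw cap reached for cluster %d (clash or lost interface)",
                  ci)
        }
        n_total <- n_total + 1L
        poses[[n_total]] <- make_pose(xyz, pid(n_total))
        labels[n_total] <- ci - 1L
      }
    }
    for (o in seq_len(spec$n_outliers)) {
      far <- 3 * max(spec$min_between_separation, 10) + 60 + 15 * o
      for (try in seq_len(50L)) {
        th <- stats::runif(1L, 0, 2 * pi)
        R <- random_rotation()
        cen <- colMeans(ab_xyz)
        xyz <- sweep(sweep(ab_xyz, 2, cen) %*% t(R), 2,
                     c(-far * cos(th) - 80, far * sin(th), 0) + cen, "+")
        seps <- vapply(centres, function(cc) ca_rmsd(cc, xyz), numeric(1))
        if ((!length(seps) || all(seps > 3 * spec$min_between_separation)) &&
            min_cross_dist(xyz, ag_xyz) >= 2) break
        if (try == 50L) stopf("could not place outlier %d", o)
      }
      n_total <- n_total + 1L
      poses[[n_total]] <- make_pose(xyz, pid(n_total))
      labels[n_total] <- -1L
    }
    list(poses = poses,
         truth = data.frame(pose_id = vapply(poses, `[[`, "", "pose_id"),
                            label = labels, stringsAsFactors = FALSE),
         annotation = ann)
  })
}

#' Write a pose ensemble to a directory
#'
#' One standalone PDB per pose, plus `manifest.tsv` (pose_id, path,
#' antibody_chain, antigen_chain) and `truth.tsv` (pose_id, label).
#'
#' @param ensemble result of [generate_pose_ensemble()].
#' @param dir output directory (created if needed).
#' @return path to the manifest, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(ensemble$poses, function(p) {
    fp <- file.path(dir, paste0(p$pose_id, ".pdb"))
    write_pdb(p$model, fp)
    fp
  }, "")
  manifest <- data.frame(
    pose_id = vapply(ensemble$poses, `[[`, "", "pose_id"),
    path = paths,
    antibody_chain = vapply(ensemble$poses, `[[`, "", "antibody_chain"),
    antigen_chain = vapply(ensemble$poses, `[[`, "", "antigen_chain"),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ensemble$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a pose ensemble back from a manifest
#' @param manifest path to a `manifest.tsv` written by [write_pose_ensemble()].
#' @return list of `complex_pose`.
#' @export
read_pose_ensemble <- function(manifest) {
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  base <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    complex_pose(man$pose_id[i], read_pdb(p)[[1L]],
                 man$antibody_chain[i], man$antigen_chain[i])
  })
}
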