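# Synthetic complex generator: a polyalanine helical-bundle receptor, a
# geometrically valid native IDP backbone grown along its surface, per-window
# decoy pose pools with known RMSD to the native window, and opaque score
# channels with a controlled rank correlation to that RMSD. Replaces the
# external docking and scoring engines for controlled benchmarking.

# Build an N/CA/CB/C backbone around a CA trace. N points toward the
# previous CA, C toward the next (idealised bond lengths); CB from
# tetrahedral construction. Termini bend their N/C direction off the chain
# axis so the three backbone atoms are never collinear.
#' @keywords internal
backbone_from_ca <- function(ca) {
  ca <- as.matrix(ca)
  m <- nrow(ca)
  stopifnot(m >= 2L)
  bend <- function(v) {
    ref <- if (abs(v[3]) < 0.9 * vnorm(v)) c(0, 0, 1) else c(1, 0, 0)
    axis <- unit(cross3(v, ref))
    as.vector(axis_rotation(axis, 35 * pi / 180) %*% v)
  }
  bb <- matrix(NA_real_, m * N_BB_ATOMS, 3L)
  max_ang <- 125 * pi / 180   # cap the N-CA-C angle at a protein-like value
  for (i in seq_len(m)) {
    to_prev <- if (i > 1L) ca[i - 1L, ] - ca[i, ] else bend(ca[1, ] - ca[2, ])
    to_next <- if (i < m) ca[i + 1L, ] - ca[i, ] else bend(ca[m, ] - ca[m - 1L, ])
    u1 <- unit(to_prev); u2 <- unit(to_next)
    ang <- acos(max(-1, min(1, sum(u1 * u2))))
    if (ang > max_ang) {
      axis <- cross3(u1, u2)
      if (vnorm(axis) < 1e-8) axis <- cross3(u1, if (abs(u1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
      axis <- unit(axis)
      half <- (ang - max_ang) / 2
      u1 <- as.vector(axis_rotation(axis, half) %*% u1)
      u2 <- as.vector(axis_rotation(axis, -half) %*% u2)
    }
    n_at <- ca[i, ] + 1.46 * u1
    c_at <- ca[i, ] + 1.52 * u2
    cb <- virtual_cbeta(n_at, ca[i, ], c_at)
    bb[bb_row(i, "N"), ] <- n_at
    bb[bb_row(i, "CA"), ] <- ca[i, ]
    bb[bb_row(i, "CB"), ] <- cb
    bb[bb_row(i, "C"), ] <- c_at
  }
  bb
}

#' Build a synthetic helical-bundle receptor
#'
#' A polyalanine bundle of ideal alpha-helices (rise 1.5 Angstrom and 100
#' degrees per residue, CA radius 2.3 Angstrom) with axes parallel to z,
#' arranged on a circle. Realistic enough for surface, contact and clash
#' logic; real receptors are read with [read_structure()].
#'
#' @param helix_len Residues per helix.
#' @param n_helices Number of helices (default 3).
#' @param bundle_radius Distance of each helix axis from the bundle centre
#'   (default 5.8 Angstrom, giving ~10 Angstrom axis spacing for 3 helices).
#' @return An `idp_structure` with role `"receptor"`.
#' @export
build_receptor <- function(helix_len = 24L, n_helices = 3L,
                           bundle_radius = 5.8) {
  all_atoms <- NULL
  res0 <- 0L
  for (h in seq_len(n_helices)) {
    phi <- 2 * pi * (h - 1) / n_helices
    centre <- c(bundle_radius * cos(phi), bundle_radius * sin(phi), 0)
    i <- seq_len(helix_len)
    ang <- (i - 1) * 100 * pi / 180 + phi
    ca <- cbind(centre[1] + 2.3 * cos(ang),
                centre[2] + 2.3 * sin(ang),
                (i - 1) * 1.5 - helix_len * 0.75)
    bb <- backbone_from_ca(ca)
    atoms <- data.frame(
      name = rep(BB_ATOMS, helix_len),
      resname = "ALA",
      residue_index = res0 + rep(i, each = N_BB_ATOMS),
      chain_id = "A",
      x = bb[, 1], y = bb[, 2], z = bb[, 3],
      element = rep(c("N", "C", "C", "C"), helix_len),
      stringsAsFactors = FALSE
    )
    all_atoms <- rbind(all_atoms, atoms)
    res0 <- res0 + helix_len
  }
  new_structure(all_atoms, role = "receptor")
}

# Grow a self-avoiding CA walk of length L hugging the receptor surface.
# Step length 3.8 +- 0.05 A; per-step turn angles of 30-60 degrees about a
# random axis keep 4- and 6-residue spans inside the bands the pair filter
# accepts for native window pairs; global span caps keep far window pairs
# inside the midpoint-distance limit.
#' @keywords internal
grow_native_ca <- function(rec_xyz, L, max_proposals = 60L,
                           max_backtracks = 4000L) {
  centre <- colMeans(rec_xyz)
  surf_band <- c(3.2, 5.0)
  ok_spans <- function(pts, p) {
    i <- nrow(pts) + 1L
    if (i >= 3L) {
      d <- sqrt(rowSums((pts[seq_len(i - 2L), , drop = FALSE] -
                           matrix(p, i - 2L, 3, byrow = TRUE))^2))
      s <- (i - 1L) - seq_len(i - 2L) + 1L   # chain separations >= 2
      if (any(s >= 4L & d < 6.2)) return(FALSE)
      if (any(s < 4L & d < 4.4)) return(FALSE)
      if (any(s == 4L & d > 13.2)) return(FALSE)
      if (any(s == 6L & (d < 6.8 | d > 17.5))) return(FALSE)
      if (any(s >= 6L & d > 3.02 * s)) return(FALSE)
    }
    dist_r <- min(cross_dist(matrix(p, 1, 3), rec_xyz))
    dist_r >= surf_band[1] && dist_r <= surf_band[2]
  }
  start_point <- function() {
    a <- rec_xyz[sample.int(nrow(rec_xyz), 1L), ]
    out <- a - centre
    out[3] <- out[3] * 0.2   # bias the outward normal toward the bundle flank
    p <- a + 4.0 * unit(out)
    dir0 <- unit(cross3(unit(out), stats::rnorm(3)))
    list(p = p, dir = dir0)
  }
  attempts_left <- integer(L)
  pts <- matrix(NA_real_, 0, 3)
  dirs <- list()
  backtracks <- 0L
  repeat {
    if (nrow(pts) == 0L) {
      st <- start_point()
      if (!ok_spans(pts, st$p)) next
      pts <- matrix(st$p, 1, 3)
      dirs[[1]] <- st$dir
      attempts_left[1] <- max_proposals
      next
    }
    i <- nrow(pts) + 1L
    if (i > L) break
    placed <- FALSE
    for (trial in seq_len(max_proposals)) {
      axis <- stats::rnorm(3)
      axis <- axis - sum(axis * dirs[[i - 1L]]) * dirs[[i - 1L]]
      if (vnorm(axis) < 1e-6) next
      theta <- stats::runif(1, 30, 60) * pi / 180
      nd <- as.vector(axis_rotation(unit(axis), theta) %*% dirs[[i - 1L]])
      step <- 3.8 + max(-0.05, min(0.05, stats::rnorm(1, 0, 0.02)))
      cand <- pts[i - 1L, ] + step * nd
      if (ok_spans(pts, cand)) {
        pts <- rbind(pts, cand)
        dirs[[i]] <- unit(nd)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      backtracks <- backtracks + 1L
      if (backtracks > max_backtracks) {
        stopf(paste0("failed to grow a self-avoiding surface walk of length %d; ",
                     "try a larger receptor or a different seed"), L)
      }
      drop_to <- max(1L, nrow(pts) - 2L)
      pts <- pts[seq_len(drop_to - 1L), , drop = FALSE]
      dirs <- dirs[seq_len(max(0L, drop_to - 1L))]
      if (nrow(pts) == 0L) dirs <- list()
    }
  }
  frac <- mean(apply(cross_dist(pts, rec_xyz), 1, min) >= surf_band[1] &
                 apply(cross_dist(pts, rec_xyz), 1, min) <= surf_band[2])
  attr(pts, "surface_fraction") <- frac
  unname(pts)
}

# Rigid perturbation of a backbone to a target in-frame RMSD: rotation about
# the centroid plus a translation, jointly scaled by bisection (RMSD is
# monotone in the scale).
#' @keywords internal
perturb_pose <- function(bb, target_rmsd) {
  if (target_rmsd <= 0) return(bb)
  ctr <- colMeans(bb)
  centred <- sweep(bb, 2, ctr)
  rg <- sqrt(mean(rowSums(centred^2)))
  axis <- unit(stats::rnorm(3))
  tdir <- unit(stats::rnorm(3))
  theta_max <- min(pi, 2 * target_rmsd / rg)
  t_max <- 1.5 * target_rmsd
  place <- function(s) {
    R <- axis_rotation(axis, s * theta_max)
    sweep(centred %*% t(R), 2, ctr + s * t_max * tdir, "+")
  }
  lo <- 0; hi <- 1
  while (rmsd_in_frame(place(hi), bb) < target_rmsd && hi < 64) hi <- hi * 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (rmsd_in_frame(place(mid), bb) < target_rmsd) lo <- mid else hi <- mid
  }
  place((lo + hi) / 2)
}

#' Attach synthetic score channels to pose pools
#'
#' Generates opaque score channels whose Spearman rank correlation with the
#' known pose RMSD is approximately `rho`: each channel is the RMSD plus
#' independent Gaussian noise whose variance is solved from the normal
#' rank-correlation relation. `rho = 1` reproduces the RMSD ranking exactly;
#' `rho = 0` gives pure noise.
#'
#' @param truth Numeric vector of pose RMSDs (Angstrom).
#' @param rho Target Spearman correlation in [0, 1].
#' @param n_channels Number of independent channels (default 2).
#' @param names Channel names (default `channel_A`, `channel_B`, ...).
#' @return Data frame of channels (lower is better), one row per pose.
#' @export
generate_channels <- function(truth, rho, n_channels = 2L, names = NULL) {
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  n <- length(truth)
  if (is.null(names)) {
    names <- paste0("channel_", LETTERS[seq_len(n_channels)])
  }
  s_truth <- stats::sd(truth)
  if (!is.finite(s_truth) || s_truth == 0) s_truth <- 1
  out <- lapply(seq_len(n_channels), function(ch) {
    if (rho >= 1) return(truth)
    if (rho <= 0) return(stats::rnorm(n, 0, s_truth))
    rho_p <- 2 * sin(pi * rho / 6)   # Pearson equivalent of the target Spearman
    noise_sd <- s_truth * sqrt(1 / rho_p^2 - 1)
    truth + stats::rnorm(n, 0, noise_sd)
  })
  names(out) <- names
  as.data.frame(out)
}

#' Generate a complete synthetic docking test instance
#'
#' Builds a helical-bundle receptor, grows a native IDP backbone of length
#' `L` along its surface (CA-CA step 3.8 Angstrom, surface distance mostly
#' in [3.2, 5.0] Angstrom), tiles it into 9-residue windows with 3-residue
#' overlap, and emits per-window pose pools: the native window (optional),
#' `n_near` rigid near-native perturbations at the requested RMSD levels,
#' and `n_random` poses placed at random orientations over the receptor
#' surface. The true in-frame RMSD of every pose to its native window is
#' recorded, and score channels correlated with it can be attached.
#'
#' @param L IDP length in residues (>= 9).
#' @param n_near Near-native poses per window.
#' @param near_levels Target RMSD levels (Angstrom) recycled over the
#'   near-native poses (default 1..6).
#' @param n_random Randomly placed poses per window.
#' @param n_decoy_chains Number of additional non-native surface chains.
#'   Docking engines tend to place fragments consistently at a few
#'   alternative surface sites; each decoy chain emulates one such site by
#'   growing another self-avoiding surface walk and contributing its window
#'   cuts (plus perturbations) to the pools, so that geometrically coherent
#'   but wrong paths exist.
#' @param decoy_poses Poses contributed per decoy chain per window (one
#'   exact cut plus `decoy_poses - 1` perturbations at `near_levels`).
#' @param include_native Include the exact native pose in every pool.
#' @param channel_rho If non-NULL, attach this many-channel score table per
#'   pool with the given Spearman correlation to the truth RMSD.
#' @param n_channels Number of score channels (default 2).
#' @param seed Integer seed; the whole instance is reproducible from it.
#' @param helix_len Receptor helix length (default scales with `L`).
#' @return An object of class `synthetic_complex`: list with `receptor`,
#'   `native_ca`, `native_bb`, `windows`, `pools` (list of [pose_pool()]
#'   with `truth_rmsd` filled), and `params`.
#' @export
generate_complex <- function(L = 27L, n_near = 20L, near_levels = 1:6,
                             n_random = 80L, n_decoy_chains = 0L,
                             decoy_poses = 20L, include_native = TRUE,
                             channel_rho = 0.7, n_channels = 2L,
                             seed = 1L,
                             helix_len = max(24L, ceiling(L * 0.9))) {
  if (L < 9L) stopf("L must be at least 9")
  if (include_native + n_near + n_random + n_decoy_chains * decoy_poses < 1L) {
    stopf("pools would be empty")
  }
  set.seed(seed)
  receptor <- build_receptor(helix_len = helix_len)
  rec_xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  native_ca <- grow_native_ca(rec_xyz, L)
  native_bb <- backbone_from_ca(native_ca)
  decoy_bbs <- lapply(seq_len(n_decoy_chains), function(d) {
    backbone_from_ca(grow_native_ca(rec_xyz, L))
  })
  windows <- make_windows(L)
  pools <- vector("list", nrow(windows))
  for (n in seq_len(nrow(windows))) {
    rows <- as.vector(vapply(windows$start[n]:windows$end[n],
                             function(r) bb_row(r, BB_ATOMS), numeric(4)))
    nat <- native_bb[rows, , drop = FALSE]
    mats <- list(); ids <- character(0); levels_used <- numeric(0)
    if (include_native) {
      mats[[length(mats) + 1L]] <- nat
      ids <- c(ids, sprintf("w%02d_native", n))
      levels_used <- c(levels_used, 0)
    }
    if (n_near > 0L) {
      lv <- rep_len(near_levels, n_near)
      for (i in seq_len(n_near)) {
        mats[[length(mats) + 1L]] <- perturb_pose(nat, lv[i])
        ids <- c(ids, sprintf("w%02d_near%03d", n, i))
        levels_used <- c(levels_used, lv[i])
      }
    }
    for (d in seq_len(n_decoy_chains)) {
      alt <- decoy_bbs[[d]][rows, , drop = FALSE]
      lv <- rep_len(near_levels, max(0L, decoy_poses - 1L))
      mats[[length(mats) + 1L]] <- alt
      ids <- c(ids, sprintf("w%02d_alt%d_000", n, d))
      levels_used <- c(levels_used, NA_real_)
      for (i in seq_len(max(0L, decoy_poses - 1L))) {
        mats[[length(mats) + 1L]] <- perturb_pose(alt, lv[i])
        ids <- c(ids, sprintf("w%02d_alt%d_%03d", n, d, i))
        levels_used <- c(levels_used, NA_real_)
      }
    }
    if (n_random > 0L) {
      ctr_nat <- colMeans(nat)
      centred <- sweep(nat, 2, ctr_nat)
      centre <- colMeans(rec_xyz)
      for (i in seq_len(n_random)) {
        a <- rec_xyz[sample.int(nrow(rec_xyz), 1L), ]
        pos <- a + stats::runif(1, 3.5, 7.0) * unit(a - centre)
        mats[[length(mats) + 1L]] <-
          sweep(centred %*% t(random_rotation()), 2, pos, "+")
        ids <- c(ids, sprintf("w%02d_rand%03d", n, i))
        levels_used <- c(levels_used, NA_real_)
      }
    }
    flat <- t(vapply(mats, flatten_bb, numeric(length(rows) * 3L)))
    truth <- apply(flat, 1, function(v) rmsd_in_frame(unflatten_bb(v), nat))
    channels <- if (!is.null(channel_rho)) {
      generate_channels(truth, channel_rho, n_channels)
    } else NULL
    pools[[n]] <- pose_pool(n, flat, pose_ids = ids, channels = channels,
                            truth_rmsd = unname(truth))
  }
  structure(list(
    receptor = receptor,
    native_ca = native_ca,
    native_bb = native_bb,
    windows = windows,
    pools = pools,
    params = list(L = L, n_near = n_near, near_levels = near_levels,
                  n_random = n_random, n_decoy_chains = n_decoy_chains,
                  decoy_poses = decoy_poses, include_native = include_native,
                  channel_rho = channel_rho, n_channels = n_channels,
                  seed = seed, helix_len = helix_len,
                  surface_fraction = attr(native_ca, "surface_fraction"))
  ), class = "synthetic_complex")
}
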