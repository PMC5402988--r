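test_that("in-frame RMSD matches its definition", {
  set.seed(1)
  a <- matrix(rnorm(36 * 3), ncol = 3)
  expect_equal(rmsd_in_frame(a, a), 0)
  b <- sweep(a, 2, c(3, 0, 0), "+")
  expect_equal(rmsd_in_frame(a, b), 3.0)
  for (i in 1:10) {
    x <- matrix(rnorm(36 * 3), ncol = 3)
    y <- matrix(rnorm(36 * 3), ncol = 3)
    expect_equal(rmsd_in_frame(x, y), oracle_rmsd(x, y), tolerance = 1e-9)
    expect_equal(rmsd_in_frame(x, y), rmsd_in_frame(y, x))
  }
  expect_error(rmsd_in_frame(a, a[1:10, ]), "differ in size")
})

test_that("Kabsch superposition recovers rigid transforms and is optimal", {
  set.seed(2)
  for (i in 1:10) {
    x <- matrix(rnorm(20 * 3, sd = 5), ncol = 3)
    tr <- random_rigid()
    y <- apply_rigid(x, tr)
    fit <- kabsch_superpose(x, y)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_transform(x, fit), y, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # optimality: no worse than the identity transform
    z <- matrix(rnorm(20 * 3, sd = 5), ncol = 3)
    expect_lte(kabsch_superpose(x, z)$rmsd, rmsd_in_frame(x, z) + 1e-12)
  }
  # reflections are not allowed: mirrored chiral set cannot reach zero
  x <- matrix(rnorm(20 * 3, sd = 5), ncol = 3)
  y <- x %*% diag(c(1, 1, -1))
  expect_gt(kabsch_superpose(x, y)$rmsd, 0.1)
  # collinear sets are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|collinear")
})

test_that("Kabsch RMSD matches brute-force rotation search on small cases", {
  set.seed(7)
  x <- matrix(rnorm(8 * 3, sd = 3), ncol = 3)
  y <- matrix(rnorm(8 * 3, sd = 3), ncol = 3)
  best <- Inf
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  for (i in 1:3000) {
    R <- fragcoalesce:::random_rotation()
    best <- min(best, oracle_rmsd(xc %*% t(R), yc))
  }
  fit <- kabsch_superpose(x, y)
  expect_lte(fit$rmsd, best + 1e-9)
  expect_gt(best, fit$rmsd - 0.5)  # dense sampling comes close
})

test_that("pair geometry of a perfect continuation and the native range", {
  bb <- curved_backbone(15)
  a <- fragment_pose(1, "a", cut_window(bb, 1))
  b <- fragment_pose(2, "b", cut_window(bb, 7))
  g <- pair_geometry(a, b)
  expect_equal(g$max_overlap_pair_distance, 0, tolerance = 1e-9)
  expect_equal(g$overlap_angle_cos, 1, tolerance = 1e-9)

  # consecutive windows of generated native chains stay inside the
  # disorder-derived overlap-distance band
  for (seed in 1:5) {
    cx <- generate_complex(L = 15, n_near = 0, n_random = 0, seed = seed)
    ga <- pair_geometry(pool_pose(cx$pools[[1]], 1), pool_pose(cx$pools[[2]], 1))
    expect_gte(ga$overlap_residue_distance, 5.2)
    expect_lte(ga$overlap_residue_distance, 13.6)
  }
})

test_that("pair geometry equals an independent loop-based recomputation", {
  set.seed(3)
  oracle_pair <- function(A, B, sep, l = 9) {
    res_of <- rep(1:l, each = 4)
    mind <- Inf
    for (i in 1:(l * 4)) for (j in 1:(l * 4)) {
      if (sep == 1 && abs(res_of[j] - res_of[i] + (l - 3)) <= 1) next
      mind <- min(mind, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
    ca <- function(M, r) M[(r - 1) * 4 + 2, ]
    out <- list(min_atom_distance = mind,
                midpoint_distance = sqrt(sum((ca(A, 5) - ca(B, 5))^2)))
    if (sep == 1) {
      out$overlap_residue_distance <- sqrt(sum((ca(A, 6) - ca(B, 4))^2))
      mx <- 0
      for (r in 0:2) for (at in 1:4) {
        i <- (6 + r) * 4 + at; j <- r * 4 + at
        mx <- max(mx, sqrt(sum((A[i, ] - B[j, ])^2)))
      }
      out$max_overlap_pair_distance <- mx
      va <- A[9 * 4, ] - A[6 * 4 + 1, ]
      vb <- B[3 * 4, ] - B[1, ]
      out$overlap_angle_cos <- sum(va * vb) /
        sqrt(sum(va^2) * sum(vb^2))
    }
    out
  }
  bb <- curved_backbone(21)
  for (i in 1:15) {
    sep <- sample(1:2, 1)
    A <- random_placed_pose(cut_window(bb, 1))
    B <- random_placed_pose(cut_window(bb, 7))
    a <- fragment_pose(1, "a", A); b <- fragment_pose(1 + sep, "b", B)
    g <- pair_geometry(a, b)
    o <- oracle_pair(A, B, sep)
    expect_equal(g$min_atom_distance, o$min_atom_distance, tolerance = 1e-9)
    expect_equal(g$midpoint_distance, o$midpoint_distance, tolerance = 1e-9)
    if (sep == 1) {
      expect_equal(g$overlap_residue_distance, o$overlap_residue_distance,
                   tolerance = 1e-9)
      expect_equal(g$max_overlap_pair_distance, o$max_overlap_pair_distance,
                   tolerance = 1e-9)
      expect_equal(g$overlap_angle_cos, o$overlap_angle_cos, tolerance = 1e-9)
    }
  }
  expect_error(pair_geometry(b, a), "positive")
})

test_that("pair geometry is invariant under joint rigid transforms", {
  set.seed(4)
  bb <- curved_backbone(15)
  A <- random_placed_pose(cut_window(bb, 1))
  B <- random_placed_pose(cut_window(bb, 7))
  g0 <- pair_geometry(fragment_pose(1, "a", A), fragment_pose(2, "b", B))
  for (i in 1:5) {
    tr <- random_rigid()
    g1 <- pair_geometry(fragment_pose(1, "a", apply_rigid(A, tr)),
                        fragment_pose(2, "b", apply_rigid(B, tr)))
    for (f in c("min_atom_distance", "midpoint_distance",
                "overlap_residue_distance", "max_overlap_pair_distance",
                "overlap_angle_cos")) {
      expect_equal(g1[[f]], g0[[f]], tolerance = 1e-6)
    }
  }
})

test_that("overlap MSD matches closed forms and a 12-term hand sum", {
  bb <- curved_backbone(15)
  a <- fragment_pose(1, "a", cut_window(bb, 1))
  b <- fragment_pose(2, "b", cut_window(bb, 7))
  expect_equal(overlap_msd(a, b), 0)

  # shifting the downstream fragment by 2 A gives 4 A^2
  b2 <- fragment_pose(2, "b2", sweep(cut_window(bb, 7), 2, c(2, 0, 0), "+"))
  expect_equal(overlap_msd(a, b2), 4.0, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    A <- random_placed_pose(cut_window(bb, 1))
    B <- random_placed_pose(cut_window(bb, 7))
    s <- 0
    for (r in 0:2) for (at in 1:4) {
      s <- s + sum((A[(6 + r) * 4 + at, ] - B[r * 4 + at, ])^2)
    }
    expect_equal(overlap_msd(fragment_pose(1, "a", A), fragment_pose(2, "b", B)),
                 s / 12, tolerance = 1e-9)
  }
  c3 <- fragment_pose(3, "c", cut_window(bb, 7))
  expect_error(overlap_msd(a, c3), "consecutive")
})
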