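# spreadsheet-style recomputation of the combined score, independent of the
# package implementation
oracle_combined <- function(zmat, w, w5) {
  out <- numeric(nrow(zmat))
  for (i in seq_len(nrow(zmat))) {
    out[i] <- w5 * sum(w * zmat[i, ]) + (1 - w5) * min(zmat[i, ])
  }
  out
}
oracle_z <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / length(x))
  if (s == 0) rep(0, length(x)) else (x - m) / s
}

test_that("Z-scores use the population sd and handle degenerate input", {
  expect_equal(zscores(c(1, 2, 3)), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(zscores(rep(7, 5)), rep(0, 5))
  set.seed(1)
  x <- rnorm(50)
  z <- zscores(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(zscores(c(1, NA)), "finite")
})

test_that("DI score is the two-channel Z sum and tracks pose quality", {
  set.seed(2)
  x <- rnorm(30)
  tab <- data.frame(a = x, b = x)
  expect_equal(di_score(tab, c("a", "b")), 2 * zscores(x))
  # anti-correlated channels of equal variance cancel exactly
  tab2 <- data.frame(a = x, b = -x)
  expect_equal(di_score(tab2), rep(0, 30), tolerance = 1e-12)
  # channels built as RMSD + noise rank poses like the RMSD
  rmsd <- runif(300, 0, 20)
  tab3 <- data.frame(a = rmsd + rnorm(300, 0, 4), b = rmsd + rnorm(300, 0, 4))
  expect_gt(cor(di_score(tab3), rmsd, method = "spearman"), 0)
  expect_error(di_score(tab3, c("a", "zz")), "not found")
})

test_that("top-k selection matches a sort-based oracle and breaks ties by id", {
  set.seed(3)
  s <- sample(rep(1:5, each = 4))
  ids <- sprintf("m%02d", seq_along(s))
  sel <- select_top(s, 7, ids)
  ord <- order(s, ids)
  expect_equal(sel, ord[1:7])
  expect_equal(select_top(s, length(s), ids), ord)
  expect_equal(select_top(c(3, 1, 2), 1), 2L)
  expect_warning(sel2 <- select_top(c(2, 1), 5), "only 2")
  expect_equal(sel2, c(2L, 1L))
})

test_that("path component scores match the defining formulas", {
  cx <- generate_complex(L = 21, n_near = 12, n_random = 30, seed = 5)
  compat <- suppressWarnings(filter_pools(cx$pools))
  pose_di <- lapply(cx$pools, function(p) {
    di <- di_score(p$channels); names(di) <- p$pose_ids; di
  })
  paths <- assemble(cx$pools, compat, cluster_params(2.0), pose_di)
  paths <- path_component_scores(paths, pose_di, cx$receptor)
  comp <- paths$component_scores
  np <- n_paths(paths)
  expect_true(np >= 2)

  # S_E: mean DI of member poses
  for (r in seq_len(min(np, 10))) {
    dis <- sapply(1:3, function(ci) pose_di[[ci]][paths$poses[r, ci]])
    expect_equal(comp$S_E[r], mean(dis), tolerance = 1e-9)
  }
  # S_O: mean overlap MSD across the two junctions (hand-summed Eq-style)
  for (r in seq_len(min(np, 10))) {
    msds <- sapply(1:2, function(n) {
      a <- fragment_pose(n, "a",
                         fragcoalesce:::unflatten_bb(paths$coords[r, (n - 1) * 108 + 1:108]))
      b <- fragment_pose(n + 1, "b",
                         fragcoalesce:::unflatten_bb(paths$coords[r, n * 108 + 1:108]))
      overlap_msd(a, b)
    })
    expect_equal(comp$S_O[r], mean(msds), tolerance = 1e-9)
  }
  # S_R consensus: recompute N_op by brute force
  rec <- cx$receptor$atoms
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  contacts <- lapply(seq_len(np), function(r) {
    lig <- fragcoalesce:::unflatten_bb(paths$coords[r, ])
    hit <- unique(rec$residue_index[apply(fragcoalesce:::cross_dist(lig, rec_xyz) <= 5, 2, any)])
    hit
  })
  nop <- table(unlist(contacts))
  for (r in seq_len(np)) {
    expect_equal(unname(comp$S_R[r]), sum(nop[as.character(contacts[[r]])]))
  }
  # a single path occupying residues alone would have S_R = its contact count
  solo <- fragcoalesce:::subset_paths(paths, 1)
  solo <- path_component_scores(solo, pose_di, cx$receptor)
  expect_equal(unname(solo$component_scores$S_R[1]), length(contacts[[1]]))
})

test_that("Path Score matches the weighted Z-combination and its reductions", {
  set.seed(6)
  comp <- data.frame(S_E = rnorm(40), S_O = rexp(40), S_C = rpois(40, 5) + 1,
                     S_R = rpois(40, 50))
  zm <- cbind(oracle_z(comp$S_E), oracle_z(comp$S_O),
              oracle_z(-comp$S_C), oracle_z(-comp$S_R))
  # trained default weights
  sp <- path_score(comp)
  expect_equal(sp, oracle_combined(zm, c(0.5, 0.1, 0.3, 0.1), 0.3),
               tolerance = 1e-9)
  # reduction: all weight on S_E with no min term ranks exactly like Z(S_E)
  sp1 <- path_score(comp, score_weights(1, 0, 0, 0, 1))
  expect_equal(order(sp1), order(zm[, 1]))
  # random weights against the spreadsheet oracle
  for (i in 1:10) {
    w <- diff(c(0, sort(runif(3)), 1))
    w5 <- runif(1, 0.1, 1)
    sp2 <- path_score(comp, score_weights(w[1], w[2], w[3], w[4], w5))
    expect_equal(sp2, oracle_combined(zm, w, w5), tolerance = 1e-9)
  }
  expect_error(score_weights(0.5, 0.5, 0.5, 0.5, 0.3), "equal 1")
  expect_error(score_weights(0.25, 0.25, 0.25, 0.25, 0), "w5")
})

test_that("Model Score combines four channels like the Path Score", {
  set.seed(7)
  tab <- data.frame(itscorepro = rnorm(30), dfire = rnorm(30),
                    molmech = rnorm(30), goap = rnorm(30))
  zm <- vapply(tab, oracle_z, numeric(30))
  sm <- model_score(tab)   # trained defaults 0.1/0.2/0.3/0.4, w5 = 0.3
  expect_equal(sm, oracle_combined(zm, c(0.1, 0.2, 0.3, 0.4), 0.3),
               tolerance = 1e-9)
  # one informative channel with all weight and w5 = 1 ranks like that channel
  sm2 <- model_score(tab, score_weights(0, 0, 1, 0, 1))
  expect_equal(order(sm2), order(tab$molmech))
  expect_error(model_score(tab[, 1:3]), "4 channels")
})

test_that("scores are invariant under affine rescaling of raw channels", {
  set.seed(8)
  comp <- data.frame(S_E = rnorm(25), S_O = rexp(25), S_C = rpois(25, 4) + 1,
                     S_R = rpois(25, 30))
  sp0 <- path_score(comp)
  comp2 <- comp
  comp2$S_E <- 100 + 7 * comp$S_E      # positive affine map
  comp2$S_O <- 0.01 * comp$S_O
  expect_equal(path_score(comp2), sp0, tolerance = 1e-9)

  tab <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25), d = rnorm(25))
  expect_equal(model_score(data.frame(a = 3 * tab$a - 2, b = tab$b,
                                      c = tab$c, d = tab$d)),
               model_score(tab), tolerance = 1e-9)
})

test_that("improving S_E never worsens the rank when w1 > 0 and w5 = 1", {
  set.seed(9)
  comp <- data.frame(S_E = rnorm(20), S_O = rexp(20), S_C = rpois(20, 4) + 1,
                     S_R = rpois(20, 30))
  w <- score_weights(0.5, 0.2, 0.2, 0.1, 1)
  s0 <- path_score(comp, w)
  r0 <- rank(s0)[3]
  comp$S_E[3] <- comp$S_E[3] - 2
  s1 <- path_score(comp, w)
  expect_lte(rank(s1)[3], r0)
})

test_that("grid-search training recovers a planted signal and equals enumeration", {
  # planted optimum: the energy term cleanly separates hits while the three
  # remaining components share one graded adversarial pattern, so recall is
  # strictly increasing in w1 and the unique optimum is (0.7, 0.1, 0.1, 0.1)
  make_set <- function() {
    i <- 1:10
    hits <- c(rep(TRUE, 10), rep(FALSE, 20))
    dvals <- c(2 * i, -2 * (1:10), rep(0, 10))
    sc <- data.frame(S_E = c(-1 + i * 1e-4, (1:20) * 1e-4),
                     S_O = dvals, S_C = -dvals, S_R = -dvals)
    list(scores = sc, hits = hits)
  }
  sets <- list(make_set(), make_set())
  tr <- train_weights(sets, "maximin_recall", retrieved_k = 10)
  expect_equal(tr$weights$w[1], 0.7)   # maximal grid weight on the informative term
  expect_equal(tr$weights$w[2:4], rep(0.1, 3))

  # objective equals a full independent enumeration of the two-stage grid
  zms <- lapply(sets, function(s) {
    cbind(oracle_z(s$scores$S_E), oracle_z(s$scores$S_O),
          oracle_z(-s$scores$S_C), oracle_z(-s$scores$S_R))
  })
  eval_one <- function(w, w5) {
    min(mapply(function(zm, s) {
      sc <- oracle_combined(zm, w, w5)
      ord <- order(sc, seq_along(sc))
      sum(s$hits[ord[1:10]]) / sum(s$hits)
    }, zms, sets))
  }
  best <- -Inf; best_w <- NULL
  for (a in 1:7) for (b in 1:7) for (c in 1:7) {
    d <- 10 - a - b - c
    if (d < 1 || d > 7) next
    v <- eval_one(c(a, b, c, d) / 10, 1)
    if (v > best + 1e-12) { best <- v; best_w <- c(a, b, c, d) / 10 }
  }
  best5 <- -Inf
  for (w5 in seq(0.1, 1, 0.1)) {
    v <- eval_one(best_w, w5)
    if (v > best5 + 1e-12) best5 <- v
  }
  expect_equal(tr$value, best5, tolerance = 1e-12)
  expect_equal(tr$weights$w, best_w)

  # duplicated training sets change nothing
  tr3 <- train_weights(list(sets[[1]], sets[[1]]), "maximin_recall", retrieved_k = 10)
  tr1 <- train_weights(sets[1], "maximin_recall", retrieved_k = 10)
  expect_equal(tr3$weights, tr1$weights)
  expect_equal(tr3$value, tr1$value)

  # hitless sets are excluded with a warning; all-hitless errors
  hitless <- make_set(); hitless$hits[] <- FALSE
  expect_warning(train_weights(c(sets, list(hitless)), retrieved_k = 10),
                 "hitless")
  expect_error(suppressWarnings(train_weights(list(hitless))), "hitless")

  # mean-RFH objective runs and returns a sane value
  trm <- train_weights(sets, "mean_rfh")
  expect_gte(trm$value, 1)
})

test_that("the interface pre-filter keeps models agreeing with the prediction", {
  cx <- generate_complex(L = 9, n_near = 0, n_random = 0, seed = 12)
  nat <- cx$native_bb
  # the model matching the native interface among far-displaced ones passes
  far <- lapply(1:9, function(i) sweep(nat, 2, c(40 + 5 * i, 0, 0), "+"))
  models <- c(list(nat), far)
  predicted <- unique(cx$receptor$atoms$residue_index[
    apply(fragcoalesce:::cross_dist(as.matrix(cx$receptor$atoms[, c("x", "y", "z")]),
                                    nat) <= 5, 1, any)])
  res <- interface_filter(models, predicted, cx$receptor)
  expect_equal(res$keep, 1L)
  expect_gte(res$z[1], 1.5)

  # identical models: all Z = 0, none pass, pass-through with warning
  same <- replicate(5, nat, simplify = FALSE)
  expect_warning(res2 <- interface_filter(same, predicted, cx$receptor),
                 "pass")
  expect_equal(res2$keep, 1:5)

  # empty prediction: pass-through with warning
  expect_warning(res3 <- interface_filter(models, integer(0), cx$receptor),
                 "empty")
  expect_equal(res3$keep, seq_along(models))
})
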