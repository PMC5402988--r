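# reference greedy-leader clustering, written as an explicit step-by-step
# loop independent of the package implementation
reference_leader <- function(coords, score, cutoff, ids) {
  ord <- order(score, ids)
  reps <- integer(0)
  assign <- integer(nrow(coords))
  for (i in ord) {
    joined <- FALSE
    for (ri in seq_along(reps)) {
      d <- oracle_rmsd(matrix(coords[i, ], ncol = 3, byrow = TRUE),
                       matrix(coords[reps[ri], ], ncol = 3, byrow = TRUE))
      if (d <= cutoff) { assign[i] <- ri; joined <- TRUE; break }
    }
    if (!joined) { reps <- c(reps, i); assign[i] <- length(reps) }
  }
  list(representatives = reps, assignment = assign)
}

test_that("greedy leader clustering merges correctly and matches the reference", {
  set.seed(1)
  x <- matrix(rnorm(27), 1)
  five <- do.call(rbind, replicate(5, x, simplify = FALSE))
  cl <- cluster_items(five, rmsd_cutoff = 4)
  expect_equal(length(cl$representatives), 1)
  expect_equal(cl$sizes, 5)

  two <- rbind(x, x + 10)
  cl2 <- cluster_items(two, rmsd_cutoff = 4)
  expect_equal(length(cl2$representatives), 2)

  for (trial in 1:5) {
    coords <- matrix(rnorm(50 * 27, sd = 3), nrow = 50)
    score <- rnorm(50)
    ids <- sprintf("p%02d", 1:50)
    cl <- cluster_items(coords, score, rmsd_cutoff = 4, ids = ids)
    ref <- reference_leader(coords, score, 4, ids)
    expect_equal(cl$representatives, ref$representatives)
    expect_equal(cl$assignment, ref$assignment)
    expect_equal(sum(cl$sizes), 50)
  }

  # cutoff 0 disables merging
  cl0 <- cluster_items(five, rmsd_cutoff = 0)
  expect_equal(length(cl0$representatives), 5)
})

test_that("extension enforces compatibility with every covered window", {
  inst <- random_instance(k = 3, n = 8, seed = 5)
  compat <- suppressWarnings(filter_pools(inst$pools))
  partials <- fragcoalesce:::initial_paths(inst$pools[[1]])
  p2 <- extend_paths(partials, inst$pools[[2]], compat)
  # each extended pair is exactly an allowed pair
  m12 <- compat[["1-2"]]
  expect_equal(n_paths(p2), sum(m12))
  for (r in seq_len(n_paths(p2))) {
    expect_true(m12[p2$poses[r, 1], p2$poses[r, 2]])
  }
  # all-pairs semantics: a pose must also be compatible with window 1's pose
  p3 <- extend_paths(p2, inst$pools[[3]], compat)
  m13 <- compat[["1-3"]]; m23 <- compat[["2-3"]]
  # brute-force filter of all (partial, pose) combinations
  expected <- 0L
  for (r in seq_len(n_paths(p2))) for (j in 1:8) {
    if (m13[p2$poses[r, 1], j] && m23[p2$poses[r, 2], j]) expected <- expected + 1L
  }
  expect_equal(n_paths(p3), expected)
  for (r in seq_len(n_paths(p3))) {
    expect_true(m13[p3$poses[r, 1], p3$poses[r, 3]])
    expect_true(m23[p3$poses[r, 2], p3$poses[r, 3]])
  }
})

test_that("native-only pools assemble to exactly the native path", {
  cx <- generate_complex(L = 21, n_near = 0, n_random = 0, seed = 3)
  compat <- filter_pools(cx$pools)
  paths <- assemble(cx$pools, compat, cluster_params(4.0))
  expect_equal(n_paths(paths), 1)
  native_concat <- unlist(lapply(1:3, function(n) cx$pools[[n]]$flat[1, ]))
  expect_equal(unname(paths$coords[1, ]), unname(native_concat))
})

test_that("with clustering disabled, assembly equals the brute-force enumeration", {
  for (seed in c(7, 8, 9)) {
    inst <- random_instance(k = 3, n = 12, seed = seed)
    compat <- suppressWarnings(filter_pools(inst$pools))
    bf <- brute_force_paths(inst$pools, compat)
    if (n_paths(bf) == 0) next
    asm <- assemble(inst$pools, compat, cluster_params(0))
    key <- function(p) sort(apply(p$poses, 1, paste, collapse = "|"))
    expect_equal(key(asm), key(bf))
  }
})

test_that("with clustering enabled, outputs are valid and cover the brute-force set", {
  covered_any <- FALSE
  for (seed in c(12, 13, 14)) {
    inst <- random_instance(k = 3, n = 12, seed = seed)
    compat <- suppressWarnings(filter_pools(inst$pools))
    bf <- brute_force_paths(inst$pools, compat)
    if (n_paths(bf) == 0) next
    asm <- assemble(inst$pools, compat, cluster_params(4.0))
    key <- function(p) apply(p$poses, 1, paste, collapse = "|")
    # subset: every clustered path is a valid brute-force path
    expect_true(all(key(asm) %in% key(bf)))
    # coverage: every brute-force path is within the cutoff of some output
    ca_cols <- fragcoalesce:::path_ca_cols(3)
    for (r in seq_len(n_paths(bf))) {
      d <- apply(asm$coords[, ca_cols, drop = FALSE], 1, function(v) {
        sqrt(mean(colSums((matrix(v, 3) - matrix(bf$coords[r, ca_cols], 3))^2)))
      })
      expect_lte(min(d), 4.0)
    }
    # merged weights cannot exceed the number of enumerable paths
    expect_lte(sum(asm$sizes), n_paths(bf))
    covered_any <- TRUE
  }
  expect_true(covered_any)
})

test_that("brute force counts products and applies constraints", {
  inst <- random_instance(k = 2, n = 4, seed = 20)
  # force an all-allowed map
  allow <- matrix(TRUE, 3, 4,
                  dimnames = list(inst$pools[[1]]$pose_ids[1:3],
                                  inst$pools[[2]]$pose_ids))
  compat <- structure(list("1-2" = allow), class = "compat_map")
  p1 <- pool_subset(inst$pools[[1]], 1:3)
  bf <- brute_force_paths(list(p1, inst$pools[[2]]), compat)
  expect_equal(n_paths(bf), 12)

  none <- allow; none[] <- FALSE
  compat0 <- structure(list("1-2" = none), class = "compat_map")
  expect_equal(n_paths(brute_force_paths(list(p1, inst$pools[[2]]), compat0)), 0)

  # self-check: every returned path passes check_pair on every window pair
  inst3 <- random_instance(k = 3, n = 8, seed = 22)
  compat3 <- suppressWarnings(filter_pools(inst3$pools))
  bf3 <- brute_force_paths(inst3$pools, compat3)
  for (r in seq_len(min(n_paths(bf3), 30))) {
    for (wi in 1:2) for (wj in (wi + 1):3) {
      v <- check_pair(pool_pose(inst3$pools[[wi]], bf3$poses[r, wi]),
                      pool_pose(inst3$pools[[wj]], bf3$poses[r, wj]))
      expect_true(v$accepted)
    }
  }

  big <- random_instance(k = 3, n = 4, seed = 23)
  compatb <- suppressWarnings(filter_pools(big$pools))
  expect_error(brute_force_paths(big$pools, compatb, max_combinations = 10),
               "exceeds")
})

test_that("assembly reports a structured error when no paths survive", {
  inst <- random_instance(k = 2, n = 3, seed = 30)
  none <- matrix(FALSE, 3, 3,
                 dimnames = list(inst$pools[[1]]$pose_ids,
                                 inst$pools[[2]]$pose_ids))
  compat <- structure(list("1-2" = none), class = "compat_map")
  err <- tryCatch(assemble(inst$pools, compat), error = identity)
  expect_s3_class(err, "assembly_stage_error")
  expect_match(conditionMessage(err), "window 2")
})
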