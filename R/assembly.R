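# Path assembly: build full-length paths from per-window pose pools with an
# extend-and-cluster strategy, plus an exhaustive enumerator used as a test
# oracle and for small problems.

#' Clustering parameters for path assembly
#'
#' @param rmsd_cutoff Leader-clustering RMSD cutoff in Angstrom (default
#'   4.0). A value of 0 disables clustering (every path kept).
#' @param ranking Label for the score that orders candidate cluster centers
#'   (informational; the assembly functions take the scores themselves).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(rmsd_cutoff = 4.0, ranking = "energy") {
  if (rmsd_cutoff < 0) stopf("rmsd_cutoff must be >= 0")
  structure(list(rmsd_cutoff = rmsd_cutoff, ranking = ranking),
            class = "cluster_params")
}

#' Greedy leader clustering of coordinate items
#'
#' Items are visited in ranking order (ties broken by id); each item joins
#' the first existing representative whose in-frame RMSD to it is within the
#' cutoff, otherwise it founds a new cluster. Deterministic; cluster counts
#' sum to the total input weight.
#'
#' @param coords Numeric n x (3m) matrix of flattened coordinates, one item
#'   per row.
#' @param score Numeric ranking score per item (lower visits first).
#' @param rmsd_cutoff RMSD cutoff in Angstrom; 0 disables merging.
#' @param sizes Prior weight per item (default 1); merged clusters sum the
#'   weights of their members.
#' @param ids Character ids used for deterministic tie-breaking.
#' @return List with `representatives` (integer indices of the founding
#'   items, in founding order), `assignment` (for each input item, the index
#'   into `representatives` of its cluster), and `sizes` (summed weights per
#'   cluster).
#' @export
cluster_items <- function(coords, score = rep(0, nrow(coords)),
                          rmsd_cutoff = 4.0,
                          sizes = rep(1, nrow(coords)),
                          ids = as.character(seq_len(nrow(coords)))) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) {
    return(list(representatives = integer(0), assignment = integer(0),
                sizes = numeric(0)))
  }
  natoms <- ncol(coords) / 3
  visit <- order(score, ids)
  if (rmsd_cutoff <= 0) {
    reps <- visit
    assignment <- integer(n)
    assignment[visit] <- seq_len(n)
    return(list(representatives = reps, assignment = assignment,
                sizes = sizes[reps]))
  }
  rep_coords <- matrix(NA_real_, n, ncol(coords))
  rep_norm2 <- numeric(n)
  rep_idx <- integer(n)
  assignment <- integer(n)
  m <- 0L
  cut2 <- rmsd_cutoff^2 * natoms
  # Blocked greedy leader pass. Items are processed in visitation order in
  # chunks: squared distances of a whole chunk to all current representatives
  # come from one crossproduct (BLAS); an item within the cutoff of any
  # pre-chunk representative joins the earliest-founded match (identical to
  # the sequential rule, since representatives founded later in the same
  # chunk always have larger founding indices). Only items matching no
  # earlier representative fall through to the sequential founding loop.
  chunk_size <- 512L
  pos <- 1L
  while (pos <= n) {
    idx <- visit[pos:min(n, pos + chunk_size - 1L)]
    pending <- idx
    if (m > 0L) {
      X <- coords[idx, , drop = FALSE]
      R <- rep_coords[seq_len(m), , drop = FALSE]
      d2 <- outer(rowSums(X^2), rep_norm2[seq_len(m)], "+") - 2 * tcrossprod(X, R)
      hitmat <- d2 <= cut2
      first_hit <- integer(length(idx))
      anyhit <- rowSums(hitmat) > 0L
      first_hit[anyhit] <- max.col(hitmat[anyhit, , drop = FALSE],
                                   ties.method = "first")
      assignment[idx[anyhit]] <- first_hit[anyhit]
      pending <- idx[!anyhit]
    }
    m0 <- m   # pending items matched no representative founded before this
              # chunk, so only chunk-local representatives need checking
    for (i in pending) {
      x <- coords[i, ]
      hit <- 0L
      if (m > m0) {
        rr <- (m0 + 1L):m
        ss <- rep_norm2[rr] + sum(x^2) -
          2 * drop(rep_coords[rr, , drop = FALSE] %*% x)
        w <- which(ss <= cut2)
        if (length(w) > 0L) hit <- rr[w[1]]
      }
      if (hit == 0L) {
        m <- m + 1L
        rep_coords[m, ] <- x
        rep_norm2[m] <- sum(x^2)
        rep_idx[m] <- i
        assignment[i] <- m
      } else {
        assignment[i] <- hit
      }
    }
    pos <- pos + chunk_size
  }
  rs <- rowsum(as.numeric(sizes), assignment)
  csizes <- rs[order(as.integer(rownames(rs))), 1]
  list(representatives = rep_idx[seq_len(m)], assignment = assignment,
       sizes = unname(csizes))
}

#' @keywords internal
new_path_set <- function(windows, poses, coords, sizes, l = 9L) {
  structure(list(
    windows = as.integer(windows),
    poses = poses,            # n x k character matrix of pose ids
    coords = coords,          # n x (l*4*3*k) flattened backbones
    sizes = as.numeric(sizes),# cluster size S_C per path
    l = as.integer(l),
    component_scores = NULL,
    stage_counts = NULL
  ), class = "path_set")
}

#' Number of paths in a path set
#' @param paths A `path_set`.
#' @return Integer path count.
#' @export
n_paths <- function(paths) nrow(paths$poses)

# flat columns of the CA atoms across all window blocks of a path
#' @keywords internal
path_ca_cols <- function(k, l = 9L) {
  one <- flat_cols(bb_row(seq_len(l), "CA"))
  block <- l * N_BB_ATOMS * 3L
  as.vector(outer(one, (seq_len(k) - 1L) * block, "+"))
}

#' @keywords internal
initial_paths <- function(pool) {
  new_path_set(
    windows = pool$window_index,
    poses = matrix(pool$pose_ids, ncol = 1,
                   dimnames = list(NULL, as.character(pool$window_index))),
    coords = unname(pool$flat),
    sizes = rep(1, pool_size(pool)),
    l = pool$l
  )
}

#' Extend partial paths by one window
#'
#' Forms every combination of a partial path and a pose from the next
#' window's pool in which the new pose is compatible with every pose already
#' in the partial (the all-window-pairs constraint), looking compatibility
#' up in the precomputed map. Cluster sizes are inherited.
#'
#' @param partials A `path_set` covering windows 1..k.
#' @param next_pool The [pose_pool()] of the next window.
#' @param compat A `compat_map` from [filter_pools()].
#' @return A `path_set` covering one more window (possibly with zero rows).
#' @export
extend_paths <- function(partials, next_pool, compat) {
  wn <- next_pool$window_index
  if (any(partials$windows >= wn)) {
    stopf("next_pool (window %d) must come after all covered windows", wn)
  }
  k <- length(partials$windows)
  np <- n_paths(partials)
  nb <- pool_size(next_pool)
  mats <- lapply(partials$windows, function(w) {
    m <- compat[[compat_key(w, wn)]]
    if (is.null(m)) stopf("compatibility map lacks window pair %d-%d", w, wn)
    m[, next_pool$pose_ids, drop = FALSE]
  })
  rows <- lapply(seq_along(partials$windows), function(ci) {
    match(partials$poses[, ci], rownames(mats[[ci]]))
  })
  js_per <- vector("list", np)
  for (i in seq_len(np)) {
    allowed <- mats[[1]][rows[[1]][i], ]
    if (k > 1L) {
      for (ci in 2:k) allowed <- allowed & mats[[ci]][rows[[ci]][i], ]
    }
    js_per[[i]] <- which(allowed)
  }
  cnt <- lengths(js_per)
  keep_i <- rep.int(seq_len(np), cnt)
  keep_j <- unlist(js_per, use.names = FALSE)
  if (is.null(keep_j)) keep_j <- integer(0)
  coords <- cbind(partials$coords[keep_i, , drop = FALSE],
                  unname(next_pool$flat)[keep_j, , drop = FALSE])
  poses <- cbind(partials$poses[keep_i, , drop = FALSE],
                 next_pool$pose_ids[keep_j])
  colnames(poses) <- c(colnames(partials$poses), as.character(wn))
  new_path_set(c(partials$windows, wn), poses, coords,
               partials$sizes[keep_i], partials$l)
}

#' Assemble full-length paths by extend-and-cluster
#'
#' Combines allowed pose pairs of the first two windows, clusters them with
#' the RMSD cutoff, extends to three windows, clusters again, and repeats
#' until all windows are covered. Clustering is greedy leader clustering on
#' the concatenated CA coordinates of the covered windows, visiting paths in
#' order of their ranking score (mean per-pose score, e.g. the DI score).
#' The final paths carry the cluster size S_C.
#'
#' @param pools List of [pose_pool()] objects ordered by window index.
#' @param compat A `compat_map` from [filter_pools()].
#' @param params A [cluster_params()] object.
#' @param pose_scores Optional list (parallel to `pools`) of numeric
#'   per-pose ranking scores, lower better; defaults to zeros (ordering then
#'   falls back to pose ids).
#' @return A `path_set` covering all windows, with `sizes` = S_C and a
#'   `stage_counts` data frame (stage label, paths after extension "P" and
#'   after clustering "C") recording the search-space reduction.
#' @export
assemble <- function(pools, compat, params = cluster_params(),
                     pose_scores = NULL) {
  if (length(pools) < 2L) stopf("need at least 2 windows to assemble")
  if (is.null(pose_scores)) {
    pose_scores <- lapply(pools, function(p) rep(0, pool_size(p)))
  }
  paths <- initial_paths(pools[[1]])
  score <- pose_scores[[1]]   # running sum of pose scores per path
  stages <- list()
  for (s in 2:length(pools)) {
    paths <- extend_paths(paths, pools[[s]], compat)
    if (n_paths(paths) == 0L) {
      stop(errorCondition(
        sprintf("no surviving paths after extending to window %d",
                pools[[s]]$window_index),
        class = c("assembly_stage_error", "error"),
        stage = sprintf("%dP", s)))
    }
    stages[[sprintf("%dP", s)]] <- n_paths(paths)
    prev_score <- score_for_paths(paths, pose_scores, pools)
    # S_C counts the member paths of the current clustering stage (each
    # entering path counts once, regardless of earlier merges)
    cl <- cluster_items(
      coords = paths$coords[, path_ca_cols(s, paths$l), drop = FALSE],
      score = prev_score,
      rmsd_cutoff = params$rmsd_cutoff,
      ids = apply(paths$poses, 1, paste, collapse = "|")
    )
    paths <- subset_paths(paths, cl$representatives)
    paths$sizes <- cl$sizes
    stages[[sprintf("%dC", s)]] <- n_paths(paths)
  }
  paths$stage_counts <- data.frame(
    stage = names(stages),
    paths = as.integer(unlist(stages)),
    row.names = NULL
  )
  paths
}

#' @keywords internal
score_for_paths <- function(paths, pose_scores, pools) {
  k <- length(paths$windows)
  total <- numeric(n_paths(paths))
  for (ci in seq_len(k)) {
    pool <- pools[[ci]]
    total <- total + pose_scores[[ci]][match(paths$poses[, ci], pool$pose_ids)]
  }
  total / k
}

#' @keywords internal
subset_paths <- function(paths, idx) {
  out <- new_path_set(paths$windows,
                      paths$poses[idx, , drop = FALSE],
                      paths$coords[idx, , drop = FALSE],
                      paths$sizes[idx], paths$l)
  if (!is.null(paths$component_scores)) {
    out$component_scores <- paths$component_scores[idx, , drop = FALSE]
  }
  out$stage_counts <- paths$stage_counts
  out
}

#' Enumerate all valid paths by brute force
#'
#' Expands the full cross-product of pose choices (one per window) and keeps
#' the combinations in which every ordered window pair is compatible. Used
#' as the assembly oracle and for very small problems.
#'
#' @param pools List of [pose_pool()] objects ordered by window index.
#' @param compat A `compat_map` from [filter_pools()].
#' @param max_combinations Safety bound on the cross-product size.
#' @return A `path_set` with `sizes` all 1.
#' @export
brute_force_paths <- function(pools, compat, max_combinations = 1e6) {
  sizes <- vapply(pools, pool_size, integer(1))
  if (prod(sizes) > max_combinations) {
    stopf("cross-product of pool sizes (%g) exceeds the bound (%g)",
          prod(sizes), max_combinations)
  }
  wins <- vapply(pools, function(p) p$window_index, integer(1))
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE))
  keep <- rep(TRUE, nrow(grid))
  for (ii in seq_along(pools)) {
    for (jj in seq_along(pools)) {
      if (wins[jj] <= wins[ii]) next
      m <- compat[[compat_key(wins[ii], wins[jj])]]
      keep <- keep & m[cbind(grid[, ii], grid[, jj])]
    }
  }
  grid <- grid[keep, , drop = FALSE]
  poses <- vapply(seq_along(pools),
                  function(ci) pools[[ci]]$pose_ids[grid[, ci]],
                  character(nrow(grid)))
  if (nrow(grid) == 1L) poses <- matrix(poses, nrow = 1)
  if (nrow(grid) == 0L) poses <- matrix(character(0), 0, length(pools))
  colnames(poses) <- as.character(wins)
  coords <- do.call(cbind, lapply(seq_along(pools), function(ci) {
    unname(pools[[ci]]$flat)[grid[, ci], , drop = FALSE]
  }))
  new_path_set(wins, poses, coords, rep(1, nrow(grid)), pools[[1]]$l)
}
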