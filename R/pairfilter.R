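# Geometric compatibility filter for ordered pairs of docked fragment
# poses. Cutoff values derive from distance distributions observed in
# disordered regions (the DisProt database); the defaults are the standard values.

#' Geometric cutoffs for fragment-pair compatibility
#'
#' @param clash_atom_min Minimum allowed fragment-fragment atom distance
#'   (Angstrom); closer pairs are rejected as clashing.
#' @param midpoint_min_neighbor Minimum midpoint (middle-residue CA) distance
#'   for consecutive windows.
#' @param midpoint_min_nonneighbor Minimum midpoint distance for
#'   non-consecutive windows.
#' @param midpoint_max_per_separation Maximum midpoint distance per window of
#'   separation (the cap is this value times the separation).
#' @param overlap_residue_min,overlap_residue_max Allowed range of the
#'   overlap residue distance (CA of the residues flanking the overlap) for
#'   consecutive windows.
#' @param overlap_pair_max Cap on the distance of every one of the 12
#'   corresponding overlap atom pairs; `strict = TRUE` switches from the
#'   permissive 10 Angstrom cap to the 6 Angstrom cap.
#' @param overlap_cos_min Minimum cosine of the overlap angle, so that only
#'   smoothly connected turns pass.
#' @param strict Use the strict 6 Angstrom overlap-pair cap.
#' @return An object of class `pair_cutoffs`.
#' @export
pair_cutoffs <- function(clash_atom_min = 3.0,
                         midpoint_min_neighbor = 6.5,
                         midpoint_min_nonneighbor = 3.8,
                         midpoint_max_per_separation = 18.5,
                         overlap_residue_min = 5.2,
                         overlap_residue_max = 13.6,
                         overlap_pair_max = if (strict) 6.0 else 10.0,
                         overlap_cos_min = 0.1,
                         strict = FALSE) {
  out <- list(
    clash_atom_min = clash_atom_min,
    midpoint_min_neighbor = midpoint_min_neighbor,
    midpoint_min_nonneighbor = midpoint_min_nonneighbor,
    midpoint_max_per_separation = midpoint_max_per_separation,
    overlap_residue_min = overlap_residue_min,
    overlap_residue_max = overlap_residue_max,
    overlap_pair_max = overlap_pair_max,
    overlap_cos_min = overlap_cos_min,
    strict = strict
  )
  num <- unlist(out[1:8])
  if (any(num <= 0)) stopf("all cutoffs must be positive")
  if (out$overlap_residue_min >= out$overlap_residue_max) {
    stopf("overlap_residue_min must be below overlap_residue_max")
  }
  class(out) <- "pair_cutoffs"
  out
}

#' Check one ordered fragment-pose pair against the cutoffs
#'
#' @param a,b `fragment_pose` objects with `a$window_index < b$window_index`.
#' @param cutoffs A [pair_cutoffs()] object.
#' @return A `pair_verdict`: list with `accepted` (logical),
#'   `failed_criteria` (character vector among `"clash"`, `"midpoint_min"`,
#'   `"midpoint_max"`, `"overlap_residue"`, `"overlap_pair"`,
#'   `"overlap_angle"`), and `geometry` (the [pair_geometry()]).
#' @export
check_pair <- function(a, b, cutoffs = pair_cutoffs()) {
  if (b$window_index <= a$window_index) {
    stopf("check_pair requires a$window_index < b$window_index")
  }
  sep <- b$window_index - a$window_index
  g <- pair_geometry(a, b, sep)
  failed <- character(0)
  if (g$min_atom_distance < cutoffs$clash_atom_min) failed <- c(failed, "clash")
  mid_min <- if (sep == 1) cutoffs$midpoint_min_neighbor else cutoffs$midpoint_min_nonneighbor
  if (g$midpoint_distance < mid_min) failed <- c(failed, "midpoint_min")
  if (g$midpoint_distance > cutoffs$midpoint_max_per_separation * sep) {
    failed <- c(failed, "midpoint_max")
  }
  if (sep == 1) {
    if (g$overlap_residue_distance < cutoffs$overlap_residue_min ||
        g$overlap_residue_distance > cutoffs$overlap_residue_max) {
      failed <- c(failed, "overlap_residue")
    }
    if (g$max_overlap_pair_distance > cutoffs$overlap_pair_max) {
      failed <- c(failed, "overlap_pair")
    }
    if (g$overlap_angle_cos < cutoffs$overlap_cos_min) {
      failed <- c(failed, "overlap_angle")
    }
  }
  structure(list(accepted = length(failed) == 0L,
                 failed_criteria = failed,
                 geometry = g),
            class = "pair_verdict")
}

# Vectorised acceptance matrix for one ordered window pair.
# Returns an n_a x n_b logical matrix (dimnames = pose ids).
#' @keywords internal
pair_accept_matrix <- function(pool_a, pool_b, cutoffs) {
  sep <- pool_b$window_index - pool_a$window_index
  stopifnot(sep >= 1L)
  l <- pool_a$l
  lm <- pair_landmarks(l)
  A <- pool_a$flat; B <- pool_b$flat
  na <- nrow(A); nb <- nrow(B)
  pt <- function(flat, row) flat[, flat_cols(row), drop = FALSE]

  mid <- cross_dist(pt(A, lm$mid_ca), pt(B, lm$mid_ca))
  mid_min <- if (sep == 1L) cutoffs$midpoint_min_neighbor else cutoffs$midpoint_min_nonneighbor
  ok <- mid >= mid_min & mid <= cutoffs$midpoint_max_per_separation * sep

  if (sep == 1L) {
    ovr <- cross_dist(pt(A, lm$a_flank_ca), pt(B, lm$b_flank_ca))
    ok <- ok & ovr >= cutoffs$overlap_residue_min & ovr <= cutoffs$overlap_residue_max

    pairmax <- matrix(0, na, nb)
    for (k in seq_along(lm$a_overlap)) {
      pairmax <- pmax(pairmax,
                      cross_dist(pt(A, lm$a_overlap[k]), pt(B, lm$b_overlap[k])))
    }
    ok <- ok & pairmax <= cutoffs$overlap_pair_max

    va <- pt(A, lm$a_vec_to) - pt(A, lm$a_vec_from)
    vb <- pt(B, lm$b_vec_to) - pt(B, lm$b_vec_from)
    cosmat <- tcrossprod(va, vb) /
      outer(sqrt(rowSums(va^2)), sqrt(rowSums(vb^2)))
    ok <- ok & cosmat >= cutoffs$overlap_cos_min
  }

  # clash screen: per-residue CA distances first, exact atom check only for
  # candidate pairs that could come within reach of the 3 A cutoff
  # max distance of N/CB/C from their own CA is ~1.6 A, so two atoms of
  # residues whose CAs are > cutoff + 3.3 A apart cannot clash
  screen <- cutoffs$clash_atom_min + 3.3
  minca <- matrix(Inf, na, nb)
  for (ra in seq_len(l)) {
    ca_a <- pt(A, bb_row(ra, "CA"))
    for (rb in seq_len(l)) {
      # residue pairs whose implied chain separation is <= 1 are never
      # clash-checked for consecutive windows (see clash_exclusion_mask)
      if (sep == 1L && abs(rb - ra + (l - 3L)) <= 1L) next
      minca <- pmin(minca, cross_dist(ca_a, pt(B, bb_row(rb, "CA"))))
    }
  }
  no_clash <- minca >= screen
  cand <- which(ok & !no_clash, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    for (q in seq_len(nrow(cand))) {
      i <- cand[q, 1]; j <- cand[q, 2]
      d <- cross_dist(unflatten_bb(A[i, ]), unflatten_bb(B[j, ]))
      if (sep == 1L) d[lm$clash_mask] <- Inf
      if (min(d) < cutoffs$clash_atom_min) ok[i, j] <- FALSE
    }
  }
  dimnames(ok) <- list(pool_a$pose_ids, pool_b$pose_ids)
  ok
}

#' @keywords internal
compat_key <- function(i, j) paste0(i, "-", j)

#' Compute the pairwise compatibility map for all window pairs
#'
#' Runs [check_pair()] (vectorised) over every ordered pair of windows and
#' every pose pair, producing the map the assembly stage consults.
#'
#' @param pools List of [pose_pool()] objects, one per window, ordered by
#'   window index.
#' @param cutoffs A [pair_cutoffs()] object.
#' @return An object of class `compat_map`: a list of logical acceptance
#'   matrices keyed `"i-j"` for windows `i < j`, with attribute `windows`.
#' @export
filter_pools <- function(pools, cutoffs = pair_cutoffs()) {
  if (length(pools) < 2L) stopf("need at least 2 windows to filter pairs")
  for (p in pools) {
    if (pool_size(p) == 0L) stopf("empty pose pool for window %d", p$window_index)
  }
  wins <- vapply(pools, function(p) p$window_index, integer(1))
  out <- list()
  for (ii in seq_along(pools)) {
    for (jj in seq_along(pools)) {
      if (wins[jj] <= wins[ii]) next
      m <- pair_accept_matrix(pools[[ii]], pools[[jj]], cutoffs)
      if (!any(m)) {
        warning(sprintf("no compatible pose pairs for windows %d and %d",
                        wins[ii], wins[jj]), call. = FALSE)
      }
      out[[compat_key(wins[ii], wins[jj])]] <- m
    }
  }
  attr(out, "windows") <- wins
  class(out) <- "compat_map"
  out
}
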