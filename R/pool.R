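# Pose pools: all docked poses of one window held in a single flat
# coordinate matrix, for vectorised filtering and assembly.

#' Create a pose pool for one window
#'
#' @param window_index 1-based window number.
#' @param poses Either a list of [fragment_pose()] objects or a numeric
#'   n x (9*4*3) matrix of flattened backbones (row-major x,y,z per atom).
#' @param pose_ids Character vector of pose identifiers (required when
#'   `poses` is a matrix; taken from the poses otherwise).
#' @param channels Optional data frame of per-pose score channels.
#' @param truth_rmsd Optional numeric vector: known in-frame backbone RMSD of
#'   each pose to the native window (synthetic data only).
#' @param l Window length (default 9).
#' @return An object of class `pose_pool`.
#' @export
pose_pool <- function(window_index, poses, pose_ids = NULL, channels = NULL,
                      truth_rmsd = NULL, l = 9L) {
  if (is.list(poses) && !is.matrix(poses)) {
    stopifnot(all(vapply(poses, inherits, logical(1), "fragment_pose")))
    flat <- t(vapply(poses, function(p) flatten_bb(p$backbone),
                     numeric(l * N_BB_ATOMS * 3L)))
    if (is.null(pose_ids)) {
      pose_ids <- vapply(poses, function(p) p$pose_id, character(1))
    }
  } else {
    flat <- as.matrix(poses)
    if (is.null(pose_ids)) stopf("pose_ids required when poses is a matrix")
  }
  if (ncol(flat) != l * N_BB_ATOMS * 3L) stopf("bad flat coordinate width")
  if (anyDuplicated(pose_ids)) stopf("pose ids within a pool must be unique")
  rownames(flat) <- pose_ids
  structure(list(
    window_index = as.integer(window_index),
    pose_ids = as.character(pose_ids),
    flat = flat,
    channels = channels,
    truth_rmsd = truth_rmsd,
    l = as.integer(l)
  ), class = "pose_pool")
}

#' Extract one pose from a pool
#' @param pool A `pose_pool`.
#' @param i Pose index (integer) or pose id (string).
#' @return A [fragment_pose()].
#' @export
pool_pose <- function(pool, i) {
  stopifnot(inherits(pool, "pose_pool"))
  if (is.character(i)) i <- match(i, pool$pose_ids)
  fragment_pose(
    window_index = pool$window_index,
    pose_id = pool$pose_ids[i],
    backbone = unflatten_bb(pool$flat[i, ]),
    channel_scores = if (!is.null(pool$channels)) unlist(pool$channels[i, , drop = FALSE]) else numeric(0),
    l = pool$l
  )
}

#' Number of poses in a pool
#' @param pool A `pose_pool`.
#' @return Integer pose count.
#' @export
pool_size <- function(pool) length(pool$pose_ids)

#' Subset a pose pool
#' @param pool A `pose_pool`.
#' @param idx Integer indices (or pose ids) of the poses to keep.
#' @return A `pose_pool` with the selected poses, in the given order.
#' @export
pool_subset <- function(pool, idx) {
  if (is.character(idx)) idx <- match(idx, pool$pose_ids)
  pose_pool(
    window_index = pool$window_index,
    poses = pool$flat[idx, , drop = FALSE],
    pose_ids = pool$pose_ids[idx],
    channels = if (!is.null(pool$channels)) pool$channels[idx, , drop = FALSE] else NULL,
    truth_rmsd = pool$truth_rmsd[idx],
    l = pool$l
  )
}
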