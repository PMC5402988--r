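# Metric computations on fragment poses: in-frame RMSD, optimal
# superposition, and the pairwise geometric quantities used by the
# compatibility filter.

#' Create a fragment pose
#'
#' A fragment pose is one docked placement of a 9-residue window backbone in
#' the receptor coordinate frame. The backbone holds the atom set
#' {N, CA, CB, C} per residue (C-beta virtual for glycine), residue-major.
#'
#' @param window_index 1-based window number.
#' @param pose_id Unique pose identifier (string).
#' @param backbone Numeric (9*4) x 3 matrix: rows are N, CA, CB, C of
#'   residue 1, then residue 2, etc.
#' @param channel_scores Optional named numeric vector of opaque score
#'   channels attached to this pose.
#' @param source_fragment_id Optional provenance string.
#' @param l Window length in residues (default 9).
#' @return An object of class `fragment_pose`.
#' @export
fragment_pose <- function(window_index, pose_id, backbone,
                          channel_scores = numeric(0),
                          source_fragment_id = NA_character_, l = 9L) {
  backbone <- as.matrix(backbone)
  if (nrow(backbone) != l * N_BB_ATOMS || ncol(backbone) != 3L) {
    stopf("backbone must be a %d x 3 matrix (N, CA, CB, C per residue)",
          l * N_BB_ATOMS)
  }
  if (any(!is.finite(backbone))) stopf("non-finite backbone coordinates")
  structure(list(
    window_index = as.integer(window_index),
    pose_id = as.character(pose_id),
    backbone = backbone,
    channel_scores = channel_scores,
    source_fragment_id = source_fragment_id,
    l = as.integer(l)
  ), class = "fragment_pose")
}

#' Root-mean-square deviation without superposition
#'
#' RMSD between two equally sized coordinate sets compared in the frame they
#' are given in (no fitting). This is the metric used throughout assembly
#' and ligand evaluation, since all poses share the receptor frame.
#'
#' @param a,b Numeric n x 3 coordinate matrices with matched atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd_in_frame <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stopf("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `target`. Reflections are excluded (determinant +1).
#'
#' @param mobile,target Numeric n x 3 matrices, n >= 3, non-collinear.
#' @return List with `rotation` (3 x 3, to be applied as `x %*% rotation`),
#'   `translation` (length-3), `rmsd` (Angstrom after superposition).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target))) stopf("coordinate sets differ in size")
  if (nrow(mobile) < 3L) stopf("need at least 3 points to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(target, 2, ct)
  H <- crossprod(X, Y)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-8)) {
    stopf("degenerate (collinear) point set; superposition is ill-defined")
  }
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  tr <- ct - as.vector(cm %*% R)
  fitted <- mobile %*% R + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  list(rotation = R, translation = tr, rmsd = rmsd_in_frame(fitted, target))
}

#' Apply a rigid transform to coordinates
#' @param x Numeric n x 3 matrix.
#' @param fit A list with `rotation` and `translation`, as returned by
#'   [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(x, fit) {
  as.matrix(x) %*% fit$rotation +
    matrix(fit$translation, nrow(x), 3, byrow = TRUE)
}

# residue/atom landmarks used by the pair filter (l = 9, v = 3)
#' @keywords internal
pair_landmarks <- function(l = 9L, v = 3L) {
  list(
    mid_ca = bb_row((l + 1L) %/% 2L, "CA"),          # CA of middle residue (5)
    a_flank_ca = bb_row(l - v, "CA"),                # CA of residue before overlap (6)
    b_flank_ca = bb_row(v + 1L, "CA"),               # CA of residue after overlap (4)
    a_overlap = as.vector(vapply((l - v + 1L):l, bb_row, numeric(4), atom = BB_ATOMS)),
    b_overlap = as.vector(vapply(1:v, bb_row, numeric(4), atom = BB_ATOMS)),
    a_vec_from = bb_row(l - v + 1L, "N"),            # N of first overlapping residue (7)
    a_vec_to = bb_row(l, "C"),                       # C of third overlapping residue (9)
    b_vec_from = bb_row(1L, "N"),
    b_vec_to = bb_row(v, "C"),
    clash_mask = clash_exclusion_mask(l, v)
  )
}

# For consecutive windows, residue i of the upstream fragment corresponds to
# chain position i and residue j of the downstream fragment to chain
# position j + (l - v); a correct continuation necessarily brings atom pairs
# whose implied chain separation is <= 1 (the shared overlap residues and
# the bonded junction neighbours) within bonding distance, so those pairs
# are excluded from the clash screen.
#' @keywords internal
clash_exclusion_mask <- function(l = 9L, v = 3L) {
  res_a <- rep(seq_len(l), each = N_BB_ATOMS)
  res_b <- rep(seq_len(l), each = N_BB_ATOMS)
  outer(res_a, res_b, function(i, j) abs(j - i + (l - v)) <= 1L)
}

#' Pairwise geometry of two fragment poses
#'
#' Computes the quantities the compatibility filter cuts on: the minimum
#' fragment-fragment atom distance, the distance between the CA atoms of the
#' two middle residues (midpoint distance), and, for consecutive windows,
#' the overlap residue distance (CA of the residues flanking the overlap),
#' the maximum distance over the 12 corresponding {N, CA, CB, C} atom pairs
#' of the 3 overlapping residues, and the cosine of the overlap angle (the
#' angle between each fragment's vector from the N of its first overlapping
#' residue to the C of its third).
#'
#' For consecutive windows the minimum atom distance excludes pairs where
#' both atoms lie in the overlap region, since a correct continuation
#' necessarily brings those close.
#'
#' @param a,b `fragment_pose` objects with `a$window_index < b$window_index`.
#' @param separation Window separation; defaults to the difference of the
#'   window indices.
#' @return An object of class `pair_geometry`: list with
#'   `min_atom_distance`, `midpoint_distance`, `separation`, and for
#'   separation 1 also `overlap_residue_distance`,
#'   `max_overlap_pair_distance`, `overlap_angle_cos`.
#' @export
pair_geometry <- function(a, b, separation = b$window_index - a$window_index) {
  stopifnot(inherits(a, "fragment_pose"), inherits(b, "fragment_pose"))
  if (separation <= 0) stopf("window separation must be positive (a before b)")
  lm <- pair_landmarks(a$l)
  A <- a$backbone; B <- b$backbone
  dmat <- cross_dist(A, B)
  if (separation == 1) dmat[lm$clash_mask] <- Inf
  out <- list(
    separation = as.integer(separation),
    min_atom_distance = min(dmat),
    midpoint_distance = vnorm(A[lm$mid_ca, ] - B[lm$mid_ca, ])
  )
  if (separation == 1) {
    out$overlap_residue_distance <- vnorm(A[lm$a_flank_ca, ] - B[lm$b_flank_ca, ])
    out$max_overlap_pair_distance <-
      max(sqrt(rowSums((A[lm$a_overlap, ] - B[lm$b_overlap, ])^2)))
    va <- A[lm$a_vec_to, ] - A[lm$a_vec_from, ]
    vb <- B[lm$b_vec_to, ] - B[lm$b_vec_from, ]
    out$overlap_angle_cos <- sum(va * vb) / (vnorm(va) * vnorm(vb))
  }
  class(out) <- "pair_geometry"
  out
}

#' Mean square distance over the overlap of consecutive fragments
#'
#' The overlap score component for one window junction: the mean, over the
#' v = 3 overlapping residues and the 4 atoms {N, CA, CB, C} of each, of the
#' squared distance between the corresponding atoms of the upstream and
#' downstream fragment.
#'
#' @param a,b `fragment_pose` objects from consecutive windows.
#' @return Mean square distance in Angstrom^2.
#' @export
overlap_msd <- function(a, b) {
  stopifnot(inherits(a, "fragment_pose"), inherits(b, "fragment_pose"))
  if (b$window_index - a$window_index != 1L) {
    stopf("overlap MSD is defined only for consecutive windows")
  }
  lm <- pair_landmarks(a$l)
  mean(rowSums((a$backbone[lm$a_overlap, ] - b$backbone[lm$b_overlap, ])^2))
}
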