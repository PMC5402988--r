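# Internal helpers shared across modules.
#
# Backbone convention: a fragment pose stores one 9-residue backbone as a
# (9*4) x 3 numeric matrix, residue-major, atoms ordered N, CA, CB, C within
# each residue (the atom set A used by the overlap score; O is never part of
# it, CB is virtual for glycine). "Flat" coordinates are the row-major
# flattening of that matrix (x,y,z of atom 1, then atom 2, ...), used to hold
# whole pose pools in a single matrix.

BB_ATOMS <- c("N", "CA", "CB", "C")
N_BB_ATOMS <- 4L

#' @keywords internal
bb_row <- function(res, atom) {
  a <- match(atom, BB_ATOMS)
  if (anyNA(a)) stop("unknown backbone atom: ", paste(atom[is.na(a)], collapse = ", "))
  (res - 1L) * N_BB_ATOMS + a
}

# flat column indices (x,y,z) of one atom row
#' @keywords internal
flat_cols <- function(row) {
  as.vector(vapply(row, function(r) (r - 1L) * 3L + 1:3, numeric(3)))
}

#' @keywords internal
flatten_bb <- function(m) as.vector(t(m))

#' @keywords internal
unflatten_bb <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' @keywords internal
vnorm <- function(x) sqrt(sum(x^2))

#' @keywords internal
unit <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  x / n
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Pairwise Euclidean distances between the rows of two n x 3 matrices.
#' @keywords internal
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Uniform random rotation matrix (Arvo's method via quaternions).
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Rotation by angle about unit axis (Rodrigues).
#' @keywords internal
axis_rotation <- function(axis, angle) {
  axis <- unit(axis)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
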