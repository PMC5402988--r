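# Consensus Z-score machinery: DI score for fragment selection, Path Score
# for assembled paths, Model Score for merged models, grid-search weight
# training, and the interface-prediction pre-filter.

#' Z-scores of a numeric vector
#'
#' Standardises with the population (n-denominator) standard deviation. A
#' constant vector yields all zeros.
#'
#' @param x Numeric vector, all finite.
#' @return Numeric vector of the same length.
#' @export
zscores <- function(x) {
  if (length(x) < 1L) stopf("zscores needs at least one value")
  if (any(!is.finite(x))) stopf("non-finite values in zscores input")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' DI score: sum of two channel Z-scores
#'
#' The fragment selection score: the sum of the Z-scores of two
#' lower-is-better docking score channels (typically,
#' ITScorePro and DFIRE). Lower DI is better.
#'
#' @param table Data frame (or matrix) of score channels.
#' @param channels Length-2 character or integer vector naming the two
#'   channels to combine (default: the first two columns).
#' @return Numeric vector of DI scores, one per row.
#' @export
di_score <- function(table, channels = 1:2) {
  table <- as.data.frame(table)
  if (length(channels) != 2L) stopf("di_score combines exactly 2 channels")
  if (is.character(channels) && !all(channels %in% names(table))) {
    stopf("channel(s) not found: %s",
          paste(setdiff(channels, names(table)), collapse = ", "))
  }
  zscores(table[[channels[1]]]) + zscores(table[[channels[2]]])
}

#' Select the k best-scoring rows
#'
#' Returns the indices of the `k` rows with the lowest score, breaking ties
#' deterministically by row id. If fewer than `k` rows exist, all are
#' returned with a warning.
#'
#' @param score Numeric vector, lower is better.
#' @param k Number of rows to keep.
#' @param ids Character ids for tie-breaking (default: row number).
#' @return Integer vector of selected indices, best first.
#' @export
select_top <- function(score, k, ids = as.character(seq_along(score))) {
  if (k < 1L) stopf("k must be >= 1")
  if (length(score) < k) {
    warning(sprintf("only %d rows available for top-%d selection",
                    length(score), k), call. = FALSE)
    k <- length(score)
  }
  order(score, ids)[seq_len(k)]
}

#' Score weights for Path Score / Model Score
#'
#' @param w1,w2,w3,w4 Component weights; must sum to 1.
#' @param w5 Weight of the weighted-sum term versus the minimum-Z term, in
#'   (0, 1].
#' @return An object of class `score_weights`.
#' @export
score_weights <- function(w1, w2, w3, w4, w5) {
  w <- c(w1, w2, w3, w4)
  if (abs(sum(w) - 1) > 1e-9) stopf("w1 + w2 + w3 + w4 must equal 1")
  if (any(w < 0)) stopf("component weights must be non-negative")
  if (w5 <= 0 || w5 > 1) stopf("w5 must lie in (0, 1]")
  structure(list(w = w, w5 = w5), class = "score_weights")
}

# combined score from an already-oriented (lower-is-better) Z matrix
#' @keywords internal
combined_score <- function(zmat, weights) {
  stopifnot(inherits(weights, "score_weights"), ncol(zmat) == 4L)
  drop(weights$w5 * (zmat %*% weights$w) +
         (1 - weights$w5) * apply(zmat, 1, min))
}

# Z matrix of the four path components, S_C and S_R negated so that low is
# favorable in every column.
#' @keywords internal
path_zmat <- function(components) {
  cbind(zscores(components$S_E), zscores(components$S_O),
        zscores(-components$S_C), zscores(-components$S_R))
}

#' Fill in the component scores of assembled paths
#'
#' Computes, for every path: the energy score S_E (mean DI score of its
#' poses), the overlap score S_O (mean over window junctions of the overlap
#' mean square distance), the cluster size S_C (from assembly), and the
#' receptor score S_R. For S_R, the number of occupying paths N_op of each
#' receptor residue is counted across the whole path set (a path occupies a
#' residue when the minimum heavy-atom distance is at most `contact_cutoff`),
#' and S_R of a path is the sum of N_op over the residues it occupies.
#'
#' @param paths A `path_set` from [assemble()].
#' @param pose_di List (one element per window, ordered as the pools) of
#'   named numeric vectors: DI score per pose id.
#' @param receptor An `idp_structure`; needed for S_R.
#' @param contact_cutoff Heavy-atom contact distance in Angstrom (default 5).
#' @return The `path_set` with `component_scores` set (data frame with
#'   columns S_E, S_O, S_C, S_R) and attribute `n_op` (named integer vector
#'   per receptor residue).
#' @export
path_component_scores <- function(paths, pose_di, receptor,
                                  contact_cutoff = 5.0) {
  k <- length(paths$windows)
  np <- n_paths(paths)
  l <- paths$l
  block <- l * N_BB_ATOMS * 3L

  s_e <- numeric(np)
  for (ci in seq_len(k)) {
    di <- pose_di[[ci]]
    s_e <- s_e + di[paths$poses[, ci]]
  }
  s_e <- unname(s_e / k)

  lm <- pair_landmarks(l)
  a_cols <- flat_cols(lm$a_overlap)
  b_cols <- flat_cols(lm$b_overlap)
  s_o <- numeric(np)
  if (k > 1L) {
    for (n in seq_len(k - 1L)) {
      d2 <- (paths$coords[, a_cols + (n - 1L) * block, drop = FALSE] -
               paths$coords[, b_cols + n * block, drop = FALSE])^2
      s_o <- s_o + rowSums(d2) / length(lm$a_overlap)
    }
    s_o <- s_o / (k - 1L)
  }

  rec_xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rec_res <- paste(receptor$atoms$chain_id, receptor$atoms$residue_index)
  res_levels <- unique(rec_res)
  res_id <- match(rec_res, res_levels)
  n_atoms <- ncol(paths$coords) / 3L
  nres <- length(res_levels)
  rec_ca <- rec_xyz[receptor$atoms$name == "CA", , drop = FALSE]
  res_atoms <- split(seq_len(nrow(rec_xyz)), res_id)
  # path x receptor-residue contact matrix, built chunkwise with a CA-level
  # prescreen: a residue's atoms all lie within 1.6 A of its CA, so a
  # path-atom/CA distance below cutoff - 1.6 guarantees a contact and one
  # above cutoff + 1.6 excludes it; only the band between needs exact checks
  contact <- matrix(FALSE, np, nres)
  chunk <- max(1L, as.integer(8e6 %/% (n_atoms * nres)) + 1L)
  for (start in seq(1L, np, by = chunk)) {
    ii <- start:min(np, start + chunk - 1L)
    pts <- unflatten_bb(t(paths$coords[ii, , drop = FALSE]))
    atom_path <- rep(seq_along(ii), each = n_atoms)
    D <- cross_dist(pts, rec_ca)
    sure <- D <= contact_cutoff - 1.6
    contact[ii, ] <- rowsum(1 * sure, atom_path) > 0L
    maybe <- D <= contact_cutoff + 1.6 & !sure
    # suppress uncertain pairs whose path/residue contact is already settled
    maybe[contact[ii, , drop = FALSE][atom_path, , drop = FALSE]] <- FALSE
    for (r in which(colSums(maybe) > 0L)) {
      arows <- which(maybe[, r])
      dd <- cross_dist(pts[arows, , drop = FALSE],
                       rec_xyz[res_atoms[[r]], , drop = FALSE])
      hit <- unique(atom_path[arows[rowSums(dd <= contact_cutoff) > 0L]])
      contact[ii[hit], r] <- TRUE
    }
  }
  n_op <- colSums(contact)
  s_r <- as.vector(contact %*% n_op)

  paths$component_scores <- data.frame(S_E = s_e, S_O = s_o,
                                       S_C = paths$sizes, S_R = s_r)
  attr(paths$component_scores, "n_op") <- stats::setNames(n_op, res_levels)
  paths
}

#' Path Score
#'
#' The path ranking score: a weighted combination of the Z-scores (over all
#' paths of one complex) of the four components, plus a minimum-Z term that
#' rescues paths detected by only some of the components:
#' `S_path = w5 * (w1 Z(S_E) + w2 Z(S_O) + w3 Z(-S_C) + w4 Z(-S_R)) +
#' (1 - w5) * min(Z(S_E), Z(S_O), Z(-S_C), Z(-S_R))`. Lower is better.
#'
#' @param paths A `path_set` with `component_scores` filled, or the
#'   component data frame itself (columns S_E, S_O, S_C, S_R).
#' @param weights A [score_weights()]; defaults to the trained values
#'   (0.5, 0.1, 0.3, 0.1, w5 = 0.3).
#' @return Numeric vector of Path Scores.
#' @export
path_score <- function(paths, weights = score_weights(0.5, 0.1, 0.3, 0.1, 0.3)) {
  comp <- if (inherits(paths, "path_set")) paths$component_scores else paths
  if (is.null(comp)) stopf("component scores missing; run path_component_scores first")
  if (nrow(comp) < 2L) stopf("Path Score needs at least 2 paths (Z-scores)")
  combined_score(path_zmat(comp), weights)
}

#' Model Score
#'
#' The model re-ranking score: the same weighted Z-score combination as the
#' Path Score, applied to four lower-is-better model score channels
#' (typically ITScorePro, DFIRE, a molecular-mechanics score and GOAP;
#' this package treats them as opaque columns).
#'
#' @param table Data frame or matrix with exactly 4 numeric channels.
#' @param weights A [score_weights()]; defaults to the trained values
#'   (0.1, 0.2, 0.3, 0.4, w5 = 0.3).
#' @return Numeric vector of Model Scores, lower better.
#' @export
model_score <- function(table, weights = score_weights(0.1, 0.2, 0.3, 0.4, 0.3)) {
  table <- as.data.frame(table)
  if (ncol(table) != 4L) stopf("Model Score requires exactly 4 channels")
  if (nrow(table) < 2L) stopf("Model Score needs at least 2 models (Z-scores)")
  zmat <- vapply(table, zscores, numeric(nrow(table)))
  combined_score(zmat, weights)
}

# all 4-tuples on the 0.1 grid summing to 1, in lexicographic order
#' @keywords internal
weight_grid <- function() {
  out <- list()
  for (a in 1:7) for (b in 1:7) for (c in 1:7) {
    d <- 10L - a - b - c
    if (d >= 1L && d <= 7L) out[[length(out) + 1L]] <- c(a, b, c, d) / 10
  }
  do.call(rbind, out)
}

#' @keywords internal
orient_zmat <- function(scores) {
  scores <- as.data.frame(scores)
  if (all(c("S_E", "S_O", "S_C", "S_R") %in% names(scores))) {
    path_zmat(scores)
  } else {
    if (ncol(scores) != 4L) stopf("training scores need 4 channels")
    vapply(scores, zscores, numeric(nrow(scores)))
  }
}

#' Train score weights by grid search
#'
#' Performs the two-stage grid search used to train the Path Score and Model
#' Score weights: first (w1..w4) on the 0.1-step simplex with the
#' minimum-Z weight w5 fixed at 1, then w5 over 0.1..1.0 with the best
#' (w1..w4) fixed. The objective is either to maximise the minimum recall
#' across training sets (`"maximin_recall"`; retrieved set = the
#' `retrieved_k` lowest-scoring items) or to minimise the mean rank of first
#' hit (`"mean_rfh"`). Ties are broken toward the lexicographically smallest
#' weight tuple.
#'
#' @param training_sets List of training sets; each is a list with `scores`
#'   (data frame: either path components S_E/S_O/S_C/S_R or four
#'   lower-is-better channels) and `hits` (logical vector).
#' @param objective `"maximin_recall"` or `"mean_rfh"`.
#' @param retrieved_k Size of the retrieved set for recall (default 1000,
#'   capped at the set size).
#' @param w5_grid Candidate values for w5.
#' @return List with `weights` (a [score_weights()]), `objective`, and
#'   `value` (the achieved objective).
#' @export
train_weights <- function(training_sets,
                          objective = c("maximin_recall", "mean_rfh"),
                          retrieved_k = 1000L,
                          w5_grid = seq(0.1, 1.0, by = 0.1)) {
  objective <- match.arg(objective)
  has_hits <- vapply(training_sets, function(s) any(s$hits), logical(1))
  if (!any(has_hits)) stopf("every training set is hitless; cannot train")
  if (!all(has_hits)) {
    warning(sprintf("%d hitless training set(s) excluded", sum(!has_hits)),
            call. = FALSE)
    training_sets <- training_sets[has_hits]
  }
  zmats <- lapply(training_sets, function(s) orient_zmat(s$scores))
  hits <- lapply(training_sets, function(s) s$hits)

  eval_obj <- function(w14, w5) {
    weights <- score_weights(w14[1], w14[2], w14[3], w14[4], w5)
    per_set <- mapply(function(zm, h) {
      s <- combined_score(zm, weights)
      ord <- order(s, seq_along(s))
      if (objective == "maximin_recall") {
        kk <- min(retrieved_k, length(s))
        sum(h[ord[seq_len(kk)]]) / sum(h)
      } else {
        which(h[ord])[1]
      }
    }, zmats, hits)
    if (objective == "maximin_recall") min(per_set) else mean(per_set)
  }
  better <- function(a, b) {
    if (objective == "maximin_recall") a > b + 1e-12 else a < b - 1e-12
  }

  grid <- weight_grid()
  best_w <- NULL; best_val <- NULL
  for (g in seq_len(nrow(grid))) {
    v <- eval_obj(grid[g, ], 1.0)
    if (is.null(best_val) || better(v, best_val)) {
      best_val <- v; best_w <- grid[g, ]
    }
  }
  best_w5 <- NULL; best_val5 <- NULL
  for (w5 in w5_grid) {
    v <- eval_obj(best_w, w5)
    if (is.null(best_val5) || better(v, best_val5)) {
      best_val5 <- v; best_w5 <- w5
    }
  }
  list(weights = score_weights(best_w[1], best_w[2], best_w[3], best_w[4], best_w5),
       objective = objective,
       value = best_val5)
}

#' Pre-filter models by agreement with predicted interface residues
#'
#' For each model, computes the fraction `f_pred` of the predicted receptor
#' interface residues that lie at the model's interface (any receptor heavy
#' atom within `contact_cutoff` of any ligand atom), and keeps the models
#' whose Z-score of `f_pred` across all models is at least `z_cutoff`. If
#' the prediction is empty, or no model passes, all models are passed
#' through with a warning.
#'
#' @param models List of ligand backbones: `merged_model` objects or
#'   (residues x atoms) x 3 coordinate matrices.
#' @param predicted_residues Integer vector of predicted receptor interface
#'   residue indices.
#' @param receptor An `idp_structure`.
#' @param z_cutoff Z-score threshold (default 1.5).
#' @param contact_cutoff Interface contact distance (default 5 Angstrom).
#' @return List with `keep` (integer indices of surviving models), `f_pred`
#'   and `z` (numeric vectors over all models).
#' @export
interface_filter <- function(models, predicted_residues, receptor,
                             z_cutoff = 1.5, contact_cutoff = 5.0) {
  n <- length(models)
  if (length(predicted_residues) == 0L) {
    warning("empty interface prediction; passing all models through",
            call. = FALSE)
    return(list(keep = seq_len(n), f_pred = rep(NA_real_, n),
                z = rep(NA_real_, n)))
  }
  rec_xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rec_res <- receptor$atoms$residue_index
  f_pred <- vapply(models, function(m) {
    bb <- if (inherits(m, "merged_model")) m$backbone else as.matrix(m)
    d <- cross_dist(bb, rec_xyz)
    iface <- unique(rec_res[colSums(d <= contact_cutoff) > 0L])
    mean(predicted_residues %in% iface)
  }, numeric(1))
  z <- zscores(f_pred)
  keep <- which(z >= z_cutoff)
  if (length(keep) == 0L) {
    warning("no model passed the interface filter; passing all through",
            call. = FALSE)
    keep <- seq_len(n)
  }
  list(keep = keep, f_pred = f_pred, z = z)
}
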