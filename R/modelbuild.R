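# Turn an assembled path into one continuous ligand backbone by averaging
# the coordinates of multiply-covered atoms, and report chain-geometry
# continuity statistics. (Force-field refinement of the merged structure is
# an external step; the merge reproduces the initial-structure construction
# and the statistics quantify the continuity defect refinement would fix.)

#' Merge a path into a single full-length ligand backbone
#'
#' Residues covered by one window copy that window's coordinates; residues
#' covered by two or more windows take the arithmetic mean of the
#' corresponding atoms across the covering fragments (`method = "average"`).
#' `method = "first"` instead keeps the coordinates of the first (most
#' N-terminal) covering window — the naive concatenation the averaging is
#' compared against.
#'
#' @param path_coords Flattened path coordinates: numeric vector of length
#'   `length(windows) * 9 * 4 * 3` (one window block per window), or one row
#'   of a `path_set`'s `coords`.
#' @param windows Window table from [make_windows()].
#' @param method `"average"` or `"first"`.
#' @return An object of class `merged_model`: list with `backbone`
#'   ((L*4) x 3 matrix, atoms N, CA, CB, C per residue), `L`, and
#'   `coverage` (number of windows covering each residue).
#' @export
merge_path <- function(path_coords, windows, method = c("average", "first")) {
  method <- match.arg(method)
  path_coords <- as.numeric(path_coords)
  k <- nrow(windows)
  l <- windows$length[1]
  block <- l * N_BB_ATOMS * 3L
  stopifnot(length(path_coords) == k * block)
  L <- max(windows$end)
  acc <- matrix(0, L * N_BB_ATOMS, 3L)
  cover <- integer(L * N_BB_ATOMS)
  for (n in seq_len(k)) {
    bb <- unflatten_bb(path_coords[(n - 1L) * block + seq_len(block)])
    rows <- as.vector(vapply(windows$start[n]:windows$end[n],
                             function(r) bb_row(r, BB_ATOMS), numeric(4)))
    if (method == "average") {
      acc[rows, ] <- acc[rows, ] + bb
      cover[rows] <- cover[rows] + 1L
    } else {
      new_rows <- cover[rows] == 0L
      acc[rows[new_rows], ] <- bb[new_rows, , drop = FALSE]
      cover[rows] <- cover[rows] + 1L
    }
  }
  if (any(cover == 0L)) {
    stopf("residue(s) %s not covered by any window",
          paste(unique(ceiling(which(cover == 0L) / N_BB_ATOMS)), collapse = ", "))
  }
  if (method == "average") acc <- acc / cover
  res_cover <- cover[bb_row(seq_len(L), "CA")]
  structure(list(backbone = acc, L = L, coverage = res_cover,
                 method = method),
            class = "merged_model")
}

#' Backbone chain continuity statistics
#'
#' The fraction of consecutive CA-CA distances falling in the ideal
#' trans-peptide band [3.75, 4.0] Angstrom (closed interval), plus the
#' minimum and maximum observed distance. Used to quantify how chain-like a
#' merged model is before refinement.
#'
#' @param model A `merged_model`, or a (residues x atoms) x 3 backbone
#'   matrix in the package's N/CA/CB/C layout, or an L x 3 matrix of CA
#'   coordinates.
#' @param lower,upper Band limits in Angstrom.
#' @return List with `fraction`, `min`, `max`, and `distances`.
#' @export
chain_stats <- function(model, lower = 3.75, upper = 4.0) {
  ca <- chain_ca(model)
  if (nrow(ca) < 2L) stopf("need at least 2 residues for chain statistics")
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
  list(fraction = mean(d >= lower & d <= upper),
       min = min(d), max = max(d), distances = d)
}

#' @keywords internal
chain_ca <- function(model) {
  if (inherits(model, "merged_model")) {
    model$backbone[bb_row(seq_len(model$L), "CA"), , drop = FALSE]
  } else {
    m <- as.matrix(model)
    if (nrow(m) %% N_BB_ATOMS == 0L && nrow(m) > 3L) {
      # assume full backbone layout unless it is a bare CA trace
      # (heuristic: full backbone has N-CA bond ~1.5 A between rows)
      d12 <- sqrt(sum((m[1, ] - m[2, ])^2))
      if (d12 < 2.5) {
        return(m[bb_row(seq_len(nrow(m) %/% N_BB_ATOMS), "CA"), , drop = FALSE])
      }
    }
    m
  }
}

#' Convert a merged model to a structure object
#'
#' @param model A `merged_model`.
#' @param chain_id Chain identifier for the ligand (default "B").
#' @param sequence Optional one-letter sequence (defaults to polyalanine).
#' @return An `idp_structure` with role `"ligand"`.
#' @export
model_as_structure <- function(model, chain_id = "B", sequence = NULL) {
  stopifnot(inherits(model, "merged_model"))
  L <- model$L
  if (is.null(sequence)) sequence <- strrep("A", L)
  aa1 <- strsplit(sequence, "")[[1]]
  resname <- names(AA3)[match(aa1, AA3)]
  atoms <- data.frame(
    name = rep(BB_ATOMS, L),
    resname = rep(resname, each = N_BB_ATOMS),
    residue_index = rep(seq_len(L), each = N_BB_ATOMS),
    chain_id = chain_id,
    x = model$backbone[, 1],
    y = model$backbone[, 2],
    z = model$backbone[, 3],
    element = rep(c("N", "C", "C", "C"), L),
    stringsAsFactors = FALSE
  )
  new_structure(atoms, role = "ligand")
}
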