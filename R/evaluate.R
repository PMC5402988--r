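# Accuracy metrics: fnat, ligand RMSD, interface RMSD, CAPRI quality class,
# pooled per-window RMSD, and ranking metrics (rank of first hit, BF10,
# recall).

#' Receptor-ligand residue contacts
#'
#' @param receptor An `idp_structure`.
#' @param ligand_bb Ligand backbone matrix ((L*4) x 3, N/CA/CB/C layout).
#' @param cutoff Heavy-atom contact distance in Angstrom (default 5).
#' @return Character vector of contact labels `"<chain> <rec_res>:<lig_res>"`.
#' @export
ligand_contacts <- function(receptor, ligand_bb, cutoff = 5.0) {
  rec_xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rec_res <- paste(receptor$atoms$chain_id, receptor$atoms$residue_index)
  ligand_bb <- as.matrix(ligand_bb)
  lig_res <- rep(seq_len(nrow(ligand_bb) %/% N_BB_ATOMS), each = N_BB_ATOMS)
  d <- cross_dist(ligand_bb, rec_xyz)
  idx <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(character(0))
  unique(paste0(rec_res[idx[, 2]], ":", lig_res[idx[, 1]]))
}

#' Fraction of native contacts (fnat)
#'
#' Native contacts are receptor-residue/ligand-residue pairs with any
#' heavy-atom distance within the cutoff in the native complex; fnat is the
#' fraction of them present in the model. Model and native must share the
#' receptor frame (superpose unbound receptors first with
#' [kabsch_superpose()]).
#'
#' @param model_bb,native_bb Ligand backbone matrices ((L*4) x 3).
#' @param receptor An `idp_structure`.
#' @param contact_cutoff Contact distance (default 5 Angstrom).
#' @return Fraction in [0, 1].
#' @export
fnat <- function(model_bb, native_bb, receptor, contact_cutoff = 5.0) {
  native <- ligand_contacts(receptor, native_bb, contact_cutoff)
  if (length(native) == 0L) stopf("native complex has no contacts at %.1f A", contact_cutoff)
  model <- ligand_contacts(receptor, model_bb, contact_cutoff)
  mean(native %in% model)
}

#' Ligand RMSD (L-RMSD)
#'
#' Backbone RMSD of the modelled ligand against the native ligand in the
#' shared receptor frame, with no ligand-only superposition.
#'
#' @param model_bb,native_bb Ligand backbone matrices with matched residues.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model_bb, native_bb) {
  model_bb <- as.matrix(model_bb); native_bb <- as.matrix(native_bb)
  if (!all(dim(model_bb) == dim(native_bb))) {
    stopf("model and native ligand differ in residue/atom count")
  }
  rmsd_in_frame(model_bb, native_bb)
}

#' Interface RMSD (I-RMSD)
#'
#' Backbone RMSD over the native interface after superposing the model's
#' interface onto the native's. The native interface comprises receptor
#' residues with any heavy atom within `interface_cutoff` of the native
#' ligand, and ligand residues within the same distance of the receptor
#' (the CAPRI convention, 10 Angstrom).
#'
#' @param model_bb,native_bb Ligand backbone matrices with matched residues.
#' @param receptor An `idp_structure` shared by model and native.
#' @param interface_cutoff Interface definition distance (default 10).
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(model_bb, native_bb, receptor,
                           interface_cutoff = 10.0) {
  model_bb <- as.matrix(model_bb); native_bb <- as.matrix(native_bb)
  if (!all(dim(model_bb) == dim(native_bb))) {
    stopf("model and native ligand differ in residue/atom count")
  }
  rec_xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rec_res <- paste(receptor$atoms$chain_id, receptor$atoms$residue_index)
  L <- nrow(native_bb) %/% N_BB_ATOMS
  lig_res <- rep(seq_len(L), each = N_BB_ATOMS)
  d <- cross_dist(native_bb, rec_xyz)
  rec_iface <- unique(rec_res[colSums(d <= interface_cutoff) > 0L])
  lig_iface <- unique(lig_res[rowSums(d <= interface_cutoff) > 0L])
  if (length(rec_iface) == 0L || length(lig_iface) == 0L) {
    stopf("no interface residues within %.1f A", interface_cutoff)
  }
  rec_keep <- rec_res %in% rec_iface & receptor$atoms$name %in% c("N", "CA", "C")
  lig_keep <- lig_res %in% lig_iface
  native_set <- rbind(rec_xyz[rec_keep, , drop = FALSE],
                      native_bb[lig_keep, , drop = FALSE])
  model_set <- rbind(rec_xyz[rec_keep, , drop = FALSE],
                     model_bb[lig_keep, , drop = FALSE])
  kabsch_superpose(model_set, native_set)$rmsd
}

#' CAPRI quality class
#'
#' Classifies a model from its (fnat, I-RMSD, L-RMSD) triplet using the
#' standard CAPRI thresholds: high if fnat >= 0.5 and (L-RMSD <= 1 or
#' I-RMSD <= 1); medium if fnat >= 0.3 and (L-RMSD <= 5 or I-RMSD <= 2);
#' acceptable if fnat >= 0.1 and (L-RMSD <= 10 or I-RMSD <= 4); otherwise
#' incorrect.
#'
#' @param fnat Fraction of native contacts.
#' @param i_rmsd Interface RMSD (Angstrom).
#' @param l_rmsd Ligand RMSD (Angstrom).
#' @return Ordered factor: incorrect < acceptable < medium < high.
#' @export
capri_class <- function(fnat, i_rmsd, l_rmsd) {
  stopifnot(is.finite(fnat), is.finite(i_rmsd), is.finite(l_rmsd))
  cls <- if (fnat >= 0.5 && (l_rmsd <= 1.0 || i_rmsd <= 1.0)) {
    "high"
  } else if (fnat >= 0.3 && (l_rmsd <= 5.0 || i_rmsd <= 2.0)) {
    "medium"
  } else if (fnat >= 0.1 && (l_rmsd <= 10.0 || i_rmsd <= 4.0)) {
    "acceptable"
  } else {
    "incorrect"
  }
  factor(cls, levels = c("incorrect", "acceptable", "medium", "high"),
         ordered = TRUE)
}

#' Pooled per-window RMSD of a path
#'
#' The square root of the mean of the squared per-window backbone ligand
#' RMSDs `d_n`: `sqrt(sum(d_n^2) / |W|)`. Paths with pooled RMSD of at most
#' 10 Angstrom are counted as hits in weight training and recall.
#'
#' @param d Numeric vector of per-window backbone L-RMSDs (Angstrom).
#' @return Pooled RMSD in Angstrom.
#' @export
pooled_rmsd <- function(d) {
  if (length(d) == 0L) stopf("pooled_rmsd needs at least one window RMSD")
  if (any(d < 0)) stopf("window RMSDs must be non-negative")
  sqrt(mean(d^2))
}

#' Per-window RMSDs of paths against the native windows
#'
#' @param paths A `path_set`.
#' @param native_pools List of single-pose [pose_pool()]s holding the native
#'   window backbones, or a list of native window backbone matrices.
#' @return Numeric matrix (paths x windows) of in-frame backbone RMSDs.
#' @export
path_window_rmsds <- function(paths, native_pools) {
  k <- length(paths$windows)
  block <- paths$l * N_BB_ATOMS * 3L
  out <- matrix(NA_real_, n_paths(paths), k)
  for (n in seq_len(k)) {
    nat <- native_pools[[n]]
    nat_flat <- if (inherits(nat, "pose_pool")) nat$flat[1, ] else flatten_bb(as.matrix(nat))
    blockcols <- (n - 1L) * block + seq_len(block)
    diff2 <- (paths$coords[, blockcols, drop = FALSE] -
                matrix(nat_flat, n_paths(paths), block, byrow = TRUE))^2
    out[, n] <- sqrt(rowSums(diff2) / (paths$l * N_BB_ATOMS))
  }
  out
}

#' Evaluate one model against the native complex
#'
#' @param model_bb Ligand backbone matrix of the model.
#' @param native_bb Native ligand backbone matrix.
#' @param receptor An `idp_structure`.
#' @param contact_cutoff fnat contact distance (default 5 Angstrom).
#' @return List of class `eval_metrics`: `fnat`, `i_rmsd`, `l_rmsd`,
#'   `capri_class`, and `ca_frac10` (fraction of ligand CA atoms within 10
#'   Angstrom of their native position, the per-model ingredient of BF10).
#' @export
eval_model <- function(model_bb, native_bb, receptor, contact_cutoff = 5.0) {
  model_bb <- as.matrix(model_bb); native_bb <- as.matrix(native_bb)
  L <- nrow(model_bb) %/% N_BB_ATOMS
  ca_rows <- bb_row(seq_len(L), "CA")
  ca_dev <- sqrt(rowSums((model_bb[ca_rows, , drop = FALSE] -
                            native_bb[ca_rows, , drop = FALSE])^2))
  fn <- fnat(model_bb, native_bb, receptor, contact_cutoff)
  ir <- interface_rmsd(model_bb, native_bb, receptor)
  lr <- ligand_rmsd(model_bb, native_bb)
  structure(list(fnat = fn, i_rmsd = ir, l_rmsd = lr,
                 capri_class = capri_class(fn, ir, lr),
                 ca_frac10 = mean(ca_dev <= 10),
                 ca_dev = ca_dev),
            class = "eval_metrics")
}

#' Ranking metrics over an ordered model list
#'
#' Given models already ordered by the selection score (best first),
#' computes: RFH, the 1-based rank of the first model of at least acceptable
#' CAPRI quality (NA if none); BF10, the maximum over the top 10 models of
#' the fraction of ligand CA atoms within 10 Angstrom of native; and recall,
#' the fraction of all hits contained in the retrieved (top `retrieved_k`)
#' set.
#'
#' @param metrics List of `eval_metrics`, in rank order.
#' @param hit_rule Function mapping an `eval_metrics` to TRUE/FALSE
#'   (default: CAPRI class at least acceptable).
#' @param retrieved_k Retrieved-set size for recall (default 10).
#' @return List with `rfh`, `bf10`, `recall`.
#' @export
rank_metrics <- function(metrics, hit_rule = NULL, retrieved_k = 10L) {
  if (is.null(hit_rule)) {
    hit_rule <- function(m) m$capri_class >= "acceptable"
  }
  hits <- vapply(metrics, hit_rule, logical(1))
  rfh <- if (any(hits)) unname(which(hits)[1]) else NA_integer_
  top <- seq_len(min(10L, length(metrics)))
  if (length(metrics) < 10L) {
    warning("fewer than 10 models; BF10 computed over available models",
            call. = FALSE)
  }
  bf10 <- max(vapply(metrics[top], function(m) m$ca_frac10, numeric(1)))
  kk <- min(retrieved_k, length(metrics))
  recall <- if (any(hits)) sum(hits[seq_len(kk)]) / sum(hits) else 0
  list(rfh = rfh, bf10 = bf10, recall = recall)
}
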