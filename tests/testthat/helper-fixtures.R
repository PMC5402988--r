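# Fixtures built in code: small backbones, random poses, and PDB text.

# a gently curved CA trace of length L (deterministic)
curved_ca <- function(L, radius = 8, pitch = 0.5) {
  ang <- (seq_len(L) - 1) * (3.8 / radius)
  cbind(radius * cos(ang), radius * sin(ang), (seq_len(L) - 1) * pitch)
}

# full N/CA/CB/C backbone on a curved trace
curved_backbone <- function(L) {
  fragcoalesce:::backbone_from_ca(curved_ca(L))
}

# cut the 9-residue window n out of a full-length backbone
cut_window <- function(bb, start, l = 9L) {
  rows <- as.vector(vapply(start:(start + l - 1L),
                           function(r) fragcoalesce:::bb_row(r, c("N", "CA", "CB", "C")),
                           numeric(4)))
  bb[rows, , drop = FALSE]
}

# random rigid placement of a 9-residue backbone
random_placed_pose <- function(bb, spread = 25) {
  ctr <- colMeans(bb)
  centred <- sweep(bb, 2, ctr)
  R <- fragcoalesce:::random_rotation()
  sweep(centred %*% t(R), 2, stats::runif(3, -spread, spread), "+")
}

# small synthetic instance for assembly oracle tests: k windows, n poses per
# window, mixing native cuts, perturbations and random placements
random_instance <- function(k = 3L, n = 10L, seed = 1L) {
  set.seed(seed)
  L <- 9L + 6L * (k - 1L)
  bb <- curved_backbone(L)
  wins <- make_windows(L)
  pools <- lapply(seq_len(k), function(w) {
    nat <- cut_window(bb, wins$start[w])
    mats <- list(nat)
    for (i in seq_len(n - 1L)) {
      if (i %% 2 == 0) {
        mats[[i + 1L]] <- fragcoalesce:::perturb_pose(nat, stats::runif(1, 0.5, 5))
      } else {
        mats[[i + 1L]] <- random_placed_pose(nat)
      }
    }
    flat <- t(vapply(mats, fragcoalesce:::flatten_bb, numeric(9 * 4 * 3)))
    pose_pool(w, flat, pose_ids = sprintf("w%d_p%02d", w, seq_len(n)))
  })
  list(windows = wins, pools = pools, native_bb = bb)
}

# text of a small polyalanine PDB (N, CA, C, O, CB per residue)
polyala_pdb_text <- function(nres = 3L, drop_ca_in = integer(0)) {
  tmpl <- rbind(
    c("N",  -0.52, 1.36, 0.00),
    c("CA",  0.00, 0.00, 0.00),
    c("C",   1.52, 0.00, 0.00),
    c("O",   2.15, 1.05, 0.00),
    c("CB", -0.53, -0.77, -1.20)
  )
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(nres)) {
    for (a in seq_len(nrow(tmpl))) {
      if (tmpl[a, 1] == "CA" && r %in% drop_ca_in) next
      serial <- serial + 1L
      xyz <- as.numeric(tmpl[a, 2:4]) + c(3.8 * (r - 1), 0, 0)
      nm <- tmpl[a, 1]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, "ALA", "A", r, xyz[1], xyz[2], xyz[3], 1.0, 0.0,
        substr(nm, 1, 1)))
    }
  }
  c(lines, "TER", "END")
}

write_pdb_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# independent slow RMSD (loop-based oracle)
oracle_rmsd <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    s <- s + sum((a[i, ] - b[i, ])^2)
  }
  sqrt(s / nrow(a))
}

random_rigid <- function() {
  list(R = fragcoalesce:::random_rotation(), t = stats::rnorm(3, 0, 10))
}

apply_rigid <- function(x, tr) {
  sweep(x %*% t(tr$R), 2, tr$t, "+")
}
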