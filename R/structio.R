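# Structure data model, PDB I/O, sequence windowing, virtual C-beta.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of a PDB file into the package's structure
#' representation. Alternate locations are resolved to the highest-occupancy
#' conformer; insertion codes are rejected; every residue must carry at least
#' the N, CA and C backbone atoms.
#'
#' @param path Path to a PDB file.
#' @param chain Optional character vector of chain identifiers to keep
#'   (default: all chains).
#' @param role Either `"receptor"` or `"ligand"`; recorded on the returned
#'   object.
#' @return An object of class `idp_structure`: a list with elements
#'   `atoms` (data frame with columns `name`, `resname`, `residue_index`,
#'   `chain_id`, `x`, `y`, `z`, `element`), `sequence` (named character,
#'   one-letter sequence per chain) and `role`.
#' @export
read_structure <- function(path, chain = NULL, role = c("receptor", "ligand")) {
  role <- match.arg(role)
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stopf("no ATOM records found in %s", path)
  ins <- !is.na(at$insert) & at$insert != ""
  if (any(ins)) {
    stopf("insertion codes are not supported (first at residue %s%s chain %s)",
          at$resno[ins][1], at$insert[ins][1], at$chain[ins][1])
  }
  # resolve alternate locations: highest occupancy wins, ties by altloc label
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$elety, sep = "\r")
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]
  }
  unknown <- setdiff(unique(at$resid), names(AA3))
  if (length(unknown) > 0L) {
    stopf("unknown residue name(s): %s", paste(unknown, collapse = ", "))
  }
  atoms <- data.frame(
    name = at$elety,
    resname = at$resid,
    residue_index = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9']", "", at$elety), 1, 1), at$elesy),
    stringsAsFactors = FALSE
  )
  new_structure(atoms, role = role)
}

#' @keywords internal
new_structure <- function(atoms, role = "receptor") {
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stopf("non-finite coordinates in structure")
  }
  if (any(atoms$residue_index < 1L)) stopf("residue indices must be >= 1")
  seqs <- character(0)
  for (ch in unique(atoms$chain_id)) {
    a <- atoms[atoms$chain_id == ch, , drop = FALSE]
    resno <- unique(a$residue_index)
    if (is.unsorted(resno, strictly = TRUE)) {
      stopf("residue indices in chain %s are not strictly increasing", ch)
    }
    for (r in resno) {
      have <- a$name[a$residue_index == r]
      miss <- setdiff(c("N", "CA", "C"), have)
      if (length(miss) > 0L) {
        stopf("residue %d chain %s is missing backbone atom(s): %s",
              r, ch, paste(miss, collapse = ", "))
      }
    }
    rn <- a$resname[match(resno, a$residue_index)]
    seqs[ch] <- paste(AA3[rn], collapse = "")
  }
  structure(list(atoms = atoms, sequence = seqs, role = role),
            class = "idp_structure")
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column ATOM records (3-decimal coordinates), with
#' chain identifiers and residue numbering preserved, re-readable by
#' [read_structure()].
#'
#' @param struct An `idp_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "idp_structure"))
  a <- struct$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000)) {
    stopf("coordinate magnitude >= 10000 Angstrom overflows the PDB field width")
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    resno = a$residue_index,
    chain = a$chain_id,
    resid = a$resname,
    elety = a$name,
    elesy = a$element
  )
  invisible(path)
}

#' Tile an IDP sequence into overlapping windows
#'
#' Divides a sequence of length `sequence_length` into `l`-residue windows
#' with `v` residues of overlap between consecutive windows. If the last
#' regular window does not end at the final residue, one extra window
#' anchored at the C-terminus is appended (its overlap with the previous
#' window then exceeds `v`), so the windows always cover the full sequence.
#'
#' @param sequence_length Number of residues (must be at least `l`).
#' @param l Window length in residues (default 9).
#' @param v Overlap between consecutive windows in residues (default 3).
#' @return A data frame with columns `index`, `start`, `end`, `length`, and
#'   `anchored` (TRUE for an appended C-anchored remainder window).
#' @examples
#' make_windows(15) # two windows starting at 1 and 7
#' @export
make_windows <- function(sequence_length, l = 9L, v = 3L) {
  sequence_length <- as.integer(sequence_length)
  l <- as.integer(l); v <- as.integer(v)
  if (v >= l || v < 1L) stopf("overlap v must satisfy 1 <= v < l")
  if (sequence_length < l) {
    stopf("sequence_length (%d) is shorter than the window length (%d)",
          sequence_length, l)
  }
  step <- l - v
  starts <- seq.int(1L, sequence_length - l + 1L, by = step)
  anchored <- rep(FALSE, length(starts))
  last_end <- starts[length(starts)] + l - 1L
  if (last_end < sequence_length) {
    starts <- c(starts, sequence_length - l + 1L)
    anchored <- c(anchored, TRUE)
  }
  data.frame(
    index = seq_along(starts),
    start = starts,
    end = starts + l - 1L,
    length = l,
    anchored = anchored
  )
}

#' Construct a virtual C-beta atom
#'
#' Places an ideal C-beta from backbone N, CA and C positions using
#' tetrahedral geometry about CA: bond length 1.53 Angstrom, N-CA-CB and
#' C-CA-CB angles of 110.5 degrees, and standard L-amino-acid chirality.
#' Used to supply the C-beta of glycine residues wherever the atom set
#' {N, CA, CB, C} is required.
#'
#' @param n,ca,c Numeric 3-vectors: backbone N, CA and C coordinates
#'   (Angstrom).
#' @param length C-beta bond length (Angstrom).
#' @param angle N-CA-CB angle (degrees).
#' @return Numeric 3-vector: the C-beta coordinates.
#' @export
virtual_cbeta <- function(n, ca, c, length = 1.53, angle = 110.5) {
  n1 <- n - ca
  c1 <- c - ca
  w <- cross3(n1, c1)
  if (vnorm(w) < 1e-8 * vnorm(n1) * vnorm(c1)) {
    stopf("N, CA and C are collinear; cannot construct a C-beta")
  }
  n1 <- unit(n1); c1 <- unit(c1)
  u <- unit(n1 + c1)
  w <- unit(cross3(n1, c1))   # sign fixes L-amino-acid chirality
  ct <- cos(angle * pi / 180)
  a <- ct / sum(u * n1)
  b2 <- 1 - a^2
  if (b2 < 0) stopf("requested C-beta angle is unreachable for this backbone")
  d <- a * u + sqrt(b2) * w
  ca + length * d
}
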