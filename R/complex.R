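#' TF-DNA complex container
#'
#' A `tfdna_complex` holds the atoms of a protein-DNA complex together with a
#' residue table, the protein chain layout, and the paired DNA duplex that
#' sequences are threaded onto. Atom coordinates are kept as an `n x 3`
#' matrix in Angstrom; all residue-level structure (duplex pairing, chain
#' membership) indexes into the residue table.
#'
#' Fields:
#' \describe{
#'   \item{atoms}{list with parallel vectors `elety` (atom name), `resid`
#'     (residue name), `chain`, `resno`, `element`, and the coordinate
#'     matrix `xyz`.}
#'   \item{residues}{data.frame with one row per residue: `chain`, `resno`,
#'     `resid`, `kind` ("protein" or "dna"), and `letter` (base letter for
#'     DNA rows, `NA` otherwise).}
#'   \item{protein_chains}{named list of residue-row indices per chain.}
#'   \item{duplex}{list with `forward` and `reverse` residue-row indices
#'     (each ordered 5' to 3' along its strand), `pairing` (for forward
#'     position i, the position in `reverse` of its Watson-Crick partner),
#'     and `sequence` (forward-strand base string).}
#'   \item{source_id}{free-text identifier.}
#' }
#'
#' @name tfdna_complex
NULL

new_tfdna_complex <- function(atoms, residues, protein_chains, duplex,
                              source_id = "complex") {
  cx <- list(atoms = atoms, residues = residues,
             protein_chains = protein_chains, duplex = duplex,
             source_id = source_id)
  cx$res_rows <- compute_res_rows(atoms, residues)
  class(cx) <- "tfdna_complex"
  cx
}

# atoms are stored grouped by residue in residue-table order; recover the
# per-residue row index list from the (chain, resno) runs
compute_res_rows <- function(atoms, residues) {
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  rkey <- paste(residues$chain, residues$resno, sep = "|")
  f <- factor(key, levels = rkey)
  if (anyNA(f)) stop("atom refers to a residue missing from the residue table")
  split(seq_along(key), f)
}

validate_complex <- function(cx) {
  stopifnot(inherits(cx, "tfdna_complex"))
  if (length(cx$protein_chains) < 1) stop("complex has no protein chain")
  if (length(cx$duplex$forward) < 1) stop("complex has no paired duplex")
  if (!all(is.finite(cx$atoms$xyz))) stop("non-finite atom coordinates")
  invisible(cx)
}

#' @export
print.tfdna_complex <- function(x, ...) {
  cat("TF-DNA complex:", x$source_id, "\n")
  cat(sprintf("  %d atoms, %d residues (%d protein / %d DNA)\n",
              nrow(x$atoms$xyz), nrow(x$residues),
              sum(x$residues$kind == "protein"),
              sum(x$residues$kind == "dna")))
  cat(sprintf("  protein chains: %s\n",
              paste(names(x$protein_chains), collapse = ", ")))
  cat(sprintf("  duplex: %d bp, forward sequence %s\n",
              length(x$duplex$forward), x$duplex$sequence))
  invisible(x)
}

#' Atom table of a complex
#'
#' @param cx a `tfdna_complex`.
#' @return data.frame with one row per atom (name, residue, chain, residue
#'   number, element, x, y, z, is_hydrogen).
#' @export
atom_table <- function(cx) {
  a <- cx$atoms
  data.frame(elety = a$elety, resid = a$resid, chain = a$chain,
             resno = a$resno, element = a$element,
             x = a$xyz[, 1], y = a$xyz[, 2], z = a$xyz[, 3],
             is_hydrogen = a$element == "H", stringsAsFactors = FALSE)
}

# atom row indices for residue-table row(s) r
residue_atom_rows <- function(cx, r) {
  unlist(cx$res_rows[r], use.names = FALSE)
}

# coordinates of a named atom in residue r (or NULL if absent)
residue_atom_xyz <- function(cx, r, name) {
  rows <- cx$res_rows[[r]]
  hit <- rows[cx$atoms$elety[rows] == name]
  if (length(hit) == 0) return(NULL)
  cx$atoms$xyz[hit[1], ]
}

# glycosidic nitrogen (N9 for purines, N1 for pyrimidines) of DNA residue r
glycosidic_n <- function(cx, r) {
  letter <- cx$residues$letter[r]
  nm <- if (letter %in% c("A", "G")) "N9" else "N1"
  p <- residue_atom_xyz(cx, r, nm)
  if (is.null(p)) stop("DNA residue lacks its glycosidic nitrogen ", nm)
  p
}

#' C-beta position of a protein residue
#'
#' Returns the observed CB coordinates, or for glycine (or any residue
#' missing CB) a virtual CB constructed from the N, CA, C backbone atoms by
#' standard tetrahedral placement.
#'
#' @param cx a `tfdna_complex`.
#' @param r residue-table row index of a protein residue.
#' @return length-3 numeric vector, or `NULL` if the backbone is incomplete.
#' @export
cbeta_position <- function(cx, r) {
  cb <- residue_atom_xyz(cx, r, "CB")
  if (!is.null(cb)) return(cb)
  n <- residue_atom_xyz(cx, r, "N")
  ca <- residue_atom_xyz(cx, r, "CA")
  c_ <- residue_atom_xyz(cx, r, "C")
  if (is.null(n) || is.null(ca) || is.null(c_)) return(NULL)
  b <- ca - n
  c2 <- c_ - ca
  a <- c(b[2] * c2[3] - b[3] * c2[2],
         b[3] * c2[1] - b[1] * c2[3],
         b[1] * c2[2] - b[2] * c2[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c2 + ca
}

# flat list of protein residue rows
protein_residues <- function(cx) {
  unlist(cx$protein_chains, use.names = FALSE)
}

#' Forward-strand positions of the duplex
#'
#' @param cx a `tfdna_complex`.
#' @return the forward strand sequence as a character vector of single bases.
#' @export
duplex_sequence <- function(cx) {
  strsplit(cx$duplex$sequence, "", fixed = TRUE)[[1]]
}
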