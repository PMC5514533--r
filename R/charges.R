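#' Partial-charge tables
#'
#' The electrostatic term needs per-atom partial charges (in electron-charge
#' units) and, for the pi channel, the list of ring atoms whose charges are
#' summed per aromatic system. Both live in a whitespace-delimited text file:
#'
#' ```
#' # residue  atom  charge
#' SER  OG  -0.66
#' SER  HG   0.43
#' [pi_atoms]
#' PHE  CG CD1 CD2 CE1 CE2 CZ
#' ```
#'
#' A force-field-inspired default set covering the 20 standard amino acids
#' and the four deoxyribonucleotides ships with the package
#' (`system.file("extdata", "default_charges.txt", package = "pentascan")`);
#' substitute your own file to use different charge derivations.
#'
#' @param path charge-table file.
#' @return a `charge_table`: list with `charges` (named numeric vector keyed
#'   `"RES|ATOM"`) and `pi_atoms` (named list of ring-atom names).
#' @export
read_charge_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  sec <- cumsum(lines == "[pi_atoms]")
  main <- lines[sec == 0]
  pi_lines <- lines[sec == 1 & lines != "[pi_atoms]"]

  charges <- numeric(0)
  if (length(main)) {
    parts <- strsplit(main, "[[:space:]]+")
    bad <- lengths(parts) != 3
    if (any(bad)) stop("malformed charge line(s): ",
                       paste(main[bad], collapse = "; "))
    m <- do.call(rbind, parts)
    charges <- as.numeric(m[, 3])
    if (any(!is.finite(charges))) stop("non-finite charge in table")
    names(charges) <- paste(m[, 1], m[, 2], sep = "|")
  }
  pi_atoms <- list()
  for (ln in pi_lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    pi_atoms[[f[1]]] <- f[-1]
  }
  structure(list(charges = charges, pi_atoms = pi_atoms),
            class = "charge_table")
}

#' @rdname read_charge_table
#' @export
default_charge_table <- function() {
  read_charge_table(system.file("extdata", "default_charges.txt",
                                package = "pentascan", mustWork = TRUE))
}

# charge lookup for atoms given residue names and atom names; NA if absent
lookup_charges <- function(table, resid, elety) {
  unname(table$charges[paste(resid, elety, sep = "|")])
}

# Hydrogen-bond acceptors: O and N atoms with available lone pairs, per
# standard residue templates. Backbone carbonyl O for every amino acid and
# the DNA phosphate/sugar oxygens are always acceptors.
ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
  CYS = "SG",
  DA = c("N1", "N3", "N7"), DC = c("O2", "N3"), DG = c("O6", "N3", "N7"),
  DT = c("O2", "O4")
)
PROTEIN_BACKBONE_ACCEPTOR <- "O"
DNA_BACKBONE_ACCEPTORS <- c("OP1", "OP2", "O3'", "O4'", "O5'")

is_acceptor <- function(resid, elety) {
  base <- mapply(function(r, e) e %in% ACCEPTOR_ATOMS[[r]], resid, elety,
                 USE.NAMES = FALSE)
  base <- vapply(base, isTRUE, logical(1))
  prot <- resid %in% AA3 & elety == PROTEIN_BACKBONE_ACCEPTOR
  dna <- resid %in% DNA_RESNAMES & elety %in% DNA_BACKBONE_ACCEPTORS
  base | prot | dna
}

#' Physical constants for the Coulomb term
#'
#' @param epsilon dielectric constant (dimensionless, default 4.0, a common
#'   effective value for a protein-DNA interface).
#' @return list with `k_e` (N m^2 C^-2), `N_A` (mol^-1), `epsilon`, and
#'   `electron_charge` (C).
#' @export
physical_constants <- function(epsilon = 4.0) {
  stopifnot(epsilon > 0)
  list(k_e = 8.9875517873681764e9, N_A = 6.02214076e23,
       epsilon = epsilon, electron_charge = 1.6e-19)
}
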