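#' Binding-site window on the forward strand
#'
#' Indices are 1-based and inclusive on the forward strand. `core_start` /
#' `core_end` delimit the TF-contacted bases; `full_start` / `full_end` add
#' `flank` base pairs on each side, clipped to the available duplex (flanking
#' bases are taken from the solved structure; no DNA is built de novo, and a
#' warning is raised when the structure cannot supply the full flank).
#'
#' @param core_start,core_end 1-based inclusive forward-strand indices.
#' @param flank base pairs added on each side (default 2).
#' @param duplex_length total forward-strand length used for clipping.
#' @return a `binding_site` object.
#' @export
binding_site <- function(core_start, core_end, flank = 2, duplex_length) {
  stopifnot(core_start >= 1, core_start <= core_end,
            core_end <= duplex_length, flank >= 0)
  full_start <- max(1, core_start - flank)
  full_end <- min(duplex_length, core_end + flank)
  if ((core_start - flank < 1) || (core_end + flank > duplex_length)) {
    warning("flanking bases truncated to the bases present in the structure")
  }
  structure(list(core_start = core_start, core_end = core_end,
                 flank = flank, full_start = full_start,
                 full_end = full_end),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("binding site: core %d..%d (%d bp), +%d bp flanks -> full %d..%d (%d bp)\n",
              x$core_start, x$core_end, x$core_end - x$core_start + 1,
              x$flank, x$full_start, x$full_end, site_length(x)))
  invisible(x)
}

#' @rdname binding_site
#' @param site a `binding_site`.
#' @export
site_length <- function(site) site$full_end - site$full_start + 1

#' Detect the TF-contacted DNA binding site
#'
#' Scans the forward strand for the first and last base whose nucleotide has
#' at least one heavy atom within `contact_cutoff` of a protein heavy atom
#' (hydrogens are excluded from the contact test), then extends the window
#' by `flank` base pairs on each side.
#'
#' @param cx a [tfdna_complex].
#' @param contact_cutoff heavy-atom distance cutoff in Angstrom (default 5).
#' @param flank flanking base pairs per side (default 2).
#' @return a [binding_site].
#' @export
detect_binding_site <- function(cx, contact_cutoff = 5.0, flank = 2) {
  validate_complex(cx)
  prot_rows <- residue_atom_rows(cx, protein_residues(cx))
  prot_rows <- prot_rows[cx$atoms$element[prot_rows] != "H"]
  if (length(prot_rows) == 0) stop("no protein heavy atoms")
  P <- cx$atoms$xyz[prot_rows, , drop = FALSE]
  p2 <- rowSums(P^2)

  L <- length(cx$duplex$forward)
  in_contact <- logical(L)
  for (i in seq_len(L)) {
    rows <- c(cx$res_rows[[cx$duplex$forward[i]]],
              cx$res_rows[[cx$duplex$reverse[cx$duplex$pairing[i]]]])
    rows <- rows[cx$atoms$element[rows] != "H"]
    B <- cx$atoms$xyz[rows, , drop = FALSE]
    d2 <- outer(p2, rowSums(B^2), "+") - 2 * P %*% t(B)
    in_contact[i] <- any(d2 <= contact_cutoff^2 + 1e-12)
  }
  if (!any(in_contact)) {
    stop("no-contact error: no base pair within ", contact_cutoff,
         " Angstrom of the protein")
  }
  binding_site(core_start = min(which(in_contact)),
               core_end = max(which(in_contact)),
               flank = flank, duplex_length = L)
}
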