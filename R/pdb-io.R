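#' Read a TF-DNA complex from PDB text
#'
#' Parses a protonated TF-DNA complex structure, classifies chains into
#' protein and DNA by residue names, and infers Watson-Crick duplex pairing
#' from complementary-base geometry: two bases on different DNA chains are
#' paired when their identities are complementary and their glycosidic
#' nitrogens (N9 in purines, N1 in pyrimidines) lie within `pair_cutoff`,
#' resolved by minimal distance and required to run antiparallel.
#'
#' Non-standard residues (modified bases, ligands, waters) are skipped with a
#' warning. Hydrogens are retained; the electrostatic hydrogen-bond channel
#' needs them.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @param source_id identifier stored on the returned object; defaults to the
#'   file name.
#' @param pair_cutoff maximum glycosidic N-N distance (Angstrom) for pairing.
#' @return a [tfdna_complex].
#' @export
read_complex <- function(pdb, source_id = NULL, pair_cutoff = 10.0) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    file <- pdb
    if (is.null(source_id)) source_id <- basename(file)
  } else {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), file)
    if (is.null(source_id)) source_id <- "pdb_text"
  }
  p <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                error = function(e) stop("unparseable PDB input: ",
                                         conditionMessage(e)))
  at <- p$atom
  if (nrow(at) == 0) stop("PDB input contains no atoms")

  resid <- trimws(at$resid)
  is_prot <- resid %in% AA3
  is_dna <- resid %in% DNA_RESNAMES
  skip <- !(is_prot | is_dna) & at$type %in% c("ATOM", "HETATM")
  if (any(skip)) {
    warning("skipping ", length(unique(paste(resid[skip], at$chain[skip],
            at$resno[skip]))), " non-standard residue(s): ",
            paste(unique(resid[skip]), collapse = ", "))
  }
  keep <- is_prot | is_dna
  if (!any(is_dna)) stop("complex contains no DNA chain")
  if (!any(is_prot)) stop("complex contains no protein chain")

  at <- at[keep, , drop = FALSE]
  resid <- resid[keep]
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- " "
  element <- trimws(as.character(at$elesy))
  miss <- is.na(element) | element == ""
  element[miss] <- guess_element(trimws(at$elety[miss]))

  key <- paste(chain, at$resno, sep = "|")
  ord <- order(match(chain, unique(chain)), at$resno,
               match(key, unique(key)))
  at <- at[ord, , drop = FALSE]
  resid <- resid[ord]; chain <- chain[ord]; element <- element[ord]
  key <- key[ord]

  first <- !duplicated(key)
  residues <- data.frame(chain = chain[first], resno = at$resno[first],
                         resid = resid[first],
                         kind = ifelse(resid[first] %in% AA3,
                                       "protein", "dna"),
                         stringsAsFactors = FALSE)
  residues$letter <- ifelse(residues$kind == "dna",
                            names(DNA_RESNAMES)[match(residues$resid,
                                                      DNA_RESNAMES)],
                            NA_character_)

  atoms <- list(elety = trimws(at$elety), resid = resid, chain = chain,
                resno = at$resno, element = element,
                xyz = cbind(at$x, at$y, at$z))

  prot_rows <- which(residues$kind == "protein")
  protein_chains <- split(prot_rows, residues$chain[prot_rows])

  cx <- new_tfdna_complex(atoms, residues, protein_chains,
                          duplex = list(forward = integer(), reverse = integer(),
                                        pairing = integer(), sequence = ""),
                          source_id = source_id)
  cx$duplex <- infer_duplex(cx, pair_cutoff)
  validate_complex(cx)
  cx
}

# Pair DNA bases across the two largest DNA chains by complementary identity
# and glycosidic-N proximity; antiparallel direction is enforced.
infer_duplex <- function(cx, pair_cutoff = 10.0) {
  dna <- which(cx$residues$kind == "dna")
  chains <- table(cx$residues$chain[dna])
  if (length(chains) < 2) {
    stop("duplex pairing error: need two DNA chains, found ",
         length(chains))
  }
  chains <- names(sort(chains, decreasing = TRUE))[1:2]
  fwd <- dna[cx$residues$chain[dna] == chains[1]]
  rev_ <- dna[cx$residues$chain[dna] == chains[2]]
  fwd <- fwd[order(cx$residues$resno[fwd])]
  rev_ <- rev_[order(cx$residues$resno[rev_])]

  gf <- t(vapply(fwd, function(r) glycosidic_n(cx, r), numeric(3)))
  gr <- t(vapply(rev_, function(r) glycosidic_n(cx, r), numeric(3)))
  lf <- cx$residues$letter[fwd]
  lr <- cx$residues$letter[rev_]

  d2 <- outer(rowSums(gf^2), rowSums(gr^2), "+") - 2 * gf %*% t(gr)
  d2[d2 < 0] <- 0
  comp <- outer(lf, lr, function(a, b) BASE_COMPLEMENT[a] == b)
  cand <- which(comp & sqrt(d2) <= pair_cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    stop("duplex pairing error: no complementary base within ",
         pair_cutoff, " Angstrom")
  }
  cand <- cand[order(sqrt(d2)[cand]), , drop = FALSE]
  pairing <- rep(NA_integer_, length(fwd))
  used_r <- logical(length(rev_))
  for (i in seq_len(nrow(cand))) {
    f <- cand[i, 1]; r <- cand[i, 2]
    if (is.na(pairing[f]) && !used_r[r]) {
      pairing[f] <- r
      used_r[r] <- TRUE
    }
  }
  ok <- which(!is.na(pairing))
  if (length(ok) == 0) stop("duplex pairing error: empty pairing")
  if (length(ok) > 1 && any(diff(pairing[ok]) >= 0)) {
    stop("duplex pairing error: strands are not antiparallel ",
         "(pairing map is not strictly decreasing)")
  }
  # restrict the duplex to the contiguously paired forward stretch
  fwd <- fwd[ok]
  pairing <- pairing[ok]
  list(forward = fwd, reverse = rev_, pairing = pairing,
       sequence = paste(cx$residues$letter[fwd], collapse = ""))
}

#' Write a TF-DNA complex as PDB text
#'
#' Serializes to standard ATOM records (3-decimal coordinate precision).
#' Reading the text back with [read_complex()] reproduces the sequences,
#' chain structure and coordinates to PDB precision.
#'
#' @param cx a `tfdna_complex`.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return character vector of PDB lines, invisibly when written to file.
#' @export
write_complex <- function(cx, file = NULL) {
  validate_complex(cx)
  a <- cx$atoms
  n <- nrow(a$xyz)
  if (n > 99999) {
    stop("cannot serialize complex with more than 99999 atoms ",
         "(PDB atom-number field width)")
  }
  out <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = out, xyz = as.numeric(t(a$xyz)),
                   type = rep("ATOM", n), resno = a$resno, resid = a$resid,
                   eleno = seq_len(n), elety = a$elety, chain = a$chain,
                   elesy = a$element)
  txt <- readLines(out)
  if (is.null(file)) {
    unlink(out)
    return(txt)
  }
  invisible(txt)
}
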