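# Base reference frames and sequence threading.
#
# Every base carries an orthonormal frame computed from its ring geometry:
# origin at the glycosidic nitrogen (N9 purine / N1 pyrimidine), x toward
# the C1' attachment, z normal to the base plane. The idealized nucleotide
# geometries shipped with the package (R/ideal-bases-data.R) are expressed
# in this frame, so replacing a base identity is a rigid placement of the
# ideal base into the observed base's frame: backbone and sugar atoms are
# untouched and the glycosidic nitrogen position is invariant.

# frame of an observed base: list(origin, R) with world = origin + R %*% local
base_frame <- function(cx, r) {
  letter <- cx$residues$letter[r]
  purine <- letter %in% c("A", "G")
  n <- residue_atom_xyz(cx, r, if (purine) "N9" else "N1")
  a1 <- residue_atom_xyz(cx, r, if (purine) "C4" else "C2")
  a2 <- residue_atom_xyz(cx, r, if (purine) "C8" else "C6")
  if (is.null(n) || is.null(a1) || is.null(a2)) {
    stop("cannot build base frame: ring atoms missing in residue row ", r)
  }
  u1 <- unit(a1 - n)
  u2 <- unit(a2 - n)
  x <- -unit(u1 + u2)
  z <- unit(c(u1[2] * u2[3] - u1[3] * u2[2],
              u1[3] * u2[1] - u1[1] * u2[3],
              u1[1] * u2[2] - u1[2] * u2[1]))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  list(origin = n, R = cbind(x, y, z))
}

# base-moiety atom block of ideal base `letter` placed into `frame`
ideal_base_block <- function(letter, frame, resno, chain) {
  tpl <- .ideal_nucleotides[[letter]]
  tpl <- tpl[tpl$is_base, , drop = FALSE]
  xyz <- cbind(tpl$x, tpl$y, tpl$z) %*% t(frame$R)
  xyz <- sweep(xyz, 2, frame$origin, "+")
  list(elety = tpl$name, resid = rep(unname(DNA_RESNAMES[letter]), nrow(tpl)),
       chain = rep(chain, nrow(tpl)), resno = rep(resno, nrow(tpl)),
       element = tpl$element, xyz = xyz)
}

#' Thread a base sequence onto the DNA structural template
#'
#' Replaces the forward-strand bases at `start .. start+nchar(new_bases)-1`
#' (1-based, inclusive) by standard-geometry bases of the new identities,
#' rigidly superposed onto each old base's reference frame. Paired
#' reverse-strand bases are replaced by the complement in the same way.
#' Backbone and sugar atoms are preserved bit-identically and the protein is
#' untouched. Threading a base to its own identity leaves the residue
#' exactly unchanged, so threading is idempotent.
#'
#' @param cx a [tfdna_complex].
#' @param start 1-based forward-strand position of the first threaded base.
#' @param new_bases string over `{A,C,G,T}`.
#' @return a new `tfdna_complex` with the threaded sequence.
#' @export
thread_sequence <- function(cx, start, new_bases) {
  stopifnot(inherits(cx, "tfdna_complex"))
  if (length(cx$duplex$forward) < 1) stop("complex has no paired duplex")
  bases <- strsplit(toupper(new_bases), "", fixed = TRUE)[[1]]
  if (!all(bases %in% DNA_BASES)) {
    stop("alphabet error: new_bases must be over {A,C,G,T}, got ", new_bases)
  }
  L <- length(cx$duplex$forward)
  if (start < 1 || start + length(bases) - 1 > L) {
    stop("index error: threading window ", start, "..",
         start + length(bases) - 1, " outside duplex 1..", L)
  }

  # residue-row -> new letter for every residue that actually changes
  repl <- list()
  for (i in seq_along(bases)) {
    pos <- start + i - 1
    fr <- cx$duplex$forward[pos]
    if (cx$residues$letter[fr] != bases[i]) {
      repl[[as.character(fr)]] <- bases[i]
    }
    rv <- cx$duplex$reverse[cx$duplex$pairing[pos]]
    comp <- unname(BASE_COMPLEMENT[bases[i]])
    if (cx$residues$letter[rv] != comp) {
      repl[[as.character(rv)]] <- comp
    }
  }
  if (length(repl) == 0) {
    new_cx <- cx
  } else {
    new_cx <- replace_bases(cx, repl)
  }
  fwd_pos <- start:(start + length(bases) - 1)
  new_cx$residues$letter[new_cx$duplex$forward[fwd_pos]] <- bases
  new_cx$residues$resid[new_cx$duplex$forward[fwd_pos]] <-
    unname(DNA_RESNAMES[bases])
  rv_rows <- new_cx$duplex$reverse[new_cx$duplex$pairing[fwd_pos]]
  new_cx$residues$letter[rv_rows] <- unname(BASE_COMPLEMENT[bases])
  new_cx$residues$resid[rv_rows] <-
    unname(DNA_RESNAMES[BASE_COMPLEMENT[bases]])
  new_cx$duplex$sequence <-
    paste(new_cx$residues$letter[new_cx$duplex$forward], collapse = "")
  new_cx
}

# rebuild atom arrays with the base moieties of the residues in `repl`
# (named by residue row) swapped for ideal geometry of the new letter
replace_bases <- function(cx, repl) {
  a <- cx$atoms
  rows_chr <- names(repl)
  piece_elety <- list(); piece_resid <- list(); piece_chain <- list()
  piece_resno <- list(); piece_element <- list(); piece_xyz <- list()
  k <- 0
  res_counts <- lengths(cx$res_rows)
  for (r in seq_len(nrow(cx$residues))) {
    rows <- cx$res_rows[[r]]
    rc <- as.character(r)
    if (!is.null(repl[[rc]])) {
      old_letter <- cx$residues$letter[r]
      new_letter <- repl[[rc]]
      fr <- base_frame(cx, r)
      old_base_names <-
        .ideal_nucleotides[[old_letter]]$name[.ideal_nucleotides[[old_letter]]$is_base]
      keep <- rows[!(a$elety[rows] %in% old_base_names)]
      blk <- ideal_base_block(new_letter, fr, cx$residues$resno[r],
                              cx$residues$chain[r])
      k <- k + 1
      piece_elety[[k]] <- c(a$elety[keep], blk$elety)
      piece_resid[[k]] <- c(rep(unname(DNA_RESNAMES[new_letter]),
                                length(keep)), blk$resid)
      piece_chain[[k]] <- c(a$chain[keep], blk$chain)
      piece_resno[[k]] <- c(a$resno[keep], blk$resno)
      piece_element[[k]] <- c(a$element[keep], blk$element)
      piece_xyz[[k]] <- rbind(a$xyz[keep, , drop = FALSE], blk$xyz)
      res_counts[r] <- length(keep) + length(blk$elety)
    } else {
      k <- k + 1
      piece_elety[[k]] <- a$elety[rows]
      piece_resid[[k]] <- a$resid[rows]
      piece_chain[[k]] <- a$chain[rows]
      piece_resno[[k]] <- a$resno[rows]
      piece_element[[k]] <- a$element[rows]
      piece_xyz[[k]] <- a$xyz[rows, , drop = FALSE]
    }
  }
  atoms <- list(elety = unlist(piece_elety, use.names = FALSE),
                resid = unlist(piece_resid, use.names = FALSE),
                chain = unlist(piece_chain, use.names = FALSE),
                resno = unlist(piece_resno, use.names = FALSE),
                element = unlist(piece_element, use.names = FALSE),
                xyz = do.call(rbind, piece_xyz))
  cx$atoms <- atoms
  ends <- cumsum(res_counts)
  starts <- ends - res_counts + 1
  cx$res_rows <- mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
  names(cx$res_rows) <- paste(cx$residues$chain, cx$residues$resno, sep = "|")
  cx
}
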