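#' Train the residue-level multibody potential
#'
#' A knowledge-based mean-force potential over (amino-acid type, DNA
#' trinucleotide "triplet" type, distance bin). The interaction unit is a
#' forward-strand triplet read 5' to 3'; its position is the geometric
#' center of the three glycosidic nitrogens (N9 in purines, N1 in
#' pyrimidines), and the distance is measured to the amino acid's beta
#' carbon (a virtual C-beta is constructed for glycine).
#'
#' Counts of (residue, triplet) pairs are accumulated per distance bin over
#' the training complexes and converted to a potential by
#' `-ln((observed + pseudocount) / (expected + pseudocount))`, where the
#' expected count is the product of the (amino acid, triplet) marginal and
#' the distance-bin marginal (reference state). The pseudocount keeps every
#' cell finite even for empty bins.
#'
#' @param complexes list of [tfdna_complex] training structures, each with a
#'   paired duplex of at least 3 consecutive bases.
#' @param bins distance-bin edges in Angstrom (default 0..15 in 1-Angstrom
#'   steps).
#' @param pseudocount positive smoothing count (default 0.5).
#' @return an `mb_potential`: list with `bins`, `table` (20 x 64 x n_bins
#'   array, amino acids x triplets x bins), `counts`, and `metadata`.
#' @export
train_mb_potential <- function(complexes, bins = 0:15, pseudocount = 0.5) {
  if (length(complexes) == 0) stop("training error: empty training set")
  stopifnot(pseudocount > 0, length(bins) >= 2, all(diff(bins) > 0))
  triplets <- enumerate_kmers(3)
  nb <- length(bins) - 1
  counts <- array(0, dim = c(length(AA3), length(triplets), nb),
                  dimnames = list(AA3, triplets, NULL))
  for (cx in complexes) {
    validate_complex(cx)
    obs <- mb_observations(cx)
    if (is.null(obs)) next
    bin <- findInterval(obs$d, bins, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    for (i in which(ok)) {
      counts[obs$aa[i], obs$triplet[i], bin[i]] <-
        counts[obs$aa[i], obs$triplet[i], bin[i]] + 1
    }
  }
  total <- sum(counts)
  if (total == 0) {
    warning("no (residue, triplet) pair fell inside the distance bins")
  }
  marg_at <- apply(counts, c(1, 2), sum)          # (AA, triplet) marginal
  marg_bin <- apply(counts, 3, sum)               # distance marginal
  expected <- if (total > 0) {
    outer(marg_at / total, marg_bin, "*")
  } else {
    array(0, dim = dim(counts))
  }
  tab <- -log((counts + pseudocount) / (expected + pseudocount))
  structure(list(bins = bins, table = tab, counts = counts,
                 metadata = list(n_complexes = length(complexes),
                                 pseudocount = pseudocount,
                                 reference_state = "marginal-product",
                                 total_pairs = total)),
            class = "mb_potential")
}

# all (protein residue, forward triplet) observations of one complex:
# amino-acid identity, triplet sequence, C-beta to triplet-center distance
mb_observations <- function(cx) {
  fwd <- cx$duplex$forward
  if (length(fwd) < 3) return(NULL)
  gly <- t(vapply(fwd, function(r) glycosidic_n(cx, r), numeric(3)))
  n_trip <- length(fwd) - 2
  centers <- (gly[1:n_trip, , drop = FALSE] +
              gly[2:(n_trip + 1), , drop = FALSE] +
              gly[3:(n_trip + 2), , drop = FALSE]) / 3
  letters <- duplex_sequence(cx)
  trip_seq <- paste0(letters[1:n_trip], letters[2:(n_trip + 1)],
                     letters[3:(n_trip + 2)])
  prot <- protein_residues(cx)
  aa <- character(0); trip <- character(0); d <- numeric(0)
  for (r in prot) {
    cb <- cbeta_position(cx, r)
    if (is.null(cb)) next
    dd <- sqrt(rowSums(sweep(centers, 2, cb)^2))
    aa <- c(aa, rep(cx$residues$resid[r], n_trip))
    trip <- c(trip, trip_seq)
    d <- c(d, dd)
  }
  if (length(d) == 0) return(NULL)
  list(aa = aa, triplet = trip, d = d)
}

#' @export
print.mb_potential <- function(x, ...) {
  cat("multibody potential:", paste(dim(x$table), collapse = " x "),
      "(AA x triplet x distance bin)\n")
  cat("  bins:", paste(x$bins, collapse = " "), "Angstrom\n")
  cat("  trained on", x$metadata$n_complexes, "complex(es),",
      x$metadata$total_pairs, "pairs, pseudocount",
      x$metadata$pseudocount, "\n")
  invisible(x)
}

#' Multibody score of a complex over a binding-site window
#'
#' Sums potential lookups over all (protein residue, triplet) pairs whose
#' C-beta-to-triplet-center distance falls inside the binned range; triplets
#' are restricted to those lying fully inside the window. Out-of-range
#' distances contribute 0; a window shorter than 3 bp has no triplets and
#' scores 0.
#'
#' @param cx a [tfdna_complex].
#' @param potential an `mb_potential`.
#' @param window a [binding_site].
#' @return raw multibody score (dimensionless mean-force units).
#' @export
score_mb <- function(cx, potential, window) {
  stopifnot(inherits(potential, "mb_potential"))
  pos <- window$full_start:window$full_end
  if (length(pos) < 3) return(0)
  fwd <- cx$duplex$forward[pos]
  gly <- t(vapply(fwd, function(r) glycosidic_n(cx, r), numeric(3)))
  n_trip <- length(pos) - 2
  centers <- (gly[1:n_trip, , drop = FALSE] +
              gly[2:(n_trip + 1), , drop = FALSE] +
              gly[3:(n_trip + 2), , drop = FALSE]) / 3
  letters <- cx$residues$letter[fwd]
  trip_seq <- paste0(letters[1:n_trip], letters[2:(n_trip + 1)],
                     letters[3:(n_trip + 2)])
  nb <- length(potential$bins) - 1
  s <- 0
  for (r in protein_residues(cx)) {
    cb <- cbeta_position(cx, r)
    if (is.null(cb)) next
    aa <- cx$residues$resid[r]
    if (!aa %in% AA3) next
    dd <- sqrt(rowSums(sweep(centers, 2, cb)^2))
    bin <- findInterval(dd, potential$bins, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    if (any(ok)) {
      idx <- cbind(match(aa, AA3), match(trip_seq[ok], colnames(potential$table)),
                   bin[ok])
      s <- s + sum(potential$table[idx])
    }
  }
  s
}

#' Serialize / restore a multibody potential
#'
#' Versioned tabular text: a header with the bin edges, then one row per
#' (amino acid, triplet) with the per-bin potential values.
#'
#' @param potential an `mb_potential`.
#' @param path file path.
#' @return `read_mb_potential` returns an `mb_potential`;
#'   `write_mb_potential` returns `path` invisibly.
#' @export
write_mb_potential <- function(potential, path) {
  stopifnot(inherits(potential, "mb_potential"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pentascan multibody potential v1",
               paste("bins:", paste(potential$bins, collapse = " "))), con)
  tab <- potential$table
  for (a in seq_len(dim(tab)[1])) {
    for (t_ in seq_len(dim(tab)[2])) {
      writeLines(paste(AA3[a], colnames(tab)[t_],
                       paste(sprintf("%.10g", tab[a, t_, ]),
                             collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname write_mb_potential
#' @export
read_mb_potential <- function(path) {
  lines <- readLines(path)
  if (!grepl("multibody potential v1", lines[1])) {
    stop("unrecognized potential file format")
  }
  bins <- as.numeric(strsplit(sub("^bins:\\s*", "", lines[2]),
                              " ")[[1]])
  body <- strsplit(lines[-(1:2)], " +")
  triplets <- enumerate_kmers(3)
  nb <- length(bins) - 1
  tab <- array(NA_real_, dim = c(length(AA3), length(triplets), nb),
               dimnames = list(AA3, triplets, NULL))
  for (f in body) {
    tab[f[1], f[2], ] <- as.numeric(f[-(1:2)])
  }
  if (anyNA(tab)) stop("incomplete potential file")
  structure(list(bins = bins, table = tab, counts = NULL,
                 metadata = list(source = path)),
            class = "mb_potential")
}

#' A zero multibody potential (all table entries 0)
#'
#' Useful for isolating the electrostatic term; any complex scores 0.
#'
#' @param bins distance-bin edges.
#' @return an `mb_potential` whose every entry is 0.
#' @export
zero_mb_potential <- function(bins = 0:15) {
  triplets <- enumerate_kmers(3)
  tab <- array(0, dim = c(length(AA3), length(triplets), length(bins) - 1),
               dimnames = list(AA3, triplets, NULL))
  structure(list(bins = bins, table = tab, counts = tab,
                 metadata = list(reference_state = "zero")),
            class = "mb_potential")
}
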