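#' Significance configuration for motif selection
#'
#' The favorable (low) tail of the score distribution is selected at a
#' critical value of `alpha_base` normalized by the predicted motif length
#' (`alpha_base / L`, a Bonferroni-style reading of "0.01 normalized by the
#' length"). Two distribution models are available: a normal fit to the
#' empirical scores (default) or the empirical percentile.
#'
#' @param alpha_base base critical value (default 0.01).
#' @param normalize_by_length divide `alpha_base` by the motif length.
#' @param model `"normal"` or `"empirical"`.
#' @return list of class `significance_config`.
#' @export
significance_config <- function(alpha_base = 0.01,
                                normalize_by_length = TRUE,
                                model = c("normal", "empirical")) {
  stopifnot(alpha_base > 0, alpha_base < 1)
  structure(list(alpha_base = alpha_base,
                 normalize_by_length = normalize_by_length,
                 model = match.arg(model)),
            class = "significance_config")
}

#' Compose full-length scores from pentamer fragment tables (Kmer-Sum)
#'
#' The integrative-energy score of a full-length sequence is the sum of the
#' scores of its overlapping pentamer subsequences, one from each fragment
#' table. All `4^L` full-length permutations are scored; the composition is
#' pure integer arithmetic over the fragment tables, so no additional
#' energy calculation is performed. Raw component sums (`e_mb`, `e_elec`)
#' are composed alongside the combined score.
#'
#' @param tables list of complete `fragment_score_table`s with consecutive
#'   offsets `1 .. L-4`.
#' @param L full site length; defaults to `length(tables) + 4`.
#' @param component which fragment column to compose into the main score
#'   (default `"e_ie"`).
#' @return a `full_score_table` with provenance `"kmer_sum"`. Scores are
#'   indexed lexicographically; use [table_sequences()] to materialize
#'   sequence strings.
#' @export
kmer_sum_scores <- function(tables, L = length(tables) + 4,
                            component = "e_ie") {
  if (length(tables) == 0) stop("coverage error: no fragment tables")
  offsets <- vapply(tables, function(t_) t_$offset, numeric(1))
  if (!setequal(offsets, seq_len(L - 4))) {
    stop("coverage error: fragment offsets ",
         paste(sort(offsets), collapse = ","),
         " do not cover 1..", L - 4)
  }
  tables <- tables[order(offsets)]
  for (t_ in tables) {
    if (!isTRUE(t_$complete) || nrow(t_$scores) != 4^5) {
      stop("completeness error: fragment table at offset ", t_$offset,
           " does not hold all 1024 pentamer scores")
    }
  }
  idx <- seq_len(4^L) - 1
  total <- numeric(4^L)
  e_mb <- numeric(4^L)
  e_elec <- numeric(4^L)
  for (p in seq_len(L - 4)) {
    tab <- tables[[p]]$scores
    ord <- order(kmer_index(tab$sequence))  # ensure lexicographic lookup
    sub <- subkmer_index(idx, L, p, k = 5) + 1
    total <- total + tab[[component]][ord][sub]
    e_mb <- e_mb + tab$e_mb[ord][sub]
    e_elec <- e_elec + tab$e_elec[ord][sub]
  }
  new_full_score_table(L = L, e_mb = e_mb, e_elec = e_elec, e_ie = total,
                       provenance = "kmer_sum")
}

#' Select sequences with statistically significant (favorable) scores
#'
#' Fits the configured distribution model to the empirical score
#' distribution and returns the sequences in the favorable low tail at
#' `alpha_base / L` (or `alpha_base` when length normalization is off).
#' The selection is never empty: when no score passes, the single
#' best-scoring sequence is returned with a warning, likewise when the
#' distribution is degenerate (zero variance).
#'
#' @param scores a `full_score_table` or `fragment_score_table`.
#' @param config a [significance_config].
#' @return data.frame with `sequence`, `score`, `p`.
#' @export
select_significant <- function(scores, config = significance_config()) {
  if (inherits(scores, "fragment_score_table")) {
    x <- scores$scores$e_ie
    seq_of <- function(i) scores$scores$sequence[i]
    L <- 5
  } else if (inherits(scores, "full_score_table")) {
    x <- scores$e_ie
    Lcap <- scores$L
    seq_of <- function(i) index_to_kmer(i - 1, Lcap)
    L <- scores$L
  } else {
    stop("scores must be a fragment_score_table or full_score_table")
  }
  if (length(x) < 100) {
    warning("fewer than 100 scores; significance selection is unstable")
  }
  alpha <- if (config$normalize_by_length) config$alpha_base / L else
    config$alpha_base
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("degenerate score distribution; returning the best-scoring ",
            "sequence only")
    i <- which.min(x)
    return(data.frame(sequence = seq_of(i), score = x[i], p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  p <- if (config$model == "normal") {
    stats::pnorm(x, mean = mean(x), sd = s)
  } else {
    (rank(x, ties.method = "max")) / length(x)
  }
  sel <- which(p < alpha)
  if (length(sel) == 0) {
    warning("no score passed alpha = ", signif(alpha, 3),
            "; returning the best-scoring sequence only")
    sel <- which.min(x)
  }
  sel <- sel[order(x[sel])]
  data.frame(sequence = seq_of(sel), score = x[sel], p = p[sel],
             stringsAsFactors = FALSE)
}

#' Position frequency matrix from selected sequences
#'
#' Unweighted per-position base counts: each significant sequence counts
#' once regardless of its score.
#'
#' @param selected data.frame with a `sequence` column (equal lengths), as
#'   returned by [select_significant()], or a character vector.
#' @return a `pfm`: 4 x L matrix (rows A, C, G, T) with `kind = "counts"`.
#' @export
sequences_to_pfm <- function(selected) {
  seqs <- if (is.data.frame(selected)) selected$sequence else selected
  if (length(seqs) == 0) stop("no sequences to build a PFM from")
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("length error: sequences differ in length")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L,
              byrow = TRUE)
  if (!all(m %in% DNA_BASES)) stop("alphabet error: non-ACGT character")
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(m[, j], DNA_BASES), nbins = 4)
  }, numeric(4))
  new_pfm(counts, kind = "counts")
}

new_pfm <- function(mat, kind = c("counts", "frequencies")) {
  kind <- match.arg(kind)
  stopifnot(nrow(mat) == 4, all(mat >= 0), all(is.finite(mat)))
  rownames(mat) <- DNA_BASES
  if (kind == "frequencies") {
    stopifnot(all(abs(colSums(mat) - 1) < 1e-9))
  }
  structure(mat, kind = kind, class = c("pfm", "matrix"))
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM (%s), %d columns:\n", attr(x, "kind"), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

# column-normalize a pfm to frequencies
pfm_frequencies <- function(pfm, pseudocount = 0) {
  m <- unclass(pfm)
  tot <- colSums(m) + 4 * pseudocount
  if (any(tot == 0)) {
    stop("all-zero PFM column; a positive pseudocount is required")
  }
  sweep(m + pseudocount, 2, tot, "/")
}

#' Predict a motif by PWM stacking
#'
#' Per fragment, the statistically significant pentamers are selected and
#' counted into a 5-column PFM; fragment column `j` maps to motif column
#' `offset + j - 1`, and all fragment columns mapping to the same motif
#' position are summed. The stacked matrix is returned as a
#' frequency-normalized PFM of length `L = n_fragments + 4`.
#'
#' @param tables list of complete `fragment_score_table`s, offsets
#'   `1 .. L-4`.
#' @param config a [significance_config]; per-pentamer selection uses
#'   `alpha_base / 5` by default (length normalization with L = 5).
#' @return a `pfm` with `kind = "frequencies"`.
#' @export
pwm_stack <- function(tables, config = significance_config()) {
  if (length(tables) == 0) stop("coverage error: no fragment tables")
  offsets <- vapply(tables, function(t_) t_$offset, numeric(1))
  L <- max(offsets) + 4
  if (!setequal(offsets, seq_len(L - 4))) {
    stop("coverage error: fragment offsets are not consecutive from 1")
  }
  acc <- matrix(0, nrow = 4, ncol = L)
  for (t_ in tables[order(offsets)]) {
    sel <- select_significant(t_, config)
    pfm5 <- sequences_to_pfm(sel)
    cols <- t_$offset:(t_$offset + 4)
    acc[, cols] <- acc[, cols] + unclass(pfm5)
  }
  new_pfm(apply(acc, 2, function(col) col / sum(col)),
          kind = "frequencies")
}

#' Convert a PFM to a PWM with per-column information content
#'
#' Column frequencies are `(count + pseudocount) / (total + 4 pseudocount)`;
#' the information content of a column with frequencies `m_B` is
#' `IC = 2 + sum_B m_B log2 m_B` bits (0 for a uniform column, 2 for a
#' perfectly conserved one). Sequence-logo letter heights are
#' `frequency x IC`, following Schneider-Stephens.
#'
#' @param pfm a `pfm` (counts or frequencies).
#' @param pseudocount added per cell before normalizing (default 0; required
#'   positive if any column is all zeros).
#' @return a `pwm`: list with `freq` (4 x L), `ic` (bits per column), and
#'   `heights` (logo letter heights).
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0) {
  freq <- pfm_frequencies(pfm, pseudocount)
  ic <- apply(freq, 2, column_ic)
  structure(list(freq = freq, ic = ic,
                 heights = sweep(freq, 2, ic, "*")),
            class = "pwm")
}

# information content (bits) of one frequency column; 0 log 0 = 0
column_ic <- function(f) {
  nz <- f > 0
  2 + sum(f[nz] * log2(f[nz]))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM, %d columns; IC (bits): %s\n", ncol(x$freq),
              paste(sprintf("%.2f", x$ic), collapse = " ")))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' @rdname pfm_to_pwm
#' @param pwm a `pwm`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 2, which.max)], collapse = "")
}

#' Plot a PWM as a simple sequence logo
#'
#' Letter heights are Schneider-Stephens `frequency x IC` (bits); letters
#' are drawn stacked per column, tallest on top.
#'
#' @param x a `pwm`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pwm <- function(x, ...) {
  L <- ncol(x$freq)
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "bits", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(L))
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  for (j in seq_len(L)) {
    h <- x$heights[, j]
    ord <- order(h)
    y0 <- 0
    for (b in ord) {
      if (h[b] <= 0) next
      graphics::rect(j - 0.42, y0, j + 0.42, y0 + h[b],
                     col = grDevices::adjustcolor(cols[DNA_BASES[b]], 0.25),
                     border = NA)
      graphics::text(j, y0 + h[b] / 2, DNA_BASES[b],
                     col = cols[DNA_BASES[b]],
                     cex = max(0.4, min(2.5, 2.2 * h[b])))
      y0 <- y0 + h[b]
    }
  }
  invisible(x)
}

#' Write logo letter heights as CSV
#'
#' @param pwm a `pwm`.
#' @param path CSV path.
#' @export
write_logo_csv <- function(pwm, path) {
  df <- data.frame(position = rep(seq_len(ncol(pwm$freq)), each = 4),
                   base = rep(DNA_BASES, ncol(pwm$freq)),
                   height = as.numeric(pwm$heights))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
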