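#' IC-weighted Pearson correlation between two PWM columns
#'
#' The Pearson correlation across the four base frequencies of a reference
#' column `m` and a predicted column `n`, multiplied by `IC(m) / 2` so that
#' poorly conserved reference columns contribute less. A predicted column is
#' counted correct when the weighted value is at least 0.25. A column with
#' zero variance (uniform) makes the correlation undefined; the comparison
#' value is then defined as 0, flagged, and counted incorrect.
#'
#' @param ref_col,pred_col numeric length-4 frequency vectors (sum 1).
#' @param cutoff correctness threshold on the weighted value (default 0.25).
#' @return list of class `column_comparison`: `pcc`, `ic_ref`,
#'   `ic_weighted_pcc`, `correct`, `degenerate`.
#' @export
ic_weighted_pcc <- function(ref_col, pred_col, cutoff = 0.25) {
  stopifnot(length(ref_col) == 4, length(pred_col) == 4,
            abs(sum(ref_col) - 1) < 1e-6, abs(sum(pred_col) - 1) < 1e-6)
  ic_ref <- column_ic(ref_col)
  if (stats::sd(ref_col) == 0 || stats::sd(pred_col) == 0) {
    return(structure(list(pcc = NA_real_, ic_ref = ic_ref,
                          ic_weighted_pcc = 0, correct = FALSE,
                          degenerate = TRUE),
                     class = "column_comparison"))
  }
  pcc <- stats::cor(ref_col, pred_col)
  v <- pcc * ic_ref / 2
  structure(list(pcc = pcc, ic_ref = ic_ref, ic_weighted_pcc = v,
                 correct = v >= cutoff, degenerate = FALSE),
            class = "column_comparison")
}

# reverse complement of a PWM/PFM frequency matrix: reverse the column
# order and swap the A/T and C/G rows
revcomp_freq <- function(freq) {
  out <- freq[c(4, 3, 2, 1), rev(seq_len(ncol(freq))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

pwm_freq <- function(x) {
  if (inherits(x, "pwm")) return(x$freq)
  if (inherits(x, "pfm")) return(pfm_frequencies(x, pseudocount = 0))
  stop("expected a pwm or pfm")
}

#' Align a predicted PWM to a reference PWM
#'
#' Slides the prediction over the reference at every offset and in both
#' orientations (the reverse complement of a PWM reverses the column order
#' and swaps the A/T and C/G rows), and returns the placement maximizing
#' the summed IC-weighted PCC over the overlapping columns. At least
#' `min_overlap` columns (default 5) must overlap; ties are broken toward
#' the smaller absolute offset, then the forward orientation.
#'
#' @param ref,pred `pwm` (or `pfm`) objects.
#' @param min_overlap minimum overlapping columns.
#' @return list with `offset` (prediction column j aligns reference column
#'   `j + offset`), `orientation` (`"forward"`/`"reverse"`), `score`.
#' @export
align_pwms <- function(ref, pred, min_overlap = 5) {
  rf <- pwm_freq(ref)
  pf <- pwm_freq(pred)
  Lr <- ncol(rf); Lp <- ncol(pf)
  if (min(Lr, Lp) < min_overlap) {
    stop("alignment error: overlap shorter than ", min_overlap,
         " columns at every offset")
  }
  best <- NULL
  for (orientation in c("forward", "reverse")) {
    pm <- if (orientation == "forward") pf else revcomp_freq(pf)
    for (off in (min_overlap - Lp):(Lr - min_overlap)) {
      js <- seq_len(Lp)
      ks <- js + off
      keep <- ks >= 1 & ks <= Lr
      if (sum(keep) < min_overlap) next
      sc <- sum(vapply(which(keep), function(j) {
        ic_weighted_pcc(rf[, js[j] + off], pm[, js[j]])$ic_weighted_pcc
      }, numeric(1)))
      cand <- list(offset = off, orientation = orientation, score = sc)
      if (is.null(best) || sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 &&
           (abs(off) < abs(best$offset) ||
            (abs(off) == abs(best$offset) && orientation == "forward" &&
             best$orientation == "reverse")))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("alignment error: no offset with at least ", min_overlap,
         " overlapping columns")
  }
  best
}

#' Count correctly predicted motif columns
#'
#' Aligns the prediction to the reference ([align_pwms()]), compares every
#' overlapping column pair with [ic_weighted_pcc()], and reports the number
#' of correct columns (weighted value >= 0.25) together with the averaged
#' Kullback-Leibler divergence over the same alignment.
#'
#' @inheritParams align_pwms
#' @param pseudocount frequency floor used in the KL term.
#' @return an `evaluation_report`: alignment, per-column comparison
#'   data.frame, `n_correct`, `akl` (summed) and `akl_per_column`.
#' @export
count_correct <- function(ref, pred, min_overlap = 5, pseudocount = 1e-4) {
  aln <- align_pwms(ref, pred, min_overlap)
  rf <- pwm_freq(ref)
  pf <- pwm_freq(pred)
  pm <- if (aln$orientation == "forward") pf else revcomp_freq(pf)
  js <- seq_len(ncol(pm))
  ks <- js + aln$offset
  keep <- ks >= 1 & ks <= ncol(rf)
  comp <- lapply(which(keep), function(j) {
    cc <- ic_weighted_pcc(rf[, ks[j]], pm[, j])
    data.frame(ref_index = ks[j], pred_index = j, pcc = cc$pcc,
               ic_ref = cc$ic_ref, ic_weighted_pcc = cc$ic_weighted_pcc,
               correct = cc$correct, degenerate = cc$degenerate)
  })
  comp <- do.call(rbind, comp)
  akl <- akl_divergence(ref, pred, alignment = aln,
                        pseudocount = pseudocount)
  structure(list(alignment = aln, columns = comp,
                 n_correct = sum(comp$correct), n_aligned = nrow(comp),
                 akl = akl, akl_per_column = akl / nrow(comp)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("PWM evaluation: %d / %d aligned columns correct (offset %d, %s)\n",
              x$n_correct, x$n_aligned, x$alignment$offset,
              x$alignment$orientation))
  cat(sprintf("  AKL divergence: %.4f (%.4f per column)\n",
              x$akl, x$akl_per_column))
  invisible(x)
}

#' Averaged Kullback-Leibler divergence between aligned PWMs
#'
#' `D_AKL = sum_i sum_B (P_iB log2 P_iB/Q_iB + Q_iB log2 Q_iB/P_iB) / 2`
#' over the aligned columns, with frequencies floored by a pseudocount
#' (`(f + pc) / (1 + 4 pc)`) so every term is finite. Symmetric in its
#' arguments and 0 for identical aligned columns.
#'
#' @inheritParams count_correct
#' @param alignment optional precomputed [align_pwms()] result; computed
#'   when `NULL`.
#' @return non-negative summed divergence (base-2 logs).
#' @export
akl_divergence <- function(ref, pred, alignment = NULL, min_overlap = 5,
                           pseudocount = 1e-4) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (is.null(alignment)) alignment <- align_pwms(ref, pred, min_overlap)
  rf <- pwm_freq(ref)
  pf <- pwm_freq(pred)
  pm <- if (alignment$orientation == "forward") pf else revcomp_freq(pf)
  js <- seq_len(ncol(pm))
  ks <- js + alignment$offset
  keep <- ks >= 1 & ks <= ncol(rf)
  total <- 0
  for (j in which(keep)) {
    P <- (pm[, j] + pseudocount) / (1 + 4 * pseudocount)
    Q <- (rf[, ks[j]] + pseudocount) / (1 + 4 * pseudocount)
    if (any(P == 0) || any(Q == 0)) {
      stop("domain error: zero frequency; use a positive pseudocount")
    }
    total <- total + sum((P * log2(P / Q) + Q * log2(Q / P)) / 2)
  }
  total
}
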