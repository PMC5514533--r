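#' Predict a TF binding motif from a TF-DNA complex structure
#'
#' End-to-end driver of the pentamer pipeline: detect the TF-contacted
#' binding site (5-Angstrom heavy-atom cutoff) and add flanking base pairs,
#' split the flanked site into overlapping pentamer fragments, thread and
#' score all 1024 sequence permutations of every fragment with the
#' integrative energy, and reconstruct the full-length motif with the
#' requested algorithm:
#' \describe{
#'   \item{kmer_sum}{compose full-length scores as sums of overlapping
#'     fragment scores, select the significant low tail at `0.01 / L`, and
#'     count the selected sequences into a PFM.}
#'   \item{pwm_stack}{select significant pentamers per fragment, build
#'     per-fragment PFMs, and sum columns mapping to the same motif
#'     position.}
#' }
#'
#' @param cx a protonated [tfdna_complex].
#' @param potential an [mb_potential].
#' @param charges a `charge_table` (default: the packaged charge set).
#' @param method motif reconstruction algorithm.
#' @param site optional precomputed [binding_site]; detected when `NULL`.
#' @param contact_cutoff,flank passed to [detect_binding_site()].
#' @param constants,config energy settings.
#' @param significance a [significance_config].
#' @param cache_dir optional fragment score-table cache directory.
#' @return a `pentascan_motif` object: the predicted `pfm` and `pwm`, the
#'   binding site, fragment score tables, the significant sequence set (for
#'   Kmer-Sum), and the call parameters.
#' @seealso [count_correct()] to compare the prediction to a reference
#'   motif, [score_full_length_direct()] for the exhaustive reference
#'   algorithm.
#' @export
predict_motif <- function(cx, potential, charges = default_charge_table(),
                          method = c("kmer_sum", "pwm_stack"),
                          site = NULL, contact_cutoff = 5.0, flank = 2,
                          constants = physical_constants(),
                          config = energy_config(),
                          significance = significance_config(),
                          cache_dir = NULL) {
  method <- match.arg(method)
  validate_complex(cx)
  if (is.null(site)) {
    site <- detect_binding_site(cx, contact_cutoff = contact_cutoff,
                                flank = flank)
  }
  tables <- score_fragments(cx, site, potential, charges, constants,
                            config, cache_dir = cache_dir)
  significant <- NULL
  if (method == "kmer_sum") {
    full <- kmer_sum_scores(tables, L = site_length(site))
    significant <- select_significant(full, significance)
    pfm <- sequences_to_pfm(significant)
  } else {
    pfm <- pwm_stack(tables, significance)
  }
  pwm <- pfm_to_pwm(pfm, pseudocount = if (attr(pfm, "kind") == "counts")
    0.0 else 0.0)
  structure(list(pfm = pfm, pwm = pwm, site = site, tables = tables,
                 significant = significant, method = method,
                 source_id = cx$source_id,
                 native_sequence = substr(cx$duplex$sequence,
                                          site$full_start, site$full_end)),
            class = "pentascan_motif")
}

#' @export
print.pentascan_motif <- function(x, ...) {
  cat("pentascan motif prediction (", x$method, ") for ", x$source_id,
      "\n", sep = "")
  print(x$site)
  cat("  native site sequence:", x$native_sequence, "\n")
  cat("  predicted consensus: ", pwm_consensus(x$pwm), "\n")
  invisible(x)
}

#' @export
summary.pentascan_motif <- function(object, ...) {
  cat("pentascan motif prediction\n")
  cat("  method:        ", object$method, "\n")
  cat("  complex:       ", object$source_id, "\n")
  cat("  site:           core ", object$site$core_start, "..",
      object$site$core_end, ", full ", object$site$full_start, "..",
      object$site$full_end, " (", site_length(object$site), " bp)\n",
      sep = "")
  cat("  fragments:     ", length(object$tables), " x 1024 = ",
      length(object$tables) * 1024, " pentamer evaluations\n", sep = "")
  if (!is.null(object$significant)) {
    cat("  significant sequences:", nrow(object$significant), "\n")
  }
  cat("  per-column IC (bits):",
      paste(sprintf("%.2f", object$pwm$ic), collapse = " "), "\n")
  cat("  consensus:", pwm_consensus(object$pwm), "\n")
  invisible(object)
}

#' @export
plot.pentascan_motif <- function(x, ...) {
  plot(x$pwm, main = paste("predicted motif,", x$method), ...)
}
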