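#' Split a binding site into overlapping pentamer fragments
#'
#' The full (flanked) site of length `L` yields exactly `L - 4` fragments of
#' 5 bp, shifted one base pair at a time. A 9-bp flanked site (5-bp core
#' with 2-bp flanks) gives 5 fragments, hence 5 x 1024 = 5120 pentamer
#' evaluations; a 12-bp site gives 8 fragments (8192 evaluations).
#'
#' @param site a [binding_site] with full length >= 5.
#' @return list of `pentamer_fragment` objects, each with `offset` (1-based
#'   position within the full site), `abs_start` (forward-strand index), and
#'   `window` (the fragment's own 5-bp [binding_site]).
#' @export
make_fragments <- function(site) {
  L <- site_length(site)
  if (L < 5) stop("too-short error: site has ", L, " bp; need at least 5")
  lapply(seq_len(L - 4), function(k) {
    abs_start <- site$full_start + k - 1
    structure(list(offset = k, abs_start = abs_start,
                   window = suppressWarnings(
                     binding_site(abs_start, abs_start + 4, flank = 0,
                                  duplex_length = site$full_end))),
              class = "pentamer_fragment")
  })
}

#' Score every 5-bp permutation of one fragment
#'
#' Threads each of the 4^5 = 1024 pentamer sequences onto the fragment
#' window and evaluates the raw multibody and electrostatic components
#' restricted to that window (multibody triplets fully inside the 5-bp
#' window; all other bases stay native, and only the 5 threaded positions
#' vary). Components are then min-max normalized across the 1024 entries
#' and combined into the integrative energy.
#'
#' Threading leaves the backbone and every glycosidic nitrogen invariant,
#' so both components decompose over window positions / triplets; the
#' scorer exploits this by evaluating the 4 base identities per position
#' once each and composing the 1024 scores, which is exactly equivalent to
#' threading each permutation in full (see the package tests).
#'
#' @param cx a [tfdna_complex].
#' @param fragment a `pentamer_fragment` from [make_fragments()].
#' @param potential an [mb_potential].
#' @param charges a `charge_table`.
#' @param constants a [physical_constants] list.
#' @param config an [energy_config].
#' @return a `fragment_score_table`: list with `offset`, `abs_start`,
#'   `scores` (data.frame: sequence, e_mb, e_elec, e_mb_norm, e_elec_norm,
#'   e_ie; 1024 rows), `complete = TRUE`.
#' @export
score_fragment <- function(cx, fragment, potential, charges,
                           constants = physical_constants(),
                           config = energy_config()) {
  validate_complex(cx)
  win <- fragment$window
  prot_res <- protein_residues(cx)

  # --- electrostatic channel: per (window position, base identity) ---
  elec_contrib <- matrix(0, nrow = 5, ncol = 4,
                         dimnames = list(NULL, DNA_BASES))
  warns <- character(0)
  for (p in 1:5) {
    abs_pos <- win$full_start + p - 1
    for (b in DNA_BASES) {
      cxb <- thread_sequence(cx, abs_pos, b)
      base_res <- c(cxb$duplex$forward[abs_pos],
                    cxb$duplex$reverse[cxb$duplex$pairing[abs_pos]])
      r <- withCallingHandlers(
        elec_pairs(cxb, charges, prot_res, base_res, constants, config,
                   on_missing = "skip"),
        warning = function(w) {
          warns <<- union(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      elec_contrib[p, b] <- r$score
    }
  }
  for (w in warns) warning(w)

  # --- multibody channel: per (triplet position, triplet identity) ---
  triplets <- enumerate_kmers(3)
  mb_contrib <- mb_triplet_contrib(cx, win, potential, prot_res)

  idx <- seq_len(4^5) - 1
  digit <- sapply(1:5, function(p) subkmer_index(idx, 5, p, k = 1)) # 1024 x 5
  e_elec <- numeric(4^5)
  for (p in 1:5) e_elec <- e_elec + elec_contrib[p, digit[, p] + 1]
  e_mb <- numeric(4^5)
  for (t_ in 1:3) {
    tid <- subkmer_index(idx, 5, t_, k = 3)
    e_mb <- e_mb + mb_contrib[t_, tid + 1]
  }

  e_mb_norm <- minmax_normalize(e_mb)
  e_elec_norm <- minmax_normalize(e_elec)
  scores <- data.frame(sequence = index_to_kmer(idx, 5),
                       e_mb = e_mb, e_elec = e_elec,
                       e_mb_norm = e_mb_norm, e_elec_norm = e_elec_norm,
                       e_ie = combine_ie(e_mb_norm, e_elec_norm,
                                         config$w_mb, config$w_e),
                       stringsAsFactors = FALSE)
  structure(list(offset = fragment$offset, abs_start = fragment$abs_start,
                 scores = scores, complete = TRUE,
                 source_id = cx$source_id),
            class = "fragment_score_table")
}

# per-(triplet position, triplet identity) multibody sums for a window:
# rows = triplet start positions inside the window, cols = 64 triplet types
mb_triplet_contrib <- function(cx, win, potential, prot_res) {
  pos <- win$full_start:win$full_end
  n_trip <- length(pos) - 2
  triplets <- enumerate_kmers(3)
  out <- matrix(0, nrow = max(n_trip, 0), ncol = length(triplets))
  if (n_trip < 1) return(out)
  gly <- t(vapply(cx$duplex$forward[pos],
                  function(r) glycosidic_n(cx, r), numeric(3)))
  centers <- (gly[1:n_trip, , drop = FALSE] +
              gly[2:(n_trip + 1), , drop = FALSE] +
              gly[3:(n_trip + 2), , drop = FALSE]) / 3
  nb <- length(potential$bins) - 1
  for (r in prot_res) {
    aa <- cx$residues$resid[r]
    if (!aa %in% AA3) next
    cb <- cbeta_position(cx, r)
    if (is.null(cb)) next
    dd <- sqrt(rowSums(sweep(centers, 2, cb)^2))
    bin <- findInterval(dd, potential$bins, rightmost.closed = TRUE)
    for (t_ in seq_len(n_trip)) {
      if (bin[t_] >= 1 && bin[t_] <= nb) {
        out[t_, ] <- out[t_, ] + potential$table[match(aa, AA3), , bin[t_]]
      }
    }
  }
  out
}

#' @export
print.fragment_score_table <- function(x, ...) {
  cat(sprintf("fragment score table: offset %d (forward strand %d..%d), %d sequences%s\n",
              x$offset, x$abs_start, x$abs_start + 4, nrow(x$scores),
              if (isTRUE(x$complete)) "" else " (incomplete)"))
  best <- x$scores[which.min(x$scores$e_ie), ]
  cat(sprintf("  best pentamer: %s (E_IE = %.4f)\n", best$sequence, best$e_ie))
  invisible(x)
}

#' Score all fragments of a binding site
#'
#' Maps [score_fragment()] over [make_fragments()], optionally caching each
#' fragment table as CSV keyed by (complex id, fragment offset, energy
#' configuration) so motif post-processing never re-runs the energetics.
#'
#' @inheritParams score_fragment
#' @param site a [binding_site].
#' @param cache_dir optional directory for score-table caching.
#' @return list of `fragment_score_table`s, offsets `1 .. L-4`.
#' @export
score_fragments <- function(cx, site, potential, charges,
                            constants = physical_constants(),
                            config = energy_config(), cache_dir = NULL) {
  frags <- make_fragments(site)
  cfg_chars <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  cfg_key <- sprintf("%08x", sum(cfg_chars * seq_along(cfg_chars)) %% 2^28)
  lapply(frags, function(fr) {
    if (!is.null(cache_dir)) {
      key <- file.path(cache_dir, sprintf("%s_frag%02d_%s.csv",
                                          gsub("[^A-Za-z0-9]", "_",
                                               cx$source_id),
                                          fr$offset, cfg_key))
      if (file.exists(key)) {
        return(read_score_table(key, offset = fr$offset,
                                abs_start = fr$abs_start))
      }
      tab <- score_fragment(cx, fr, potential, charges, constants, config)
      write_score_table(tab, key)
      return(tab)
    }
    score_fragment(cx, fr, potential, charges, constants, config)
  })
}

#' Read/write fragment score tables as CSV
#'
#' Columns: sequence, e_mb, e_elec, e_mb_norm, e_elec_norm, e_ie.
#'
#' @param table a `fragment_score_table`.
#' @param path CSV path.
#' @param offset,abs_start fragment placement restored on read.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_score_table <- function(table, path) {
  utils::write.csv(table$scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path, offset = 1, abs_start = offset) {
  scores <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(offset = offset, abs_start = abs_start, scores = scores,
                 complete = nrow(scores) == 4^5, source_id = path),
            class = "fragment_score_table")
}

#' Full-length reference algorithm: direct 4^L enumeration
#'
#' Threads each of the `4^L` full-length sequences onto the site and scores
#' the whole site with the raw integrative-energy components, which are then
#' min-max normalized across all `4^L` entries and combined. This is the
#' exhaustive reference the pentamer path approximates; its cost grows as
#' `4^L`, so sites longer than `cap` are refused (use the pentamer path,
#' [score_fragments()] plus [kmer_sum_scores()], instead).
#'
#' @inheritParams score_fragments
#' @param cap refuse enumeration beyond this site length (default 12).
#' @return a `full_score_table` (see [kmer_sum_scores()]) with provenance
#'   `"direct_enumeration"`.
#' @export
score_full_length_direct <- function(cx, site, potential, charges,
                                     constants = physical_constants(),
                                     config = energy_config(), cap = 12) {
  L <- site_length(site)
  if (L > cap) {
    stop("site length ", L, " exceeds the direct-enumeration cap (", cap,
         "); use the pentamer path (score_fragments + kmer_sum_scores)")
  }
  n <- 4^L
  e_mb <- numeric(n)
  e_elec <- numeric(n)
  seqs <- enumerate_kmers(L)
  warns <- character(0)
  for (i in seq_len(n)) {
    cxi <- thread_sequence(cx, site$full_start, seqs[i])
    r <- withCallingHandlers(
      score_site(cxi, site, potential, charges, constants, config),
      warning = function(w) {
        warns <<- union(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    e_mb[i] <- r$e_mb
    e_elec[i] <- r$e_elec
  }
  for (w in warns) warning(w)
  e_mb_norm <- minmax_normalize(e_mb)
  e_elec_norm <- minmax_normalize(e_elec)
  new_full_score_table(L = L, e_mb = e_mb, e_elec = e_elec,
                       e_ie = combine_ie(e_mb_norm, e_elec_norm,
                                         config$w_mb, config$w_e),
                       provenance = "direct_enumeration")
}

#' In-place fragment-sum score of one full-length sequence
#'
#' The independent route to a composed pentamer score: thread the whole
#' sequence onto the site once, then evaluate the raw energy components of
#' every overlapping 5-bp fragment window in place and sum them. For a
#' window-local energy this must equal the Kmer-Sum composition of the
#' per-fragment score tables, sequence by sequence.
#'
#' @inheritParams score_fragments
#' @param sequence full-length base string, `nchar(sequence) ==
#'   site_length(site)`.
#' @return list with `e_mb` and `e_elec` fragment sums.
#' @export
score_site_by_fragments <- function(cx, site, sequence, potential, charges,
                                    constants = physical_constants(),
                                    config = energy_config()) {
  stopifnot(nchar(sequence) == site_length(site))
  cxs <- thread_sequence(cx, site$full_start, sequence)
  frags <- make_fragments(site)
  e_mb <- 0; e_elec <- 0
  for (fr in frags) {
    e_mb <- e_mb + score_mb(cxs, potential, fr$window)
    el <- score_electrostatic(cxs, charges, fr$window, constants, config)
    e_elec <- e_elec + el$score
  }
  list(e_mb = e_mb, e_elec = e_elec)
}

new_full_score_table <- function(L, e_mb, e_elec, e_ie, provenance) {
  structure(list(L = L, e_mb = e_mb, e_elec = e_elec, e_ie = e_ie,
                 provenance = provenance),
            class = "full_score_table")
}

#' @export
print.full_score_table <- function(x, ...) {
  cat(sprintf("full-length score table: L = %d, %d sequences (%s)\n",
              x$L, length(x$e_ie), x$provenance))
  b <- which.min(x$e_ie)
  cat(sprintf("  best sequence: %s (score %.4f)\n",
              index_to_kmer(b - 1, x$L), x$e_ie[b]))
  invisible(x)
}

#' Sequences of a full-length score table
#'
#' @param table a `full_score_table`.
#' @param idx optional 1-based indices (default: all `4^L`, which can be
#'   large; prefer passing indices).
#' @return character vector of sequences in table order.
#' @export
table_sequences <- function(table, idx = seq_along(table$e_ie)) {
  index_to_kmer(idx - 1, table$L)
}
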