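#' Coulomb energy between two partial charges
#'
#' Evaluates `k_e * N_A * (q_a e)(q_b e) / (epsilon d)` with the distance
#' converted to meters, giving a molar energy in J/mol. The sign follows the
#' charge product. Units are immaterial downstream: integrative-energy
#' components are min-max normalized before they are combined.
#'
#' @param q_a,q_b partial charges in electron-charge units.
#' @param d separation in Angstrom (> 0).
#' @param constants a [physical_constants] list.
#' @return energy in J/mol.
#' @export
pair_electrostatic <- function(q_a, q_b, d, constants = physical_constants()) {
  if (any(d <= 0)) stop("domain error: distance must be positive")
  constants$k_e * constants$N_A *
    (q_a * constants$electron_charge) * (q_b * constants$electron_charge) /
    (constants$epsilon * d * 1e-10)
}

#' Electrostatic score of a TF-DNA complex over a binding-site window
#'
#' Sums [pair_electrostatic()] over two interaction channels between the
#' protein and the window's base pairs (both strands):
#' \describe{
#'   \item{hydrogen-bond channel}{pairs of a hydrogen on one molecule and an
#'     O/N/S acceptor on the other, with the hydrogen-acceptor distance
#'     inside `[hbond_min, hbond_max]` (default 1.5-2.9 Angstrom). No
#'     angular criterion is applied.}
#'   \item{pi channel}{an aromatic residue (Phe/Tyr/Trp/His) and a base
#'     whose ring systems approach within `pi_cutoff` (default 4.5 Angstrom,
#'     any ring-atom pair) are scored once per (residue, base) pair, using
#'     the summed ring charges of each pi system at the centroid-centroid
#'     distance.}
#' }
#'
#' Atoms without a charge-table entry are skipped with a single aggregated
#' warning (set `on_missing = "error"` to fail instead).
#'
#' @param cx a protonated [tfdna_complex].
#' @param charges a `charge_table` (see [read_charge_table()]).
#' @param window a [binding_site]; only its bases enter the score.
#' @param constants a [physical_constants] list.
#' @param config an [energy_config] list (distance windows).
#' @param on_missing `"skip"` or `"error"` for atoms lacking charges.
#' @return list with `score` (J/mol), `n_ab` (number of contributing
#'   amino-acid/base interactions), and per-channel subtotals.
#' @export
score_electrostatic <- function(cx, charges, window,
                                constants = physical_constants(),
                                config = energy_config(),
                                on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  validate_complex(cx)
  pos <- window$full_start:window$full_end
  base_res <- c(cx$duplex$forward[pos],
                cx$duplex$reverse[cx$duplex$pairing[pos]])
  prot_res <- protein_residues(cx)
  acc <- elec_pairs(cx, charges, prot_res, base_res, constants, config,
                    on_missing)
  acc
}

# shared worker: all channel pairs between the given protein residues and
# the given base residues (residue-table rows)
elec_pairs <- function(cx, charges, prot_res, base_res, constants, config,
                      on_missing) {
  a <- cx$atoms
  p_rows <- residue_atom_rows(cx, prot_res)
  b_rows <- residue_atom_rows(cx, base_res)
  missing_keys <- character(0)

  q_p <- lookup_charges(charges, a$resid[p_rows], a$elety[p_rows])
  q_b <- lookup_charges(charges, a$resid[b_rows], a$elety[b_rows])

  hb <- 0; n_hb <- 0L
  channel_pairs <- function(h_rows, q_h, acc_rows, q_acc) {
    if (length(h_rows) == 0 || length(acc_rows) == 0) return(NULL)
    H <- a$xyz[h_rows, , drop = FALSE]
    A_ <- a$xyz[acc_rows, , drop = FALSE]
    d2 <- outer(rowSums(H^2), rowSums(A_^2), "+") - 2 * H %*% t(A_)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    hit <- which(d >= config$hbond_min & d <= config$hbond_max,
                 arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    qh <- q_h[hit[, 1]]; qa <- q_acc[hit[, 2]]
    ok <- !is.na(qh) & !is.na(qa)
    if (any(!ok)) {
      ks <- c(paste(a$resid[h_rows[hit[!ok, 1]]],
                    a$elety[h_rows[hit[!ok, 1]]], sep = "|"),
              paste(a$resid[acc_rows[hit[!ok, 2]]],
                    a$elety[acc_rows[hit[!ok, 2]]], sep = "|"))
      ks <- ks[is.na(c(qh[!ok], qa[!ok]))]
      missing_keys <<- union(missing_keys, ks)
      if (on_missing == "error") {
        stop("no charge entry for atom(s): ", paste(ks, collapse = ", "))
      }
    }
    list(e = sum(pair_electrostatic(qh[ok], qa[ok], d[hit][ok], constants)),
         n = sum(ok))
  }

  p_h <- p_rows[a$element[p_rows] == "H"]
  b_h <- b_rows[a$element[b_rows] == "H"]
  p_acc <- p_rows[is_acceptor(a$resid[p_rows], a$elety[p_rows])]
  b_acc <- b_rows[is_acceptor(a$resid[b_rows], a$elety[b_rows])]

  r1 <- channel_pairs(p_h, q_p[match(p_h, p_rows)],
                      b_acc, q_b[match(b_acc, b_rows)])
  r2 <- channel_pairs(b_h, q_b[match(b_h, b_rows)],
                      p_acc, q_p[match(p_acc, p_rows)])
  for (r in list(r1, r2)) {
    if (!is.null(r)) { hb <- hb + r$e; n_hb <- n_hb + r$n }
  }

  # pi channel: once per (aromatic residue, base) pair
  pi_e <- 0; n_pi <- 0L
  arom <- prot_res[cx$residues$resid[prot_res] %in% AROMATIC_AA]
  for (pr in arom) {
    ring_p <- ring_atoms(cx, charges, pr)
    if (is.null(ring_p)) next
    for (br in base_res) {
      ring_b <- ring_atoms(cx, charges, br)
      if (is.null(ring_b)) next
      d2 <- outer(rowSums(ring_p$xyz^2), rowSums(ring_b$xyz^2), "+") -
        2 * ring_p$xyz %*% t(ring_b$xyz)
      if (min(d2) <= config$pi_cutoff^2 + 1e-12) {
        cen_d <- vnorm(colMeans(ring_p$xyz) - colMeans(ring_b$xyz))
        pi_e <- pi_e + pair_electrostatic(ring_p$q, ring_b$q, cen_d,
                                          constants)
        n_pi <- n_pi + 1L
      }
    }
  }
  if (length(missing_keys) && on_missing == "skip") {
    warning("skipped atoms with no charge entry: ",
            paste(sort(missing_keys), collapse = ", "))
  }
  list(score = hb + pi_e, n_ab = n_hb + n_pi, hbond = hb, pi = pi_e,
       n_hbond = n_hb, n_pi = n_pi)
}

# ring-atom coordinates and summed pi-system charge for residue r, or NULL
# if the residue has no pi system or the ring is incomplete
ring_atoms <- function(cx, charges, r) {
  resid <- cx$residues$resid[r]
  ring <- charges$pi_atoms[[resid]]
  if (is.null(ring)) return(NULL)
  rows <- cx$res_rows[[r]]
  hit <- rows[match(ring, cx$atoms$elety[rows])]
  if (anyNA(hit)) return(NULL)
  q <- lookup_charges(charges, cx$atoms$resid[hit], cx$atoms$elety[hit])
  if (anyNA(q)) return(NULL)
  list(xyz = cx$atoms$xyz[hit, , drop = FALSE], q = sum(q))
}
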