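#' Energy configuration
#'
#' Collects the tunable parameters of the integrative energy in one place.
#' Defaults: hydrogen-bond window 1.5-2.9 Angstrom (hydrogen to acceptor),
#' pi-interaction cutoff 4.5 Angstrom, weights 1.0 (multibody) and 0.5
#' (electrostatics), dielectric constant 4.0, multibody distance bins of
#' 1 Angstrom from 0 to 15 with pseudocount 0.5.
#'
#' @param epsilon dielectric constant.
#' @param hbond_min,hbond_max hydrogen-bond distance window (Angstrom).
#' @param pi_cutoff pi-interaction ring-atom cutoff (Angstrom).
#' @param w_mb,w_e weights of the normalized multibody and electrostatic
#'   terms in the integrative energy.
#' @param mb_bins multibody potential distance-bin edges (Angstrom).
#' @param mb_pseudocount pseudocount used when training the potential.
#' @return list of class `energy_config`.
#' @export
energy_config <- function(epsilon = 4.0, hbond_min = 1.5, hbond_max = 2.9,
                          pi_cutoff = 4.5, w_mb = 1.0, w_e = 0.5,
                          mb_bins = 0:15, mb_pseudocount = 0.5) {
  stopifnot(hbond_min > 0, hbond_max > hbond_min, pi_cutoff > 0,
            length(mb_bins) >= 2, all(diff(mb_bins) > 0),
            mb_pseudocount > 0)
  structure(list(epsilon = epsilon, hbond_min = hbond_min,
                 hbond_max = hbond_max, pi_cutoff = pi_cutoff,
                 w_mb = w_mb, w_e = w_e, mb_bins = mb_bins,
                 mb_pseudocount = mb_pseudocount),
            class = "energy_config")
}

#' Min-max normalization
#'
#' Maps scores linearly onto `[0, 1]`: the minimum to 0 and the maximum
#' to 1. A degenerate input (all values equal) yields all zeros with a
#' warning. Normalization preserves ranking order and is invariant to affine
#' rescaling of the input.
#'
#' @param scores numeric vector, length >= 1.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 1, all(is.finite(scores)))
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    warning("degenerate score distribution (all values equal); ",
            "normalized scores set to 0")
    return(rep(0, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Combine normalized energy components into the integrative energy
#'
#' `E_IE = w_mb * e_mb_norm + w_e * e_elec_norm`. With the default weights
#' (1, 0.5) two maximal components give 1.5. Lower integrative energy is
#' more favorable throughout the package: raw mean-force and Coulomb scores
#' are negative for favored contacts, min-max normalization is monotone, so
#' the favorable tail of `E_IE` is the low one.
#'
#' @param e_mb_norm,e_elec_norm normalized component scores.
#' @param w_mb,w_e component weights.
#' @return the combined score.
#' @export
combine_ie <- function(e_mb_norm, e_elec_norm, w_mb = 1.0, w_e = 0.5) {
  stopifnot(all(is.finite(e_mb_norm)), all(is.finite(e_elec_norm)))
  w_mb * e_mb_norm + w_e * e_elec_norm
}

#' Raw integrative-energy components of one complex over a window
#'
#' Convenience wrapper returning the raw multibody and electrostatic scores
#' of a single (threaded) complex restricted to a binding-site window. Used
#' by the full-length reference path; the pentamer engine normalizes such
#' raw components across a permutation set before combining them.
#'
#' @inheritParams score_electrostatic
#' @param potential an [mb_potential].
#' @return list with `e_mb`, `e_elec`, `n_ab`.
#' @export
score_site <- function(cx, window, potential, charges,
                       constants = physical_constants(),
                       config = energy_config(),
                       on_missing = "skip") {
  e_mb <- score_mb(cx, potential, window)
  el <- score_electrostatic(cx, charges, window, constants, config,
                            on_missing = on_missing)
  list(e_mb = e_mb, e_elec = el$score, n_ab = el$n_ab)
}
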