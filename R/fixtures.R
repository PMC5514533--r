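#' Build an idealized straight-helix B-DNA duplex
#'
#' Constructs a paired, complementary duplex from the package's idealized
#' nucleotide geometries: base pair `i` sits at `(i-1) * rise` Angstrom
#' along the helix (z) axis, rotated by `(i-1) * twist` degrees. Watson-
#' Crick partners are placed with the frozen pair transforms fitted to
#' canonical hydrogen-bond distances. The helix is rigid and sequence
#' independent apart from base identity — no sequence-dependent shape, no
#' bending — which is exactly what threading assumes.
#'
#' @param sequence forward-strand base string over `{A,C,G,T}`.
#' @param rise helical rise per base pair in Angstrom (default 3.38).
#' @param twist helical twist per base pair in degrees (default 36).
#' @return a [tfdna_complex] with an empty protein part (add probe residues
#'   with [build_toy_complex()] to obtain a scoreable complex).
#' @export
build_bdna <- function(sequence, rise = 3.38, twist = 36.0) {
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(letters) < 1 || !all(letters %in% DNA_BASES)) {
    stop("alphabet error: sequence must be a non-empty string over {A,C,G,T}")
  }
  n <- length(letters)
  fwd_blocks <- vector("list", n)
  rev_blocks <- vector("list", n)
  for (i in seq_len(n)) {
    X <- letters[i]
    Y <- unname(BASE_COMPLEMENT[X])
    tx <- .ideal_nucleotides[[X]]
    ty <- .ideal_nucleotides[[Y]]
    tr <- .wc_pair_transforms[[X]]
    xc <- cbind(tx$x, tx$y, tx$z)
    yc <- cbind(ty$x, ty$y, ty$z) %*% t(tr$R)
    yc <- sweep(yc, 2, tr$t, "+")
    # pair frame in the forward base's coordinates: origin at the midpoint
    # of the two glycosidic nitrogens, e1 toward the forward base, e3 the
    # base-plane normal (helix axis)
    M <- tr$t / 2
    e1 <- unit(-M)
    e3 <- c(0, 0, 1)
    e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
            e3[3] * e1[1] - e3[1] * e1[3],
            e3[1] * e1[2] - e3[2] * e1[1])
    B <- rbind(e1, e2, e3)
    phi <- (i - 1) * twist * pi / 180
    Rz <- matrix(c(cos(phi), sin(phi), 0,
                   -sin(phi), cos(phi), 0, 0, 0, 1), 3, 3)
    place <- function(cm) {
      w <- sweep(cm, 2, M) %*% t(B) %*% t(Rz)
      sweep(w, 2, c(0, 0, (i - 1) * rise), "+")
    }
    fwd_blocks[[i]] <- list(elety = tx$name, element = tx$element,
                            letter = X, xyz = place(xc))
    rev_blocks[[i]] <- list(elety = ty$name, element = ty$element,
                            letter = Y, xyz = place(yc))
  }
  # chain A: forward 5'->3'; chain B: reverse strand, its own 5'->3' order
  # runs from the last pair back to the first
  blocks <- c(fwd_blocks, rev_blocks[n:1])
  chains <- c(rep("A", n), rep("B", n))
  resnos <- c(seq_len(n), seq_len(n))
  letters_all <- vapply(blocks, function(b) b$letter, character(1))
  atoms <- list(
    elety = unlist(lapply(blocks, function(b) b$elety), use.names = FALSE),
    resid = unlist(mapply(function(b, l) rep(unname(DNA_RESNAMES[l]),
                                             length(b$elety)),
                          blocks, letters_all, SIMPLIFY = FALSE),
                   use.names = FALSE),
    chain = rep(chains, vapply(blocks, function(b) length(b$elety),
                               integer(1))),
    resno = rep(resnos, vapply(blocks, function(b) length(b$elety),
                               integer(1))),
    element = unlist(lapply(blocks, function(b) b$element),
                     use.names = FALSE),
    xyz = do.call(rbind, lapply(blocks, function(b) b$xyz)))
  residues <- data.frame(chain = chains, resno = resnos,
                         resid = unname(DNA_RESNAMES[letters_all]),
                         kind = "dna", letter = letters_all,
                         stringsAsFactors = FALSE)
  duplex <- list(forward = seq_len(n),
                 reverse = (n + 1):(2 * n),
                 pairing = n:1,
                 sequence = paste(letters, collapse = ""))
  new_tfdna_complex(atoms, residues, protein_chains = list(),
                    duplex = duplex, source_id = "bdna_fixture")
}

#' Fixture specification for a toy TF-DNA complex
#'
#' @param sequence forward-strand bases, or `"random"` to draw one of
#'   length `dna_length` under `seed`.
#' @param dna_length used when `sequence = "random"`.
#' @param seed integer fixing all randomness of the fixture.
#' @param probe_atoms list of probe placement rules; each is a list with
#'   `resid` (amino-acid 3-letter code), `atom` (probe atom name, or
#'   `"RING"` for an aromatic six-ring), `base_pos` (forward-strand
#'   position), `base_atom` (target atom name), `distance` (Angstrom
#'   between probe atom — or nearest ring atom — and the target atom).
#'   Optional fields: `clear = "heavy"` maximizes clearance against all
#'   duplex heavy atoms (for contact-detection fixtures) instead of the
#'   energy-channel partner set, and `support = FALSE` omits the backbone
#'   support atoms.
#' @param rise,twist helix parameters passed to [build_bdna()].
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(sequence = "random", dna_length = 9, seed = 1,
                         probe_atoms = list(), rise = 3.38, twist = 36.0) {
  stopifnot(dna_length >= 5)
  structure(list(sequence = sequence, dna_length = dna_length, seed = seed,
                 probe_atoms = probe_atoms, rise = rise, twist = twist),
            class = "fixture_spec")
}

#' Build a toy TF-DNA complex with analytically placed probe atoms
#'
#' Produces an idealized duplex plus minimal protein residues whose probe
#' atoms sit at exact prescribed distances from named base atoms, so the
#' behavior of the energy distance windows is known by construction. The
#' probe direction is chosen deterministically to maximize clearance from
#' the rest of the relevant partner set (acceptors for a hydrogen probe,
#' hydrogens for an acceptor probe, base-ring atoms for an aromatic ring),
#' so the prescribed contact is the only one near the window. Each probe
#' residue carries backbone support atoms (N, CA, C, and CB except for
#' glycine) further out along the same direction so the multibody term has
#' a C-beta to work with. Toy residues are deliberately not chemically
#' complete.
#'
#' @param spec a [fixture_spec].
#' @return a [tfdna_complex] (deterministic function of the spec).
#' @export
build_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  seq_str <- spec$sequence
  if (identical(seq_str, "random")) {
    seq_str <- local({
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(spec$seed)
      paste(sample(DNA_BASES, spec$dna_length, replace = TRUE),
            collapse = "")
    })
  }
  cx <- build_bdna(seq_str, rise = spec$rise, twist = spec$twist)
  n <- length(cx$duplex$forward)

  a <- cx$atoms
  res <- cx$residues
  pn <- 0
  for (pr in spec$probe_atoms) {
    pn <- pn + 1
    r <- cx$duplex$forward[pr$base_pos]
    target <- residue_atom_xyz(cx, r, pr$base_atom)
    if (is.null(target)) {
      stop("spec error: base position ", pr$base_pos, " has no atom ",
           pr$base_atom)
    }
    if (identical(pr$atom, "RING")) {
      if (!pr$resid %in% AROMATIC_AA) {
        stop("spec error: RING probes need an aromatic residue")
      }
      partners <- duplex_ring_xyz(cx)
      sol <- place_probe(target, pr$distance, partners, ring = TRUE)
      names_i <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      xyz_i <- sol$xyz
      elem_i <- rep("C", 6)
      anchor <- sol$anchor
    } else if (identical(pr$clear, "heavy")) {
      # contact-detection probe: prescribed distance is the global minimum
      # to any duplex heavy atom; clearance is maximized against the base
      # pairs the probe is NOT allowed to contact
      allowed <- if (is.null(pr$allowed)) pr$base_pos else pr$allowed
      sol <- place_contact_probe(cx, target, pr$distance, allowed, target_pos = pr$base_pos)
      xyz_i <- sol$xyz
      names_i <- pr$atom
      elem_i <- guess_element(pr$atom)
      anchor <- sol$anchor
    } else {
      elem1 <- guess_element(pr$atom)
      partners <- if (elem1 == "H") duplex_acceptor_xyz(cx) else
        duplex_hydrogen_xyz(cx)
      sol <- place_probe(target, pr$distance, partners, ring = FALSE)
      xyz_i <- sol$xyz
      names_i <- pr$atom
      elem_i <- elem1
      anchor <- sol$anchor
    }
    u <- sol$u
    if (!isFALSE(pr$support)) {
      support <- list(CB = anchor + 1.2 * u, CA = anchor + 2.7 * u,
                      N = anchor + 2.7 * u + c(0, 0, 1.45),
                      C = anchor + 2.7 * u - c(0, 0, 1.52))
      if (pr$resid == "GLY") support$CB <- NULL
      names_i <- c(names_i, names(support))
      xyz_i <- rbind(xyz_i, do.call(rbind, support))
      elem_i <- c(elem_i, substr(names(support), 1, 1))
    }
    keep_new <- !duplicated(names_i)
    names_i <- names_i[keep_new]
    xyz_i <- xyz_i[keep_new, , drop = FALSE]
    elem_i <- elem_i[keep_new]

    a$elety <- c(a$elety, names_i)
    a$resid <- c(a$resid, rep(pr$resid, length(names_i)))
    a$chain <- c(a$chain, rep("P", length(names_i)))
    a$resno <- c(a$resno, rep(pn, length(names_i)))
    a$element <- c(a$element, elem_i)
    a$xyz <- rbind(a$xyz, xyz_i)
    res <- rbind(res, data.frame(chain = "P", resno = pn, resid = pr$resid,
                                 kind = "protein", letter = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  if (pn == 0) stop("spec error: a toy complex needs at least one probe")
  cx2 <- new_tfdna_complex(a, res, protein_chains = list(P = which(res$kind ==
                                                                   "protein")),
                           duplex = cx$duplex,
                           source_id = sprintf("toy_seed%d", spec$seed))
  validate_complex(cx2)
  cx2
}

# --- probe placement helpers -------------------------------------------
#
# A probe must sit at an exact prescribed distance from its interaction
# partner set (acceptors for an H probe, hydrogens for an acceptor probe,
# base-ring atoms for an aromatic ring) so the energy distance windows
# behave analytically. The placement searches a fixed Fibonacci sphere of
# directions from the target atom, solves for the offset at which the
# global minimum probe-partner distance equals the prescribed one, and
# keeps the direction with the largest clearance to the second-nearest
# partner. Fully deterministic.

duplex_rows <- function(cx) {
  residue_atom_rows(cx, c(cx$duplex$forward, cx$duplex$reverse))
}

duplex_acceptor_xyz <- function(cx) {
  rows <- duplex_rows(cx)
  rows <- rows[is_acceptor(cx$atoms$resid[rows], cx$atoms$elety[rows])]
  cx$atoms$xyz[rows, , drop = FALSE]
}

duplex_hydrogen_xyz <- function(cx) {
  rows <- duplex_rows(cx)
  rows <- rows[cx$atoms$element[rows] == "H"]
  cx$atoms$xyz[rows, , drop = FALSE]
}

BASE_RING_ATOMS <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  DG = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  DC = c("N1", "C2", "N3", "C4", "C5", "C6"),
  DT = c("N1", "C2", "N3", "C4", "C5", "C6"))

duplex_ring_xyz <- function(cx) {
  rows <- duplex_rows(cx)
  keep <- mapply(function(rs, e) e %in% BASE_RING_ATOMS[[rs]],
                 cx$atoms$resid[rows], cx$atoms$elety[rows])
  cx$atoms$xyz[rows[vapply(keep, isTRUE, logical(1))], , drop = FALSE]
}

fibonacci_sphere <- function(n = 200) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# six-membered ring with its nearest atom (CG) at `t` along `u` from target
probe_ring_xyz <- function(target, u, t) {
  cen <- target + (t + 1.39) * u
  w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- unit(w - sum(w * u) * u)
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  t(vapply(ang, function(a) cen + 1.39 * (cos(a) * (-u) + sin(a) * v),
           numeric(3)))
}

place_probe <- function(target, distance, partners, ring = FALSE) {
  # partners excluding the target atom itself
  keep <- sqrt(rowSums(sweep(partners, 2, target)^2)) > 1e-6
  others <- partners[keep, , drop = FALSE]
  dirs <- fibonacci_sphere(300)
  probe_at <- function(u) {
    if (ring) probe_ring_xyz(target, u, distance) else
      matrix(target + distance * u, nrow = 1)
  }
  best <- NULL
  for (k in seq_len(nrow(dirs))) {
    u <- dirs[k, ]
    xyz <- probe_at(u)
    # clearance: every probe-partner pair other than (primary atom, target)
    d_others <- sqrt(outer(rowSums(xyz^2), rowSums(others^2), "+") -
                     2 * xyz %*% t(others))
    margin <- min(d_others)
    if (ring && nrow(xyz) > 1) {
      d_tgt <- sqrt(rowSums(sweep(xyz[-1, , drop = FALSE], 2, target)^2))
      margin <- min(margin, d_tgt)
    }
    if (is.null(best) || margin > best$margin) {
      best <- list(u = u, margin = margin)
    }
  }
  if (best$margin <= distance) {
    warning("probe clearance ", round(best$margin, 2),
            " Angstrom does not exceed the prescribed distance ", distance)
  }
  xyz <- probe_at(best$u)
  anchor <- if (ring) colMeans(xyz) + 1.39 * best$u else xyz[1, ]
  list(xyz = xyz, anchor = anchor, u = best$u, margin = best$margin)
}

# forward-strand pair position of every atom (NA for protein atoms)
atom_pair_position <- function(cx) {
  pos <- rep(NA_integer_, nrow(cx$atoms$xyz))
  for (i in seq_along(cx$duplex$forward)) {
    pos[cx$res_rows[[cx$duplex$forward[i]]]] <- i
    pos[cx$res_rows[[cx$duplex$reverse[cx$duplex$pairing[i]]]]] <- i
  }
  pos
}

place_contact_probe <- function(cx, target, distance, allowed, target_pos = allowed[1]) {
  heavy <- cx$atoms$element != "H"
  all_xyz <- cx$atoms$xyz[heavy, , drop = FALSE]
  pp <- atom_pair_position(cx)[heavy]
  dis_xyz <- all_xyz[!(pp %in% allowed), , drop = FALSE]
  dirs <- fibonacci_sphere(300)
  best <- NULL
  for (k in seq_len(nrow(dirs))) {
    u <- dirs[k, ]
    f <- function(t) {
      p <- target + t * u
      min(sqrt(colSums((t(all_xyz) - p)^2))) - distance
    }
    if (f(0.1) >= 0 || f(distance + 10) <= 0) next
    t_ <- stats::uniroot(f, c(0.1, distance + 10), tol = 1e-9)$root
    p <- target + t_ * u
    d_all <- sqrt(colSums((t(all_xyz) - p)^2))
    on_target <- pp[which.min(d_all)] %in% target_pos
    margin <- if (nrow(dis_xyz)) {
      min(sqrt(colSums((t(dis_xyz) - p)^2)))
    } else Inf
    if (is.null(best) || (on_target && !best$on_target) ||
        (on_target == best$on_target && margin > best$margin)) {
      best <- list(u = u, t = t_, margin = margin, on_target = on_target)
    }
  }
  if (is.null(best)) stop("spec error: could not place contact probe")
  list(xyz = matrix(target + best$t * best$u, nrow = 1),
       anchor = target + best$t * best$u, u = best$u,
       margin = best$margin)
}

#' Planted-motif score landscape
#'
#' Synthetic fragment score tables carrying a planted preference for a
#' target sequence `s_star`: each pentamer's score is Gaussian baseline
#' noise minus `bonus` times the number of positions matching the target's
#' subsequence in that window. With `bonus` well above the noise scale,
#' both motif-prediction algorithms must recover `s_star`; with
#' `bonus = 0` the landscape is pure noise and the recovered motif carries
#' no information. Used for parameter-recovery testing without structural
#' energetics.
#'
#' @param s_star target full-length sequence (length >= 5).
#' @param bonus score bonus per matching position (> 0, or 0 for the null
#'   landscape).
#' @param noise_sd Gaussian baseline noise standard deviation.
#' @param seed integer; the landscape is a deterministic function of
#'   `(s_star, bonus, noise_sd, seed)`.
#' @return list of `fragment_score_table`s, offsets `1 .. L-4`.
#' @export
plant_landscape <- function(s_star, bonus = 1, noise_sd = 0.1, seed = 1) {
  L <- nchar(s_star)
  stopifnot(L >= 5, bonus >= 0)
  target <- strsplit(toupper(s_star), "", fixed = TRUE)[[1]]
  stopifnot(all(target %in% DNA_BASES))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  kmers <- enumerate_kmers(5)
  km <- matrix(unlist(strsplit(kmers, "", fixed = TRUE)), ncol = 5,
               byrow = TRUE)
  lapply(seq_len(L - 4), function(o) {
    sub <- target[o:(o + 4)]
    matches <- rowSums(km == matrix(sub, nrow = 4^5, ncol = 5,
                                    byrow = TRUE))
    e <- stats::rnorm(4^5, 0, noise_sd) - bonus * matches
    scores <- data.frame(sequence = kmers, e_mb = e, e_elec = 0,
                         e_mb_norm = 0, e_elec_norm = 0, e_ie = e,
                         stringsAsFactors = FALSE)
    structure(list(offset = o, abs_start = o, scores = scores,
                   complete = TRUE, source_id = "planted"),
              class = "fragment_score_table")
  })
}
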