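test_that("pair electrostatics matches hand-computed Coulomb arithmetic", {
  cst <- physical_constants(epsilon = 1)
  # independent constant arithmetic: k_e N_A (q_a e)(q_b e) / (eps d)
  hand <- 8.9875517873681764e9 * 6.02214076e23 *
    (0.4 * 1.6e-19) * (-0.4 * 1.6e-19) / (1 * 2.0e-10)
  got <- pair_electrostatic(0.4, -0.4, 2.0, cst)
  expect_equal(got, hand, tolerance = 1e-6)
  # zero charge annihilates, symmetry in the charge pair
  expect_equal(pair_electrostatic(0, 0.7, 1.7), 0)
  expect_equal(pair_electrostatic(0.3, -0.2, 2.4),
               pair_electrostatic(-0.2, 0.3, 2.4))
  expect_error(pair_electrostatic(0.1, 0.1, 0), "domain error")
  expect_error(pair_electrostatic(0.1, 0.1, -1), "domain error")
})

test_that("hydrogen-bond channel honors the 1.5-2.9 A window", {
  el <- score_electrostatic(toy_hbond_probe(2.0), default_charges, window9)
  expect_equal(el$n_hbond, 1L)
  # exactly one pair: serine HG (+0.43) to adenine N7 (-0.62) at 2.0 A
  expect_equal(el$score, pair_electrostatic(0.43, -0.62, 2.0))
  el3 <- score_electrostatic(toy_hbond_probe(3.0), default_charges, window9)
  expect_equal(el3$n_ab, 0L)
  expect_equal(el3$score, 0)
  # just inside the near edge is kept, just below is dropped
  el_in <- score_electrostatic(toy_hbond_probe(1.6), default_charges, window9)
  expect_equal(el_in$n_hbond, 1L)
  el_out <- score_electrostatic(toy_hbond_probe(1.4), default_charges,
                                window9)
  expect_equal(el_out$n_hbond, 0L)
})

test_that("pi channel honors the 4.5 A ring-atom cutoff and counts once per pair", {
  e_in <- score_electrostatic(toy_ring_probe(4.4), default_charges, window9)
  expect_gte(e_in$n_pi, 1L)
  e_out <- score_electrostatic(toy_ring_probe(4.6), default_charges, window9)
  expect_equal(e_out$n_pi, 0L)
  # scored once with summed ring charges at centroid distance
  cx <- toy_ring_probe(4.4)
  ring_p <- pentascan:::ring_atoms(cx, default_charges,
                                   which(cx$residues$kind == "protein")[1])
  r_base <- cx$duplex$forward[5]
  ring_b <- pentascan:::ring_atoms(cx, default_charges, r_base)
  d <- sqrt(sum((colMeans(ring_p$xyz) - colMeans(ring_b$xyz))^2))
  expect_equal(e_in$pi, pair_electrostatic(ring_p$q, ring_b$q, d))
})

test_that("electrostatic score flips sign when one molecule's charges flip", {
  ch2 <- default_charges
  is_dna <- grepl("^D[ACGT]\\|", names(ch2$charges))
  ch2$charges[is_dna] <- -ch2$charges[is_dna]
  a <- score_electrostatic(toy_hbond_probe(2.0), default_charges, window9)
  b <- score_electrostatic(toy_hbond_probe(2.0), ch2, window9)
  expect_equal(a$score, -b$score)
})

test_that("electrostatic window score is additive over per-pair sub-windows", {
  full <- binding_site(1, 9, flank = 0, duplex_length = 9)
  whole <- score_electrostatic(toy9, default_charges, full)
  parts <- lapply(1:9, function(i) {
    w <- binding_site(i, i, flank = 0, duplex_length = 9)
    score_electrostatic(toy9, default_charges, w)
  })
  expect_equal(whole$score, sum(vapply(parts, `[[`, numeric(1), "score")))
  expect_equal(whole$n_ab, sum(vapply(parts, function(p) as.numeric(p$n_ab),
                                      numeric(1))))
})

test_that("missing charge entries skip with warning or fail on request", {
  ch <- default_charges
  ch$charges <- ch$charges[names(ch$charges) != "SER|HG"]
  expect_warning(
    el <- score_electrostatic(toy_hbond_probe(2.0), ch, window9),
    "no charge entry")
  expect_equal(el$n_hbond, 0L)
  expect_error(
    score_electrostatic(toy_hbond_probe(2.0), ch, window9,
                        on_missing = "error"),
    "no charge entry")
})

test_that("min-max normalization maps to [0,1] and preserves order", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(c(5, 5, 5)), "degenerate")
  expect_equal(z, c(0, 0, 0))
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(50)
    n1 <- minmax_normalize(x)
    expect_true(all(n1 >= 0 & n1 <= 1))
    expect_equal(order(n1), order(x))
    # affine invariance
    expect_equal(minmax_normalize(3.7 * x - 2.2), n1)
  }
})

test_that("integrative-energy combination is the stated weighted sum", {
  expect_equal(combine_ie(0, 0), 0)
  expect_equal(combine_ie(1, 1), 1.5)        # weights (1, 0.5)
  expect_equal(combine_ie(0.4, 0.8), 0.4 + 0.5 * 0.8)
  # linear in each argument
  expect_equal(combine_ie(0.6, 0.2) - combine_ie(0.3, 0.2),
               combine_ie(0.3, 0), tolerance = 1e-12)
  # monotone in each component for positive weights
  expect_gt(combine_ie(0.5, 0.9), combine_ie(0.5, 0.4))
  expect_gt(combine_ie(0.9, 0.5), combine_ie(0.4, 0.5))
})

test_that("multibody training conserves counts against brute enumeration", {
  pot <- mb_pot
  brute <- 0
  for (cx in list(toy9, toy9b)) {
    fwd <- cx$duplex$forward
    gly <- t(vapply(fwd, function(r) pentascan:::glycosidic_n(cx, r),
                    numeric(3)))
    nt <- length(fwd) - 2
    cen <- (gly[1:nt, ] + gly[2:(nt + 1), ] + gly[3:(nt + 2), ]) / 3
    for (r in pentascan:::protein_residues(cx)) {
      cb <- cbeta_position(cx, r)
      d <- sqrt(rowSums(sweep(cen, 2, cb)^2))
      brute <- brute + sum(d > 0 & d <= 15)
    }
  }
  expect_equal(sum(pot$counts), brute)
  expect_true(all(is.finite(pot$table)))
})

test_that("a cell with observed equal to expected scores zero potential", {
  # one residue, one triplet: every observation lands in the same cell, so
  # the marginal-product expectation reproduces the observation exactly
  cx <- build_toy_complex(fixture_spec(
    sequence = "GGG", seed = 2,
    probe_atoms = list(list(resid = "ARG", atom = "HH11", base_pos = 2,
                            base_atom = "O6", distance = 2.5))))
  pot <- train_mb_potential(list(cx))
  filled <- which(pot$counts > 0, arr.ind = TRUE)
  expect_equal(nrow(filled), 1)
  expect_equal(pot$table[filled], 0)
})

test_that("training is invariant to complex order and safe on one complex", {
  p1 <- train_mb_potential(list(toy9, toy9b))
  p2 <- train_mb_potential(list(toy9b, toy9))
  expect_identical(p1$table, p2$table)
  p3 <- train_mb_potential(list(toy9))
  expect_true(all(is.finite(p3$table)))
  expect_error(train_mb_potential(list()), "training error")
})

test_that("multibody scoring matches a manual lookup on a single pair", {
  cx <- build_toy_complex(fixture_spec(
    sequence = "GGG", seed = 2,
    probe_atoms = list(list(resid = "ARG", atom = "HH11", base_pos = 2,
                            base_atom = "O6", distance = 2.5))))
  win <- binding_site(1, 3, flank = 0, duplex_length = 3)
  s <- score_mb(cx, mb_pot, win)
  # manual: the one residue's CB to the single GGG triplet center
  gly <- t(vapply(cx$duplex$forward,
                  function(r) pentascan:::glycosidic_n(cx, r), numeric(3)))
  cen <- colMeans(gly)
  cb <- cbeta_position(cx, which(cx$residues$kind == "protein"))
  d <- sqrt(sum((cb - cen)^2))
  bin <- findInterval(d, mb_pot$bins, rightmost.closed = TRUE)
  expect_equal(s, mb_pot$table["ARG", "GGG", bin])
})

test_that("zero potential and sub-triplet windows score zero", {
  expect_equal(score_mb(toy9, zero_mb_potential(), window9), 0)
  w2 <- binding_site(4, 5, flank = 0, duplex_length = 9)
  expect_equal(score_mb(toy9, mb_pot, w2), 0)
})

test_that("multibody potential survives its text serialization", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mb_potential(mb_pot, f)
  back <- read_mb_potential(f)
  expect_equal(back$bins, mb_pot$bins)
  expect_equal(back$table, mb_pot$table, tolerance = 1e-9)
})

test_that("charge table file round trips including pi systems", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SER OG -0.66", "SER HG 0.43", "[pi_atoms]",
               "PHE CG CD1 CD2 CE1 CE2 CZ"), f)
  ct <- read_charge_table(f)
  expect_equal(unname(ct$charges["SER|OG"]), -0.66)
  expect_equal(ct$pi_atoms$PHE, c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
})
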