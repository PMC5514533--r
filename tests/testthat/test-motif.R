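test_that("Kmer-Sum composes fragment scores by subsequence lookup", {
  # single fragment: the composed table is the fragment table
  land <- plant_landscape("ACGTT", bonus = 0.5, noise_sd = 0.05, seed = 2)
  ks <- kmer_sum_scores(land)
  expect_equal(ks$e_ie, land[[1]]$scores$e_ie[
    order(pentascan:::kmer_index(land[[1]]$scores$sequence))])
  # two fragments: hand-checked two-term sums
  land6 <- plant_landscape("ACGTTA", bonus = 0.5, noise_sd = 0.05, seed = 3)
  ks6 <- kmer_sum_scores(land6)
  for (s in c("AAAAAA", "ACGTTA", "TTTTTT", "GACGTT")) {
    i <- pentascan:::kmer_index(s) + 1
    t0 <- land6[[1]]$scores
    t1 <- land6[[2]]$scores
    expect_equal(ks6$e_ie[i],
                 t0$e_ie[t0$sequence == substr(s, 1, 5)] +
                 t1$e_ie[t1$sequence == substr(s, 2, 6)])
  }
  # fragment evaluation order is irrelevant
  ks6r <- kmer_sum_scores(rev(land6))
  expect_identical(ks6$e_ie, ks6r$e_ie)
})

test_that("Kmer-Sum validates coverage and completeness", {
  land6 <- plant_landscape("ACGTTA", bonus = 0.5, noise_sd = 0.05, seed = 3)
  expect_error(kmer_sum_scores(land6[1], L = 6), "coverage error")
  broken <- land6
  broken[[2]]$scores <- broken[[2]]$scores[1:100, ]
  broken[[2]]$complete <- FALSE
  expect_error(kmer_sum_scores(broken), "completeness error")
})

test_that("Kmer-Sum equals exhaustive in-place fragment sums at L=6", {
  # scaled-down exhaustive oracle on real energetics with a window-local
  # energy (zero multibody + electrostatics); the full L=7 sweep runs in
  # the acceptance suite
  pot0 <- zero_mb_potential()
  site <- binding_site(1, 6, flank = 0, duplex_length = 7)
  tabs <- suppressWarnings(
    score_fragments(toy7, site, pot0, default_charges))
  ks <- kmer_sum_scores(tabs)
  set.seed(4)
  idx <- sample(4^6, 40)
  for (i in idx) {
    s <- index_to_kmer(i - 1, 6)
    inplace <- suppressWarnings(
      score_site_by_fragments(toy7, site, s, pot0, default_charges))
    expect_equal(ks$e_elec[i], inplace$e_elec, tolerance = 1e-9)
  }
})

test_that("significance selection takes the favorable low tail at alpha/L", {
  land <- plant_landscape("ACGTACGT", bonus = 1, noise_sd = 0.1, seed = 5)
  ks <- kmer_sum_scores(land)
  sel <- select_significant(ks)
  expect_gt(nrow(sel), 0)
  expect_equal(sel$sequence[1], "ACGTACGT")  # planted optimum scores best
  # independent recomputation: normal lower-tail p-values at 0.01 / L
  m <- mean(ks$e_ie); s <- sd(ks$e_ie)
  expected_n <- sum(pnorm(ks$e_ie, m, s) < 0.01 / 8)
  expect_equal(nrow(sel), expected_n)
  expect_true(all(pnorm(sel$score, m, s) < 0.01 / 8))
  # empirical-percentile mode agrees with a direct rank computation
  sel_e <- select_significant(ks, significance_config(model = "empirical"))
  expect_equal(nrow(sel_e), sum(rank(ks$e_ie, ties.method = "max") /
                                  length(ks$e_ie) < 0.01 / 8))
})

test_that("degenerate and empty-tail selections fall back to the best scorer", {
  land <- plant_landscape("ACGTT", bonus = 0, noise_sd = 0, seed = 1)
  expect_warning(sel <- select_significant(land[[1]]), "degenerate")
  expect_equal(nrow(sel), 1)
  # one extreme outlier among normal scores is always selected
  land2 <- plant_landscape("ACGTT", bonus = 0, noise_sd = 1, seed = 8)
  land2[[1]]$scores$e_ie[17] <- -10 * sd(land2[[1]]$scores$e_ie)
  sel2 <- select_significant(land2[[1]],
                             significance_config(alpha_base = 0.01))
  expect_true(land2[[1]]$scores$sequence[17] %in% sel2$sequence)
})

test_that("PFMs count selected sequences once each", {
  p <- sequences_to_pfm(c("ACGT"))
  expect_equal(unname(unclass(p)[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(unclass(p)[, 3]), c(0, 0, 1, 0))
  p2 <- sequences_to_pfm(c("AAAA", "AAAA"))
  expect_true(all(unclass(p2)["A", ] == 2))
  expect_error(sequences_to_pfm(c("ACGT", "ACG")), "length")
  # uniform selection gives uniform frequencies
  p3 <- sequences_to_pfm(enumerate_kmers(2))
  f <- pentascan:::pfm_frequencies(p3)
  expect_equal(unname(f[, 1]), rep(0.25, 4))
})

test_that("PWM stacking sums fragment columns mapped to motif positions", {
  land <- plant_landscape("ACGTT", bonus = 2, noise_sd = 0.1, seed = 6)
  stacked <- pwm_stack(land)
  sel <- select_significant(land[[1]],
                            significance_config())
  own <- pentascan:::pfm_frequencies(sequences_to_pfm(sel))
  expect_equal(unclass(stacked), own, tolerance = 1e-12,
               ignore_attr = TRUE)
  # two fragments with hand-set counts: motif column = sum of mapped columns
  land6 <- plant_landscape("ACGTTA", bonus = 2, noise_sd = 0.1, seed = 6)
  st6 <- pwm_stack(land6)
  sel0 <- select_significant(land6[[1]], significance_config())
  sel1 <- select_significant(land6[[2]], significance_config())
  c0 <- unclass(sequences_to_pfm(sel0))
  c1 <- unclass(sequences_to_pfm(sel1))
  hand2 <- c0[, 2] + c1[, 1]   # motif column 2
  expect_equal(unname(unclass(st6)[, 2]), unname(hand2 / sum(hand2)))
  # every stacked column is a frequency vector
  expect_equal(unname(colSums(unclass(st6))), rep(1, 6))
})

test_that("PFM to PWM conversion reproduces the analytic IC cases", {
  uni <- pentascan:::new_pfm(matrix(0.25, 4, 1), "frequencies")
  expect_equal(pfm_to_pwm(uni)$ic, 0)
  cons <- pentascan:::new_pfm(matrix(c(1, 0, 0, 0), 4, 1), "frequencies")
  expect_equal(pfm_to_pwm(cons)$ic, 2)
  half <- pentascan:::new_pfm(matrix(c(0.5, 0.5, 0, 0), 4, 1),
                              "frequencies")
  expect_equal(pfm_to_pwm(half)$ic, 1)
  # logo heights are frequency times IC
  pwm <- pfm_to_pwm(half)
  expect_equal(unname(pwm$heights[1, 1]), 0.5 * 1)
  # all-zero column requires a pseudocount
  zero <- pentascan:::new_pfm(matrix(0, 4, 2), "counts")
  expect_error(pfm_to_pwm(zero), "pseudocount")
  expect_equal(pfm_to_pwm(zero, pseudocount = 1)$ic, c(0, 0))
})

test_that("planted preferences are recovered by both algorithms", {
  s_star <- "ACGTACGTAC"
  land <- plant_landscape(s_star, bonus = 1, noise_sd = 0.1, seed = 12)
  ks <- kmer_sum_scores(land)
  pwm_k <- pfm_to_pwm(sequences_to_pfm(select_significant(ks)))
  expect_equal(pwm_consensus(pwm_k), s_star)
  pwm_s <- pfm_to_pwm(pwm_stack(land))
  expect_equal(pwm_consensus(pwm_s), s_star)
  # a clearly stronger preference never loses information content: with a
  # noise-dominated bonus the recovered columns are weak, with a dominant
  # bonus they are fully conserved
  wide <- significance_config(alpha_base = 0.1, normalize_by_length = FALSE)
  land_weak <- plant_landscape(s_star, bonus = 0.05, noise_sd = 0.5,
                               seed = 12)
  land_strong <- plant_landscape(s_star, bonus = 5, noise_sd = 0.5,
                                 seed = 12)
  ic_weak <- pfm_to_pwm(pwm_stack(land_weak, wide), pseudocount = 1e-6)$ic
  ic_strong <- pfm_to_pwm(pwm_stack(land_strong, wide),
                          pseudocount = 1e-6)$ic
  expect_true(all(ic_strong >= ic_weak - 1e-9))
})

test_that("JASPAR text round trips in both dialects", {
  p <- sequences_to_pfm(c("ACGTA", "ACGTT", "ACGAA"))
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(p, f, name = "TOY.1 toy")
  back <- read_jaspar(f)
  expect_equal(unclass(back), unclass(p), ignore_attr = TRUE)
  expect_equal(attr(back, "name"), "TOY.1 toy")
  # raw 4-row dialect
  raw <- c("1 2 0", "0 0 3", "2 1 0", "0 0 0")
  m <- read_jaspar(raw)
  expect_equal(unname(unclass(m)[2, 3]), 3)
  expect_error(read_jaspar(c(">x", "A [ 1 ]", "C [ 1 ]")), "4 matrix rows")
})

test_that("the end-to-end driver produces a valid motif on a toy complex", {
  pred <- suppressWarnings(
    predict_motif(toy9, mb_pot, default_charges, method = "kmer_sum",
                  flank = 2))
  expect_s3_class(pred, "pentascan_motif")
  expect_equal(ncol(pred$pwm$freq), site_length(pred$site))
  expect_true(all(abs(colSums(pred$pwm$freq) - 1) < 1e-9))
  expect_true(all(pred$pwm$ic >= 0 & pred$pwm$ic <= 2 + 1e-12))
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pred$pfm, f)
  expect_s3_class(read_jaspar(f), "pfm")
  pred2 <- suppressWarnings(
    predict_motif(toy9, mb_pot, default_charges, method = "pwm_stack"))
  expect_equal(attr(pred2$pfm, "kind"), "frequencies")
})
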