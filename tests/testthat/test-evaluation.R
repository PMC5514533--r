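test_that("IC-weighted PCC reproduces the analytic column cases", {
  # identical perfectly conserved columns: pcc 1, IC 2, weighted 1.0
  cc <- ic_weighted_pcc(c(1, 0, 0, 0), c(1, 0, 0, 0))
  expect_equal(cc$pcc, 1)
  expect_equal(cc$ic_ref, 2)
  expect_equal(cc$ic_weighted_pcc, 1)
  expect_true(cc$correct)
  # conserved reference vs anti-correlated prediction: weighted -1
  anti <- ic_weighted_pcc(c(1, 0, 0, 0), c(0, 1, 1, 1) / 3)
  expect_equal(anti$ic_weighted_pcc, -1)
  expect_false(anti$correct)
  # a column against itself: weighted value IC/2, by direct formula
  m <- c(0.7, 0.1, 0.1, 0.1)
  self <- ic_weighted_pcc(m, m)
  ic_hand <- 2 + sum(m * log2(m))
  expect_equal(self$pcc, 1)
  expect_equal(self$ic_weighted_pcc, ic_hand / 2)
  # hand-evaluated cross-column case
  n <- c(0.55, 0.25, 0.1, 0.1)
  hand_pcc <- sum((m - 0.25) * (n - 0.25)) /
    sqrt(sum((m - 0.25)^2) * sum((n - 0.25)^2))
  expect_equal(ic_weighted_pcc(m, n)$ic_weighted_pcc,
               hand_pcc * ic_hand / 2)
})

test_that("IC-weighted PCC is bounded and handles uniform columns", {
  set.seed(21)
  for (i in 1:25) {
    a <- as.numeric(rmultinom(1, 40, runif(4))) / 40
    b <- as.numeric(rmultinom(1, 40, runif(4))) / 40
    cc <- ic_weighted_pcc(a, b)
    expect_gte(cc$ic_weighted_pcc, -1)
    expect_lte(cc$ic_weighted_pcc, 1)
    expect_lte(abs(cc$ic_weighted_pcc), cc$ic_ref / 2 + 1e-12)
  }
  u <- ic_weighted_pcc(rep(0.25, 4), c(1, 0, 0, 0))
  expect_true(u$degenerate)
  expect_equal(u$ic_weighted_pcc, 0)
  expect_false(u$correct)
})

test_that("alignment recovers planted shifts and orientations", {
  set.seed(31)
  counts <- t(rmultinom(8, 50, c(4, 1, 1, 1)))
  counts[3, ] <- c(1, 1, 1, 47); counts[6, ] <- c(2, 40, 6, 2)
  ref <- pfm_to_pwm(pentascan:::new_pfm(t(counts), "counts"))
  expect_equal(align_pwms(ref, ref),
               list(offset = 0, orientation = "forward",
                    score = align_pwms(ref, ref)$score))
  # shift by 2: prediction drops the first two columns
  shifted <- pfm_to_pwm(pentascan:::new_pfm(t(counts)[, 3:8], "counts"))
  aln <- align_pwms(ref, shifted)
  expect_equal(aln$offset, 2)
  expect_equal(aln$orientation, "forward")
  # reverse complement orientation
  rc <- pfm_to_pwm(pentascan:::new_pfm(
    pentascan:::revcomp_freq(ref$freq) * 50, "counts"))
  aln_rc <- align_pwms(ref, rc)
  expect_equal(aln_rc$orientation, "reverse")
  expect_equal(aln_rc$offset, 0)
  # too short to overlap
  tiny <- pfm_to_pwm(pentascan:::new_pfm(matrix(c(1, 0, 0, 0), 4, 2),
                                         "counts"))
  expect_error(align_pwms(ref, tiny), "alignment error")
})

test_that("correct-column counting matches per-column hand evaluation", {
  set.seed(32)
  counts <- t(rmultinom(6, 60, c(12, 1, 1, 1)))
  ref <- pfm_to_pwm(pentascan:::new_pfm(t(counts), "counts"))
  rep_same <- count_correct(ref, ref)
  expect_equal(rep_same$n_correct, 6)
  expect_equal(rep_same$akl, 0)
  # uniform prediction: zero variance everywhere, nothing correct
  uni <- pfm_to_pwm(pentascan:::new_pfm(matrix(0.25, 4, 6), "frequencies"))
  expect_equal(count_correct(ref, uni)$n_correct, 0)
  # exactly 3 matching and 3 anti-correlated columns
  pm <- unclass(ref$freq)
  for (j in 4:6) pm[, j] <- rev(pm[, j])
  mixed <- pfm_to_pwm(pentascan:::new_pfm(pm * 60, "counts"))
  rep_mix <- count_correct(ref, mixed)
  hand <- vapply(seq_len(6), function(j) {
    ic_weighted_pcc(ref$freq[, j], pm[, j])$correct
  }, logical(1))
  expect_equal(rep_mix$n_correct, sum(hand))
  expect_equal(rep_mix$n_correct, 3)
})

test_that("correctness is invariant under joint reverse complement", {
  set.seed(33)
  counts <- t(rmultinom(7, 50, c(4, 2, 1, 1)))
  ref <- pfm_to_pwm(pentascan:::new_pfm(t(counts), "counts"))
  set.seed(34)
  counts2 <- t(rmultinom(7, 50, c(3, 2, 2, 1)))
  pred <- pfm_to_pwm(pentascan:::new_pfm(t(counts2), "counts"))
  n1 <- count_correct(ref, pred)$n_correct
  rc <- function(p) pfm_to_pwm(pentascan:::new_pfm(
    pentascan:::revcomp_freq(p$freq) * 50, "counts"))
  n2 <- count_correct(rc(ref), rc(pred))$n_correct
  expect_equal(n1, n2)
})

test_that("AKL divergence is symmetric, zero at identity, hand-checkable", {
  set.seed(35)
  counts <- t(rmultinom(6, 50, c(4, 1, 1, 1)))
  P <- pfm_to_pwm(pentascan:::new_pfm(t(counts), "counts"))
  expect_equal(akl_divergence(P, P), 0, tolerance = 1e-12)
  counts2 <- t(rmultinom(6, 50, c(1, 4, 1, 1)))
  Q <- pfm_to_pwm(pentascan:::new_pfm(t(counts2), "counts"))
  aln0 <- list(offset = 0, orientation = "forward")
  d1 <- akl_divergence(P, Q, alignment = aln0)
  # symmetry: swap arguments at the same alignment
  d2 <- akl_divergence(Q, P, alignment = aln0)
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_gte(d1, 0)
  # two fixed 5-column toy PWMs against an independent term-by-term sum
  pa <- matrix(c(0.7, 0.1, 0.1, 0.1), 4, 5)
  pb <- matrix(c(0.4, 0.3, 0.2, 0.1), 4, 5)
  A <- pfm_to_pwm(pentascan:::new_pfm(pa, "frequencies"))
  B <- pfm_to_pwm(pentascan:::new_pfm(pb, "frequencies"))
  pc_ <- 1e-4
  pav <- (pa[, 1] + pc_) / (1 + 4 * pc_)
  pbv <- (pb[, 1] + pc_) / (1 + 4 * pc_)
  hand <- 5 * sum((pbv * log2(pbv / pav) + pav * log2(pav / pbv)) / 2)
  expect_equal(
    akl_divergence(A, B, alignment = list(offset = 0,
                                          orientation = "forward")),
    hand, tolerance = 1e-9)
})
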