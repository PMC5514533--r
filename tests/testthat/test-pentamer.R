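test_that("k-mer enumeration is lexicographic and complete", {
  expect_equal(enumerate_kmers(1), c("A", "C", "G", "T"))
  k5 <- enumerate_kmers(5)
  expect_equal(length(k5), 1024)
  expect_false(any(duplicated(k5)))
  expect_identical(k5, sort(k5))
  expect_equal(length(enumerate_kmers(8)), 65536)
  expect_error(enumerate_kmers(0), "1..15")
  expect_error(enumerate_kmers(16), "1..15")
  # index arithmetic round trip
  idx <- c(0, 1, 511, 1023)
  expect_equal(pentascan:::kmer_index(k5[idx + 1]), idx)
})

test_that("fragment counts follow site length minus four", {
  s9 <- binding_site(3, 7, flank = 2, duplex_length = 11)   # 9-bp full site
  expect_equal(length(make_fragments(s9)), 5)
  s5 <- binding_site(1, 5, flank = 0, duplex_length = 5)
  expect_equal(length(make_fragments(s5)), 1)
  s12 <- binding_site(1, 12, flank = 0, duplex_length = 12)
  expect_equal(length(make_fragments(s12)), 8)
  s4 <- binding_site(1, 4, flank = 0, duplex_length = 4)
  expect_error(make_fragments(s4), "too-short")
  # offsets are consecutive and windows are 5 bp
  fr <- make_fragments(s9)
  expect_equal(vapply(fr, `[[`, numeric(1), "offset"), 1:5)
  expect_true(all(vapply(fr, function(f) site_length(f$window), numeric(1))
                  == 5))
})

test_that("fragment tables hold all 1024 pentamers with the native one intact", {
  site <- binding_site(3, 7, flank = 0, duplex_length = 9)
  fr <- make_fragments(site)[[1]]
  tab <- suppressWarnings(score_fragment(toy9, fr, mb_pot, default_charges))
  expect_true(tab$complete)
  expect_equal(nrow(tab$scores), 1024)
  expect_false(any(duplicated(tab$scores$sequence)))
  native <- substr(toy9$duplex$sequence, 3, 7)
  expect_true(native %in% tab$scores$sequence)
  expect_true(all(tab$scores$e_mb_norm >= 0 & tab$scores$e_mb_norm <= 1))
  expect_equal(tab$scores$e_ie,
               combine_ie(tab$scores$e_mb_norm, tab$scores$e_elec_norm))
})

test_that("factorized fragment scores equal explicit thread-then-score", {
  site <- binding_site(3, 7, flank = 0, duplex_length = 9)
  fr <- make_fragments(site)[[1]]
  tab <- suppressWarnings(score_fragment(toy9, fr, mb_pot, default_charges))
  set.seed(99)
  for (i in sample(1024, 12)) {
    s <- tab$scores$sequence[i]
    cxi <- thread_sequence(toy9, fr$abs_start, s)
    raw <- suppressWarnings(score_site(cxi, fr$window, mb_pot,
                                       default_charges))
    expect_equal(raw$e_mb, tab$scores$e_mb[i], tolerance = 1e-12)
    expect_equal(raw$e_elec, tab$scores$e_elec[i], tolerance = 1e-12)
  }
})

test_that("rescoring is deterministic", {
  site <- binding_site(3, 7, flank = 1, duplex_length = 9)
  fr <- make_fragments(site)[[2]]
  t1 <- suppressWarnings(score_fragment(toy9, fr, mb_pot, default_charges))
  t2 <- suppressWarnings(score_fragment(toy9, fr, mb_pot, default_charges))
  expect_identical(t1$scores, t2$scores)
})

test_that("null energies give identically zero integrative scores", {
  ch0 <- default_charges
  ch0$charges[] <- 0
  site <- binding_site(3, 7, flank = 0, duplex_length = 9)
  fr <- make_fragments(site)[[1]]
  tab <- suppressWarnings(score_fragment(toy9, fr, zero_mb_potential(),
                                         ch0))
  expect_true(all(tab$scores$e_ie == 0))
})

test_that("direct enumeration at L=5 equals the single-fragment table", {
  site <- binding_site(2, 6, flank = 0, duplex_length = 7)
  direct <- suppressWarnings(
    score_full_length_direct(toy7, site, mb_pot, default_charges, cap = 5))
  fr <- make_fragments(site)[[1]]
  tab <- suppressWarnings(score_fragment(toy7, fr, mb_pot, default_charges))
  expect_equal(direct$e_mb, tab$scores$e_mb, tolerance = 1e-12)
  expect_equal(direct$e_elec, tab$scores$e_elec, tolerance = 1e-12)
  expect_equal(direct$e_ie, tab$scores$e_ie, tolerance = 1e-12)
})

test_that("direct enumeration at L=2 matches a hand-written double loop", {
  site <- binding_site(4, 5, flank = 0, duplex_length = 7)
  direct <- suppressWarnings(
    score_full_length_direct(toy7, site, zero_mb_potential(),
                             default_charges, cap = 4))
  brute <- numeric(16)
  k <- 0
  for (b1 in c("A", "C", "G", "T")) for (b2 in c("A", "C", "G", "T")) {
    k <- k + 1
    cxi <- thread_sequence(toy7, 4, paste0(b1, b2))
    brute[k] <- suppressWarnings(
      score_electrostatic(cxi, default_charges, site))$score
  }
  expect_equal(direct$e_elec, brute, tolerance = 1e-12)
})

test_that("direct enumeration refuses sites beyond the cap", {
  site <- binding_site(1, 7, flank = 0, duplex_length = 7)
  expect_error(score_full_length_direct(toy7, site, mb_pot,
                                        default_charges, cap = 6),
               "pentamer")
})

test_that("score tables survive the CSV cache", {
  site <- binding_site(2, 6, flank = 0, duplex_length = 7)
  dir <- withr::local_tempdir()
  t1 <- suppressWarnings(score_fragments(toy7, site, mb_pot,
                                         default_charges, cache_dir = dir))
  expect_equal(length(list.files(dir, pattern = "csv$")), 1)
  t2 <- suppressWarnings(score_fragments(toy7, site, mb_pot,
                                         default_charges, cache_dir = dir))
  expect_equal(t2[[1]]$scores$e_ie, t1[[1]]$scores$e_ie, tolerance = 1e-9)
})
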