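benign_window <- function(seed = 10) {
  set.seed(seed)
  genome <- tibble::tibble(id = "s1", seq = rand_dna(2000))
  extract_window(genome, "s1", 1000, flank = 150)
}

test_that("nearest-neighbour Tm is sane and GC-monotone", {
  tm_at <- primer_tm("ATATATATATATATATATAT")
  tm_gc <- primer_tm("GCGCGCGCGCGCGCGCGCGC")
  expect_lt(tm_at, tm_gc)
  # a typical 20-mer near 50% GC lands in a usable panel-design range
  expect_gt(primer_tm("ACGTTGCAATGCCTAGGATC"), 45)
  expect_lt(primer_tm("ACGTTGCAATGCCTAGGATC"), 75)
  # longer primers of the same composition melt higher
  expect_lt(primer_tm("ACGTTGCAATGCCTAG"), primer_tm("ACGTTGCAATGCCTAGGATCAA"))
})

test_that("primer pairs on a benign window satisfy every design constraint", {
  w <- benign_window()
  cfg <- pipeline_config()
  cand <- design_primer_pair(w, cfg, max_candidates = 25)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$product_size >= 120 & cand$product_size <= 160))
  # site strictly inside the amplicon and outside both primer intervals
  expect_true(all(cand$fwd_end < w$site_offset))
  expect_true(all(cand$rev_start > w$site_offset))
  expect_true(all(cand$fwd_start >= 1 & cand$rev_end <= 300))
  # thermodynamic constraints
  expect_true(all(cand$fwd_tm >= 57 & cand$fwd_tm <= 63))
  expect_true(all(cand$rev_tm >= 57 & cand$rev_tm <= 63))
  expect_true(all(abs(cand$fwd_tm - cand$rev_tm) <= 3))
  expect_true(all(nchar(cand$fwd_seq) >= 18 & nchar(cand$fwd_seq) <= 25))
  gc <- ampliconpanel:::gc_percent(c(cand$fwd_seq, cand$rev_seq))
  expect_true(all(gc >= 30 & gc <= 70))
  expect_false(any(ampliconpanel:::has_homopolymer(c(cand$fwd_seq,
                                                     cand$rev_seq))))
  # ranking: penalties non-decreasing
  expect_true(all(diff(cand$penalty) >= -1e-12))
  # reverse primer is the reverse complement of its plus-strand interval
  expect_equal(cand$rev_seq[1],
               rc_chr(substr(w$seq, cand$rev_start[1], cand$rev_end[1])))
})

test_that("a fully masked window yields no candidates with reason 'masked'", {
  w <- benign_window()
  w$mask <- rep(TRUE, 300)
  out <- design_primer_pair(w, pipeline_config())
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "reason"), "masked")
})

test_that("amplicons below the minimum size are rejected", {
  w <- benign_window()
  narrow <- pipeline_config(amplicon_min = 120, amplicon_max = 160)
  cand <- design_primer_pair(w, narrow, max_candidates = 100)
  expect_false(any(cand$product_size == 119))
  # and an impossible window (site too near the edge) gives no pairs
  w_edge <- benign_window()
  w_edge$site_offset <- 8L
  out <- design_primer_pair(w_edge, narrow)
  expect_equal(nrow(out), 0L)
})

test_that("masked 3'-terminal bases disqualify primers", {
  w <- benign_window()
  cfg <- pipeline_config()
  free <- design_primer_pair(w, cfg, max_candidates = 200)
  # mask the 3' ends of every previously feasible forward primer
  w2 <- w
  w2$mask[unique(free$fwd_end)] <- TRUE
  constrained <- design_primer_pair(w2, cfg, max_candidates = 200)
  if (nrow(constrained) > 0) {
    expect_false(any(constrained$fwd_end %in% unique(free$fwd_end)))
  } else {
    succeed()
  }
})

test_that("common sequence tags are appended once and only once", {
  p <- tibble::tibble(fwd_seq = "ATGACGTGACGT", rev_seq = "GGCATTACGGAT")
  tagged <- append_common_tags(p)
  expect_equal(tagged$fwd_tagged, "ACACTGACGACATGGTTCTACAATGACGTGACGT")
  expect_equal(tagged$rev_tagged, "TACGGTAGCAGAGACTTGGTCTGGCATTACGGAT")
  twice <- append_common_tags(tagged)
  expect_equal(twice$fwd_tagged, tagged$fwd_tagged)
  expect_equal(twice$rev_tagged, tagged$rev_tagged)
})

test_that("binding sites and products match a brute-force scan", {
  set.seed(12)
  g <- tibble::tibble(id = c("s1", "s2"),
                      seq = c(rand_dna(3000), rand_dna(2000)))
  fwd <- substr(g$seq[1], 1001, 1020)
  rev <- rc_chr(substr(g$seq[1], 1101, 1120))
  res <- count_binding_sites(fwd, g, partner = rev)
  expect_equal(res$n_sites, 1L)
  expect_equal(nrow(res$products), 1L)
  expect_equal(res$products$size, 110L)  # seed-to-seed span of the amplicon

  # duplicate the forward binding region on the other scaffold: 2 sites
  g2 <- g
  substr(g2$seq[2], 501, 520) <- fwd
  res2 <- count_binding_sites(fwd, g2, partner = rev)
  expect_equal(res2$n_sites, 2L)
  # brute-force oracle over all positions of the 15-nt seed
  seed15 <- substr(fwd, 6, 20)
  brute <- sum(vapply(g2$seq, function(s) {
    n <- nchar(s) - 14
    kms <- substring(s, 1:n, 15:nchar(s))
    sum(kms == seed15) + sum(kms == rc_chr(seed15))
  }, 0))
  expect_equal(res2$n_sites, brute)

  # both primers matching a second locus within 500 bp: 2 products
  g3 <- g
  substr(g3$seq[2], 501, 520) <- fwd
  substr(g3$seq[2], 801, 820) <- rc_chr(rev)
  res3 <- count_binding_sites(fwd, g3, partner = rev)
  expect_equal(nrow(res3$products), 2L)
})

test_that("pooling balances sizes and respects the pool count", {
  set.seed(13)
  mk <- function(n) tibble::tibble(
    fwd_seq = replicate(n, rand_dna(20)),
    rev_seq = replicate(n, rand_dna(20)))
  p480 <- pool_primers(mk(480), 48)
  expect_equal(as.integer(table(p480$pool)), rep(48L, 10))
  p441 <- pool_primers(mk(441), 48)
  expect_equal(length(unique(p441$pool)), 10L)
  expect_lte(diff(range(table(p441$pool))), 1)
  p1 <- pool_primers(mk(1), 48)
  expect_equal(p1$pool, 1L)
})

test_that("3'-end complementarity scoring finds reverse-complement matches", {
  p <- "ACGTACGTACGTACGTACGT"      # 3' 8-mer: ACGTACGT (palindromic rc)
  q <- paste0("TTTTT", rc_chr(substr(p, 13, 20)), "TTTTT")
  expect_equal(ampliconpanel:::three_prime_complementarity(p, q), 8L)
  expect_lte(ampliconpanel:::three_prime_complementarity("AAAAAAAAAAAAAAA",
                                                         "AAAAAAAAAAAAAAA"), 1L)
})
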