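aln_row <- function(qstart, qend, sstart, send, subject = "s1",
                    bitscore = 100, pct = 100, trace = NA_character_,
                    query = "u1") {
  aln_len <- if (!is.na(trace)) nchar(trace) else qend - qstart + 1L
  tibble::tibble(query_id = query, subject_id = subject, pct_identity = pct,
                 aln_len = as.integer(aln_len), mismatches = 0L,
                 gap_opens = 0L, qstart = as.integer(qstart),
                 qend = as.integer(qend), sstart = as.integer(sstart),
                 send = as.integer(send), evalue = 0,
                 bitscore = bitscore, trace = trace,
                 strand = ifelse(sstart > send, "-", "+"))
}

test_that("best_alignment maximizes bitscore with deterministic tie-breaks", {
  a <- dplyr::bind_rows(aln_row(1, 50, 1, 50, bitscore = 90),
                        aln_row(1, 50, 101, 150, bitscore = 250))
  expect_equal(best_alignment(a)$bitscore, 250)

  b <- dplyr::bind_rows(aln_row(1, 50, 1, 50, bitscore = 100, pct = 98.0),
                        aln_row(1, 50, 101, 150, bitscore = 100, pct = 99.5))
  expect_equal(best_alignment(b)$pct_identity, 99.5)

  single <- aln_row(1, 50, 1, 50)
  expect_equal(nrow(best_alignment(single)), 1L)
  expect_false(best_alignment(single)$ambiguous_hit)

  ties <- dplyr::bind_rows(aln_row(1, 50, 1, 50, subject = "s2"),
                           aln_row(1, 50, 1, 50, subject = "s1"))
  top <- best_alignment(ties)
  expect_equal(top$subject_id, "s1")  # lexicographic tie-break
  expect_true(top$ambiguous_hit)

  expect_error(best_alignment(aln_row(1, 1, 1, 1)[0, ]), "empty")
})

test_that("gapless projection is the linear offset on both strands", {
  plus <- aln_row(1, 100, 501, 600)
  expect_equal(project_position(plus, 10),
               list(scaffold = "s1", position = 510L, strand = "+"))
  expect_equal(project_position(plus, 10)$position,
               as.integer(oracle_project(plus, 10)))

  minus <- aln_row(1, 100, 600, 501)
  got <- project_position(minus, 10)
  expect_equal(got$position, 591L)
  expect_equal(got$strand, "-")
  expect_equal(got$position, as.integer(oracle_project(minus, 10)))
})

test_that("trace projection walks gaps exactly and matches the walk oracle", {
  # 40 query bases; subject gap (D) of 5 inserted after 10 matches:
  # subject advances 5 extra bases before qpos
  trace <- paste0(strrep("M", 10), strrep("D", 5), strrep("M", 30))
  aln <- aln_row(1, 40, 201, 245, trace = trace)
  got <- project_position(aln, 20)
  linear <- 201 + (20 - 1)
  expect_equal(got$position, linear + 5L)
  expect_equal(got$position, as.integer(oracle_project(aln, 20)))

  # query insertion (I): base 12 has no subject partner
  trace_i <- paste0(strrep("M", 11), "I", strrep("M", 28))
  aln_i <- aln_row(1, 40, 201, 239, trace = trace_i)
  expect_error(project_position(aln_i, 12), "unprojectable")
  expect_true(is.na(oracle_project(aln_i, 12)))
  # bases after the insertion shift back by one relative to linear
  expect_equal(project_position(aln_i, 13)$position, 201L + 13L - 1L - 1L)

  # minus-strand trace walk agrees with the oracle everywhere
  trace_m <- paste0(strrep("M", 8), strrep("D", 3), strrep("M", 12))
  aln_m <- aln_row(5, 24, 300, 278, trace = trace_m)
  for (q in 5:24) {
    expect_equal(project_position(aln_m, q)$position,
                 as.integer(oracle_project(aln_m, q)))
  }
})

test_that("projection refuses out-of-span and traceless gapped input", {
  hsp <- aln_row(1, 100, 1, 100)
  expect_error(project_position(hsp, 200), "outside alignment span")
  gapped <- aln_row(1, 100, 1, 90)  # span mismatch, no trace
  expect_error(project_position(gapped, 10), "trace")
})

test_that("projection round-trips alignment end points", {
  plus <- aln_row(3, 60, 1001, 1058)
  expect_equal(project_position(plus, 3)$position, 1001L)
  expect_equal(project_position(plus, 60)$position, 1058L)
  minus <- aln_row(3, 60, 1058, 1001)
  expect_equal(project_position(minus, 3)$position, 1058L)
  expect_equal(project_position(minus, 60)$position, 1001L)
})

test_that("match/mismatch-only traces agree with the linear formula", {
  set.seed(3)
  for (i in 1:20) {
    qs <- sample(1:50, 1); len <- sample(20:80, 1)
    ss <- sample(1000:2000, 1)
    strand_minus <- runif(1) < 0.5
    trace <- paste(sample(c("M", "X"), len, TRUE, prob = c(0.9, 0.1)),
                   collapse = "")
    aln <- if (strand_minus) {
      aln_row(qs, qs + len - 1, ss + len - 1, ss, trace = trace)
    } else {
      aln_row(qs, qs + len - 1, ss, ss + len - 1, trace = trace)
    }
    notrace <- aln; notrace$trace <- NA_character_
    q <- sample(qs:(qs + len - 1), 1)
    expect_equal(project_position(aln, q), project_position(notrace, q))
  }
})

test_that("lift_sites drops and flags sites with reasons", {
  sites <- tibble::tibble(
    unigene_id = c("u1", "u1", "u2", "u3"),
    position = c(500L, 30L, 10L, 10L),
    ref_allele = "A", alt_allele = "T", fixed_line = "P1", support = 4L)
  aln <- dplyr::bind_rows(
    aln_row(1, 1000, 2001, 3000, query = "u1"),
    aln_row(1, 100, 1, 100, query = "u2"))
  lifted <- lift_sites(sites, aln, flank = 150)
  expect_true(is.na(lifted$drop_reason[1]))       # mid-alignment, clear
  expect_equal(lifted$genome_position[1], 2500L)
  expect_equal(lifted$drop_reason[2], "near-junction")  # < 150 bp from end
  expect_equal(lifted$drop_reason[3], "near-junction")
  expect_equal(lifted$drop_reason[4], "no-alignment")
})
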