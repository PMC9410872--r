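depth_row <- function(ref, alt, sample = "f2_1", marker = "m1",
                      hotspot = TRUE, pos = 100L) {
  tibble::tibble(sample_id = sample, marker_id = marker, scaffold = "s1",
                 position = as.integer(pos), ref_allele = "A",
                 alt_allele = "G", is_hotspot = hotspot,
                 ref_count = as.integer(ref), alt_count = as.integer(alt))
}

test_that("genotype calling thresholds match the zygosity conventions", {
  d <- dplyr::bind_rows(depth_row(0, 30), depth_row(15, 15), depth_row(2, 2),
                        depth_row(25, 3), depth_row(4, 24), depth_row(24, 4))
  calls <- call_genotypes(d)$call
  expect_equal(calls, c("alt_hom",  # 100%
                        "het",      # 50%
                        "no_call",  # depth 4 < 5
                        "ref_hom",  # 10.7% < 20%
                        "alt_hom",  # 85.7% > 80%
                        "ref_hom")) # 14.3% < 20%
})

test_that("parental consensus requires unanimity among called replicates", {
  mk <- function(calls, line = "P1") {
    dplyr::bind_rows(lapply(seq_along(calls), function(i) {
      counts <- switch(calls[i], ref_hom = c(30, 0), het = c(15, 15),
                       alt_hom = c(0, 30), no_call = c(1, 1))
      depth_row(counts[1], counts[2], sample = paste0(line, "_", i))
    })) |> dplyr::mutate(line_id = line)
  }
  cons <- function(calls) {
    parental_consensus(call_genotypes(mk(calls)))$consensus
  }
  expect_equal(cons(c("ref_hom", "ref_hom", "ref_hom")), "ref_hom")
  expect_equal(cons(c("ref_hom", "het", "ref_hom")), "unfixed")
  expect_equal(cons(c("no_call", "no_call", "no_call")), "no_call")
  expect_equal(cons(c("alt_hom", "no_call", "alt_hom")), "alt_hom")
})

test_that("marker classification is total, single-valued and matches the rules", {
  states <- c("ref_hom", "het", "alt_hom", "unfixed", "no_call")
  combos <- expand.grid(p1 = states, p2 = states,
                        flag = c(TRUE, FALSE), stringsAsFactors = FALSE)
  cls <- marker_class(combos$p1, combos$p2, combos$flag)
  expect_length(cls, nrow(combos))
  expect_true(all(cls %in% 1:5))
  expect_false(anyNA(cls))

  expect_equal(marker_class("ref_hom", "alt_hom"), 1L)
  expect_equal(marker_class("ref_hom", "alt_hom", FALSE), 2L)  # no variant
  expect_equal(marker_class("no_call", "no_call"), 3L)
  expect_equal(marker_class("alt_hom", "no_call"), 4L)
  expect_equal(marker_class("unfixed", "ref_hom"), 5L)
  expect_equal(marker_class("ref_hom", "ref_hom"), 2L)  # same genotype
})

test_that("A/H/B coding follows the parent, not the allele", {
  expect_equal(to_parental_code(c("het", "ref_hom", "alt_hom", "no_call"),
                                "ref_hom", "alt_hom"),
               c("H", "A", "B", "-"))
  # orientation flips with the parents
  expect_equal(to_parental_code("alt_hom", "alt_hom", "ref_hom"), "A")
  expect_error(to_parental_code("het", "unfixed", "alt_hom"),
               "not convertible")
})

test_that("representative-site selection prefers F1-heterozygous hotspots", {
  sites <- tibble::tibble(
    marker_id = c("m1", "m1", "m2", "m2", "m3"),
    scaffold = "s1",
    position = c(100L, 140L, 200L, 240L, 300L),
    is_hotspot = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    f1_het = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    missing_fraction = c(0.05, 0.01, 0.02, 0.03, 0.0))
  sel <- select_representative_site(sites)
  expect_equal(sel$position[sel$marker_id == "m1"], 100L)  # hotspot wins
  expect_equal(sel$position[sel$marker_id == "m2"], 240L)  # non-hotspot het
  expect_false("m3" %in% sel$marker_id)                    # nothing het in F1
})

test_that("missing and distortion filters use strict printed boundaries", {
  codes_row <- function(nA, nH, nB, nmiss, id) {
    codes <- c(rep("A", nA), rep("H", nH), rep("B", nB), rep("-", nmiss))
    tibble::as_tibble(as.list(setNames(codes, sprintf("i%03d", seq_along(codes))))) |>
      dplyr::mutate(marker_id = id, .before = 1)
  }
  m <- dplyr::bind_rows(
    codes_row(22, 45, 22, 11, "miss11"),   # 11% missing: dropped
    codes_row(23, 45, 22, 10, "miss10"),   # exactly 10%: retained
    codes_row(60, 20, 10, 10, "distort"))  # heavily distorted: dropped
  out <- filter_matrix(m, pipeline_config())
  rep_ <- out$report
  expect_equal(rep_$reason[rep_$marker_id == "miss11"], "missing")
  expect_true(is.na(rep_$reason[rep_$marker_id == "miss10"]))
  expect_equal(rep_$reason[rep_$marker_id == "distort"], "distorted")
  expect_equal(out$matrix$marker_id, "miss10")

  # closed-form chi-square values on same-width rows
  m2 <- dplyr::bind_rows(codes_row(40, 10, 14, 6, "d"),
                         codes_row(16, 32, 16, 6, "p"))
  rep2 <- filter_matrix(m2, pipeline_config())$report
  expect_equal(rep2$chisq[rep2$marker_id == "d"], 51.375)
  expect_equal(rep2$reason[rep2$marker_id == "d"], "distorted")
  expect_equal(rep2$chisq[rep2$marker_id == "p"], 0)
  expect_true(is.na(rep2$reason[rep2$marker_id == "p"]))
})

test_that("marker-set refinement keeps one mapped marker per scaffold", {
  panel <- tibble::tibble(
    marker_id = paste0("m", 1:6),
    scaffold = c("sc1", "sc1", "sc1", "sc2", "sc3", "sc4"),
    genome_position = c(1000L, 5000L, 9000L, 1000L, 1000L, 1000L))
  classes <- tibble::tibble(
    marker_id = paste0("m", 1:6),
    consensus_p1 = "ref_hom", consensus_p2 = "alt_hom",
    class = c(1L, 1L, 1L, 1L, 3L, 1L))
  status <- tibble::tibble(
    marker_id = paste0("m", 1:6),
    used_in_map = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    missing_fraction = c(0.02, 0.01, 0.05, 0.0, NA, 0.03))
  out <- refine_marker_set(panel, classes, status)
  # three mapped markers on sc1 collapse to the lowest-missing one
  expect_equal(sum(out$panel$scaffold == "sc1"), 1L)
  expect_equal(out$panel$marker_id[out$panel$scaffold == "sc1"], "m2")
  # class-3 marker removed; class-1 non-segregating marker retained
  expect_false("m5" %in% out$panel$marker_id)
  expect_true("m6" %in% out$panel$marker_id)
  expect_equal(out$report$n_coscaffold_removed, 2L)
})

test_that("the genotype matrix is built only from informative markers", {
  classes <- tibble::tibble(
    marker_id = c("m1", "m2"),
    consensus_p1 = c("ref_hom", "unfixed"),
    consensus_p2 = c("alt_hom", "alt_hom"),
    class = c(1L, 5L))
  f2 <- dplyr::bind_rows(
    depth_row(30, 0, sample = "F2_001"),
    depth_row(15, 15, sample = "F2_002"),
    depth_row(0, 30, sample = "F2_003"),
    depth_row(30, 0, sample = "F2_001", marker = "m2"),
    depth_row(15, 15, sample = "F2_002", marker = "m2"),
    depth_row(0, 30, sample = "F2_003", marker = "m2"))
  mat <- build_genotype_matrix(call_genotypes(f2), classes)
  expect_equal(mat$marker_id, "m1")
  expect_equal(unlist(mat[1, c("F2_001", "F2_002", "F2_003")],
                      use.names = FALSE),
               c("A", "H", "B"))
})
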