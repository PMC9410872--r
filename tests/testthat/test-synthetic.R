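test_that("generators are seed-deterministic", {
  cfg <- sim_config(n_genes = 12, n_scaffolds = 2,
                    scaffold_target_length = 15000, n_f2 = 10)
  a <- simulate_reference(cfg, 99)
  b <- simulate_reference(cfg, 99)
  expect_identical(a$genome, b$genome)
  expect_identical(a$alignments, b$alignments)
  ca <- simulate_lines_and_cross(a, cfg, 99)
  cb <- simulate_lines_and_cross(b, cfg, 99)
  expect_identical(ca$variants, cb$variants)
  expect_identical(ca$f2, cb$f2)
  d <- simulate_reference(cfg, 100)
  expect_false(identical(a$genome, d$genome))
})

test_that("the reference bookkeeping is internally consistent", {
  cfg <- sim_config(n_genes = 16, n_scaffolds = 2,
                    scaffold_target_length = 20000)
  ref <- simulate_reference(cfg, 41)
  expect_equal(nrow(ref$unigenes), 16L)
  expect_equal(nrow(ref$truth$loci), 16L)
  # unigene = spliced exons: locus base on the unigene equals the genome base
  loci <- ref$truth$loci
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    u <- ref$unigenes$seq[ref$unigenes$id == l$unigene_id]
    g <- ref$genome$seq[ref$genome$id == l$scaffold]
    expect_equal(substr(u, l$unigene_pos, l$unigene_pos),
                 substr(g, l$genome_pos, l$genome_pos))
  }
  # planted repeats reach the blacklist at the default k and cutoff
  bl <- build_kmer_blacklist(ref$genome, 16, 10)
  rep1 <- ref$truth$repeats[1, ]
  g <- ref$genome$seq[ref$genome$id == rep1$scaffold]
  km <- substr(g, rep1$start, rep1$start + 15)
  expect_true(min(km, rc_chr(km)) %in% bl$kmers)
})

test_that("transcript SNP projection through the emitted alignments is exact", {
  study <- tiny_study(seed = 55)
  loci <- study$ref$truth$loci
  best <- best_alignment(study$ref$alignments)
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    hit <- best[best$query_id == l$unigene_id, ]
    proj <- project_position(hit, l$unigene_pos)
    expect_equal(proj$position, l$genome_pos)
    expect_equal(proj$scaffold, l$scaffold)
  }
})

test_that("full fixation recovers exactly the founder differences", {
  study <- tiny_study(seed = 56, fixation_rate = 1.0, noise_het_sites = 0)
  sites <- detect_polymorphic_sites(study$cross$variants, pipeline_config())
  loci <- study$ref$truth$loci
  expect_equal(nrow(sites), nrow(loci))
  merged <- dplyr::inner_join(sites, loci,
                              by = c("unigene_id", "position" = "unigene_pos"))
  expect_equal(nrow(merged), nrow(loci))
  expect_equal(merged$fixed_line.x, merged$fixed_line.y)
})

test_that("recovered-site fraction rises with the within-line fixation rate", {
  frac <- vapply(c(0.5, 0.8, 1.0), function(f) {
    study <- tiny_study(seed = 57, fixation_rate = f, n_genes = 48)
    sites <- detect_polymorphic_sites(study$cross$variants, pipeline_config())
    nrow(sites) / nrow(study$ref$truth$loci)
  }, 0)
  expect_lt(frac[1], frac[2])
  expect_lt(frac[2], frac[3])
  expect_equal(frac[3], 1.0)
})

test_that("meioses reproduce the Haldane recombination fraction", {
  cfg <- sim_config(n_genes = 2, n_scaffolds = 1,
                    scaffold_target_length = 5000, n_chromosomes = 1,
                    chrom_cm = 20, fixation_rate = 1.0, n_f2 = 1500,
                    noise_het_sites = 0)
  ref <- simulate_reference(cfg, 58)
  # genes sit at 5 and 15 cM: 10 cM apart
  expect_equal(diff(sort(ref$truth$loci$cm)), 10)
  cross <- simulate_lines_and_cross(ref, cfg, 58)
  # convert alt dose to parental dose so both loci are in coupling phase
  pdose <- function(i) {
    d <- cross$f2[i, ]
    if (ref$truth$loci$fixed_line[i] == "P1") d else 2L - d
  }
  tab <- table(factor(pdose(1), levels = 0:2), factor(pdose(2), levels = 0:2))
  est <- estimate_rf_em(unclass(tab))
  expect_lt(abs(est$rf - haldane_rf(10)), 0.02)
})

test_that("amplicon depth simulation shows marker heterogeneity and dropout", {
  study <- tiny_study(seed = 59, n_genes = 48, fixation_rate = 1.0,
                      dropout_prob = 0.25)
  loci <- study$ref$truth$loci
  panel <- tibble::tibble(
    marker_id = paste0(loci$unigene_id, "_", loci$unigene_pos),
    unigene_id = loci$unigene_id, scaffold = loci$scaffold,
    genome_position = loci$genome_pos, ref_allele = loci$ref_allele,
    alt_allele = loci$alt_allele, fixed_line = loci$fixed_line)
  amp <- simulate_amplicon_depths(panel, study$cross, study$ref, study$cfg, 59)
  means <- amp$depths |>
    dplyr::group_by(marker_id) |>
    dplyr::summarise(m = mean(ref_count + alt_count))
  q <- stats::quantile(means$m, c(0.1, 0.9))
  expect_gt(q[2] / max(q[1], 0.1), 10)  # log-normal sd 1 spans > 10x

  # one-parent dropout of a truly fixed marker produces Class 4
  calls <- call_genotypes(amp$depths)
  pcalls <- calls |>
    dplyr::filter(grepl("^P[12]_amp", sample_id)) |>
    dplyr::mutate(line_id = sub("_amp.*$", "", sample_id))
  classes <- classify_markers(parental_consensus(pcalls))
  flagged <- amp$dropout$marker_id[xor(amp$dropout$drop_p1,
                                       amp$dropout$drop_p2)]
  truly_fixed <- amp$truth_class$marker_id[amp$truth_class$true_class == 1L]
  target <- intersect(flagged, truly_fixed)
  expect_gt(length(target), 0)
  got <- classes$class[match(target, classes$marker_id)]
  expect_true(all(got == 4L))
})

test_that("the noiseless high-depth limit calls every heterozygote correctly", {
  study <- tiny_study(seed = 60, fixation_rate = 1.0,
                      depth_meanlog = log(100), depth_sdlog = 0,
                      overdispersion = 0, dropout_prob = 0)
  loci <- study$ref$truth$loci
  panel <- tibble::tibble(
    marker_id = paste0(loci$unigene_id, "_", loci$unigene_pos),
    unigene_id = loci$unigene_id, scaffold = loci$scaffold,
    genome_position = loci$genome_pos, ref_allele = loci$ref_allele,
    alt_allele = loci$alt_allele, fixed_line = loci$fixed_line)
  amp <- simulate_amplicon_depths(panel, study$cross, study$ref, study$cfg, 60)
  calls <- call_genotypes(amp$depths)
  f2_ids <- study$cross$sample_ids$f2
  idx <- match(panel$unigene_id, rownames(study$cross$f2))
  truth_dose <- study$cross$f2[idx, , drop = FALSE]
  f2_calls <- calls |> dplyr::filter(sample_id %in% f2_ids)
  truth_call <- c("ref_hom", "het", "alt_hom")[
    truth_dose[cbind(match(f2_calls$marker_id, panel$marker_id),
                     match(f2_calls$sample_id, colnames(truth_dose)))] + 1L]
  het <- truth_call == "het"
  expect_true(all(f2_calls$call[het] == "het"))
})
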