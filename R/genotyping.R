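#' Call genotypes from per-sample allele depths
#'
#' Diploid genotype calls at amplicon sites from ref/alt read counts,
#' reusing the transcriptome-calling thresholds: a site is `no_call` when
#' total depth is below `min_coverage`; otherwise `alt_hom` when the
#' alternate frequency strictly exceeds `hom_cutoff` percent, `ref_hom`
#' when strictly below `100 - hom_cutoff`, and `het` in between provided
#' both alleles have at least `min_count` reads (else `no_call`).
#'
#' @param depths Site-depth tibble ([read_depth_table()]).
#' @param cfg A [pipeline_config()].
#' @return The input with `total_depth`, `alt_freq` and `call` columns.
#' @examples
#' d <- tibble::tibble(sample_id = "f2_1", marker_id = "m1", scaffold = "s1",
#'                     position = 100L, ref_allele = "A", alt_allele = "G",
#'                     is_hotspot = TRUE, ref_count = c(0L, 15L, 2L, 25L),
#'                     alt_count = c(30L, 15L, 2L, 3L))
#' call_genotypes(d)$call
#' @export
call_genotypes <- function(depths, cfg = NULL) {
  cfg <- as_config(cfg)
  depths |>
    mutate(
      total_depth = .data$ref_count + .data$alt_count,
      alt_freq = ifelse(.data$total_depth > 0,
                        100 * .data$alt_count / .data$total_depth, 0),
      call = case_when(
        .data$total_depth < cfg$min_coverage ~ "no_call",
        .data$alt_freq > cfg$hom_cutoff ~ "alt_hom",
        .data$alt_freq < 100 - cfg$hom_cutoff ~ "ref_hom",
        pmin(.data$ref_count, .data$alt_count) >= cfg$min_count ~ "het",
        .default = "no_call"
      )
    )
}

#' Consensus genotype of replicate parent plants
#'
#' Per site and line: if every non-missing replicate call agrees the
#' consensus is that call; if all replicates are `no_call` the consensus is
#' `no_call`; any disagreement among non-missing calls yields `unfixed`.
#'
#' @param calls Genotype calls ([call_genotypes()]) for replicate plants of
#'   parental lines, with a `line_id` column.
#' @return Tibble with one row per line x marker x site: `consensus` and
#'   the number of replicates supporting it.
#' @export
parental_consensus <- function(calls) {
  calls |>
    group_by(.data$line_id, .data$marker_id, .data$scaffold, .data$position,
             .data$ref_allele, .data$alt_allele, .data$is_hotspot) |>
    summarise(
      n_replicates = n(),
      consensus = {
        obs <- unique(.data$call[.data$call != "no_call"])
        if (length(obs) == 0) "no_call"
        else if (length(obs) == 1) obs
        else "unfixed"
      },
      .groups = "drop"
    )
}

#' Classify markers by parental hotspot behaviour
#'
#' Five validation classes from the two parental consensus genotypes at the
#' marker's hotspot: (1) both parents fixed for different genotypes
#' (polymorphism captured); (2) no variant observed at the hotspot in any
#' sample (or parents fixed for the same genotype); (3) neither parent
#' callable; (4) exactly one parent callable; (5) either parent unfixed
#' among its replicates.
#'
#' @param consensus Output of [parental_consensus()] filtered to hotspot
#'   sites, with exactly two lines.
#' @param variant_seen Optional tibble `marker_id`, `had_any_variant`; a
#'   marker with `had_any_variant = FALSE` is Class 2 regardless of calls.
#' @return Tibble `marker_id`, `consensus_p1`, `consensus_p2`, `class`.
#' @export
classify_markers <- function(consensus, variant_seen = NULL) {
  lines <- sort(unique(consensus$line_id))
  if (length(lines) != 2) abort("classify_markers() expects exactly 2 lines")
  wide <- consensus |>
    filter(.data$is_hotspot) |>
    select("line_id", "marker_id", "consensus") |>
    tidyr::pivot_wider(names_from = "line_id", values_from = "consensus") |>
    rename(consensus_p1 = !!lines[1], consensus_p2 = !!lines[2])
  if (!is.null(variant_seen)) {
    wide <- left_join(wide, variant_seen, by = "marker_id")
  } else {
    wide$had_any_variant <- TRUE
  }
  wide |>
    mutate(
      had_any_variant = ifelse(is.na(.data$had_any_variant), TRUE,
                               .data$had_any_variant),
      class = marker_class(.data$consensus_p1, .data$consensus_p2,
                           .data$had_any_variant)
    ) |>
    select("marker_id", "consensus_p1", "consensus_p2", "class")
}

#' Single-marker class rule
#'
#' Vectorized classification underlying [classify_markers()]; total over
#' all consensus combinations and the variant flag.
#'
#' @param p1,p2 Parental consensus calls (`ref_hom`, `het`, `alt_hom`,
#'   `unfixed`, `no_call`).
#' @param had_any_variant Logical; was any variant observed at the hotspot?
#' @return Integer class 1-5.
#' @export
marker_class <- function(p1, p2, had_any_variant = TRUE) {
  fixed <- function(x) x %in% c("ref_hom", "het", "alt_hom")
  case_when(
    !had_any_variant ~ 2L,
    p1 == "no_call" & p2 == "no_call" ~ 3L,
    xor(p1 == "no_call", p2 == "no_call") ~ 4L,
    p1 == "unfixed" | p2 == "unfixed" ~ 5L,
    fixed(p1) & fixed(p2) & p1 != p2 ~ 1L,
    .default = 2L
  )
}

#' Convert F2 calls to parental A/H/B codes
#'
#' Requires an informative site: both parental consensus genotypes fixed,
#' homozygous and different. An F2 call equal to parent 1's homozygous
#' genotype becomes `A`, equal to parent 2's becomes `B`, `het` becomes
#' `H`, and `no_call` becomes `-`.
#'
#' @param f2_calls Character vector of F2 calls.
#' @param consensus_p1,consensus_p2 Parental consensus calls (scalars).
#' @return Character vector of codes `A`, `H`, `B`, `-`.
#' @export
to_parental_code <- function(f2_calls, consensus_p1, consensus_p2) {
  homs <- c("ref_hom", "alt_hom")
  if (!(consensus_p1 %in% homs && consensus_p2 %in% homs &&
        consensus_p1 != consensus_p2)) {
    abort("site not convertible: parental genotypes not fixed, homozygous and different")
  }
  case_when(
    f2_calls == consensus_p1 ~ "A",
    f2_calls == consensus_p2 ~ "B",
    f2_calls == "het" ~ "H",
    .default = "-"
  )
}

#' Select one representative site per amplicon
#'
#' When several polymorphic sites fall inside one amplicon, keeps a single
#' one: candidates are the sites called heterozygous in the reference F1
#' plant; among candidates the hotspot is preferred, else the site with the
#' lowest missing fraction, ties broken by smallest coordinate. A marker
#' with no F1-heterozygous site yields no row.
#'
#' @param site_info Tibble with one row per marker x site: `marker_id`,
#'   `scaffold`, `position`, `is_hotspot`, `f1_het` (logical),
#'   `missing_fraction`.
#' @return Tibble of selected sites, one row per retained marker.
#' @export
select_representative_site <- function(site_info) {
  site_info |>
    filter(.data$f1_het) |>
    group_by(.data$marker_id) |>
    arrange(desc(.data$is_hotspot), .data$missing_fraction, .data$position,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Build an A/H/B genotype matrix from F2 calls
#'
#' Converts per-sample F2 genotype calls at informative sites into a
#' markers-by-individuals code matrix.
#'
#' @param f2_calls Genotype calls ([call_genotypes()]) for F2 individuals.
#' @param marker_classes Output of [classify_markers()]; only Class 1
#'   markers are convertible and used.
#' @return A `geno_matrix` tibble: `marker_id` plus one column per F2
#'   individual.
#' @export
build_genotype_matrix <- function(f2_calls, marker_classes) {
  informative <- marker_classes |>
    filter(.data$class == 1L,
           .data$consensus_p1 %in% c("ref_hom", "alt_hom"),
           .data$consensus_p2 %in% c("ref_hom", "alt_hom"))
  coded <- f2_calls |>
    filter(.data$is_hotspot) |>
    inner_join(informative, by = "marker_id") |>
    group_by(.data$marker_id) |>
    mutate(code = to_parental_code(.data$call, .data$consensus_p1[1],
                                   .data$consensus_p2[1])) |>
    ungroup()
  out <- coded |>
    select("marker_id", "sample_id", "code") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "code",
                       values_fill = "-") |>
    arrange(.data$marker_id)
  class(out) <- c("geno_matrix", class(out))
  out
}

#' Missing-data and segregation-distortion filter
#'
#' Removes matrix rows with a missing fraction strictly above
#' `max_missing`, or whose (nA, nH, nB) counts reject the 1:2:1 F2
#' expectation in a chi-square test (2 df) at p strictly below
#' `distortion_alpha`.
#'
#' @param matrix A genotype-matrix tibble (`marker_id` + code columns).
#' @param cfg A [pipeline_config()].
#' @return List with `matrix` (kept rows) and `report` (one row per input
#'   marker: counts, missing fraction, chi-square statistic, p-value,
#'   `dropped`, `reason`).
#' @export
filter_matrix <- function(matrix, cfg = NULL) {
  cfg <- as_config(cfg)
  counts <- segregation_counts(matrix)
  report <- counts |>
    mutate(
      n = .data$nA + .data$nH + .data$nB + .data$nMissing,
      missing_fraction = .data$nMissing / .data$n,
      chisq = chisq_121(.data$nA, .data$nH, .data$nB),
      p_value = pchisq(.data$chisq, df = 2, lower.tail = FALSE),
      reason = case_when(
        .data$missing_fraction > cfg$max_missing ~ "missing",
        .data$p_value < cfg$distortion_alpha ~ "distorted",
        .default = NA_character_
      ),
      dropped = !is.na(.data$reason)
    )
  kept <- matrix[!report$dropped, ]
  list(matrix = kept, report = report)
}

# 1:2:1 goodness-of-fit statistic on non-missing counts (df = 2).
chisq_121 <- function(nA, nH, nB) {
  n <- nA + nH + nB
  exp_counts <- cbind(n / 4, n / 2, n / 4)
  obs <- cbind(nA, nH, nB)
  out <- rowSums((obs - exp_counts)^2 / exp_counts)
  out[n == 0] <- NA_real_
  out
}

#' Refine a marker set after a first genotyping round
#'
#' Rebuilds the panel for later populations: markers that failed
#' amplification (Class 3) or never captured a parental polymorphism at any
#' site (Classes 2 and 4) are removed; among co-scaffold markers that were
#' all used for map construction only one representative is kept (lowest
#' missing fraction, ties by smallest genome coordinate); Class 1 or 5
#' markers that captured a parental polymorphism but did not segregate in
#' this population are retained, since they may segregate in an F2 from a
#' different F1 plant.
#'
#' @param panel Panel tibble (`marker_id`, `scaffold`, `genome_position`).
#' @param marker_classes Output of [classify_markers()].
#' @param mapping_status Tibble `marker_id`, `used_in_map` (logical),
#'   `missing_fraction`.
#' @return List with `panel` (kept markers) and `report` (counts per
#'   criterion).
#' @export
refine_marker_set <- function(panel, marker_classes, mapping_status) {
  info <- panel |>
    left_join(marker_classes, by = "marker_id") |>
    left_join(mapping_status, by = "marker_id") |>
    mutate(used_in_map = ifelse(is.na(.data$used_in_map), FALSE,
                                .data$used_in_map))
  captured <- info |> filter(.data$class %in% c(1L, 5L))
  mapped <- captured |> filter(.data$used_in_map)
  dedup <- mapped |>
    group_by(.data$scaffold) |>
    arrange(.data$missing_fraction, .data$genome_position, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  removed_coscaffold <- nrow(mapped) - nrow(dedup)
  non_segregating <- captured |> filter(!.data$used_in_map)
  kept <- bind_rows(
    dedup |> mutate(criterion = "mapped-representative"),
    non_segregating |> mutate(criterion = "retained-non-segregating")
  ) |>
    arrange(.data$marker_id)
  report <- tibble(
    n_input = nrow(panel),
    n_failed_or_uncaptured = nrow(info) - nrow(captured),
    n_coscaffold_removed = removed_coscaffold,
    n_mapped_kept = nrow(dedup),
    n_non_segregating_kept = nrow(non_segregating),
    n_kept = nrow(kept)
  )
  list(panel = kept, report = report)
}
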