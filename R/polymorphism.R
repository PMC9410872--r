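#' Call zygosity from per-individual transcriptome variant observations
#'
#' Applies the variant-detection thresholds to each observation and labels
#' it `homozygous`, `heterozygous` or `none`. An observation fails the
#' thresholds (`none`) when its total depth is below `min_coverage`, its
#' alternate count below `min_count`, or its alternate frequency below
#' `min_freq` percent. A kept call is `homozygous` when the alternate
#' frequency strictly exceeds `hom_cutoff` percent, otherwise
#' `heterozygous` (a frequency exactly at the cutoff is heterozygous).
#'
#' @param variants Tibble of variant observations (see
#'   [read_variant_table()]).
#' @param cfg A [pipeline_config()] (or `NULL` for defaults).
#' @return The input with `alt_freq` (percent) and `zygosity` columns.
#' @examples
#' v <- tibble::tibble(sample_id = "p1", line_id = "L1", unigene_id = "u1",
#'                     position = 10L, ref_allele = "A", alt_allele = "G",
#'                     total_depth = 20L, alt_count = c(20L, 10L))
#' call_zygosity(v)$zygosity
#' @export
call_zygosity <- function(variants, cfg = NULL) {
  cfg <- as_config(cfg)
  validate_variants(variants)
  variants |>
    mutate(
      alt_freq = ifelse(.data$total_depth > 0,
                        100 * .data$alt_count / .data$total_depth, 0),
      zygosity = case_when(
        .data$total_depth < cfg$min_coverage ~ "none",
        .data$alt_count < cfg$min_count ~ "none",
        .data$alt_freq < cfg$min_freq ~ "none",
        .data$alt_freq > cfg$hom_cutoff ~ "homozygous",
        .default = "heterozygous"
      )
    )
}

#' Fixed homozygous variant sites of one parental line
#'
#' A site (unigene, position, alt allele) is fixed within a line when at
#' least `min_support` of the line's individuals carry a homozygous call for
#' the same alternate allele. With the default `min_support = NULL` the
#' threshold is n - 1 for a line of n individuals, tolerating one
#' incompletely fixed or poorly covered plant per site.
#'
#' @param calls Output of [call_zygosity()] for individuals of one line.
#' @param min_support Absolute count, fraction in (0, 1], or `NULL` (n - 1).
#' @return Tibble of fixed sites: `line_id`, `unigene_id`, `position`,
#'   `ref_allele`, `alt_allele`, `support`, `n_individuals`.
#' @export
line_fixed_sites <- function(calls, min_support = NULL) {
  if (length(unique(calls$line_id)) > 1) {
    abort("line_fixed_sites() expects calls from a single line")
  }
  n <- length(unique(calls$sample_id))
  if (n < 2) abort("need at least 2 individuals per line")
  thr <- resolve_min_support(min_support, n)
  calls |>
    filter(.data$zygosity == "homozygous") |>
    distinct(.data$sample_id, .data$line_id, .data$unigene_id, .data$position,
             .data$ref_allele, .data$alt_allele) |>
    count(.data$line_id, .data$unigene_id, .data$position, .data$ref_allele,
          .data$alt_allele, name = "support") |>
    filter(.data$support >= thr) |>
    mutate(n_individuals = n) |>
    arrange(.data$unigene_id, .data$position, .data$alt_allele)
}

#' Inter-line polymorphic sites
#'
#' A polymorphic site between two parental lines is a site with a fixed
#' homozygous variant in one line while no individual of the other line has
#' any called variant (homozygous or heterozygous, any alternate allele) at
#' the same unigene position. Sites fixed in both lines are therefore never
#' reported. The result is the union over both orientations, sorted by
#' unigene and position.
#'
#' @param fixed_1,fixed_2 Fixed-site tibbles from [line_fixed_sites()] for
#'   each line.
#' @param calls_1,calls_2 Full zygosity-call tibbles ([call_zygosity()]) for
#'   each line; used to veto sites detected in the opposite line.
#' @return Tibble of polymorphic sites with a `fixed_line` column.
#' @export
interline_polymorphic_sites <- function(fixed_1, calls_2, fixed_2, calls_1) {
  one_way <- function(fixed, other_calls) {
    detected <- other_calls |>
      filter(.data$zygosity != "none") |>
      distinct(.data$unigene_id, .data$position)
    fixed |>
      anti_join(detected, by = c("unigene_id", "position"))
  }
  bind_rows(one_way(fixed_1, calls_2), one_way(fixed_2, calls_1)) |>
    rename(fixed_line = "line_id") |>
    arrange(.data$unigene_id, .data$position, .data$alt_allele)
}

#' Detect polymorphic sites between two parental lines
#'
#' Convenience wrapper chaining [call_zygosity()], [line_fixed_sites()] per
#' line and [interline_polymorphic_sites()] over a combined variant table of
#' exactly two lines.
#'
#' @param variants Combined variant table for both lines.
#' @param cfg A [pipeline_config()].
#' @return Polymorphic-site tibble (see [interline_polymorphic_sites()]).
#' @export
detect_polymorphic_sites <- function(variants, cfg = NULL) {
  cfg <- as_config(cfg)
  lines <- sort(unique(variants$line_id))
  if (length(lines) != 2) {
    abort(paste0("expected exactly 2 parental lines, got ", length(lines)))
  }
  calls <- call_zygosity(variants, cfg)
  c1 <- filter(calls, .data$line_id == lines[1])
  c2 <- filter(calls, .data$line_id == lines[2])
  f1 <- line_fixed_sites(c1, cfg$min_support)
  f2 <- line_fixed_sites(c2, cfg$min_support)
  interline_polymorphic_sites(f1, c2, f2, c1)
}

#' Categorize polymorphic sites by genetic-map knowledge
#'
#' Joins sites to the unigene anchor table and labels each site `anchored`
#' (cM position known), `chromosome_only` (chromosome known) or
#' `no_information`.
#'
#' @param sites Polymorphic-site tibble.
#' @param anchors Anchor tibble ([read_anchor_table()]); may be `NULL`, in
#'   which case every site is `no_information`.
#' @return `sites` with `chromosome`, `cm_position` and `category` columns.
#' @export
categorize_sites <- function(sites, anchors = NULL) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    return(mutate(sites, chromosome = NA_character_,
                  cm_position = NA_real_, category = "no_information"))
  }
  anchors <- anchor_categories(anchors)
  sites |>
    left_join(anchors[c("unigene_id", "chromosome", "cm_position", "category")],
              by = "unigene_id") |>
    mutate(category = ifelse(is.na(.data$category), "no_information",
                             .data$category))
}

#' Per-chromosome classification summary of polymorphic sites
#'
#' Counts polymorphisms and distinct unigenes per chromosome within each
#' map-knowledge category, in the layout of a site-classification table.
#'
#' @param sites Categorized site tibble ([categorize_sites()]).
#' @return Tibble with one row per chromosome (plus `NA` for
#'   `no_information`), columns per category.
#' @export
summarize_site_classification <- function(sites) {
  sites |>
    group_by(.data$category,
             chromosome = ifelse(.data$category == "no_information",
                                 NA_character_, .data$chromosome)) |>
    summarise(n_polymorphisms = n(),
              n_unigenes = n_distinct(.data$unigene_id), .groups = "drop") |>
    arrange(.data$category, .data$chromosome)
}

#' Column totals of a site-classification / marker-count table
#'
#' Sums the numeric count columns of a per-chromosome classification table
#' (such as the output of [summarize_site_classification()], or a published
#' classification table used as input) into a one-row totals tibble.
#'
#' @param class_table Tibble with a `chromosome` column and numeric count
#'   columns.
#' @return One-row tibble of column sums.
#' @export
classification_totals <- function(class_table) {
  num <- class_table |>
    select(-any_of("chromosome")) |>
    select(where(is.numeric))
  summarise(num, across(everything(), ~ sum(.x, na.rm = TRUE)))
}

#' Class-frequency summary of a marker classification
#'
#' Tallies marker validation classes and expresses each as a percentage of
#' the classified total (one decimal, as conventionally printed).
#'
#' @param classes Tibble with `marker_id` and `class` columns (see
#'   [classify_markers()]).
#' @return Tibble with `class`, `n` and `pct` columns.
#' @export
summarize_marker_classes <- function(classes) {
  classes |>
    count(.data$class, name = "n") |>
    mutate(pct = round(100 * .data$n / sum(.data$n), 1))
}
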