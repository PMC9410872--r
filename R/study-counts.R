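#' Bundled onion-study bookkeeping tables
#'
#' Small plain-text tables bundled with the package, holding the printed
#' per-chromosome site-classification rows, the five-class marker
#' validation counts and assorted panel counts from the onion
#' amplicon-genotyping campaign the package's defaults emulate. They serve
#' as worked-example inputs for the summary functions
#' ([classification_totals()], [summarize_marker_classes()]).
#'
#' @param which One of `"site_classification"`, `"marker_validation"`,
#'   `"panel_counts"`.
#' @return A tibble.
#' @examples
#' classification_totals(onion_study_counts("site_classification"))
#' @export
onion_study_counts <- function(which = c("site_classification",
                                         "marker_validation",
                                         "panel_counts")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("onion_", which, ".tsv"),
                      package = "ampliconpanel", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
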