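#' Per-marker segregation counts
#'
#' Tallies A/H/B/missing codes for each row of a genotype matrix.
#'
#' @param matrix Genotype-matrix tibble (`marker_id` + code columns), or a
#'   single character vector of codes.
#' @return Tibble with `marker_id`, `nA`, `nH`, `nB`, `nMissing`.
#' @export
segregation_counts <- function(matrix) {
  if (is.character(matrix)) {
    matrix <- tibble(marker_id = "row1", !!!setNames(as.list(matrix),
                                                     paste0("i", seq_along(matrix))))
  }
  codes <- as.matrix(matrix[-1])
  if (ncol(codes) == 0) abort("genotype matrix has no individuals")
  tibble(
    marker_id = matrix$marker_id,
    nA = rowSums(codes == "A"),
    nH = rowSums(codes == "H"),
    nB = rowSums(codes == "B"),
    nMissing = rowSums(codes == "-")
  )
}

# Joint F2 two-locus genotype probabilities for recombination fraction r.
# Rows/cols in order A, H, B for marker 1 / marker 2; the H,H cell pools the
# two double-heterozygote phases.
f2_joint_probs <- function(r) {
  p <- 1 - r
  # gametes: parental (1-r)/2 each, recombinant r/2 each
  g1 <- c(p / 2, r / 2, r / 2, p / 2)  # AB, Ab, aB, ab
  hap_m1 <- c(1, 1, 2, 2)  # allele at locus 1 per gamete (1 = A)
  hap_m2 <- c(1, 2, 1, 2)
  probs <- matrix(0, 3, 3)
  for (i in 1:4) {
    for (j in 1:4) {
      m1 <- hap_m1[i] + hap_m1[j]  # 2 hom A, 3 het, 4 hom a
      m2 <- hap_m2[i] + hap_m2[j]
      probs[m1 - 1, m2 - 1] <- probs[m1 - 1, m2 - 1] + g1[i] * g1[j]
    }
  }
  probs
}

f2_loglik <- function(r, tab) {
  pr <- f2_joint_probs(r)
  if (any(tab > 0 & pr == 0)) return(-Inf)
  sum(tab[pr > 0] * log(pr[pr > 0]))
}

#' EM estimate of the recombination fraction for two F2 markers
#'
#' Maximum-likelihood recombination fraction under the codominant F2
#' intercross model from a 3x3 table of A/H/B joint counts (missing pairs
#' excluded). The double-heterozygote cell mixes the two phase classes
#' (0 or 2 recombinant gametes); EM resolves it by splitting that cell at
#' each step according to the current estimate. Convergence at
#' `|delta rf| < 1e-8` or 200 iterations; the estimate is clipped to
#' `[0, 0.5]`. LOD is `log10 L(rf) - log10 L(0.5)`.
#'
#' @param tab 3x3 numeric matrix of joint counts, rows marker 1 (A, H, B),
#'   columns marker 2 (A, H, B).
#' @return Tibble with `rf`, `lod`, `n` (informative pairs) and
#'   `low_information` (fewer than 10 pairs).
#' @export
estimate_rf_em <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(3, 3)))
  n <- sum(tab)
  if (n == 0) {
    return(tibble(rf = NA_real_, lod = NA_real_, n = 0L,
                  low_information = TRUE))
  }
  # recombinant gametes contributed by each cell (H,H handled separately)
  rec <- matrix(c(0, 1, 2,
                  1, NA, 1,
                  2, 1, 0), 3, 3, byrow = TRUE)
  n_hh <- tab[2, 2]
  fixed_rec <- sum(tab * ifelse(is.na(rec), 0, rec))
  r <- 0.25
  for (iter in 1:200) {
    p <- 1 - r
    w_rec <- r^2 / (p^2 + r^2)  # P(repulsion phase | double het)
    e_rec <- fixed_rec + n_hh * 2 * w_rec
    r_new <- min(max(e_rec / (2 * n), 0), 0.5)
    if (abs(r_new - r) < 1e-8) {
      r <- r_new
      break
    }
    r <- r_new
  }
  lod <- (f2_loglik(r, tab) - f2_loglik(0.5, tab)) / log(10)
  tibble(rf = r, lod = max(lod, 0), n = as.integer(n),
         low_information = n < 10)
}

#' Haldane map distance and its inverse
#'
#' `haldane_cm()` converts a recombination fraction to centimorgans under
#' no crossover interference, `d = -50 ln(1 - 2 rf)`; `haldane_rf()` is the
#' inverse, `rf = (1 - exp(-d / 50)) / 2`.
#'
#' @param rf Recombination fraction in `[0, 0.5)`.
#' @param cm Map distance in centimorgans, `>= 0`.
#' @return Numeric vector of distances (cM) or recombination fractions.
#' @examples
#' haldane_cm(0.1)            # 11.157...
#' haldane_rf(haldane_cm(0.3))
#' @export
haldane_cm <- function(rf) {
  if (any(rf < 0 | rf >= 0.5)) {
    abort("recombination fraction must be in [0, 0.5): distance is infinite at 0.5")
  }
  -50 * log(1 - 2 * rf)
}

#' @rdname haldane_cm
#' @export
haldane_rf <- function(cm) {
  if (any(cm < 0)) abort("map distance must be non-negative")
  (1 - exp(-cm / 50)) / 2
}

#' All-pairs two-point linkage scan of a genotype matrix
#'
#' Estimates the recombination fraction and LOD for every marker pair and
#' converts each rf to a Haldane distance.
#'
#' @param matrix Genotype-matrix tibble.
#' @return An object of class `linkage_scan`: list with `pairs` (tibble
#'   `marker1`, `marker2`, `rf`, `cm`, `lod`, `n`, `low_information`) and
#'   `markers`.
#' @export
pairwise_linkage <- function(matrix) {
  markers <- matrix$marker_id
  codes <- as.matrix(matrix[-1])
  rownames(codes) <- markers
  m <- length(markers)
  if (m < 1) abort("empty genotype matrix")
  combos <- if (m >= 2) utils::combn(m, 2) else matrix(numeric(), 2, 0)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    x <- codes[i, ]; y <- codes[j, ]
    keep <- x != "-" & y != "-"
    tab <- table(factor(x[keep], levels = c("A", "H", "B")),
                 factor(y[keep], levels = c("A", "H", "B")))
    est <- estimate_rf_em(unclass(tab))
    est$marker1 <- markers[i]
    est$marker2 <- markers[j]
    est
  })
  pairs <- list_rbind(rows)
  if (nrow(pairs) > 0) {
    pairs <- pairs |>
      mutate(cm = ifelse(.data$rf < 0.5, haldane_cm(pmin(.data$rf, 0.4999999)),
                         Inf)) |>
      select("marker1", "marker2", "rf", "cm", "lod", "n", "low_information")
  } else {
    pairs <- tibble(marker1 = character(), marker2 = character(),
                    rf = numeric(), cm = numeric(), lod = numeric(),
                    n = integer(), low_information = logical())
  }
  structure(list(pairs = pairs, markers = markers), class = "linkage_scan")
}

#' Group markers by LOD-threshold single linkage
#'
#' Places two markers in the same linkage group when they are connected by
#' a chain of marker pairs each with LOD strictly above `lod_threshold` and
#' estimated rf below `max_rf` (the rf guard keeps distorted high-LOD,
#' high-rf pairs from merging groups). Groups are numbered by their
#' smallest member id.
#'
#' @param scan A `linkage_scan` ([pairwise_linkage()]) or its `pairs`
#'   tibble.
#' @param lod_threshold LOD grouping threshold.
#' @param max_rf Maximum rf for a grouping edge.
#' @param markers Optional character vector of all marker ids (needed when
#'   passing a bare pairs tibble so singleton markers are kept).
#' @return Tibble `marker_id`, `group`.
#' @export
group_markers <- function(scan, lod_threshold = 4.0, max_rf = 0.45,
                          markers = NULL) {
  if (inherits(scan, "linkage_scan")) {
    pairs <- scan$pairs
    markers <- scan$markers
  } else {
    pairs <- scan
    markers <- markers %||% sort(unique(c(pairs$marker1, pairs$marker2)))
  }
  edges <- pairs |>
    filter(!is.na(.data$rf), .data$lod > lod_threshold, .data$rf < max_rf)
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(length(markers), name = markers)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$marker1, edges$marker2))
  }
  comp <- igraph::components(g)$membership
  out <- tibble(marker_id = names(comp), component = as.integer(comp))
  renumber <- out |>
    group_by(.data$component) |>
    summarise(first_member = min(.data$marker_id), .groups = "drop") |>
    arrange(.data$first_member) |>
    mutate(group = row_number())
  out |>
    left_join(renumber, by = "component") |>
    select("marker_id", "group") |>
    arrange(.data$group, .data$marker_id)
}

#' Label linkage groups with chromosomes via anchored markers
#'
#' Assigns each group the majority chromosome among its members with known
#' chromosome; groups with no anchored member get `NA`.
#'
#' @param groups Output of [group_markers()].
#' @param marker_chromosomes Tibble `marker_id`, `chromosome`.
#' @return `groups` with a `chromosome` column.
#' @export
label_groups <- function(groups, marker_chromosomes) {
  lab <- groups |>
    left_join(marker_chromosomes, by = "marker_id") |>
    filter(!is.na(.data$chromosome)) |>
    count(.data$group, .data$chromosome) |>
    group_by(.data$group) |>
    arrange(desc(.data$n), .data$chromosome, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("group", "chromosome")
  left_join(groups, lab, by = "group")
}

#' @export
print.linkage_scan <- function(x, ...) {
  cat("<linkage_scan>", length(x$markers), "markers,",
      nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' @describeIn pairwise_linkage `tidy()` returns the pairwise tibble.
#' @param x A `linkage_scan`.
#' @param ... Unused.
#' @export
tidy.linkage_scan <- function(x, ...) x$pairs

#' @describeIn pairwise_linkage `glance()` returns a one-row scan summary.
#' @export
glance.linkage_scan <- function(x, ...) {
  tibble(
    n_markers = length(x$markers),
    n_pairs = nrow(x$pairs),
    mean_rf = mean(x$pairs$rf, na.rm = TRUE),
    max_lod = ifelse(nrow(x$pairs) > 0, max(x$pairs$lod, na.rm = TRUE), NA_real_),
    n_low_information = sum(x$pairs$low_information, na.rm = TRUE)
  )
}
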