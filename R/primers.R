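# Nearest-neighbour duplex parameters (SantaLucia 1998 unified set):
# dH kcal/mol, dS cal/(mol K), 5'->3' top-strand dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbour primer melting temperature
#'
#' Two-state nearest-neighbour Tm with the unified duplex parameter set,
#' terminal initiation corrections, an entropic salt correction of
#' `0.368 (N-1) ln[Na+]`, 50 mM monovalent cation and 500 nM total primer.
#'
#' @param seqs Character vector of primer sequences (ACGT).
#' @param na_conc Monovalent cation concentration, mol/L.
#' @param primer_conc Total single-strand concentration, mol/L.
#' @return Numeric vector of Tm in degrees Celsius.
#' @export
primer_tm <- function(seqs, na_conc = 0.05, primer_conc = 5e-7) {
  seqs <- toupper(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 2) return(NA_real_)
    di <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(NN_DH[di])
    ds <- sum(NN_DS[di])
    ends <- c(substr(s, 1, 1), substr(s, n, n))
    for (e in ends) {
      if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1) * log(na_conc)
    r <- 1.987
    dh * 1000 / (ds + r * log(primer_conc / 4)) - 273.15
  }, 0, USE.NAMES = FALSE)
}

gc_percent <- function(seqs) {
  100 * stringr::str_count(toupper(seqs), "[GC]") / nchar(seqs)
}

has_homopolymer <- function(seqs, run = 5) {
  pat <- paste0("A{", run, "}|C{", run, "}|G{", run, "}|T{", run, "}")
  grepl(pat, toupper(seqs))
}

# Candidate primers on one strand of the window. For forward primers the
# 3' end is the interval end; for reverse primers (given as plus-strand
# intervals) the 3' end is the interval start.
enumerate_candidates <- function(window, cfg, side) {
  so <- window$site_offset
  wlen <- nchar(window$seq)
  lens <- cfg$primer_len_min:cfg$primer_len_max
  if (side == "fwd") {
    lo <- max(cfg$primer_len_min, so - cfg$amplicon_max + cfg$primer_len_min)
    if (lo > so - 1L) return(tibble())
    ends <- seq.int(lo, so - 1L)
    grid <- expand.grid(end = ends, len = lens)
    grid$start <- grid$end - grid$len + 1L
    grid <- grid[grid$start >= 1L, ]
    grid$three_prime <- grid$end
  } else {
    hi <- min(wlen - cfg$primer_len_min + 1L,
              so + cfg$amplicon_max - cfg$primer_len_min)
    if (so + 1L > hi) return(tibble())
    starts <- seq.int(so + 1L, hi)
    grid <- expand.grid(start = starts, len = lens)
    grid$end <- grid$start + grid$len - 1L
    grid <- grid[grid$end <= wlen, ]
    grid$three_prime <- grid$start
  }
  if (nrow(grid) == 0) return(tibble())
  plus_seq <- substring(window$seq, grid$start, grid$end)
  seq <- if (side == "fwd") plus_seq else revcomp(plus_seq)
  out <- tibble(start = grid$start, end = grid$end, seq = seq,
                three_prime = grid$three_prime)
  out$tm <- primer_tm(out$seq)
  out$gc <- gc_percent(out$seq)
  out |>
    filter(!window$mask[.data$three_prime],
           .data$tm >= cfg$tm_min, .data$tm <= cfg$tm_max,
           .data$gc >= cfg$gc_min, .data$gc <= cfg$gc_max,
           !has_homopolymer(.data$seq))
}

#' Design candidate primer pairs over one masked window
#'
#' Enumerates forward/reverse primer pairs on a masked design window so
#' that the amplicon (product) size lies within the configured range, the
#' polymorphic site sits strictly inside the amplicon and outside both
#' primer binding intervals, no primer 3'-terminal base is masked, primer
#' length, Tm, pair Tm difference, GC content and homopolymer constraints
#' hold. Candidates are ranked by `|Tm_f - 60| + |Tm_r - 60|`, best first.
#'
#' @param window A masked `flank_window` ([mask_window()]).
#' @param cfg A [pipeline_config()].
#' @param max_candidates Maximum candidates returned.
#' @return Tibble of candidates (window-relative 1-based intervals,
#'   genome-relative amplicon coordinates, primer sequences, Tm, product
#'   size). When empty, attribute `reason` explains why (`"masked"`,
#'   `"no-candidate-primer"`, `"no-feasible-pair"`).
#' @export
design_primer_pair <- function(window, cfg = NULL, max_candidates = 10) {
  cfg <- as_config(cfg)
  empty <- function(reason) {
    out <- tibble()
    attr(out, "reason") <- reason
    out
  }
  if (all(window$mask)) return(empty("masked"))
  fwd <- enumerate_candidates(window, cfg, "fwd")
  rev <- enumerate_candidates(window, cfg, "rev")
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    reason <- if (mean(window$mask) > 0.5) "masked" else "no-candidate-primer"
    return(empty(reason))
  }
  pairs <- tidyr::crossing(
    fwd |> rename_with(~ paste0("fwd_", .x)),
    rev |> rename_with(~ paste0("rev_", .x))
  ) |>
    mutate(product_size = .data$rev_end - .data$fwd_start + 1L) |>
    filter(.data$product_size >= cfg$amplicon_min,
           .data$product_size <= cfg$amplicon_max,
           abs(.data$fwd_tm - .data$rev_tm) <= cfg$tm_pair_max_diff)
  if (nrow(pairs) == 0) return(empty("no-feasible-pair"))
  pairs |>
    mutate(penalty = abs(.data$fwd_tm - 60) + abs(.data$rev_tm - 60),
           scaffold = window$scaffold,
           amplicon_start = window$window_start + .data$fwd_start - 1L,
           amplicon_end = window$window_start + .data$rev_end - 1L,
           hotspot_position = window$window_start + window$site_offset - 1L,
           hotspot_offset = window$site_offset - .data$fwd_start + 1L) |>
    arrange(.data$penalty, .data$fwd_start, .data$rev_end) |>
    head(max_candidates)
}

CS1_TAG <- "ACACTGACGACATGGTTCTACA"
CS2_TAG <- "TACGGTAGCAGAGACTTGGTCT"

#' Append common sequence tags to panel primers
#'
#' Prefixes each forward primer with the CS1 tag
#' (`ACACTGACGACATGGTTCTACA`) and each reverse primer with the CS2 tag
#' (`TACGGTAGCAGAGACTTGGTCT`), enabling barcode/adaptor addition in a
#' second PCR round. Idempotent: already-tagged primers are left unchanged.
#'
#' @param panel Tibble with `fwd_seq` and `rev_seq` columns.
#' @return The panel with `fwd_tagged` and `rev_tagged` columns.
#' @export
append_common_tags <- function(panel) {
  fwd0 <- if ("fwd_tagged" %in% names(panel)) panel$fwd_tagged else panel$fwd_seq
  rev0 <- if ("rev_tagged" %in% names(panel)) panel$rev_tagged else panel$rev_seq
  panel$fwd_tagged <- ifelse(startsWith(fwd0, CS1_TAG), fwd0,
                             paste0(CS1_TAG, fwd0))
  panel$rev_tagged <- ifelse(startsWith(rev0, CS2_TAG), rev0,
                             paste0(CS2_TAG, rev0))
  panel
}

#' Count primer binding sites and predicted PCR products
#'
#' A binding site is an exact occurrence of the primer's 3'-terminal
#' `seed_len` bases on either genome strand. Predicted products pair a
#' plus-oriented site of one primer with a minus-oriented site of the other
#' (3' ends facing) on the same scaffold, separated by at most
#' `max_product` bp.
#'
#' @param primer Forward primer sequence (>= `seed_len` nt, untagged).
#' @param genome Sequence tibble (`id`, `seq`).
#' @param partner Optional reverse primer; defaults to `primer` itself so a
#'   single primer's self-products are reported.
#' @param seed_len 3'-terminal match length, nt.
#' @param max_product Maximum predicted product size, bp.
#' @return List with `n_sites` (binding sites of `primer`), `sites`
#'   (tibble), and `products` (tibble of predicted products).
#' @export
count_binding_sites <- function(primer, genome, partner = NULL,
                                seed_len = 15, max_product = 1000) {
  if (nchar(primer) < seed_len) abort("primer shorter than the 3' seed")
  partner <- partner %||% primer
  sites_p <- binding_sites(primer, genome, seed_len)
  sites_q <- if (identical(partner, primer)) sites_p else
    binding_sites(partner, genome, seed_len)
  products <- predict_products(sites_p, sites_q, max_product)
  list(n_sites = nrow(sites_p), sites = sites_p, products = products)
}

binding_sites <- function(primer, genome, seed_len = 15) {
  seed <- toupper(substr(primer, nchar(primer) - seed_len + 1L, nchar(primer)))
  seed_rc <- revcomp(seed)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    subj <- Biostrings::DNAString(toupper(genome$seq[i]))
    plus <- Biostrings::matchPattern(seed, subj)
    minus <- Biostrings::matchPattern(seed_rc, subj)
    bind_rows(
      tibble(scaffold = genome$id[i],
             start = BiocGenerics::start(plus), end = BiocGenerics::end(plus),
             strand = "+"),
      tibble(scaffold = genome$id[i],
             start = BiocGenerics::start(minus), end = BiocGenerics::end(minus),
             strand = "-")
    )
  })
  out <- list_rbind(out)
  if (nrow(out) == 0) return(out)
  # extension runs rightwards from a plus-strand 3' end, leftwards from minus
  out$three_prime <- ifelse(out$strand == "+", out$end, out$start)
  arrange(out, .data$scaffold, .data$start)
}

predict_products <- function(sites_a, sites_b, max_product = 1000) {
  empty <- tibble(scaffold = character(), start = integer(), end = integer(),
                  size = integer())
  pairs <- function(plus, minus) {
    if (nrow(plus) == 0 || nrow(minus) == 0) return(empty)
    tidyr::crossing(plus |> select(scaffold_p = "scaffold", p_start = "start"),
                    minus |> select(scaffold_m = "scaffold", m_end = "end")) |>
      filter(.data$scaffold_p == .data$scaffold_m,
             .data$m_end > .data$p_start,
             .data$m_end - .data$p_start + 1L <= max_product) |>
      transmute(scaffold = .data$scaffold_p, start = .data$p_start,
                end = .data$m_end, size = .data$end - .data$start + 1L)
  }
  bind_rows(
    pairs(filter(sites_a, .data$strand == "+"),
          filter(sites_b, .data$strand == "-")),
    pairs(filter(sites_b, .data$strand == "+"),
          filter(sites_a, .data$strand == "-"))
  ) |>
    distinct() |>
    arrange(.data$scaffold, .data$start)
}

# Longest stretch of the 3'-terminal 8-mer of p that is reverse-complementary
# to any substring of q (and vice versa).
three_prime_complementarity <- function(p, q) {
  score_one <- function(a, b) {
    tail8 <- substr(a, max(1L, nchar(a) - 7L), nchar(a))
    rc <- revcomp(tail8)
    for (len in seq.int(nchar(rc), 1L)) {
      subs <- unique(substring(rc, 1:(nchar(rc) - len + 1L),
                               len:nchar(rc)))
      if (any(vapply(subs, grepl, TRUE, x = b, fixed = TRUE))) return(len)
    }
    0L
  }
  max(score_one(p, q), score_one(q, p))
}

#' Partition a panel into multiplex primer pools
#'
#' Assigns primer pairs to `ceiling(n / pool_size)` pools of nearly equal
#' size (differing by at most one). Pairs are taken in panel order and each
#' is placed, among the currently smallest pools, into the one minimizing
#' its worst 3'-end complementarity (reverse-complement match length of
#' 3'-terminal 8-mers) against the primers already in the pool.
#'
#' @param panel Panel tibble with `fwd_seq` and `rev_seq`.
#' @param pool_size Maximum pairs per pool.
#' @return The panel with an integer `pool` column.
#' @export
pool_primers <- function(panel, pool_size = 48) {
  n <- nrow(panel)
  if (n == 0) abort("empty panel")
  n_pools <- ceiling(n / pool_size)
  pool_of <- integer(n)
  # per pool: concatenated member primers and concatenated member 3'-8mer
  # reverse complements ("|" separators block cross-member matches)
  pool_seqs <- rep("", n_pools)
  pool_rc8 <- rep("", n_pools)
  tail8 <- function(s) substr(s, pmax(1L, nchar(s) - 7L), nchar(s))
  all_subs <- function(strings, len) {
    unique(unlist(lapply(strings, function(s) {
      if (nchar(s) < len) return(character())
      substring(s, 1:(nchar(s) - len + 1L), len:nchar(s))
    })))
  }
  for (i in seq_len(n)) {
    prim <- c(panel$fwd_seq[i], panel$rev_seq[i])
    rc8 <- revcomp(tail8(prim))
    sizes <- stringr::str_count(pool_seqs, stringr::fixed("|")) / 2
    eligible <- which(sizes == min(sizes))
    if (length(eligible) == 1 || all(!nzchar(pool_seqs[eligible]))) {
      best <- eligible[1]
    } else {
      score <- vapply(eligible, function(p) {
        if (!nzchar(pool_seqs[p])) return(0L)
        for (len in 8:1) {
          s1 <- all_subs(rc8, len)       # candidate 3' rc vs pool primers
          s2 <- all_subs(prim, len)      # pool 3' rc vs candidate primers
          if (any(stringr::str_detect(pool_seqs[p], stringr::fixed(s1))) ||
              any(stringr::str_detect(pool_rc8[p], stringr::fixed(s2)))) {
            return(len)
          }
        }
        0L
      }, 0L)
      best <- eligible[which.min(score)]
    }
    pool_of[i] <- best
    pool_seqs[best] <- paste0(pool_seqs[best], prim[1], "|", prim[2], "|")
    pool_rc8[best] <- paste0(pool_rc8[best], rc8[1], "|", rc8[2], "|")
  }
  panel$pool <- pool_of
  panel
}
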