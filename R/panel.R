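#' Design marker candidates for lifted polymorphic sites
#'
#' For each kept lifted site, extracts and masks the design window, designs
#' the best feasible primer pair, and (optionally) keeps only pairs whose
#' forward and reverse primers each bind the genome exactly once. The
#' result is the pool of designable markers from which [select_panel()]
#' draws.
#'
#' @param sites Lifted, categorized site tibble ([lift_sites()] +
#'   [categorize_sites()]); rows with non-`NA` `drop_reason` are skipped.
#' @param genome Sequence tibble (`id`, `seq`).
#' @param blacklist A `kmer_blacklist` ([build_kmer_blacklist()]).
#' @param cfg A [pipeline_config()].
#' @param check_specificity When `TRUE`, drop designs whose primers do not
#'   both have exactly one binding site, or that predict more than one
#'   product.
#' @return Tibble of marker designs, one per designable site: ids, primer
#'   sequences/intervals, amplicon interval, product size, hotspot, map
#'   columns, and a `design_status` for sites that failed.
#' @export
design_markers <- function(sites, genome, blacklist, cfg = NULL,
                           check_specificity = TRUE) {
  cfg <- as_config(cfg)
  usable <- sites |> filter(is.na(.data$drop_reason))
  if (nrow(usable) == 0) return(tibble())
  rows <- purrr::map(seq_len(nrow(usable)), function(i) {
    s <- usable[i, ]
    base <- s |>
      transmute(marker_id = paste0(.data$unigene_id, "_", .data$position),
                unigene_id = .data$unigene_id,
                unigene_position = .data$position,
                scaffold = .data$scaffold,
                genome_position = .data$genome_position,
                ref_allele = .data$ref_allele, alt_allele = .data$alt_allele,
                fixed_line = .data$fixed_line,
                chromosome = .data$chromosome,
                cm_position = .data$cm_position,
                category = .data$category)
    win <- tryCatch(
      extract_window(genome, s$scaffold, s$genome_position, cfg$flank),
      error = function(e) e
    )
    if (inherits(win, "error")) {
      return(mutate(base, design_status = "near-scaffold-end"))
    }
    win <- mask_window(win, blacklist)
    cand <- design_primer_pair(win, cfg, max_candidates = 1)
    if (nrow(cand) == 0) {
      return(mutate(base, design_status = attr(cand, "reason")))
    }
    d <- cand[1, ]
    if (check_specificity) {
      bs_f <- count_binding_sites(d$fwd_seq, genome, partner = d$rev_seq)
      bs_r <- count_binding_sites(d$rev_seq, genome, partner = d$fwd_seq)
      if (bs_f$n_sites != 1 || bs_r$n_sites != 1 ||
          nrow(bs_f$products) > 1) {
        return(mutate(base, design_status = "non-specific"))
      }
    }
    bind_cols(base, d |>
                select("fwd_seq", "rev_seq", "fwd_tm" = "fwd_tm",
                       "rev_tm" = "rev_tm", "product_size",
                       "amplicon_start", "amplicon_end",
                       "hotspot_position", "hotspot_offset")) |>
      mutate(design_status = "ok")
  })
  list_rbind(rows)
}

#' Select a genome-covering marker panel
#'
#' Chooses markers so the panel spans the genetic map. For each chromosome,
#' the cM range of anchored candidates is divided into as many equal bins
#' as the chromosome's anchored quota and the candidate nearest each bin
#' centre is selected (empty bins are reported). Chromosome-only quotas are
#' then filled preferring unseen unigenes and unseen scaffolds, in
#' deterministic (unigene, position) order. No two selected markers may lie
#' within `min_separation` bp on one scaffold.
#'
#' @param designs Designable markers ([design_markers()], rows with
#'   `design_status == "ok"`).
#' @param quotas Tibble with `chromosome`, `anchored` and `chromosome_only`
#'   integer quota columns; or a single total count split evenly over
#'   chromosomes and categories.
#' @param min_separation Minimum bp between panel members on one scaffold.
#' @return The selected panel tibble, with a `selection` column
#'   (`anchored-bin` / `chromosome-only`).
#' @export
select_panel <- function(designs, quotas, min_separation = 1000) {
  designs <- designs |>
    filter(.data$design_status == "ok") |>
    arrange(.data$unigene_id, .data$unigene_position)
  if (is.numeric(quotas) && length(quotas) == 1) {
    chroms <- sort(unique(designs$chromosome[!is.na(designs$chromosome)]))
    per <- ceiling(quotas / (2 * max(length(chroms), 1)))
    quotas <- tibble(chromosome = chroms, anchored = per,
                     chromosome_only = per)
  }
  selected <- designs[0, ]
  too_close <- function(cand) {
    same <- selected[selected$scaffold == cand$scaffold, ]
    nrow(same) > 0 &&
      any(abs(same$genome_position - cand$genome_position) < min_separation)
  }
  for (ci in seq_len(nrow(quotas))) {
    chrom <- quotas$chromosome[ci]
    q_anch <- quotas$anchored[ci]
    q_only <- quotas$chromosome_only[ci]
    anch <- designs |>
      filter(.data$category == "anchored", .data$chromosome == chrom)
    if (nrow(anch) > 0 && q_anch > 0) {
      if (nrow(anch) <= q_anch) {
        if (nrow(anch) < q_anch) {
          warn(paste0("chromosome ", chrom, ": anchored quota ", q_anch,
                      " exceeds ", nrow(anch), " candidates; selecting all"))
        }
        for (i in seq_len(nrow(anch))) {
          cand <- anch[i, ]
          if (!too_close(cand)) {
            cand$selection <- "anchored-bin"
            selected <- bind_rows(selected, cand)
          }
        }
      } else {
        lo <- min(anch$cm_position); hi <- max(anch$cm_position)
        width <- (hi - lo) / q_anch
        centres <- lo + (seq_len(q_anch) - 0.5) * width
        used <- rep(FALSE, nrow(anch))
        for (centre in centres) {
          ord <- order(abs(anch$cm_position - centre), anch$unigene_id,
                       anch$unigene_position)
          picked <- FALSE
          for (j in ord) {
            if (used[j]) next
            cand <- anch[j, ]
            if (too_close(cand)) next
            cand$selection <- "anchored-bin"
            selected <- bind_rows(selected, cand)
            used[j] <- TRUE
            picked <- TRUE
            break
          }
          if (!picked) {
            inform(paste0("chromosome ", chrom, ": unfilled anchored bin at ",
                          round(centre, 2), " cM"))
          }
        }
      }
    }
    only <- designs |>
      filter(.data$category == "chromosome_only", .data$chromosome == chrom)
    if (nrow(only) > 0 && q_only > 0) {
      if (nrow(only) < q_only) {
        warn(paste0("chromosome ", chrom, ": chromosome-only quota ", q_only,
                    " exceeds ", nrow(only), " candidates; selecting all"))
      }
      # prefer unigenes then scaffolds not already represented
      n_taken <- 0L
      for (pass in 1:3) {
        for (i in seq_len(nrow(only))) {
          if (n_taken >= q_only) break
          cand <- only[i, ]
          if (cand$marker_id %in% selected$marker_id) next
          novel_unigene <- !cand$unigene_id %in% selected$unigene_id
          novel_scaffold <- !cand$scaffold %in% selected$scaffold
          ok <- switch(pass, novel_unigene && novel_scaffold,
                       novel_unigene, TRUE)
          if (!ok || too_close(cand)) next
          cand$selection <- "chromosome-only"
          selected <- bind_rows(selected, cand)
          n_taken <- n_taken + 1L
        }
        if (n_taken >= q_only) break
      }
    }
  }
  arrange(selected, .data$chromosome, .data$cm_position, .data$unigene_id,
          .data$unigene_position)
}
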