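#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults mirror the study
#' conditions the package emulates: two parental lines with incomplete
#' within-line fixation (rate `f`), five and six genotyped individuals per
#' line, three replicate parent plants in the amplicon run, an F2 of 63
#' individuals over eight 100-cM chromosomes, log-normally heterogeneous
#' per-marker amplicon depths with beta-binomial allele overdispersion, and
#' occasional one-parent allele dropout.
#'
#' @param n_scaffolds,scaffold_target_length Genome shape; scaffolds grow to
#'   roughly the target length, bp.
#' @param repeat_families,repeat_length,repeat_copies Planted repeat
#'   families: count, unit length (bp), copies per family genome-wide.
#' @param n_genes Genes (= unigenes); distributed over scaffolds.
#' @param exons_per_gene,exon_length,intron_length Gene structure, bp.
#' @param n_chromosomes,chrom_cm Genetic map shape.
#' @param anchored_fraction,chromosome_only_fraction Fractions of unigenes
#'   whose anchor row carries a cM position / a chromosome only.
#' @param fixation_rate Within-line fixation rate `f` in `[0, 1]`: the
#'   probability that a parent individual is homozygous for its line's
#'   founder allele at a polymorphic locus.
#' @param n_parent1,n_parent2 Individuals genotyped by RNA-seq per line.
#' @param n_parent_replicates Replicate parent plants in the amplicon run.
#' @param n_f2 F2 individuals.
#' @param rnaseq_depth Mean RNA-seq depth per site, reads.
#' @param noise_het_sites Extra within-line heterozygous (non-polymorphic)
#'   sites per line, emulating residual line heterogeneity.
#' @param depth_meanlog,depth_sdlog Log-normal per-marker amplicon mean
#'   depth.
#' @param overdispersion Beta-binomial rho for heterozygote allele counts.
#' @param dropout_prob Per marker and per parental line, probability that
#'   the line's founder allele fails to amplify at that marker.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 4,
                       scaffold_target_length = 50000,
                       repeat_families = 2,
                       repeat_length = 200,
                       repeat_copies = 30,
                       n_genes = 64,
                       exons_per_gene = 3,
                       exon_length = 150,
                       intron_length = 120,
                       n_chromosomes = 8,
                       chrom_cm = 100,
                       anchored_fraction = 0.6,
                       chromosome_only_fraction = 0.25,
                       fixation_rate = 0.8,
                       n_parent1 = 5,
                       n_parent2 = 6,
                       n_parent_replicates = 3,
                       n_f2 = 63,
                       rnaseq_depth = 50,
                       noise_het_sites = 40,
                       depth_meanlog = log(100),
                       depth_sdlog = 1,
                       overdispersion = 0.05,
                       dropout_prob = 0.04) {
  cfg <- as.list(environment())
  stopifnot(cfg$fixation_rate >= 0, cfg$fixation_rate <= 1,
            cfg$n_genes >= 1, cfg$n_scaffolds >= 1,
            cfg$exons_per_gene >= 1)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1)
}

#' Simulate the reference pair, alignments, anchors and truth
#'
#' Builds a scaffolded genome with planted repeat families and intron-
#' bearing genes, the spliced unigene set, one trace-bearing unigene-vs-
#' genome alignment per gene (so transcript-to-genome projection must cross
#' intron gaps), a genetic-map anchor table hiding map knowledge for a
#' configurable fraction of unigenes, and a truth set recording gene
#' structures and the designed polymorphic locus of each gene.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return List with `genome`, `unigenes` (sequence tibbles), `alignments`,
#'   `anchors`, and `truth` (list with `genes` and `loci` tibbles).
#' @export
simulate_reference <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  gene_len <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1) * cfg$intron_length
  # repeat family consensus sequences
  fam_seqs <- vapply(seq_len(cfg$repeat_families), function(i)
    random_dna(cfg$repeat_length), "")
  genes_per_scaffold <- rep(ceiling(cfg$n_genes / cfg$n_scaffolds),
                            cfg$n_scaffolds)
  genes_per_scaffold[cfg$n_scaffolds] <-
    cfg$n_genes - sum(genes_per_scaffold[-cfg$n_scaffolds])
  copies_per_scaffold <- ceiling(cfg$repeat_copies / cfg$n_scaffolds)
  gene_rows <- list()
  repeat_rows <- list()
  scaffolds <- character(cfg$n_scaffolds)
  gene_counter <- 0L
  for (s in seq_len(cfg$n_scaffolds)) {
    segs <- list(random_dna(400))
    pos <- 401L
    rep_queue <- rep(seq_len(cfg$repeat_families),
                     each = copies_per_scaffold)
    for (gi in seq_len(genes_per_scaffold[s])) {
      gene_counter <- gene_counter + 1L
      gseq <- random_dna(gene_len)
      gene_rows[[gene_counter]] <- tibble(
        unigene_id = sprintf("u%03d", gene_counter),
        scaffold = sprintf("scaf%02d", s),
        gene_start = pos, gene_end = pos + gene_len - 1L
      )
      segs <- c(segs, gseq)
      pos <- pos + gene_len
      spacer <- random_dna(sample(250:400, 1))
      segs <- c(segs, spacer)
      pos <- pos + nchar(spacer)
      # interleave repeat copies between genes
      n_rep_here <- min(length(rep_queue),
                        sample(0:2, 1))
      if (n_rep_here > 0) {
        for (r in seq_len(n_rep_here)) {
          fam <- rep_queue[1]
          rep_queue <- rep_queue[-1]
          repeat_rows[[length(repeat_rows) + 1L]] <- tibble(
            scaffold = sprintf("scaf%02d", s), family = fam,
            start = pos, end = pos + cfg$repeat_length - 1L)
          segs <- c(segs, fam_seqs[fam])
          pos <- pos + cfg$repeat_length
          sp <- random_dna(sample(150:250, 1))
          segs <- c(segs, sp)
          pos <- pos + nchar(sp)
        }
      }
    }
    # park leftover repeat copies at the scaffold tail
    for (fam in rep_queue) {
      repeat_rows[[length(repeat_rows) + 1L]] <- tibble(
        scaffold = sprintf("scaf%02d", s), family = fam,
        start = pos, end = pos + cfg$repeat_length - 1L)
      segs <- c(segs, fam_seqs[fam])
      pos <- pos + cfg$repeat_length
      sp <- random_dna(60)
      segs <- c(segs, sp)
      pos <- pos + nchar(sp)
    }
    segs <- c(segs, random_dna(max(0, cfg$scaffold_target_length - pos)))
    scaffolds[s] <- paste(unlist(segs), collapse = "")
  }
  genome <- tibble(id = sprintf("scaf%02d", seq_len(cfg$n_scaffolds)),
                   seq = scaffolds)
  genes <- list_rbind(gene_rows)
  # gene structure: exon offsets within the gene (plus strand throughout)
  exon_starts <- (seq_len(cfg$exons_per_gene) - 1L) *
    (cfg$exon_length + cfg$intron_length)
  # map to chromosomes / cM, uniformly spaced per chromosome
  genes$chromosome_true <- as.character(
    rep_len(seq_len(cfg$n_chromosomes), nrow(genes)))
  genes <- genes |>
    group_by(.data$chromosome_true) |>
    mutate(cm_true = (row_number() - 0.5) / n() * cfg$chrom_cm) |>
    ungroup()
  # unigene sequences (spliced exons) + one polymorphic locus per gene, in a
  # middle position far from both gene ends
  unigene_len <- cfg$exons_per_gene * cfg$exon_length
  mid_exon <- ceiling(cfg$exons_per_gene / 2)
  loci <- genes |>
    mutate(
      unigene_pos = (mid_exon - 1L) * cfg$exon_length +
        sample(30:(cfg$exon_length - 30), n(), replace = TRUE),
      exon_idx = mid_exon
    )
  unigene_seq <- character(nrow(genes))
  trace <- character(nrow(genes))
  genome_pos <- integer(nrow(genes))
  ref_allele <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    scaf_seq <- genome$seq[genome$id == g$scaffold]
    exseq <- vapply(exon_starts, function(off) {
      substr(scaf_seq, g$gene_start + off,
             g$gene_start + off + cfg$exon_length - 1L)
    }, "")
    unigene_seq[i] <- paste(exseq, collapse = "")
    trace[i] <- paste(rep(c(strrep("M", cfg$exon_length),
                            strrep("D", cfg$intron_length)),
                          length.out = 2 * cfg$exons_per_gene - 1),
                      collapse = "")
    upos <- loci$unigene_pos[i]
    exon_i <- ceiling(upos / cfg$exon_length)
    within <- upos - (exon_i - 1L) * cfg$exon_length
    genome_pos[i] <- g$gene_start + exon_starts[exon_i] + within - 1L
    ref_allele[i] <- substr(unigene_seq[i], upos, upos)
  }
  loci$genome_pos <- genome_pos
  loci$ref_allele <- ref_allele
  loci$alt_allele <- vapply(ref_allele, mutate_base, "")
  loci$fixed_line <- sample(c("P1", "P2"), nrow(loci), replace = TRUE)
  unigenes <- tibble(id = genes$unigene_id, seq = unigene_seq)
  alignments <- tibble(
    query_id = genes$unigene_id, subject_id = genes$scaffold,
    pct_identity = 100, aln_len = gene_len, mismatches = 0L, gap_opens = 0L,
    qstart = 1L, qend = unigene_len,
    sstart = genes$gene_start, send = genes$gene_end,
    evalue = 0, bitscore = 2 * unigene_len, trace = trace, strand = "+"
  )
  # decoy secondary hits exercise best-hit selection
  n_decoy <- min(5L, nrow(genes))
  decoys <- tibble(
    query_id = genes$unigene_id[seq_len(n_decoy)],
    subject_id = genome$id[(seq_len(n_decoy) %% cfg$n_scaffolds) + 1L],
    pct_identity = 90, aln_len = 60L, mismatches = 6L, gap_opens = 0L,
    qstart = 1L, qend = 60L, sstart = 101L, send = 160L,
    evalue = 1e-5, bitscore = 80, trace = NA_character_, strand = "+"
  )
  alignments <- bind_rows(alignments, decoys)
  # anchor table: hide map knowledge for a configurable share of unigenes
  u <- runif(nrow(genes))
  anchors <- tibble(
    unigene_id = genes$unigene_id,
    chromosome = ifelse(u < cfg$anchored_fraction + cfg$chromosome_only_fraction,
                        genes$chromosome_true, NA_character_),
    cm_position = ifelse(u < cfg$anchored_fraction, genes$cm_true, NA_real_)
  )
  truth_genes <- genes |>
    mutate(unigene_length = unigene_len,
           exon_starts = list(exon_starts),
           exon_length = cfg$exon_length)
  truth_loci <- loci |>
    select("unigene_id", "scaffold", "unigene_pos", "genome_pos",
           "ref_allele", "alt_allele", "fixed_line",
           chromosome = "chromosome_true", cm = "cm_true")
  list(genome = genome, unigenes = unigenes, alignments = alignments,
       anchors = anchors,
       truth = list(genes = truth_genes, loci = truth_loci,
                    repeats = list_rbind(repeat_rows)))
}

# True genotype (alt-allele dose 0/1/2) of one parent individual at the
# line's loci: homozygous for the founder allele with probability f, else
# heterozygous.
draw_parent_genotypes <- function(loci, line, f) {
  founder_dose <- ifelse(loci$fixed_line == line, 2L, 0L)
  fixed <- runif(nrow(loci)) < f
  ifelse(fixed, founder_dose, 1L)
}

# Emit an RNA-seq-like variant table for one individual from alt doses.
emit_variant_rows <- function(sample_id, line, loci, dose, depth_mean) {
  depth <- rpois(nrow(loci), depth_mean)
  p_alt <- c(0.004, 0.5, 0.996)[dose + 1L]
  alt <- rbinom(nrow(loci), depth, p_alt)
  keep <- alt >= 1 & depth >= 1
  tibble(
    sample_id = sample_id, line_id = line,
    unigene_id = loci$unigene_id, position = as.integer(loci$unigene_pos),
    ref_allele = loci$ref_allele, alt_allele = loci$alt_allele,
    total_depth = as.integer(depth), alt_count = as.integer(alt)
  )[keep, ]
}

#' Simulate parental lines, the F1 and a selfed F2
#'
#' Draws founder alleles per locus per line, parent individuals with
#' incomplete within-line fixation, RNA-seq-like variant tables for the
#' genotyped parent individuals (plus within-line heterozygous noise
#' sites), replicate parent plants for the amplicon run, one F1 (one gamete
#' per cross parent) and a selfed F2 with crossovers as a Poisson process
#' along each chromosome (Haldane model, no interference).
#'
#' @param ref Output of [simulate_reference()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `variants` (parental variant table), `parent_truth`
#'   (replicate-plant alt doses, loci x plants per line), `f1` (alt dose
#'   per locus), `f2` (matrix loci x individuals of alt doses), and
#'   `sample_ids`.
#' @export
simulate_lines_and_cross <- function(ref, cfg = sim_config(), seed = 1) {
  set.seed(seed + 1L)
  loci <- ref$truth$loci
  nl <- nrow(loci)
  f <- cfg$fixation_rate
  variants <- list()
  for (i in seq_len(cfg$n_parent1)) {
    dose <- draw_parent_genotypes(loci, "P1", f)
    variants[[length(variants) + 1L]] <-
      emit_variant_rows(sprintf("P1_rna_%d", i), "P1", loci, dose,
                        cfg$rnaseq_depth)
  }
  for (i in seq_len(cfg$n_parent2)) {
    dose <- draw_parent_genotypes(loci, "P2", f)
    variants[[length(variants) + 1L]] <-
      emit_variant_rows(sprintf("P2_rna_%d", i), "P2", loci, dose,
                        cfg$rnaseq_depth)
  }
  variants <- list_rbind(variants)
  # residual heterozygosity: extra het sites private to each line
  if (cfg$noise_het_sites > 0) {
    noise <- list()
    for (line in c("P1", "P2")) {
      n_ind <- if (line == "P1") cfg$n_parent1 else cfg$n_parent2
      pick <- loci[sample.int(nl, min(cfg$noise_het_sites, nl),
                              replace = FALSE), ]
      # shift position away from the designed locus; new alt allele
      pick$unigene_pos <- pmax(1L, pick$unigene_pos - 11L)
      pick$ref_allele <- "A"; pick$alt_allele <- "T"
      for (i in seq_len(n_ind)) {
        dose <- ifelse(runif(nrow(pick)) < 0.5, 1L, 0L)
        noise[[length(noise) + 1L]] <-
          emit_variant_rows(sprintf("%s_rna_%d", line, i), line, pick, dose,
                            cfg$rnaseq_depth)
      }
    }
    variants <- bind_rows(variants, list_rbind(noise)) |>
      arrange(.data$sample_id, .data$unigene_id, .data$position)
  }
  # replicate parent plants for the amplicon run
  parent_truth <- list(
    P1 = vapply(seq_len(cfg$n_parent_replicates), function(i)
      draw_parent_genotypes(loci, "P1", f), integer(nl)),
    P2 = vapply(seq_len(cfg$n_parent_replicates), function(i)
      draw_parent_genotypes(loci, "P2", f), integer(nl))
  )
  # cross parents and the F1: one gamete from each
  cross_p1 <- draw_parent_genotypes(loci, "P1", f)
  cross_p2 <- draw_parent_genotypes(loci, "P2", f)
  gamete_of <- function(dose) {
    # one allele per locus, no linkage needed within a fully homozygous or
    # independent-residual parent model
    ifelse(dose == 2L, 1L, ifelse(dose == 0L, 0L,
                                  as.integer(runif(length(dose)) < 0.5)))
  }
  f1_hap1 <- gamete_of(cross_p1)
  f1_hap2 <- gamete_of(cross_p2)
  f1 <- f1_hap1 + f1_hap2
  # selfed F2: recombine the two F1 haplotypes along each chromosome
  ord <- order(loci$chromosome, loci$cm)
  meiosis <- function() {
    gam <- integer(nl)
    for (chrom in unique(loci$chromosome)) {
      idx <- ord[loci$chromosome[ord] == chrom]
      cms <- loci$cm[idx]
      cur <- sample(1:2, 1)
      for (k in seq_along(idx)) {
        if (k > 1) {
          r <- haldane_rf(cms[k] - cms[k - 1])
          if (runif(1) < r) cur <- 3L - cur
        }
        gam[idx[k]] <- if (cur == 1L) f1_hap1[idx[k]] else f1_hap2[idx[k]]
      }
    }
    gam
  }
  f2 <- vapply(seq_len(cfg$n_f2), function(i) meiosis() + meiosis(),
               integer(nl))
  colnames(f2) <- sprintf("F2_%03d", seq_len(cfg$n_f2))
  rownames(f2) <- loci$unigene_id
  list(variants = variants, parent_truth = parent_truth,
       f1 = f1, f2 = f2,
       sample_ids = list(
         p1 = sprintf("P1_amp_%d", seq_len(cfg$n_parent_replicates)),
         p2 = sprintf("P2_amp_%d", seq_len(cfg$n_parent_replicates)),
         f1 = "F1_A", f2 = colnames(f2)))
}

#' Simulate amplicon read depths for a designed panel
#'
#' Per-marker mean depths are log-normal (emulating strong between-marker
#' amplification differences); per-sample site depths are Poisson around
#' the marker mean; heterozygote alternate counts are beta-binomial around
#' 0.5; and a marker flagged with dropout for one parental line produces
#' zero reads of that line's founder allele in every sample.
#'
#' @param panel Designed panel ([design_markers()] / [select_panel()]) with
#'   `marker_id`, `unigene_id`, `scaffold`, `genome_position`,
#'   `ref_allele`, `alt_allele`, `fixed_line`.
#' @param cross Output of [simulate_lines_and_cross()].
#' @param ref Output of [simulate_reference()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param include List of sample groups to emit (default all).
#' @param marker_effects Optional `marker_effects` tibble from a previous
#'   run (columns `marker_id`, `mean_depth`, `drop_p1`, `drop_p2`). Marker
#'   amplification efficiency and allele dropout are properties of the
#'   marker, not of a library: pass the first run's effects to simulate a
#'   technical duplicate of the same panel.
#' @return List with `depths` (site-depth tibble for every sample),
#'   `marker_effects` (per-marker mean depth and dropout flags), `dropout`
#'   (marker x line flags) and `truth_class` (true validation class per
#'   marker, from the noiseless replicate-plant genotypes).
#' @export
simulate_amplicon_depths <- function(panel, cross, ref, cfg = sim_config(),
                                     seed = 1,
                                     include = c("parents", "f1", "f2"),
                                     marker_effects = NULL) {
  set.seed(seed + 2L)
  loci <- ref$truth$loci
  idx <- match(panel$unigene_id, loci$unigene_id)
  stopifnot(!anyNA(idx))
  nm <- nrow(panel)
  if (is.null(marker_effects)) {
    marker_effects <- tibble(
      marker_id = panel$marker_id,
      mean_depth = rlnorm(nm, cfg$depth_meanlog, cfg$depth_sdlog),
      drop_p1 = runif(nm) < cfg$dropout_prob,
      drop_p2 = runif(nm) < cfg$dropout_prob
    )
  }
  stopifnot(identical(marker_effects$marker_id, panel$marker_id))
  mean_depth <- marker_effects$mean_depth
  dropout <- marker_effects[c("marker_id", "drop_p1", "drop_p2")]
  # allele carried by each line's founder at each marker (alt for the fixed
  # line, ref for the other)
  fixed_line <- loci$fixed_line[idx]
  rho <- cfg$overdispersion
  het_p <- function(n) {
    if (rho <= 0) return(rep(0.5, n))
    ab <- 0.5 * (1 / rho - 1)
    rbeta(n, ab, ab)
  }
  emit_sample <- function(sample_id, dose) {
    depth <- rpois(nm, mean_depth)
    p_alt <- ifelse(dose == 1L, het_p(nm),
                    ifelse(dose == 2L, 0.998, 0.002))
    alt <- rbinom(nm, depth, p_alt)
    ref_n <- depth - alt
    # dropout of a line's founder allele
    p1_allele_is_alt <- fixed_line == "P1"
    kill_alt <- (dropout$drop_p1 & p1_allele_is_alt) |
      (dropout$drop_p2 & !p1_allele_is_alt)
    kill_ref <- (dropout$drop_p1 & !p1_allele_is_alt) |
      (dropout$drop_p2 & p1_allele_is_alt)
    alt[kill_alt] <- 0L
    ref_n[kill_ref] <- 0L
    tibble(
      sample_id = sample_id, marker_id = panel$marker_id,
      scaffold = panel$scaffold, position = as.integer(panel$genome_position),
      ref_allele = panel$ref_allele, alt_allele = panel$alt_allele,
      is_hotspot = TRUE,
      ref_count = as.integer(ref_n), alt_count = as.integer(alt)
    )
  }
  out <- list()
  ids <- cross$sample_ids
  if ("parents" %in% include) {
    for (r in seq_len(cfg$n_parent_replicates)) {
      out[[length(out) + 1L]] <-
        emit_sample(ids$p1[r], cross$parent_truth$P1[idx, r])
      out[[length(out) + 1L]] <-
        emit_sample(ids$p2[r], cross$parent_truth$P2[idx, r])
    }
  }
  if ("f1" %in% include) {
    out[[length(out) + 1L]] <- emit_sample(ids$f1, cross$f1[idx])
  }
  if ("f2" %in% include) {
    for (j in seq_len(ncol(cross$f2))) {
      out[[length(out) + 1L]] <- emit_sample(colnames(cross$f2)[j],
                                             cross$f2[idx, j])
    }
  }
  depths <- list_rbind(out)
  truth_class <- true_marker_classes(panel, cross, idx)
  list(depths = depths, marker_effects = marker_effects, dropout = dropout,
       truth_class = truth_class)
}

# Noiseless validation class per marker from the replicate plants' true
# genotypes (dose -> call), ignoring depth and dropout.
true_marker_classes <- function(panel, cross, idx) {
  dose_call <- c("ref_hom", "het", "alt_hom")
  cons <- function(mat) {
    apply(mat, 1, function(d) {
      calls <- unique(dose_call[d + 1L])
      if (length(calls) == 1) calls else "unfixed"
    })
  }
  p1 <- cons(cross$parent_truth$P1[idx, , drop = FALSE])
  p2 <- cons(cross$parent_truth$P2[idx, , drop = FALSE])
  tibble(marker_id = panel$marker_id,
         true_p1 = p1, true_p2 = p2,
         true_class = marker_class(p1, p2, TRUE))
}
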