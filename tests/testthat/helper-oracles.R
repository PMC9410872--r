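# Independent oracles and fixture builders shared across tests.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# --- projection oracle: materialize every aligned (query, subject) base pair
# from the trace, then look the query position up in the table.
walk_alignment <- function(aln) {
  dir <- if (aln$sstart > aln$send) -1L else 1L
  ops <- if (!is.na(aln$trace) && nzchar(aln$trace)) {
    strsplit(aln$trace, "")[[1]]
  } else {
    rep("M", aln$qend - aln$qstart + 1L)
  }
  q <- aln$qstart; s <- aln$sstart
  pairs <- list()
  for (op in ops) {
    if (op %in% c("M", "X")) {
      pairs[[length(pairs) + 1L]] <- c(q, s)
      q <- q + 1L; s <- s + dir
    } else if (op == "I") {
      pairs[[length(pairs) + 1L]] <- c(q, NA)
      q <- q + 1L
    } else if (op == "D") {
      s <- s + dir
    }
  }
  do.call(rbind, pairs)
}

oracle_project <- function(aln, qpos) {
  tab <- walk_alignment(as.list(aln))
  row <- tab[tab[, 1] == qpos, , drop = FALSE]
  if (nrow(row) == 0) stop("outside span")
  row[1, 2]  # NA means subject gap
}

# --- brute-force k-mer counting oracle: occurrences of w on both strands =
# forward occurrences of w plus forward occurrences of its reverse
# complement (a palindromic w is counted on both strands automatically)
oracle_count_kmer <- function(genome, w) {
  k <- nchar(w)
  targets <- c(w, rc_chr(w))
  total <- 0L
  for (seq in toupper(genome$seq)) {
    n <- nchar(seq) - k + 1
    if (n < 1) next
    kms <- substring(seq, seq_len(n), seq_len(n) + k - 1)
    total <- total + sum(kms == targets[1]) + sum(kms == targets[2])
  }
  total
}

# --- brute-force window masking oracle
oracle_mask <- function(window_seq, blacklist) {
  k <- blacklist$k
  n <- nchar(window_seq)
  mask <- rep(FALSE, n)
  for (pos in seq_len(n)) {
    for (j in max(1, pos - k + 1):pos) {
      if (j + k - 1 > n) next
      km <- substr(window_seq, j, j + k - 1)
      can <- min(km, rc_chr(km))
      if (can %in% blacklist$kmers) {
        mask[pos] <- TRUE
        break
      }
    }
  }
  mask
}

# --- grid-search likelihood oracle for the two-point rf (log-probability
# matrix cached across calls)
grid_cache <- new.env()
grid_search_rf <- function(tab, step = 1e-4) {
  key <- as.character(step)
  if (is.null(grid_cache[[key]])) {
    rs <- seq(step, 0.5 - step, by = step)
    logpr <- vapply(rs, function(r) {
      log(as.vector(ampliconpanel:::f2_joint_probs(r)))
    }, numeric(9))
    grid_cache[[key]] <- list(rs = rs, logpr = logpr)
  }
  g <- grid_cache[[key]]
  ll <- as.vector(crossprod(g$logpr, as.vector(tab)))
  g$rs[which.max(ll)]
}

# simulate a joint F2 3x3 table at a given rf
sim_f2_table <- function(r, n) {
  pr <- ampliconpanel:::f2_joint_probs(r)
  cells <- sample(9, n, replace = TRUE, prob = as.vector(pr))
  matrix(tabulate(cells, 9), 3, 3)
}

# simulate an F2 genotype-code matrix for chromosomes of equally spaced
# markers (Haldane meioses, no interference); truth = chromosome labels
sim_f2_matrix <- function(n_chrom, markers_per_chrom, spacing_cm, n_f2) {
  r <- haldane_rf(spacing_cm)
  gamete <- function() {
    unlist(lapply(seq_len(n_chrom), function(ch) {
      h <- integer(markers_per_chrom)
      h[1] <- sample(0:1, 1)
      for (k in 2:markers_per_chrom) {
        h[k] <- if (runif(1) < r) 1L - h[k - 1] else h[k - 1]
      }
      h
    }))
  }
  m <- n_chrom * markers_per_chrom
  codes <- vapply(seq_len(n_f2), function(i) {
    dose <- gamete() + gamete()
    c("A", "H", "B")[dose + 1L]
  }, character(m))
  ids <- sprintf("m_%02d_%02d", rep(seq_len(n_chrom), each = markers_per_chrom),
                 rep(seq_len(markers_per_chrom), n_chrom))
  out <- tibble::as_tibble(codes, .name_repair = ~ sprintf("F2_%03d", seq_len(n_f2)))
  out <- dplyr::bind_cols(tibble::tibble(marker_id = ids), out)
  attr(out, "truth_chrom") <- rep(seq_len(n_chrom), each = markers_per_chrom)
  out
}

# small deterministic simulated study shared by several test files
tiny_study <- function(seed = 11, ...) {
  base <- list(n_genes = 24, n_scaffolds = 2,
               scaffold_target_length = 25000, n_chromosomes = 3,
               fixation_rate = 0.95, n_f2 = 40)
  cfg <- do.call(sim_config, utils::modifyList(base, list(...)))
  ref <- simulate_reference(cfg, seed)
  cross <- simulate_lines_and_cross(ref, cfg, seed)
  list(cfg = cfg, ref = ref, cross = cross)
}
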