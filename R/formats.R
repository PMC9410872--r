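#' Read and write FASTA sequence sets
#'
#' Thin tibble-returning wrappers around Biostrings FASTA I/O. Sequence ids
#' are the first whitespace-delimited token of each header and must be
#' unique within a file. Lowercase (masked) bases are preserved.
#'
#' @param path FASTA file path.
#' @return [read_fasta()] returns a tibble with columns `id` and `seq`, in
#'   file order. [write_fasta()] returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(tibble::tibble(id = "s1", seq = "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate id ", dup[1], " in FASTA file ", path))
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) < 1)) abort("FASTA records must have sequence length >= 1")
  tibble(id = ids, seq = unname(seqs))
}

#' @rdname read_fasta
#' @param sequences Tibble with columns `id`, `seq`.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("id", "seq") %in% names(sequences)))
  if (anyDuplicated(sequences$id)) abort("duplicate sequence ids")
  set <- Biostrings::BStringSet(setNames(sequences$seq, sequences$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read tabular (BLAST outfmt-6 style) alignments
#'
#' Parses 12-column tab-separated alignment records, with an optional 13th
#' column carrying a per-base alignment trace. Trace characters: `M` match
#' and `X` mismatch (consume one query and one subject base), `I` a query
#' base aligned to a gap in the subject, `D` a subject base aligned to a gap
#' in the query. Strand is inferred from subject coordinate order:
#' `sstart > send` means the minus strand.
#'
#' @param path Tab-separated file; columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `mismatches`, `gap_opens`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore` (+ optional `trace`).
#' @return Tibble of alignment records with a `strand` column (`+`/`-`) and
#'   a `trace` column (`NA` when absent).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(empty_alignment_tbl())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(paste0("alignment line ", which(nf < 12)[1],
                 " has ", nf[nf < 12][1], " columns; expected >= 12"))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, name) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      abort(paste0("non-numeric ", name, " on alignment line ", which(is.na(v))[1]))
    }
    v
  }
  trace <- ifelse(nf >= 13, vapply(fields, function(f) {
    if (length(f) >= 13) f[[13]] else NA_character_
  }, ""), NA_character_)
  out <- tibble(
    query_id = col(1), subject_id = col(2),
    pct_identity = num(3, "pct_identity"),
    aln_len = as.integer(num(4, "aln_len")),
    mismatches = as.integer(num(5, "mismatches")),
    gap_opens = as.integer(num(6, "gap_opens")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    trace = trace
  )
  bad <- out$qstart > out$qend
  if (any(bad)) {
    abort(paste0("qstart > qend on alignment line ", which(bad)[1]))
  }
  out$strand <- ifelse(out$sstart > out$send, "-", "+")
  validate_traces(out)
  out
}

empty_alignment_tbl <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_len = integer(), mismatches = integer(),
    gap_opens = integer(), qstart = integer(), qend = integer(),
    sstart = integer(), send = integer(), evalue = numeric(),
    bitscore = numeric(), trace = character(), strand = character()
  )
}

validate_traces <- function(aln) {
  has <- !is.na(aln$trace)
  if (!any(has)) return(invisible(aln))
  ops <- strsplit(aln$trace[has], "", fixed = TRUE)
  qlen <- vapply(ops, function(o) sum(o %in% c("M", "X", "I")), 0L)
  slen <- vapply(ops, function(o) sum(o %in% c("M", "X", "D")), 0L)
  bad_chr <- vapply(ops, function(o) any(!o %in% c("M", "X", "I", "D")), TRUE)
  if (any(bad_chr)) abort("trace contains characters outside {M,X,I,D}")
  exp_q <- aln$qend[has] - aln$qstart[has] + 1L
  exp_s <- abs(aln$send[has] - aln$sstart[has]) + 1L
  if (any(qlen != exp_q)) {
    abort("trace consumed query length disagrees with qstart..qend span")
  }
  if (any(slen != exp_s)) {
    abort("trace consumed subject length disagrees with sstart..send span")
  }
  invisible(aln)
}

#' @rdname read_alignments
#' @param alignments Tibble as returned by [read_alignments()].
#' @export
write_alignments <- function(alignments, path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  stopifnot(all(cols %in% names(alignments)))
  body <- alignments[cols]
  if ("trace" %in% names(alignments) && any(!is.na(alignments$trace))) {
    body$trace <- ifelse(is.na(alignments$trace), "", alignments$trace)
  }
  lines <- do.call(paste, c(unname(as.list(body)), sep = "\t"))
  lines <- sub("\t$", "", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-individual variant table
#'
#' The canonical tab-separated dialect has columns `sample_id`, `line_id`,
#' `unigene_id`, `position` (1-based on the unigene), `ref_allele`,
#' `alt_allele`, `total_depth`, `alt_count`. Alleles may be SNPs, MNPs or
#' indel strings.
#'
#' @param path TSV file path.
#' @return Tibble of variant observations.
#' @export
read_variant_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sample_id = "c", line_id = "c", unigene_id = "c",
                           position = "i", ref_allele = "c", alt_allele = "c",
                           total_depth = "i", alt_count = "i"
                         ))
  validate_variants(out)
  out
}

validate_variants <- function(v) {
  stopifnot(all(c("sample_id", "line_id", "unigene_id", "position",
                  "ref_allele", "alt_allele", "total_depth",
                  "alt_count") %in% names(v)))
  if (any(v$alt_count > v$total_depth)) abort("alt_count exceeds total_depth")
  if (any(v$total_depth < 0) || any(v$alt_count < 0)) {
    abort("negative read counts in variant table")
  }
  if (any(!nzchar(v$ref_allele)) || any(!nzchar(v$alt_allele))) {
    abort("empty allele string in variant table")
  }
  invisible(v)
}

#' @rdname read_variant_table
#' @param variants Tibble of variant observations.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}

#' Read a genetic-map anchor table
#'
#' Anchors place unigenes on the genetic map: `anchored` rows carry a
#' chromosome and a cM position, `chromosome_only` rows a chromosome only,
#' and unigenes absent from the table have no map information.
#'
#' @param path TSV with columns `unigene_id`, `chromosome`, `cm_position`
#'   (`NA` allowed).
#' @return Tibble with a derived `category` column.
#' @export
read_anchor_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           unigene_id = "c", chromosome = "c", cm_position = "d"
                         ))
  anchor_categories(out)
}

anchor_categories <- function(anchors) {
  anchors |>
    mutate(category = case_when(
      !is.na(.data$cm_position) & !is.na(.data$chromosome) ~ "anchored",
      !is.na(.data$chromosome) ~ "chromosome_only",
      .default = "no_information"
    ))
}

#' @rdname read_anchor_table
#' @param anchors Anchor tibble.
#' @export
write_anchor_table <- function(anchors, path) {
  readr::write_tsv(anchors[c("unigene_id", "chromosome", "cm_position")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read a per-sample per-site allele-depth table
#'
#' Depths observed at amplicon sites: columns `sample_id`, `marker_id`,
#' `scaffold`, `position`, `ref_allele`, `alt_allele`, `is_hotspot`,
#' `ref_count`, `alt_count`.
#'
#' @param path TSV file path.
#' @return Tibble of site depths.
#' @export
read_depth_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sample_id = "c", marker_id = "c", scaffold = "c",
                           position = "i", ref_allele = "c", alt_allele = "c",
                           is_hotspot = "l", ref_count = "i", alt_count = "i"
                         ))
  if (any(out$ref_count < 0) || any(out$alt_count < 0)) {
    abort("negative read counts in depth table")
  }
  out
}

#' @rdname read_depth_table
#' @param depths Tibble of site depths.
#' @export
write_depth_table <- function(depths, path) {
  readr::write_tsv(depths, path, progress = FALSE)
  invisible(path)
}

GENO_CODES <- c("A", "H", "B", "-")

#' Write / read an A-H-B genotype matrix
#'
#' Markers as rows, F2 individuals as columns, codes in `A` (homozygous for
#' parent 1's allele), `H` (heterozygous), `B` (homozygous for parent 2's
#' allele) and `-` (missing). Round-trips losslessly.
#'
#' @param matrix Tibble whose first column is `marker_id` and remaining
#'   columns are individual codes.
#' @param path TSV file path.
#' @return [read_genotype_matrix()] returns the matrix tibble;
#'   [write_genotype_matrix()] returns `path` invisibly.
#' @export
write_genotype_matrix <- function(matrix, path) {
  stopifnot(names(matrix)[1] == "marker_id")
  codes <- unlist(matrix[-1], use.names = FALSE)
  bad <- setdiff(unique(codes), GENO_CODES)
  if (length(bad) > 0) {
    abort(paste0("unknown genotype code(s): ", paste(bad, collapse = ", ")))
  }
  readr::write_tsv(matrix, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (names(out)[1] != "marker_id") abort("first column must be marker_id")
  codes <- unlist(out[-1], use.names = FALSE)
  bad <- setdiff(unique(codes), GENO_CODES)
  if (length(bad) > 0) {
    abort(paste0("unknown genotype code(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' Write amplicon intervals as BED
#'
#' Emits 0-based half-open amplicon intervals for a designed panel.
#'
#' @param panel Panel tibble with `scaffold`, `amplicon_start`,
#'   `amplicon_end` (1-based inclusive) and `marker_id`.
#' @param path Output BED path.
#' @export
write_amplicon_bed <- function(panel, path) {
  bed <- tibble(
    chrom = panel$scaffold,
    start = panel$amplicon_start - 1L,
    end = panel$amplicon_end,
    name = panel$marker_id
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
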