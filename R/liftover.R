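#' Best alignment per query
#'
#' Picks, for each query, the record with the highest bitscore; ties broken
#' by higher percent identity, then longer alignment length, then
#' lexicographically smallest subject id. A query whose winning score is
#' shared by hits on more than one subject is flagged `ambiguous_hit`.
#'
#' @param alignments Alignment tibble ([read_alignments()]).
#' @return One row per `query_id`, with an `ambiguous_hit` logical column.
#' @export
best_alignment <- function(alignments) {
  if (nrow(alignments) == 0) abort("best_alignment() on empty input")
  alignments |>
    group_by(.data$query_id) |>
    mutate(ambiguous_hit =
             n_distinct(.data$subject_id[.data$bitscore == max(.data$bitscore)]) > 1) |>
    arrange(desc(.data$bitscore), desc(.data$pct_identity),
            desc(.data$aln_len), .data$subject_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Project a query position through one alignment
#'
#' Maps a 1-based query coordinate to its aligned subject coordinate. With a
#' per-base trace the alignment is walked base by base; without one the
#' alignment must be gapless (`aln_len == qend - qstart + 1 ==
#' |send - sstart| + 1`) and the projection is the linear offset. Gapped
#' alignments without a trace are refused rather than interpolated, and a
#' query base aligned to a subject gap is unprojectable.
#'
#' @param aln One alignment record (single-row tibble or list).
#' @param qpos 1-based query position, within `[qstart, qend]`.
#' @return List with `scaffold`, `position`, `strand`.
#' @examples
#' aln <- tibble::tibble(query_id = "u1", subject_id = "s1",
#'   pct_identity = 100, aln_len = 100L, mismatches = 0L, gap_opens = 0L,
#'   qstart = 1L, qend = 100L, sstart = 501L, send = 600L,
#'   evalue = 0, bitscore = 185, trace = NA_character_, strand = "+")
#' project_position(aln, 10)  # subject base 510
#' @export
project_position <- function(aln, qpos) {
  aln <- as.list(aln)
  if (qpos < aln$qstart || qpos > aln$qend) {
    abort(paste0("query position ", qpos, " outside alignment span ",
                 aln$qstart, "-", aln$qend))
  }
  dir <- if (aln$sstart > aln$send) -1L else 1L
  strand <- if (dir < 0) "-" else "+"
  if (is.na(aln$trace) || !nzchar(aln$trace)) {
    qlen <- aln$qend - aln$qstart + 1L
    slen <- abs(aln$send - aln$sstart) + 1L
    if (aln$aln_len != qlen || qlen != slen) {
      abort("gapped alignment without a per-base trace cannot be projected")
    }
    spos <- aln$sstart + dir * (qpos - aln$qstart)
    return(list(scaffold = aln$subject_id, position = as.integer(spos),
                strand = strand))
  }
  ops <- strsplit(aln$trace, "", fixed = TRUE)[[1]]
  cur_q <- aln$qstart
  cur_s <- aln$sstart
  for (op in ops) {
    if (op == "M" || op == "X") {
      if (cur_q == qpos) {
        return(list(scaffold = aln$subject_id, position = as.integer(cur_s),
                    strand = strand))
      }
      cur_q <- cur_q + 1L
      cur_s <- cur_s + dir
    } else if (op == "I") {
      if (cur_q == qpos) {
        abort(paste0("query position ", qpos,
                     " is aligned to a subject gap: unprojectable"))
      }
      cur_q <- cur_q + 1L
    } else if (op == "D") {
      cur_s <- cur_s + dir
    } else {
      abort(paste0("unknown trace op '", op, "'"))
    }
  }
  abort("trace exhausted before reaching query position")  # defensive
}

#' Project polymorphic sites onto genome scaffolds
#'
#' Lifts each site's unigene position onto the genome through the best
#' alignment of its unigene. Sites are dropped (with a reason) when the
#' unigene has no alignment (`no-alignment`), the site is outside the best
#' HSP (`out-of-span`), the best HSP is gapped and traceless
#' (`gapped-no-trace`), the site falls in a subject gap (`unprojectable`),
#' or the projected position lies closer than `flank` bp to either end of
#' the aligned subject span (`near-junction`, avoiding primer design across
#' intron-exon junctions).
#'
#' @param sites Polymorphic-site tibble (needs `unigene_id`, `position`).
#' @param alignments Unigene-vs-genome alignment tibble.
#' @param flank Required clearance (bp) inside the aligned subject span.
#' @return `sites` plus `scaffold`, `genome_position`, `genome_strand`,
#'   `ambiguous_hit` and `drop_reason` (`NA` for kept sites).
#' @export
lift_sites <- function(sites, alignments, flank = 150) {
  best <- if (nrow(alignments) > 0) best_alignment(alignments) else
    empty_alignment_tbl() |> mutate(ambiguous_hit = logical())
  one <- function(unigene_id, position) {
    hit <- best[best$query_id == unigene_id, ]
    if (nrow(hit) == 0) {
      return(tibble(scaffold = NA_character_, genome_position = NA_integer_,
                    genome_strand = NA_character_, ambiguous_hit = FALSE,
                    drop_reason = "no-alignment"))
    }
    if (position < hit$qstart || position > hit$qend) {
      return(tibble(scaffold = hit$subject_id, genome_position = NA_integer_,
                    genome_strand = NA_character_,
                    ambiguous_hit = hit$ambiguous_hit,
                    drop_reason = "out-of-span"))
    }
    proj <- tryCatch(project_position(hit, position), error = function(e) e)
    if (inherits(proj, "error")) {
      reason <- if (grepl("subject gap", conditionMessage(proj)))
        "unprojectable" else "gapped-no-trace"
      return(tibble(scaffold = hit$subject_id, genome_position = NA_integer_,
                    genome_strand = NA_character_,
                    ambiguous_hit = hit$ambiguous_hit, drop_reason = reason))
    }
    s_lo <- min(hit$sstart, hit$send)
    s_hi <- max(hit$sstart, hit$send)
    reason <- if (proj$position - s_lo < flank || s_hi - proj$position < flank)
      "near-junction" else NA_character_
    tibble(scaffold = proj$scaffold, genome_position = proj$position,
           genome_strand = proj$strand, ambiguous_hit = hit$ambiguous_hit,
           drop_reason = reason)
  }
  proj <- purrr::map2(sites$unigene_id, sites$position, one) |> list_rbind()
  bind_cols(sites, proj)
}
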