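#' Pipeline configuration
#'
#' Bundles every tunable threshold of the workflow into one validated list.
#' Defaults follow the study conditions the package emulates: transcriptome
#' variant calls are kept when they have at least 5 reads of coverage, at
#' least 2 alternate reads and at least 20% alternate frequency, and a kept
#' call is homozygous when the alternate frequency exceeds 80% (exactly 80%
#' is heterozygous). A site is fixed within a parental line when at least
#' n - 1 of its n genotyped individuals share the same homozygous call.
#'
#' @param min_coverage Minimum total read depth (reads) for a variant call.
#' @param min_count Minimum alternate-allele read count (reads).
#' @param min_freq Minimum alternate-allele frequency (percent).
#' @param hom_cutoff Homozygous/heterozygous frequency cutoff (percent,
#'   exclusive: calls strictly above are homozygous).
#' @param min_support Within-line consensus support. Either `NULL` (default,
#'   meaning n - 1 individuals of the line), an absolute count, or a fraction
#'   in (0, 1] of the line's individuals (rounded up).
#' @param max_missing Maximum tolerated per-marker missing fraction in the F2
#'   matrix (strictly greater is removed).
#' @param distortion_alpha Chi-square p-value threshold for the 1:2:1
#'   segregation-distortion filter (strictly smaller is removed).
#' @param flank Flanking length (bp) extracted on each side of a projected
#'   site for primer design; the design window is `2 * flank` bp.
#' @param amplicon_min,amplicon_max Allowed amplicon (product) size range, bp.
#' @param kmer_k K-mer length (bp) for the repeat blacklist.
#' @param blacklist_cutoff Occurrence count above which a k-mer is
#'   blacklisted (both strands counted).
#' @param primer_len_min,primer_len_max Target-specific primer length range, nt.
#' @param tm_min,tm_max Allowed nearest-neighbour melting temperature, Celsius.
#' @param tm_pair_max_diff Maximum Tm difference within a primer pair, Celsius.
#' @param gc_min,gc_max Allowed primer GC content, percent.
#' @param pool_size Primer pairs per multiplex pool.
#' @param lod_threshold LOD threshold for linkage grouping.
#' @param max_rf Maximum recombination fraction for a grouping edge.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_coverage = 5,
                            min_count = 2,
                            min_freq = 20,
                            hom_cutoff = 80,
                            min_support = NULL,
                            max_missing = 0.10,
                            distortion_alpha = 0.001,
                            flank = 150,
                            amplicon_min = 120,
                            amplicon_max = 160,
                            kmer_k = 16,
                            blacklist_cutoff = 10,
                            primer_len_min = 18,
                            primer_len_max = 25,
                            tm_min = 57,
                            tm_max = 63,
                            tm_pair_max_diff = 3,
                            gc_min = 30,
                            gc_max = 70,
                            pool_size = 48,
                            lod_threshold = 4.0,
                            max_rf = 0.45) {
  cfg <- list(
    min_coverage = min_coverage, min_count = min_count, min_freq = min_freq,
    hom_cutoff = hom_cutoff, min_support = min_support,
    max_missing = max_missing, distortion_alpha = distortion_alpha,
    flank = flank, amplicon_min = amplicon_min, amplicon_max = amplicon_max,
    kmer_k = kmer_k, blacklist_cutoff = blacklist_cutoff,
    primer_len_min = primer_len_min, primer_len_max = primer_len_max,
    tm_min = tm_min, tm_max = tm_max, tm_pair_max_diff = tm_pair_max_diff,
    gc_min = gc_min, gc_max = gc_max,
    pool_size = pool_size, lod_threshold = lod_threshold, max_rf = max_rf
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$hom_cutoff > 0, cfg$hom_cutoff < 100,
    cfg$amplicon_min <= cfg$amplicon_max,
    cfg$amplicon_max <= 2 * cfg$flank,
    cfg$min_coverage >= 0, cfg$min_count >= 0,
    cfg$max_missing >= 0, cfg$max_missing <= 1,
    cfg$distortion_alpha > 0, cfg$distortion_alpha < 1,
    cfg$kmer_k >= 8, cfg$pool_size >= 1
  )
  invisible(cfg)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (inherits(cfg, "pipeline_config")) return(cfg)
  do.call(pipeline_config, cfg)
}

#' Read / write a key = value configuration file
#'
#' A flat `key = value` text format holding any subset of the
#' [pipeline_config()] fields; unlisted keys keep their defaults. Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @return [read_config()] returns a `pipeline_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(pipeline_config())
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) abort(paste0("malformed config line: '", lines[bad][1], "'"))
  keys <- trimws(vapply(parts, `[[`, "", 1))
  vals <- trimws(vapply(parts, `[[`, "", 2))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  cfg <- as_config(cfg)
  flat <- cfg[!vapply(cfg, is.null, TRUE)]
  writeLines(paste(names(flat), unlist(flat), sep = " = "), path)
  invisible(path)
}

# Effective min_support for a line of n individuals (default n - 1).
resolve_min_support <- function(min_support, n) {
  if (is.null(min_support)) return(max(n - 1L, 1L))
  if (min_support > 0 && min_support <= 1) return(as.integer(ceiling(min_support * n)))
  as.integer(min_support)
}
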