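revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of one sequence as uppercase character vector (may contain N).
seq_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character())
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  pmin(kmers, rc)
}

#' Build a repeat k-mer blacklist from a genome
#'
#' Counts every k-mer of the genome on both strands (collapsed to canonical,
#' lexicographically smaller of a k-mer and its reverse complement) and
#' blacklists those occurring strictly more than `cutoff` times. K-mers
#' containing `N` are excluded. Primer design later refuses to place a
#' primer 3' end on any base covered by a blacklisted k-mer, keeping primers
#' out of repeat families.
#'
#' @param genome Sequence tibble (`id`, `seq`) from [read_fasta()].
#' @param k K-mer length (>= 8).
#' @param cutoff Occurrence count; k-mers with count > `cutoff` are
#'   blacklisted.
#' @return A list of class `kmer_blacklist` with elements `k`, `cutoff`,
#'   `kmers` (character vector of canonical k-mers) and `counts`.
#' @export
build_kmer_blacklist <- function(genome, k = 16, cutoff = 10) {
  stopifnot(k >= 8)
  if (nrow(genome) == 0 || all(!nzchar(genome$seq))) abort("empty genome")
  if (min(nchar(genome$seq)) < k) {
    warn("k exceeds the shortest scaffold; it contributes no k-mers")
  }
  all_kmers <- unlist(lapply(genome$seq, seq_kmers, k = k), use.names = FALSE)
  if (length(all_kmers) == 0) {
    warn("k exceeds every scaffold length; blacklist is empty")
    return(structure(list(k = k, cutoff = cutoff, kmers = character(),
                          counts = integer()), class = "kmer_blacklist"))
  }
  all_kmers <- all_kmers[!grepl("N", all_kmers, fixed = TRUE)]
  canon <- canonical_kmer(all_kmers)
  tab <- table(canon)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  # a palindromic k-mer is its own reverse complement: both-strand count
  # doubles the forward count
  pal <- names(counts) == revcomp(names(counts))
  counts[pal] <- 2L * counts[pal]
  keep <- counts > cutoff
  structure(list(k = k, cutoff = cutoff,
                 kmers = names(counts)[keep],
                 counts = unname(counts[keep])),
            class = "kmer_blacklist")
}

#' @export
print.kmer_blacklist <- function(x, ...) {
  cat("<kmer_blacklist> k =", x$k, ", cutoff =", x$cutoff, ",",
      length(x$kmers), "blacklisted k-mers\n")
  invisible(x)
}

#' Extract the design window around a projected site
#'
#' Returns the `flank` bp upstream of the site, the site base itself and
#' `flank - 1` bp downstream: a `2 * flank` bp window (300 bp at the default
#' flank of 150) with the site at 1-based offset `flank + 1`. Sites too
#' close to a scaffold end for a full window are rejected.
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param scaffold Scaffold id.
#' @param pos 1-based site position on the scaffold.
#' @param flank Flank length, bp.
#' @return List of class `flank_window`: `scaffold`, `window_start` (1-based
#'   genomic), `seq`, `site_offset` (1-based within window), `mask` (logical
#'   vector, all `FALSE` until [mask_window()]).
#' @export
extract_window <- function(genome, scaffold, pos, flank = 150) {
  i <- match(scaffold, genome$id)
  if (is.na(i)) abort(paste0("scaffold not found: ", scaffold))
  len <- nchar(genome$seq[i])
  if (pos < 1 || pos > len) {
    abort(paste0("position ", pos, " outside scaffold ", scaffold,
                 " (length ", len, ")"))
  }
  start <- pos - flank
  end <- pos + flank - 1L
  if (start < 1 || end > len) {
    abort(paste0("near-scaffold-end: site ", scaffold, ":", pos,
                 " lacks a full ", 2 * flank, "-bp window"))
  }
  wseq <- toupper(substr(genome$seq[i], start, end))
  structure(list(scaffold = scaffold, window_start = as.integer(start),
                 seq = wseq, site_offset = flank + 1L,
                 mask = rep(FALSE, 2L * flank)),
            class = "flank_window")
}

#' Mask blacklisted k-mers in a design window
#'
#' Sets the mask to `TRUE` at every window position covered by an occurrence
#' of a blacklisted k-mer (canonical comparison, so both strands are
#' masked).
#'
#' @param window A `flank_window` from [extract_window()].
#' @param blacklist A `kmer_blacklist`.
#' @return The window with its `mask` updated.
#' @export
mask_window <- function(window, blacklist) {
  k <- blacklist$k
  kmers <- seq_kmers(window$seq, k)
  if (length(kmers) == 0 || length(blacklist$kmers) == 0) return(window)
  hit <- canonical_kmer(kmers) %in% blacklist$kmers
  mask <- window$mask
  for (i in which(hit)) mask[i:(i + k - 1L)] <- TRUE
  window$mask <- mask
  window
}
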