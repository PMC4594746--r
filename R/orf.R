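#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the alphabet `ACGTN` (other
#' letters pass through unchanged).
#'
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
rev_comp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan", rawToChar(rev(charToRaw(seq))))
}

#' Longest open reading frame length
#'
#' Length in nucleotides of the longest ATG-initiated, stop-terminated
#' (TAA/TAG/TGA) open reading frame, stop codon included, across all six
#' frames (three on each strand) by default. ORFs truncated by the sequence
#' end (no in-frame stop) do not count; codons containing `N` match neither
#' start nor stop. Returns 0 when no complete ORF exists.
#'
#' @param seq nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param both_strands scan the reverse complement too (default `TRUE`,
#'   matching six-frame ORF finders; `FALSE` restricts to the three forward
#'   frames).
#' @return integer ORF length in nt (a multiple of 3), 0 if none.
#' @export
longest_orf <- function(seq, both_strands = TRUE) {
  seq <- toupper(seq)
  strands <- if (both_strands) c(seq, rev_comp(seq)) else seq
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (s in strands) {
    n <- nchar(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2L) next
      at <- f + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, at, at + 2L)
      start_i <- which(codons == "ATG")
      stop_i <- which(codons %in% stops)
      if (!length(start_i) || !length(stop_i)) next
      # index of first stop codon at or after each start (ATG is never a
      # stop, so the stop is strictly downstream)
      k <- findInterval(start_i - 1L, stop_i) + 1L
      ok <- k <= length(stop_i)
      if (!any(ok)) next
      len <- (stop_i[k[ok]] - start_i[ok] + 1L) * 3L
      best <- max(best, len)
    }
  }
  as.integer(best)
}

#' Spliced (mature) transcript sequence
#'
#' Concatenates exon sequences 5'->3'; minus-strand transcripts are
#' reverse-complemented after concatenation in genomic order.
#'
#' @param tx_exons exon table rows of a single transcript.
#' @param genome [Biostrings::DNAStringSet] as from [read_genome()].
#' @return nucleotide string of length `sum(end - start)`.
#' @export
spliced_sequence <- function(tx_exons, genome) {
  abort_if(length(unique(tx_exons$transcript_id)) != 1L,
           "tx_exons must contain exactly one transcript")
  chrom <- tx_exons$chrom[1]
  abort_if(!chrom %in% names(genome), "chromosome %s absent from genome", chrom)
  chr <- genome[[chrom]]
  abort_if(any(tx_exons$end > length(chr)) || any(tx_exons$start < 0L),
           "exon outside chromosome bounds on %s (length %d)", chrom, length(chr))
  tx_exons <- tx_exons[order(tx_exons$start), , drop = FALSE]
  parts <- as.character(Biostrings::extractAt(
    chr, IRanges::IRanges(tx_exons$start + 1L, tx_exons$end)
  ))
  s <- paste(parts, collapse = "")
  if (tx_exons$strand[1] == "-") rev_comp(s) else s
}

#' Spliced sequences for a whole exon table
#'
#' @param exons exon table.
#' @param genome [Biostrings::DNAStringSet].
#' @return named character vector, `transcript_id -> sequence`.
#' @export
spliced_sequences <- function(exons, genome) {
  exons <- validate_exons(exons)
  ids <- unique(exons$transcript_id)
  by_tx <- split(exons, exons$transcript_id)[ids]
  vapply(by_tx, spliced_sequence, "", genome = genome)
}
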