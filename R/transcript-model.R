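#' Spliced transcript lengths
#'
#' Sum of exon lengths per transcript, in nucleotides.
#'
#' @param exons exon table (see [read_gtf()]).
#' @return data.frame with columns `transcript_id`, `length`, in first
#'   appearance order.
#' @export
transcript_length <- function(exons) {
  exons <- validate_exons(exons)
  ids <- unique(exons$transcript_id)
  len <- tapply(exons$end - exons$start, exons$transcript_id, sum)
  data.frame(
    transcript_id = ids,
    length = as.integer(len[ids]),
    stringsAsFactors = FALSE
  )
}

#' Intron intervals of transcripts
#'
#' Introns are the gaps between consecutive exons of a transcript, in
#' 0-based half-open coordinates; single-exon transcripts contribute no
#' rows.
#'
#' @param exons exon table.
#' @return data.frame with the same columns as the exon table, one row per
#'   intron, ordered 5'->3' along the genome within each transcript.
#' @export
transcript_introns <- function(exons) {
  exons <- validate_exons(exons)
  multi <- exons$transcript_id %in%
    names(which(table(exons$transcript_id) > 1L))
  ex <- exons[multi, , drop = FALSE]
  if (nrow(ex) == 0L) {
    return(exons[0, , drop = FALSE])
  }
  # exons are sorted by start within transcript; a row opens an intron when
  # the next row belongs to the same transcript
  n <- nrow(ex)
  same <- ex$transcript_id[-n] == ex$transcript_id[-1]
  introns <- data.frame(
    transcript_id = ex$transcript_id[-n][same],
    gene_id = ex$gene_id[-n][same],
    chrom = ex$chrom[-n][same],
    strand = ex$strand[-n][same],
    start = ex$end[-n][same],
    end = ex$start[-1][same],
    stringsAsFactors = FALSE
  )
  rownames(introns) <- NULL
  introns
}

#' Transcript spans
#'
#' Per-transcript genomic span (min start to max end over exons).
#'
#' @param exons exon table.
#' @return data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, one row per transcript in first appearance order.
#' @export
transcript_spans <- function(exons) {
  exons <- validate_exons(exons)
  ids <- unique(exons$transcript_id)
  s <- tapply(exons$start, exons$transcript_id, min)[ids]
  e <- tapply(exons$end, exons$transcript_id, max)[ids]
  first <- exons[!duplicated(exons$transcript_id), , drop = FALSE]
  data.frame(
    transcript_id = ids,
    chrom = first$chrom[match(ids, first$transcript_id)],
    strand = first$strand[match(ids, first$transcript_id)],
    start = as.integer(s),
    end = as.integer(e),
    stringsAsFactors = FALSE
  )
}

#' Group transcripts into loci by same-strand exonic overlap
#'
#' A locus is a connected component of transcripts under the relation
#' "same chromosome, same strand, at least 1 bp of exon--exon overlap"
#' (transitive closure), the operational behaviour of assembler locus
#' grouping. Unstranded (`*`) transcripts only group with other unstranded
#' transcripts.
#'
#' @param exons exon table.
#' @return data.frame with columns `locus_id`, `transcript_id`, `chrom`,
#'   `strand`; `locus_id`s are dense (`LOC1`, `LOC2`, ...) ordered by
#'   (chrom, locus start).
#' @export
group_loci <- function(exons) {
  exons <- validate_exons(exons)
  ids <- unique(exons$transcript_id)
  gr <- exon_granges(exons)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keep <- exons$strand[q] == exons$strand[s]
  edges <- unique(data.frame(
    a = exons$transcript_id[q[keep]],
    b = exons$transcript_id[s[keep]],
    stringsAsFactors = FALSE
  ))
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership[ids]
  spans <- transcript_spans(exons)
  # order components by (chrom, min start) for dense, position-stable ids
  comp_start <- tapply(spans$start, comp[spans$transcript_id], min)
  comp_chrom <- tapply(spans$chrom, comp[spans$transcript_id], function(x) x[1])
  comp_order <- order(comp_chrom, comp_start)
  lab <- setNames(seq_along(comp_order), names(comp_start)[comp_order])
  out <- data.frame(
    locus_id = sprintf("LOC%d", lab[as.character(comp)]),
    transcript_id = ids,
    chrom = spans$chrom,
    strand = spans$strand,
    stringsAsFactors = FALSE
  )
  out <- out[order(as.integer(sub("^LOC", "", out$locus_id)), out$transcript_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
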