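#' Read assembled transcript models from a GTF file
#'
#' Parses the `exon` features of a Cufflinks-style GTF into an exon table,
#' one row per exon. Coordinates are converted from GTF's 1-based inclusive
#' convention to the package-internal 0-based half-open convention, so that
#' `end - start` is the exon length. Exons are grouped by `transcript_id`
#' and sorted by start within each transcript.
#'
#' Strand `"."` (unknown) is accepted with a warning — such transcripts are
#' carried as strand `"*"` and are excluded from strand-specific location
#' classes downstream. Use [read_annotation()] for the reference annotation,
#' which rejects unstranded features.
#'
#' @param path path to a GTF file with `exon` features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @return a `data.frame` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`+`, `-` or `*`), `start`, `end` (0-based half-open), sorted
#'   by (transcript first appearance, start).
#' @export
read_gtf <- function(path) {
  abort_if(!file.exists(path), "GTF file not found: %s", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  abort_if(length(gr) == 0L, "no exon features in %s", path)
  abort_if(
    is.null(gr$transcript_id) || anyNA(gr$transcript_id),
    "exon feature without transcript_id attribute in %s", path
  )
  gene_id <- if (is.null(gr$gene_id)) gr$transcript_id else gr$gene_id
  ex <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(ex$strand == "*")) {
    warning(
      sprintf(
        "%d transcript(s) have unknown strand '.'; they are excluded from strand-specific classes",
        length(unique(ex$transcript_id[ex$strand == "*"]))
      ),
      call. = FALSE
    )
  }
  validate_exons(ex)
}

# Cheap structural pre-scan so malformed input is reported with a line number
# (the importer reports none).
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    abort_if(length(f) < 9L, "malformed GTF line %d: expected 9 tab-delimited fields, got %d", i, length(f))
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    abort_if(is.na(s) || is.na(e), "malformed GTF line %d: non-numeric coordinates", i)
    abort_if(e < s, "invalid GTF line %d: end (%d) < start (%d)", i, e, s)
  }
  invisible(NULL)
}

# Validate and canonicalise an exon table: sorted, non-overlapping exons,
# one chromosome and strand per transcript.
validate_exons <- function(ex) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  abort_if(!all(req %in% names(ex)), "exon table must have columns: %s", paste(req, collapse = ", "))
  abort_if(any(ex$end <= ex$start), "exon with end <= start (0-based half-open)")
  first <- !duplicated(ex$transcript_id)
  n_chrom <- tapply(ex$chrom, ex$transcript_id, function(x) length(unique(x)))
  if (any(n_chrom > 1L)) {
    stop(sprintf(
      "transcript_id on multiple chromosomes (duplicate ID?): %s",
      paste(head(names(n_chrom)[n_chrom > 1L], 5), collapse = ", ")
    ), call. = FALSE)
  }
  n_str <- tapply(ex$strand, ex$transcript_id, function(x) length(unique(x)))
  abort_if(any(n_str > 1L), "transcript with inconsistent strand: %s",
           paste(head(names(n_str)[n_str > 1L], 5), collapse = ", "))
  ord <- order(match(ex$transcript_id, ex$transcript_id[first]), ex$start)
  ex <- ex[ord, , drop = FALSE]
  # non-overlapping exons within a transcript
  by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- ex$start[idx]; e <- ex$end[idx]
      abort_if(any(s[-1] < e[-length(e)]),
               "overlapping exons within transcript %s", ex$transcript_id[idx[1]])
    }
  }
  rownames(ex) <- NULL
  ex
}

#' Write an exon table to GTF
#'
#' Emits one `exon` line per row, converting internal 0-based half-open
#' coordinates back to GTF's 1-based inclusive convention. Extra attributes
#' (e.g. assigned class and name) may be supplied per transcript.
#'
#' @param exons exon table as returned by [read_gtf()].
#' @param path output path.
#' @param source value for the GTF source column.
#' @param extra_attrs optional `data.frame` with a `transcript_id` column;
#'   remaining columns are written as additional attributes.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "lncloc", extra_attrs = NULL) {
  exons <- validate_exons(exons)
  attr_str <- sprintf('transcript_id "%s"; gene_id "%s";',
                      exons$transcript_id, exons$gene_id)
  if (!is.null(extra_attrs)) {
    m <- match(exons$transcript_id, extra_attrs$transcript_id)
    for (col in setdiff(names(extra_attrs), "transcript_id")) {
      val <- extra_attrs[[col]][m]
      add <- ifelse(is.na(val), "", sprintf(' %s "%s";', col, val))
      attr_str <- paste0(attr_str, add)
    }
  }
  strand <- ifelse(exons$strand == "*", ".", exons$strand)
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, source, exons$start + 1L, exons$end,
                   strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-coding reference annotation (GTF or GFF3)
#'
#' Builds a [genome_annotation] from a reference gene annotation. GFF3 files
#' are resolved through their `gene -> mRNA/transcript -> exon` `Parent`
#' hierarchy; GTF files through `transcript_id`/`gene_id` attributes.
#' Unstranded features are rejected: the location classifier requires a
#' strand for every reference gene.
#'
#' @param path path to a GTF or GFF3 file.
#' @param format `"auto"` (by extension), `"gtf"` or `"gff3"`.
#' @return a `genome_annotation` object.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  if (format == "gtf") {
    ex <- read_gtf(path)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- tolower(as.character(gr$type))
    tx <- gr[type %in% c("mrna", "transcript")]
    exn <- gr[type == "exon"]
    abort_if(length(tx) == 0L || length(exn) == 0L,
             "GFF3 %s lacks mRNA/transcript or exon features", path)
    tx_gene <- setNames(vapply(tx$Parent, `[`, "", 1L), tx$ID)
    ex_tx <- vapply(exn$Parent, `[`, "", 1L)
    abort_if(anyNA(match(ex_tx, names(tx_gene))),
             "GFF3 exon with Parent not matching any mRNA/transcript in %s", path)
    ex <- data.frame(
      transcript_id = ex_tx,
      gene_id = unname(tx_gene[ex_tx]),
      chrom = as.character(GenomicRanges::seqnames(exn)),
      strand = as.character(GenomicRanges::strand(exn)),
      start = GenomicRanges::start(exn) - 1L,
      end = GenomicRanges::end(exn),
      stringsAsFactors = FALSE
    )
    ex <- validate_exons(ex)
  }
  genome_annotation(ex)
}

#' Build an indexed genome annotation from an exon table
#'
#' Derives gene spans and introns from the exon table and prepares
#' strand-aware interval indexes (as `GRanges`) over exons, introns and gene
#' spans for the location classifier and neighbour search.
#'
#' @param exons exon table (see [read_gtf()]); strand must be `+` or `-`.
#' @return an object of class `genome_annotation` with elements `exons`,
#'   `introns`, `genes` (data.frames) and `GRanges` indexes.
#' @export
genome_annotation <- function(exons) {
  exons <- validate_exons(exons)
  abort_if(any(exons$strand == "*"),
           "reference annotation contains unstranded features; strand is required")
  introns <- transcript_introns(exons)
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(g) {
    data.frame(
      gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
      start = min(g$start), end = max(g$end), stringsAsFactors = FALSE
    )
  }))
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  ann <- list(
    exons = exons,
    introns = introns,
    genes = genes,
    exons_gr = exon_granges(exons),
    introns_gr = exon_granges(introns),
    genes_gr = GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(genes$start + 1L, genes$end),
      strand = genes$strand, gene_id = genes$gene_id
    )
  )
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d genes, %d transcripts, %d exons on %d chromosome(s)\n",
    nrow(x$genes), length(unique(x$exons$transcript_id)), nrow(x$exons),
    length(unique(x$genes$chrom))
  ))
  invisible(x)
}

# exon table -> GRanges (1-based inclusive), carrying ids; '*' strand kept
exon_granges <- function(ex) {
  GenomicRanges::GRanges(
    ex$chrom,
    IRanges::IRanges(ex$start + 1L, ex$end),
    strand = ex$strand,
    transcript_id = ex$transcript_id,
    gene_id = ex$gene_id
  )
}

#' Read a genome FASTA with per-chromosome access
#'
#' Sequences are uppercased and any non-ACGT letter is replaced by `N`.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  abort_if(!file.exists(path), "FASTA file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGT]", "N", chr)
  Biostrings::DNAStringSet(setNames(chr, names(seqs)))
}

#' Write classified transcripts as BED12
#'
#' One BED12 line per transcript with exon blocks; scores are 0 and the
#' `name` column takes the supplied per-transcript names (defaults to the
#' transcript id).
#'
#' @param exons exon table.
#' @param path output path.
#' @param names optional named character vector, `transcript_id -> name`.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(exons, path, names = NULL) {
  exons <- validate_exons(exons)
  by_tx <- split(exons, exons$transcript_id)
  # preserve first-appearance order
  by_tx <- by_tx[unique(exons$transcript_id)]
  lines <- vapply(by_tx, function(t) {
    s0 <- min(t$start); e0 <- max(t$end)
    nm <- if (!is.null(names) && t$transcript_id[1] %in% base::names(names)) {
      names[[t$transcript_id[1]]]
    } else {
      t$transcript_id[1]
    }
    sprintf(
      "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
      t$chrom[1], s0, e0, nm,
      ifelse(t$strand[1] == "*", ".", t$strand[1]),
      s0, e0, nrow(t),
      paste0(paste(t$end - t$start, collapse = ","), ","),
      paste0(paste(t$start - s0, collapse = ","), ",")
    )
  }, "")
  writeLines(lines, path)
  invisible(path)
}
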