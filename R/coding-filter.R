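#' Filter cascade configuration
#'
#' Thresholds of the lncRNA candidate filter: minimum spliced length,
#' minimum exon count, and the ORF length at and above which a transcript
#' is considered protein-coding and removed (the kept set has
#' `longest_orf < max_orf`). Defaults are the standard lncRNA criteria:
#' length >= 200 nt, >= 2 exons, ORF < 300 nt.
#'
#' @param min_length minimum spliced transcript length (nt), default 200.
#' @param min_exons minimum exon count, default 2.
#' @param max_orf exclusive-keep ORF threshold (nt, stop codon included),
#'   default 300.
#' @param orf_both_strands scan both strands for ORFs (default `TRUE`).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_length = 200L, min_exons = 2L, max_orf = 300L,
                          orf_both_strands = TRUE) {
  abort_if(min_length < 1L, "min_length must be >= 1")
  abort_if(min_exons < 1L, "min_exons must be >= 1")
  structure(
    list(
      min_length = as.integer(min_length),
      min_exons = as.integer(min_exons),
      max_orf = if (is.finite(max_orf)) as.integer(max_orf) else Inf,
      orf_both_strands = isTRUE(orf_both_strands)
    ),
    class = "filter_config"
  )
}

# evidence labels, in cascade order
EVIDENCE_LABELS <- c(
  "protein_hit", "utr_fragment", "coding_potential",
  "pfam_domain", "structural_ncrna"
)

#' Read a transcript-ID evidence list
#'
#' One transcript ID per line; blank lines and `#` comments ignored.
#' Evidence lists carry the IDs flagged by external tools (protein BLAST,
#' coding-potential scoring, domain or structural-RNA searches) whose
#' thresholds are applied upstream by whoever produced the list.
#'
#' @param path file path.
#' @return character vector of transcript IDs.
#' @export
read_evidence_ids <- function(path) {
  abort_if(!file.exists(path), "evidence file not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Extract flagged query IDs from tabular BLAST output
#'
#' Parses BLAST `-outfmt 6` (12 standard columns) and returns the query IDs
#' with at least one hit at `evalue < max_evalue` (the protein-homology
#' removal rule; default e < 0.001).
#'
#' @param path path to a tabular BLAST file.
#' @param max_evalue e-value cutoff (exclusive), default `1e-3`.
#' @return character vector of query IDs.
#' @export
read_blast_outfmt6 <- function(path, max_evalue = 1e-3) {
  abort_if(!file.exists(path), "BLAST file not found: %s", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 11L, "expected >= 11 tab-delimited columns (outfmt 6) in %s", path)
  unique(tab[[1]][as.numeric(tab[[11]]) < max_evalue])
}

#' Run the lncRNA candidate filter cascade
#'
#' Applies, in order: (1) spliced length and exon-count thresholds; (2) the
#' longest-ORF rule; then removal of transcripts named in each evidence
#' list — protein homology hits, putative UTR fragments of known mRNAs,
#' coding-potential calls, conserved protein domains, and structural
#' non-coding RNAs (tRNA/rRNA/sno/snRNA). Each step's input, removed and
#' surviving counts telescope in the report.
#'
#' @param exons exon table of assembled transcripts.
#' @param genome [Biostrings::DNAStringSet]; may be `NULL` when `max_orf`
#'   is `Inf` (ORF step skipped).
#' @param evidence named list of transcript-ID character vectors; names
#'   drawn from `protein_hit`, `utr_fragment`, `coding_potential`,
#'   `pfam_domain`, `structural_ncrna`. Missing labels are treated as empty.
#' @param cfg a [filter_config()].
#' @return list with `survivors` (exon table subset), `survivor_ids`,
#'   `report` (per-step data.frame with columns `step`, `input`, `removed`,
#'   `surviving`) and `stale_evidence` (evidence IDs absent from the
#'   input, per label).
#' @export
run_cascade <- function(exons, genome = NULL, evidence = list(),
                        cfg = filter_config()) {
  exons <- validate_exons(exons)
  abort_if(anyDuplicated(names(evidence)) > 0L, "evidence labels must be unique")
  bad <- setdiff(names(evidence), EVIDENCE_LABELS)
  abort_if(length(bad) > 0L, "unknown evidence label(s): %s", paste(bad, collapse = ", "))

  ids <- unique(exons$transcript_id)
  stale <- lapply(evidence, function(v) setdiff(v, ids))
  stale <- stale[vapply(stale, length, 0L) > 0L]
  if (length(stale)) {
    warning(sprintf(
      "stale evidence: %d ID(s) not present in the input (%s)",
      sum(vapply(stale, length, 0L)), paste(names(stale), collapse = ", ")
    ), call. = FALSE)
  }

  report <- data.frame(step = character(), input = integer(),
                       removed = integer(), surviving = integer(),
                       stringsAsFactors = FALSE)
  log_step <- function(step, before, after) {
    report[nrow(report) + 1L, ] <<- list(step, length(before),
                                         length(before) - length(after),
                                         length(after))
  }

  alive <- ids

  # step 1: size and exon count
  len <- transcript_length(exons)
  n_ex <- table(exons$transcript_id)
  pass1 <- len$transcript_id[
    len$length >= cfg$min_length &
      as.integer(n_ex[len$transcript_id]) >= cfg$min_exons
  ]
  after <- intersect(alive, pass1)
  log_step("length_exons", alive, after)
  alive <- after

  # step 2: longest ORF below threshold
  if (is.finite(cfg$max_orf)) {
    abort_if(is.null(genome), "genome is required for the ORF step")
    seqs <- spliced_sequences(exons[exons$transcript_id %in% alive, , drop = FALSE], genome)
    orf <- vapply(seqs, longest_orf, 0L, both_strands = cfg$orf_both_strands)
    after <- alive[orf[alive] < cfg$max_orf]
  } else {
    after <- alive
  }
  log_step("orf", alive, after)
  alive <- after

  # steps 3-7: evidence removal in cascade order
  for (label in EVIDENCE_LABELS) {
    after <- setdiff(alive, evidence[[label]] %||% character())
    log_step(label, alive, after)
    alive <- after
  }

  survivors <- exons[exons$transcript_id %in% alive, , drop = FALSE]
  rownames(survivors) <- NULL
  structure(
    list(
      survivors = survivors,
      survivor_ids = alive,
      report = report,
      stale_evidence = stale
    ),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat("lncRNA filter cascade:\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("%d transcript(s) surviving\n", length(x$survivor_ids)))
  invisible(x)
}
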