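#' Run the full lncRNA pipeline
#'
#' Orchestrates filter -> locus grouping -> classification -> naming ->
#' structural summary -> expression calling -> neighbour co-expression on
#' file inputs, writing per-stage outputs and a JSON run report whose
#' counts telescope through the stages. Any stage failure aborts with an
#' error naming the stage; outputs of completed stages are retained.
#'
#' @param config either a path to a YAML file or a list with entries:
#'   \describe{
#'     \item{inputs}{`lnc_gtf`, `annotation`, `genome` (optional when the
#'       ORF step is disabled), `fpkm` (optional), `evidence` (optional
#'       named list of ID-list file paths or `label=path` strings).}
#'     \item{filter}{`min_length`, `min_exons`, `max_orf` (see
#'       [filter_config()]).}
#'     \item{classify}{`prefix` for assigned names.}
#'     \item{expression}{`specific_hi`, `specific_lo`, `fold`, optionally
#'       `groups` (named sample -> group) with `p_cut`, `q_cut`.}
#'     \item{coexpression}{`n_random`, `strong_cut`.}
#'     \item{outdir}{output directory.}
#'     \item{seed}{seed for the co-expression null.}
#'   }
#' @return the run report (list), invisibly; also written as
#'   `run_report.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% "lncloc_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  report <- list(
    package = "lncloc",
    version = as.character(utils::packageVersion("lncloc")),
    seed = seed,
    stages = list()
  )

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------------
  inp <- config$inputs
  lnc <- stage("read_inputs", read_gtf(inp$lnc_gtf))
  ann <- stage("read_inputs", read_annotation(inp$annotation))
  genome <- if (!is.null(inp$genome)) stage("read_inputs", read_genome(inp$genome)) else NULL
  evidence <- list()
  for (label in names(inp$evidence %||% list())) {
    evidence[[label]] <- stage("read_inputs", read_evidence_ids(inp$evidence[[label]]))
  }
  report$stages$input <- list(
    n_transcripts = length(unique(lnc$transcript_id)),
    n_reference_genes = nrow(ann$genes)
  )

  # --- filter ---------------------------------------------------------------
  fc <- config$filter %||% list()
  cfg <- filter_config(
    min_length = fc$min_length %||% 200L,
    min_exons = fc$min_exons %||% 2L,
    max_orf = fc$max_orf %||% 300L
  )
  filt <- stage("filter", run_cascade(lnc, genome, evidence, cfg))
  utils::write.table(filt$report, file.path(outdir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$filter <- list(
    steps = filt$report,
    n_survivors = length(filt$survivor_ids)
  )
  survivors <- filt$survivors

  empty_out <- function() {
    for (f in c("classified.tsv", "class_table.tsv", "specific_calls.tsv",
                "neighbors.tsv")) {
      utils::write.table(data.frame(), file.path(outdir, f),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (nrow(survivors) == 0L) {
    empty_out()
    report$stages$note <- "no surviving lncRNA candidates; downstream outputs empty"
    jsonlite::write_json(serialize_report(report),
                         file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }

  # --- classify + name ------------------------------------------------------
  loci <- stage("classify", group_loci(survivors))
  recs <- stage("classify", classify_transcripts(survivors, ann))
  recs <- stage("classify", assign_names(
    recs, loci, prefix = (config$classify %||% list())$prefix %||% "BPH"
  ))
  nb <- stage("classify", nearest_genes(survivors, ann))
  recs$distance_to_nearest_gene <- nb$distance[match(recs$transcript_id, nb$lnc_id)]
  utils::write.table(recs, file.path(outdir, "classified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- class_table(recs)
  utils::write.table(ct, file.path(outdir, "class_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("classify", write_gtf(
    survivors, file.path(outdir, "lnc_classified.gtf"),
    extra_attrs = recs[, c("transcript_id", "lnc_class", "assigned_name")]
  ))
  stage("classify", write_bed12(
    survivors, file.path(outdir, "lnc_classified.bed"),
    names = setNames(recs$assigned_name, recs$transcript_id)
  ))
  report$stages$classify <- list(
    n_loci = length(unique(loci$locus_id)),
    class_counts = setNames(as.list(ct$count), ct$lnc_class)
  )

  # --- structure ------------------------------------------------------------
  ss <- stage("structure", structure_summary(survivors, loci))
  report$stages$structure <- list(
    n_transcripts = ss$n_transcripts,
    mean_transcript_length = ss$mean_transcript_length,
    mean_exon_length = ss$mean_exon_length,
    mean_intron_length = ss$mean_intron_length,
    as_fraction = ss$as_fraction
  )

  # --- expression -----------------------------------------------------------
  if (!is.null(inp$fpkm)) {
    ec <- config$expression %||% list()
    m <- stage("expression", read_fpkm(inp$fpkm))
    sp <- stage("expression", call_specific(
      m[intersect(rownames(m), recs$transcript_id), , drop = FALSE],
      hi = ec$specific_hi %||% 3, lo = ec$specific_lo %||% 1,
      fold = ec$fold %||% 10
    ))
    utils::write.table(sp, file.path(outdir, "specific_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$expression <- list(n_specific_calls = nrow(sp))
    if (!is.null(ec$groups)) {
      dm <- stage("expression", call_differential(
        m, unlist(ec$groups),
        p_cut = ec$p_cut %||% 0.01, q_cut = ec$q_cut %||% 0.05
      ))
      utils::write.table(dm, file.path(outdir, "differential_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$expression$n_differential_calls <- sum(dm$called)
    }

    # --- co-expression ------------------------------------------------------
    cc <- config$coexpression %||% list()
    pairs <- nb[!is.na(nb$nearest_gene_id), c("lnc_id", "nearest_gene_id")]
    names(pairs) <- c("lnc_id", "gene_id")
    pairs <- pairs[pairs$lnc_id %in% rownames(m) & pairs$gene_id %in% rownames(m), ,
                   drop = FALSE]
    utils::write.table(nb, file.path(outdir, "neighbors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(pairs) > 0L) {
      cx <- stage("coexpression", coexpression_test(
        pairs, m,
        n_random = cc$n_random %||% max(1000L, nrow(pairs)),
        seed = seed, strong_cut = cc$strong_cut %||% 0.8
      ))
      utils::write.table(cx$pair_r, file.path(outdir, "coexpression_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$coexpression <- list(
        n_pairs = nrow(cx$pair_r),
        observed_mean_r = cx$observed_mean_r,
        null_mean_r = cx$null_mean_r,
        p_value = cx$p_value,
        n_strong = nrow(cx$strong_pairs)
      )
    }
  }

  jsonlite::write_json(serialize_report(report),
                       file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# data.frames inside the report -> plain lists for stable JSON
serialize_report <- function(x) {
  rapply(x, function(v) v, how = "replace")
}
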