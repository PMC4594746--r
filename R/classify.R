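#' Genomic-location classes
#'
#' The seven location classes assigned to lncRNA candidates relative to a
#' protein-coding reference annotation, in the order used by the summary
#' table: intergenic; entirely within a reference intron (sense); intron
#' overlap on the opposite strand; exon overlap on the same strand; exon
#' overlap on the opposite strand; at least one splice junction shared with
#' a reference transcript; unclassified.
#'
#' @export
LNC_CLASSES <- c(
  "INTERGENIC", "INTRONIC_SENSE", "INTRONIC_ANTISENSE",
  "EXONIC_SENSE", "EXONIC_ANTISENSE", "JUNCTION_SHARED", "UNCLASSIFIED"
)

# default precedence among the overlap rules (strongest structural evidence
# first: shared junction, then exonic beats intronic, sense beats antisense)
DEFAULT_PRECEDENCE <- c(
  "JUNCTION_SHARED", "EXONIC_SENSE", "EXONIC_ANTISENSE",
  "INTRONIC_SENSE", "INTRONIC_ANTISENSE"
)

intron_key <- function(df) paste(df$chrom, df$strand, df$start, df$end, sep = ":")

#' Classify lncRNA candidates by genomic location
#'
#' Assigns every transcript exactly one of [LNC_CLASSES] relative to the
#' reference annotation. Rules (1 bp is enough for "overlap"):
#' * `JUNCTION_SHARED`: same strand, at least one intron of the transcript
#'   identical (both coordinates) to a reference intron;
#' * `EXONIC_SENSE` / `EXONIC_ANTISENSE`: exon--exon overlap on the same /
#'   opposite strand;
#' * `INTRONIC_SENSE`: entire transcript span within one reference intron,
#'   same strand;
#' * `INTRONIC_ANTISENSE`: exons overlap a reference intron on the opposite
#'   strand without overlapping that gene's exons;
#' * `INTERGENIC`: no overlap with any gene span;
#' * `UNCLASSIFIED`: the residual — unstranded transcripts overlapping a
#'   gene, or overlap patterns matching no rule.
#'
#' Overlap rules are resolved in `precedence` order. The partner gene is
#' the gene satisfying the winning rule, ties broken by largest exonic
#' overlap, then smallest `gene_id`.
#'
#' @param exons exon table of candidate lncRNA transcripts.
#' @param ann a [genome_annotation()].
#' @param precedence character vector ordering the five overlap classes.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (span), `lnc_class`,
#'   `partner_gene_id` (`NA` for `INTERGENIC`/`UNCLASSIFIED`).
#' @export
classify_transcripts <- function(exons, ann, precedence = DEFAULT_PRECEDENCE) {
  exons <- validate_exons(exons)
  abort_if(!inherits(ann, "genome_annotation"), "ann must be a genome_annotation")
  abort_if(
    !setequal(precedence, DEFAULT_PRECEDENCE),
    "precedence must be a permutation of the five overlap classes"
  )
  ids <- unique(exons$transcript_id)
  spans <- transcript_spans(exons)

  missing_chrom <- setdiff(unique(exons$chrom), unique(ann$genes$chrom))
  if (length(missing_chrom)) {
    warning(sprintf(
      "chromosome(s) absent from the annotation (classified as intergenic): %s",
      paste(missing_chrom, collapse = ", ")
    ), call. = FALSE)
  }

  lv <- union(unique(exons$chrom), unique(ann$genes$chrom))
  widen <- function(gr) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr), lv)
    gr
  }
  lx_gr <- widen(exon_granges(exons))
  sp_gr <- widen(GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end),
    strand = spans$strand
  ))
  ann_exons_gr <- widen(ann$exons_gr)
  ann_introns_gr <- widen(ann$introns_gr)
  ann_genes_gr <- widen(ann$genes_gr)

  # exon--exon overlaps, split by strand relation, overlap width retained
  h <- GenomicRanges::findOverlaps(lx_gr, ann_exons_gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  ov_bp <- pmin(exons$end[q], ann$exons$end[s]) -
    pmax(exons$start[q], ann$exons$start[s])
  exov <- data.frame(
    tx = exons$transcript_id[q],
    gene = ann$exons$gene_id[s],
    rel = ifelse(exons$strand[q] == "*", "unknown",
                 ifelse(exons$strand[q] == ann$exons$strand[s], "sense", "anti")),
    bp = ov_bp,
    stringsAsFactors = FALSE
  )
  pair_of <- function(df) unique(df[, c("tx", "gene"), drop = FALSE])

  # shared splice junctions: lnc intron identical to a reference intron
  lintr <- transcript_introns(exons)
  ref_map <- split(ann$introns$gene_id, intron_key(ann$introns))
  jx <- data.frame(tx = character(), gene = character(), stringsAsFactors = FALSE)
  if (nrow(lintr)) {
    kk <- intron_key(lintr)
    hit <- kk %in% names(ref_map)
    if (any(hit)) {
      jx <- unique(do.call(rbind, lapply(which(hit), function(i) {
        data.frame(tx = lintr$transcript_id[i], gene = unique(ref_map[[kk[i]]]),
                   stringsAsFactors = FALSE)
      })))
    }
  }

  # span entirely within one reference intron, same strand
  wi <- GenomicRanges::findOverlaps(sp_gr, ann_introns_gr,
                                    type = "within", ignore.strand = TRUE)
  wq <- S4Vectors::queryHits(wi); ws <- S4Vectors::subjectHits(wi)
  keep <- spans$strand[wq] == ann$introns$strand[ws]
  intr_sense <- unique(data.frame(
    tx = spans$transcript_id[wq[keep]],
    gene = ann$introns$gene_id[ws[keep]], stringsAsFactors = FALSE
  ))

  # exons overlapping a reference intron on the opposite strand
  ei <- GenomicRanges::findOverlaps(lx_gr, ann_introns_gr, ignore.strand = TRUE)
  eq <- S4Vectors::queryHits(ei); es <- S4Vectors::subjectHits(ei)
  opp <- (exons$strand[eq] == "+" & ann$introns$strand[es] == "-") |
    (exons$strand[eq] == "-" & ann$introns$strand[es] == "+")
  intr_anti <- unique(data.frame(
    tx = exons$transcript_id[eq[opp]],
    gene = ann$introns$gene_id[es[opp]], stringsAsFactors = FALSE
  ))
  # ... but only where the transcript does not touch that gene's exons
  anti_ex <- pair_of(exov[exov$rel == "anti", , drop = FALSE])
  if (nrow(intr_anti) && nrow(anti_ex)) {
    drop <- paste(intr_anti$tx, intr_anti$gene) %in% paste(anti_ex$tx, anti_ex$gene)
    intr_anti <- intr_anti[!drop, , drop = FALSE]
  }

  # span overlap with any gene span (strand-ignored): intergenic test
  so <- GenomicRanges::findOverlaps(sp_gr, ann_genes_gr, ignore.strand = TRUE)
  overlaps_gene <- ids %in% spans$transcript_id[S4Vectors::queryHits(so)]
  names(overlaps_gene) <- ids

  cand <- list(
    JUNCTION_SHARED = jx,
    EXONIC_SENSE = pair_of(exov[exov$rel == "sense", , drop = FALSE]),
    EXONIC_ANTISENSE = anti_ex,
    INTRONIC_SENSE = intr_sense,
    INTRONIC_ANTISENSE = intr_anti
  )
  cand_by_tx <- lapply(cand, function(df) split(df$gene, df$tx))

  # total exonic overlap per (tx, gene) for partner tie-breaking
  bp_tot <- tapply(exov$bp, paste(exov$tx, exov$gene), sum)

  pick_partner <- function(tx, genes) {
    if (length(genes) == 1L) return(genes)
    bp <- bp_tot[paste(tx, genes)]
    bp[is.na(bp)] <- 0
    genes <- genes[bp == max(bp)]
    sort(genes)[1]
  }

  lnc_class <- character(length(ids))
  partner <- rep(NA_character_, length(ids))
  strand_of <- setNames(spans$strand, spans$transcript_id)
  for (i in seq_along(ids)) {
    tx <- ids[i]
    if (strand_of[[tx]] == "*") {
      lnc_class[i] <- if (overlaps_gene[[tx]]) "UNCLASSIFIED" else "INTERGENIC"
      next
    }
    assigned <- FALSE
    for (cl in precedence) {
      genes <- cand_by_tx[[cl]][[tx]]
      if (!is.null(genes) && length(genes)) {
        lnc_class[i] <- cl
        partner[i] <- pick_partner(tx, genes)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      lnc_class[i] <- if (overlaps_gene[[tx]]) "UNCLASSIFIED" else "INTERGENIC"
    }
  }

  data.frame(
    transcript_id = ids,
    chrom = spans$chrom,
    strand = spans$strand,
    start = spans$start,
    end = spans$end,
    lnc_class = lnc_class,
    partner_gene_id = partner,
    stringsAsFactors = FALSE
  )
}

# precedence rank for locus-level naming (lower = stronger)
class_rank <- function(cl) {
  match(cl, c(DEFAULT_PRECEDENCE, "INTERGENIC", "UNCLASSIFIED"))
}

# -RA, -RB, ..., -RZ, -RAA, ...
iso_letters <- function(n) {
  vapply(seq_len(n), function(i) {
    s <- ""
    repeat {
      s <- paste0(LETTERS[(i - 1L) %% 26L + 1L], s)
      i <- (i - 1L) %/% 26L
      if (i == 0L) break
    }
    s
  }, "")
}

#' Assign names to classified lncRNA transcripts
#'
#' Implements the gene-set naming scheme: intergenic loci become
#' `<prefix>LINC<n>` and unclassified loci `<prefix>LNC-unc<n>` (dense
#' numbering ordered by chromosome and start); loci overlapping a reference
#' gene take the partner gene id with a suffix — `-IT` for sense intronic,
#' `-AS` for antisense (exonic or intronic), `-OT` for sense exonic or
#' shared-junction overlap. Two loci sharing the same base name are
#' disambiguated with a numeric suffix (`-OT`, `-OT2`, ...). Within a
#' multi-isoform locus, transcripts get `-RA`, `-RB`, ... ordered by
#' (start, transcript_id).
#'
#' @param records output of [classify_transcripts()].
#' @param loci output of [group_loci()] over the same transcripts.
#' @param prefix species/project prefix for intergenic and unclassified
#'   names (e.g. `"BPH"`).
#' @param intronic_antisense_suffix suffix for intron-antisense overlaps;
#'   `"AS"` (default, antisense semantics) or `"IT"`.
#' @return `records` with added columns `locus_id`, `assigned_name`,
#'   `isoform_suffix`.
#' @export
assign_names <- function(records, loci, prefix = "BPH",
                         intronic_antisense_suffix = c("AS", "IT")) {
  intronic_antisense_suffix <- match.arg(intronic_antisense_suffix)
  abort_if(!all(records$transcript_id %in% loci$transcript_id),
           "every classified transcript must appear in the locus table")
  m <- match(records$transcript_id, loci$transcript_id)
  records$locus_id <- loci$locus_id[m]

  suffix_map <- c(
    JUNCTION_SHARED = "OT", EXONIC_SENSE = "OT", EXONIC_ANTISENSE = "AS",
    INTRONIC_SENSE = "IT", INTRONIC_ANTISENSE = intronic_antisense_suffix
  )

  # locus-level representative: strongest-precedence member, ties by
  # (start, transcript_id)
  ord <- order(records$locus_id, class_rank(records$lnc_class),
               records$start, records$transcript_id)
  rep_rows <- records[ord, , drop = FALSE]
  rep_rows <- rep_rows[!duplicated(rep_rows$locus_id), , drop = FALSE]
  rep_rows <- rep_rows[order(rep_rows$chrom, rep_rows$start, rep_rows$locus_id), ,
                       drop = FALSE]

  base_of <- character(nrow(rep_rows))
  names(base_of) <- rep_rows$locus_id
  is_linc <- rep_rows$lnc_class == "INTERGENIC"
  is_unc <- rep_rows$lnc_class == "UNCLASSIFIED"
  base_of[is_linc] <- sprintf("%sLINC%d", prefix, seq_len(sum(is_linc)))
  base_of[is_unc] <- sprintf("%sLNC-unc%d", prefix, seq_len(sum(is_unc)))
  gene_based <- !is_linc & !is_unc
  raw <- sprintf("%s-%s", rep_rows$partner_gene_id[gene_based],
                 suffix_map[rep_rows$lnc_class[gene_based]])
  # disambiguate colliding base names in positional order
  dup_n <- stats::ave(seq_along(raw), raw, FUN = seq_along)
  base_of[gene_based] <- ifelse(dup_n == 1L, raw, sprintf("%s%d", raw, dup_n))

  # isoform suffixes within multi-member loci
  records$isoform_suffix <- ""
  ord2 <- order(records$locus_id, records$start, records$transcript_id)
  by_locus <- split(ord2, records$locus_id[ord2])
  for (rows in by_locus) {
    if (length(rows) > 1L) {
      records$isoform_suffix[rows] <- paste0("-R", iso_letters(length(rows)))
    }
  }
  records$assigned_name <- paste0(base_of[records$locus_id],
                                  records$isoform_suffix)
  records
}

#' Per-class counts and percentages
#'
#' Tabulates location classes with percentages of the total, rounded to two
#' decimals with ties away from zero. Accepts either the output of
#' [classify_transcripts()] or a named count vector (names in
#' [LNC_CLASSES]).
#'
#' @param x classified records data.frame, or named numeric vector of
#'   per-class counts.
#' @return data.frame with columns `lnc_class`, `count`, `percentage` (all
#'   seven classes, table order) and attribute `total`; zero rows for empty
#'   input.
#' @export
class_table <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) {
      out <- data.frame(lnc_class = character(), count = integer(),
                        percentage = numeric(), stringsAsFactors = FALSE)
      attr(out, "total") <- 0L
      return(out)
    }
    counts <- table(factor(x$lnc_class, levels = LNC_CLASSES))
    counts <- setNames(as.integer(counts), LNC_CLASSES)
  } else {
    abort_if(is.null(names(x)) || !all(names(x) %in% LNC_CLASSES),
             "count vector must be named by LNC_CLASSES")
    counts <- setNames(integer(length(LNC_CLASSES)), LNC_CLASSES)
    counts[names(x)] <- as.integer(x)
  }
  total <- sum(counts)
  out <- data.frame(
    lnc_class = LNC_CLASSES,
    count = unname(counts),
    percentage = if (total > 0) round_half_up(100 * unname(counts) / total, 2) else rep(NA_real_, length(counts)),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  out
}
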