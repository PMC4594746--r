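# Fixture generator: toy genome + annotation + lncRNAs with planted truth.
#
# Background sequence carries the motif CTAGCTAGCTAG every 60 nt. CTAG is
# its own reverse complement and the motif holds TAG at all three codon
# phases, so every one of the six frames meets a stop inside each motif:
# no spurious ORF can exceed ~130 nt, and only deliberately planted
# cassettes pass the 300 nt rule.

STOP_MOTIF <- "CTAGCTAGCTAG"
BG_PERIOD <- 60L

#' Fixture generation parameters
#'
#' Defines the synthetic study: a toy genome, a protein-coding annotation,
#' lncRNA transcripts planted with known location classes, and an FPKM
#' matrix with planted sample-specific rows and lncRNA--neighbour
#' correlation. Structural defaults emulate the empirical feature scales of
#' insect transcriptomes: coding exons average 250 nt and introns 2583 nt;
#' lncRNA exons average 363 nt; most lncRNAs have two exons; about 19.9%
#' of lncRNA loci carry a second isoform; twelve expression samples.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (nt).
#' @param n_coding_genes total protein-coding genes to place.
#' @param lnc_counts named integer vector of planted lncRNAs per location
#'   class (names in [LNC_CLASSES] minus none; all seven supported).
#' @param n_samples expression samples.
#' @param n_specific planted specifically-expressed lncRNA rows.
#' @param n_specific_decoys planted near-miss rows failing exactly one
#'   specificity clause.
#' @param rho planted Pearson correlation (log scale) between a lncRNA and
#'   its neighbouring gene.
#' @param sigma lognormal expression noise (sd on the log2 scale).
#' @param as_fraction fraction of intergenic lncRNA loci given a second
#'   spliced isoform.
#' @param n_short,n_single_exon planted transcripts failing the length /
#'   exon-count rule.
#' @param n_orf planted transcripts carrying an ORF cassette of
#'   `orf_nt` nt.
#' @param orf_nt planted ORF length (nt, stop included).
#' @param n_evidence named integer vector: how many clean lncRNAs to list
#'   in each coding-evidence set (`protein_hit`, `utr_fragment`,
#'   `coding_potential`, `pfam_domain`, `structural_ncrna`).
#' @param coding_exon_probs,lnc_exon_probs exon-count distributions
#'   (coding over 1..8 exons, lncRNA over 2..6).
#' @param seed RNG seed (mandatory).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_chroms = 2L,
                         chrom_length = 1e6,
                         n_coding_genes = 60L,
                         lnc_counts = c(
                           INTERGENIC = 35L, INTRONIC_SENSE = 8L,
                           INTRONIC_ANTISENSE = 5L, EXONIC_SENSE = 16L,
                           EXONIC_ANTISENSE = 9L, JUNCTION_SHARED = 10L,
                           UNCLASSIFIED = 17L
                         ),
                         n_samples = 12L,
                         n_specific = 12L,
                         n_specific_decoys = 6L,
                         rho = 0.5,
                         sigma = 0.5,
                         as_fraction = 0.199,
                         n_short = 0L,
                         n_single_exon = 0L,
                         n_orf = 0L,
                         orf_nt = 402L,
                         n_evidence = c(
                           protein_hit = 0L, utr_fragment = 0L,
                           coding_potential = 0L, pfam_domain = 0L,
                           structural_ncrna = 0L
                         ),
                         coding_exon_probs = c(0.08, 0.404, 0.20, 0.117,
                                               0.09, 0.05, 0.035, 0.024),
                         lnc_exon_probs = c(0.779, 0.13, 0.0434, 0.03, 0.0176),
                         seed) {
  abort_if(missing(seed), "a seed is mandatory for fixture generation")
  abort_if(!all(names(lnc_counts) %in% LNC_CLASSES), "unknown class in lnc_counts")
  abort_if(!all(names(n_evidence) %in% EVIDENCE_LABELS), "unknown evidence label")
  abort_if(orf_nt %% 3L != 0L || orf_nt < 9L, "orf_nt must be a multiple of 3 >= 9")
  structure(
    list(
      n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
      n_coding_genes = as.integer(n_coding_genes), lnc_counts = lnc_counts,
      n_samples = as.integer(n_samples), n_specific = as.integer(n_specific),
      n_specific_decoys = as.integer(n_specific_decoys), rho = rho,
      sigma = sigma, as_fraction = as_fraction, n_short = as.integer(n_short),
      n_single_exon = as.integer(n_single_exon), n_orf = as.integer(n_orf),
      orf_nt = as.integer(orf_nt), n_evidence = n_evidence,
      coding_exon_probs = coding_exon_probs, lnc_exon_probs = lnc_exon_probs,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# truncated lognormal with a target arithmetic mean
rlnorm_trunc <- function(n, mean_target, sdlog, lo, hi) {
  x <- rlnorm(n, meanlog = log(mean_target) - sdlog^2 / 2, sdlog = sdlog)
  as.integer(round(pmin(pmax(x, lo), hi)))
}

# background chromosome with stop motifs every BG_PERIOD nt
bg_sequence <- function(n) {
  motif <- strsplit(STOP_MOTIF, "")[[1]]
  res <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  phase <- (seq_len(n) - 1L) %% BG_PERIOD
  in_motif <- phase >= (BG_PERIOD - length(motif))
  res[in_motif] <- motif[phase[in_motif] - (BG_PERIOD - length(motif)) + 1L]
  paste(res, collapse = "")
}

NON_STOP_CODONS <- {
  all3 <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0
  ))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# ATG + random non-stop codons + TAA, total length nt
orf_cassette <- function(nt) {
  k <- nt / 3L - 2L
  paste0("ATG", paste(sample(NON_STOP_CODONS, k, replace = TRUE), collapse = ""), "TAA")
}

# lay out coding genes with one transcript each; returns exon table
place_coding_genes <- function(spec, gene_prefix = "BPHOGS10") {
  rows <- list()
  chrom_i <- 1L
  cursor <- 3000L
  for (g in seq_len(spec$n_coding_genes)) {
    n_ex <- sample(seq_along(spec$coding_exon_probs), 1L, prob = spec$coding_exon_probs)
    ex_len <- rlnorm_trunc(n_ex, 250, 0.5, 50, 1500)
    in_len <- if (n_ex > 1L) rlnorm_trunc(n_ex - 1L, 2583, 0.5, 200, 9000) else integer()
    span <- sum(ex_len) + sum(in_len)
    while (cursor + span > spec$chrom_length - 3000L) {
      chrom_i <- chrom_i + 1L
      abort_if(chrom_i > spec$n_chroms,
               "infeasible placement: %d coding genes exceed the genome space", spec$n_coding_genes)
      cursor <- 3000L
    }
    gene_id <- sprintf("%s%06d", gene_prefix, g)
    strand <- sample(c("+", "-"), 1L)
    starts <- cursor + cumsum(c(0L, head(ex_len, -1L) + in_len))
    rows[[g]] <- data.frame(
      transcript_id = paste0(gene_id, ".t1"),
      gene_id = gene_id,
      chrom = sprintf("chr%d", chrom_i),
      strand = strand,
      start = starts,
      end = starts + ex_len,
      stringsAsFactors = FALSE
    )
    cursor <- cursor + span + as.integer(runif(1, 15000, 30000))
  }
  do.call(rbind, rows)
}

# intergenic gap inventory with per-gap placement cursors (environment so
# the planting helpers can advance them)
gap_inventory <- function(gene_exons, spec) {
  spans <- do.call(rbind, lapply(split(gene_exons, gene_exons$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)
  }))
  gaps <- list()
  for (ch in sprintf("chr%d", seq_len(spec$n_chroms))) {
    sp <- spans[spans$chrom == ch, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    bounds <- rbind(
      data.frame(lo = 500L, hi = if (nrow(sp)) sp$start[1] else spec$chrom_length - 500L,
                 left_gene = NA_character_,
                 right_gene = if (nrow(sp)) sp$gene_id[1] else NA_character_),
      if (nrow(sp) > 1L) data.frame(
        lo = sp$end[-nrow(sp)], hi = sp$start[-1],
        left_gene = sp$gene_id[-nrow(sp)], right_gene = sp$gene_id[-1]
      ),
      if (nrow(sp)) data.frame(
        lo = sp$end[nrow(sp)], hi = spec$chrom_length - 500L,
        left_gene = sp$gene_id[nrow(sp)], right_gene = NA_character_
      )
    )
    bounds$chrom <- ch
    gaps[[ch]] <- bounds
  }
  gaps <- do.call(rbind, gaps)
  gaps <- gaps[gaps$hi - gaps$lo > 2000L, , drop = FALSE]
  env <- new.env()
  env$gaps <- gaps
  env$cursor <- gaps$lo + 400L
  env
}

# reserve `span` nt inside a gap; returns list(start, chrom, left/right gene
# + distances) or NULL when no gap fits
reserve_gap <- function(inv, span, margin = 300L) {
  fits <- which(inv$cursor + span + margin <= inv$gaps$hi - 200L)
  if (!length(fits)) return(NULL)
  # rotate across gaps: pick the gap with the least-used cursor offset
  i <- fits[which.min(inv$cursor[fits] - inv$gaps$lo[fits])]
  s <- inv$cursor[i]
  inv$cursor[i] <- s + span + margin
  g <- inv$gaps[i, ]
  list(start = s, chrom = g$chrom, left_gene = g$left_gene,
       right_gene = g$right_gene, gap_lo = g$lo, gap_hi = g$hi)
}

# structure of a generic (intergenic-style) lncRNA
draw_lnc_structure <- function(spec, max_span = 15000L) {
  n_ex <- sample(seq_along(spec$lnc_exon_probs) + 1L, 1L, prob = spec$lnc_exon_probs)
  ex_len <- rlnorm_trunc(n_ex, 363, 0.5, 60, 1500)
  in_len <- rlnorm_trunc(n_ex - 1L, 7792, 0.5, 200, 12000)
  # shrink introns if the draw exceeds the local budget
  while (sum(ex_len) + sum(in_len) > max_span && max(in_len) > 300L) {
    in_len <- pmax(300L, in_len %/% 2L)
  }
  # planted lncRNAs are meant to survive the length filter
  if (sum(ex_len) < 220L) ex_len[1] <- ex_len[1] + (220L - sum(ex_len))
  list(ex_len = ex_len, in_len = in_len, span = sum(ex_len) + sum(in_len))
}

exon_rows <- function(tx_id, chrom, strand, start, ex_len, in_len) {
  starts <- start + cumsum(c(0L, head(ex_len, -1L) + in_len))
  data.frame(
    transcript_id = tx_id, gene_id = tx_id, chrom = chrom, strand = strand,
    start = as.integer(starts), end = as.integer(starts + ex_len),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic fixture set
#'
#' Builds, under the spec's seed: a genome, a protein-coding annotation,
#' lncRNA transcripts planted per location class (plus optional
#' filter-failing and ORF-carrying transcripts and coding-evidence lists),
#' and an FPKM matrix with planted specific rows and neighbour
#' correlation. Identical specs produce byte-identical outputs.
#'
#' @param spec a [fixture_spec()].
#' @return a `fixture_set` list: `genome` (DNAStringSet), `coding_exons`,
#'   `annotation` ([genome_annotation]), `lnc_exons`, `fpkm`, `evidence`
#'   (named ID lists), `truth` (list of data.frames: `class`, `filter`,
#'   `orf`, `specific`, `pairs`) and `spec`.
#' @export
generate_fixtures <- function(spec) {
  abort_if(!inherits(spec, "fixture_spec"), "spec must be a fixture_spec")
  with_seed(spec$seed, generate_fixtures_impl(spec))
}

generate_fixtures_impl <- function(spec) {
  coding <- place_coding_genes(spec)
  introns <- transcript_introns(coding)
  slots <- data.frame(
    gene_id = introns$gene_id, chrom = introns$chrom, strand = introns$strand,
    i0 = introns$start, i1 = introns$end, len = introns$end - introns$start,
    used = FALSE, stringsAsFactors = FALSE
  )
  # host exon preceding each intron (exon ending exactly at i0)
  key_end <- paste(coding$gene_id, coding$end)
  slots$exon_start <- coding$start[match(paste(slots$gene_id, slots$i0), key_end)]
  inv <- gap_inventory(coding, spec)

  take_slot <- function(min_len) {
    i <- which(!slots$used & slots$len >= min_len)[1]
    abort_if(is.na(i), "infeasible placement: no free intron of >= %d nt left", min_len)
    slots$used[i] <<- TRUE
    slots[i, ]
  }
  opposite <- function(s) if (s == "+") "-" else "+"

  lnc <- list()
  truth_class <- list()
  truth_pairs_host <- list() # lnc -> its partner/nearest gene
  tx_n <- 0L
  new_id <- function() {
    tx_n <<- tx_n + 1L
    sprintf("TCONS_%05d", tx_n)
  }
  add <- function(rows, class, partner, neighbour = partner) {
    lnc[[length(lnc) + 1L]] <<- rows
    truth_class[[length(truth_class) + 1L]] <<- data.frame(
      transcript_id = rows$transcript_id[1], true_class = class,
      true_partner = partner, stringsAsFactors = FALSE
    )
    if (!is.na(neighbour)) {
      truth_pairs_host[[length(truth_pairs_host) + 1L]] <<- data.frame(
        lnc_id = rows$transcript_id[1], gene_id = neighbour,
        stringsAsFactors = FALSE
      )
    }
  }

  counts <- spec$lnc_counts
  n_of <- function(cl) if (cl %in% names(counts)) counts[[cl]] else 0L

  # --- intergenic (plus optional AS isoforms) ------------------------------
  intergenic_primary <- character()
  for (i in seq_len(n_of("INTERGENIC"))) {
    st <- draw_lnc_structure(spec)
    slot <- reserve_gap(inv, st$span, margin = 500L)
    abort_if(is.null(slot), "infeasible placement: no intergenic gap fits %d nt", st$span)
    strand <- sample(c("+", "-"), 1L)
    id <- new_id()
    rows <- exon_rows(id, slot$chrom, strand, slot$start, st$ex_len, st$in_len)
    # nearest flanking gene by plain arithmetic (planted truth)
    d_left <- if (is.na(slot$left_gene)) Inf else slot$start - slot$gap_lo
    d_right <- if (is.na(slot$right_gene)) Inf else slot$gap_hi - (slot$start + st$span)
    nb <- if (d_left <= d_right) slot$left_gene else slot$right_gene
    add(rows, "INTERGENIC", NA_character_, neighbour = nb)
    intergenic_primary <- c(intergenic_primary, id)
  }
  n_as <- min(length(intergenic_primary),
              as.integer(round(spec$as_fraction * length(intergenic_primary))))
  for (id in head(intergenic_primary, n_as)) {
    base <- lnc[[match(id, vapply(lnc, function(x) x$transcript_id[1], ""))]]
    iso <- base
    iso$transcript_id <- new_id()
    iso$gene_id <- iso$transcript_id
    n <- nrow(iso)
    iso$end[n] <- iso$end[n] + 60L   # inside the reserved margin
    if (n > 1L) iso$start[n] <- iso$start[n] + 30L
    add(iso, "INTERGENIC", NA_character_, neighbour = NA_character_)
  }

  # --- intronic sense / antisense / unclassified ---------------------------
  place_in_intron <- function(strand_fun, class) {
    slot <- take_slot(700L)
    strand <- strand_fun(slot$strand)
    rows <- exon_rows(new_id(), slot$chrom, strand, slot$i0 + 50L,
                      ex_len = c(150L, 120L), in_len = 200L)
    # unclassified transcripts never get a partner, but the host gene is
    # still their expression neighbour
    partner <- if (class == "UNCLASSIFIED") NA_character_ else slot$gene_id
    add(rows, class, partner, neighbour = slot$gene_id)
  }
  for (i in seq_len(n_of("INTRONIC_SENSE"))) place_in_intron(identity, "INTRONIC_SENSE")
  for (i in seq_len(n_of("INTRONIC_ANTISENSE"))) place_in_intron(opposite, "INTRONIC_ANTISENSE")
  for (i in seq_len(n_of("UNCLASSIFIED"))) place_in_intron(function(s) "*", "UNCLASSIFIED")

  # --- exonic sense / antisense --------------------------------------------
  place_exonic <- function(strand_fun, class) {
    slot <- take_slot(400L)
    abort_if(is.na(slot$exon_start), "internal: intron without host exon")
    e0 <- slot$exon_start; e1 <- slot$i0
    mid <- e0 + (e1 - e0) %/% 2L
    # second exon stretches so the transcript always clears 200 nt
    len2 <- max(120L, 220L - (e1 + 40L - mid))
    id <- new_id()
    rows <- data.frame(
      transcript_id = id, gene_id = id, chrom = slot$chrom,
      strand = strand_fun(slot$strand),
      start = c(mid, e1 + 240L),
      end = c(e1 + 40L, e1 + 240L + len2),
      stringsAsFactors = FALSE
    )
    add(rows, class, slot$gene_id)
  }
  for (i in seq_len(n_of("EXONIC_SENSE"))) place_exonic(identity, "EXONIC_SENSE")
  for (i in seq_len(n_of("EXONIC_ANTISENSE"))) place_exonic(opposite, "EXONIC_ANTISENSE")

  # --- shared splice junction ----------------------------------------------
  for (i in seq_len(n_of("JUNCTION_SHARED"))) {
    slot <- take_slot(0L)
    id <- new_id()
    rows <- data.frame(
      transcript_id = id, gene_id = id, chrom = slot$chrom, strand = slot$strand,
      start = c(max(0L, slot$i0 - 100L), slot$i1),
      end = c(slot$i0, slot$i1 + 100L),
      stringsAsFactors = FALSE
    )
    add(rows, "JUNCTION_SHARED", slot$gene_id)
  }

  # --- filter-failing transcripts ------------------------------------------
  truth_filter_extra <- list()
  add_plain <- function(ex_len, in_len, fate) {
    span <- sum(ex_len) + sum(in_len)
    slot <- reserve_gap(inv, span)
    abort_if(is.null(slot), "infeasible placement: gap space exhausted")
    id <- new_id()
    rows <- exon_rows(id, slot$chrom, sample(c("+", "-"), 1L), slot$start, ex_len, in_len)
    lnc[[length(lnc) + 1L]] <<- rows
    truth_filter_extra[[length(truth_filter_extra) + 1L]] <<- data.frame(
      transcript_id = id, fate = fate, stringsAsFactors = FALSE
    )
    id
  }
  for (i in seq_len(spec$n_short)) add_plain(c(80L, 80L), 150L, "removed_length_exons")
  for (i in seq_len(spec$n_single_exon)) add_plain(500L, integer(), "removed_length_exons")
  orf_ids <- character()
  for (i in seq_len(spec$n_orf)) {
    orf_ids <- c(orf_ids,
                 add_plain(c(spec$orf_nt + 12L, 120L), 200L, "removed_orf"))
  }

  empty_exons <- data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE
  )
  lnc_exons <- if (length(lnc)) do.call(rbind, lnc) else empty_exons
  rownames(lnc_exons) <- NULL
  truth_class <- if (length(truth_class)) do.call(rbind, truth_class) else
    data.frame(transcript_id = character(), true_class = character(),
               true_partner = character(), stringsAsFactors = FALSE)

  # --- genome sequence + ORF cassettes -------------------------------------
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  genome_chr <- setNames(
    vapply(chroms, function(ch) bg_sequence(spec$chrom_length), ""),
    chroms
  )
  truth_orf <- data.frame(transcript_id = character(), orf_nt = integer(),
                          stringsAsFactors = FALSE)
  for (id in orf_ids) {
    tx <- lnc_exons[lnc_exons$transcript_id == id, , drop = FALSE]
    # paint the cassette into the (contiguous) first exon; retried when a
    # shifted frame happens to beat the planted ORF
    big <- which.max(tx$end - tx$start)
    for (try in 1:50) {
      cas <- orf_cassette(spec$orf_nt)
      s <- genome_chr[[tx$chrom[1]]]
      # a stop codon immediately 5' of the cassette pins the ORF start at
      # the cassette's own ATG
      substr(s, tx$start[big] + 1L, tx$start[big] + 3L) <- "TAA"
      substr(s, tx$start[big] + 4L, tx$start[big] + 3L + spec$orf_nt) <- cas
      genome_chr[[tx$chrom[1]]] <- s
      spl <- spliced_sequence(tx, Biostrings::DNAStringSet(genome_chr[tx$chrom[1]]))
      if (longest_orf(spl) == spec$orf_nt) break
    }
    truth_orf[nrow(truth_orf) + 1L, ] <- list(id, spec$orf_nt)
  }
  genome <- Biostrings::DNAStringSet(genome_chr)

  # --- evidence lists over clean transcripts -------------------------------
  clean <- setdiff(
    truth_class$transcript_id,
    c(orf_ids, unlist(lapply(truth_filter_extra, `[[`, "transcript_id")))
  )
  evidence <- list()
  pool <- clean
  truth_filter_ev <- list()
  for (label in names(spec$n_evidence)) {
    k <- spec$n_evidence[[label]]
    if (k > 0L) {
      abort_if(k > length(pool), "infeasible: not enough clean transcripts for evidence lists")
      picked <- sample(pool, k)
      pool <- setdiff(pool, picked)
      evidence[[label]] <- picked
      truth_filter_ev[[label]] <- data.frame(
        transcript_id = picked, fate = paste0("removed_", label),
        stringsAsFactors = FALSE
      )
    }
  }
  truth_filter <- rbind(
    do.call(rbind, truth_filter_extra),
    do.call(rbind, unname(truth_filter_ev)),
    data.frame(transcript_id = pool, fate = rep("survivor", length(pool)),
               stringsAsFactors = FALSE)
  )
  # AS isoforms and class-planted transcripts not in truth_class are absent
  # from truth_filter only if never planted; ensure full coverage
  missing_ids <- setdiff(unique(lnc_exons$transcript_id), truth_filter$transcript_id)
  if (length(missing_ids)) {
    truth_filter <- rbind(truth_filter, data.frame(
      transcript_id = missing_ids, fate = "survivor", stringsAsFactors = FALSE
    ))
  }
  rownames(truth_filter) <- NULL

  # --- expression matrix ---------------------------------------------------
  gene_ids <- unique(coding$gene_id)
  lnc_ids <- unique(lnc_exons$transcript_id)
  all_ids <- c(lnc_ids, gene_ids)
  ns <- spec$n_samples
  mu <- rnorm(length(all_ids), 5, 1.5)
  x <- matrix(rnorm(length(all_ids) * ns, 0, spec$sigma),
              nrow = length(all_ids), dimnames = list(all_ids, sprintf("S%02d", seq_len(ns))))
  x <- x + mu

  # planted specific + decoy rows come first, then correlated pairs on the rest
  spec_rows <- head(lnc_ids, spec$n_specific)
  decoy_rows <- head(setdiff(lnc_ids, spec_rows), spec$n_specific_decoys)
  host_pairs <- if (length(truth_pairs_host)) do.call(rbind, truth_pairs_host) else
    data.frame(lnc_id = character(), gene_id = character(), stringsAsFactors = FALSE)
  host_pairs <- host_pairs[!host_pairs$lnc_id %in% c(spec_rows, decoy_rows) &
                             !is.na(host_pairs$gene_id), , drop = FALSE]
  # one latent factor per gene so that every lncRNA sharing a neighbour
  # gene stays correlated with it at rho
  for (g in unique(host_pairs$gene_id)) {
    z <- rnorm(ns)
    mix <- function(id) mu[match(id, all_ids)] +
      spec$sigma * (sqrt(spec$rho) * z + sqrt(1 - spec$rho) * rnorm(ns))
    x[g, ] <- mix(g)
    for (l in host_pairs$lnc_id[host_pairs$gene_id == g]) x[l, ] <- mix(l)
  }
  fpkm <- 2^x

  truth_specific <- data.frame(transcript_id = character(), sample_id = character(),
                               stringsAsFactors = FALSE)
  for (i in seq_along(spec_rows)) {
    s_j <- (i - 1L) %% ns + 1L
    fpkm[spec_rows[i], ] <- runif(ns, 0.05, 0.45)
    fpkm[spec_rows[i], s_j] <- runif(1, 4.6, 9)
    truth_specific[i, ] <- list(spec_rows[i], sprintf("S%02d", s_j))
  }
  if (length(decoy_rows)) {
    patterns <- c("fold", "hi", "lo")
    for (i in seq_along(decoy_rows)) {
      s_j <- (i - 1L) %% ns + 1L
      v <- runif(ns, 0.05, 0.45)
      p <- patterns[(i - 1L) %% 3L + 1L]
      if (p == "fold") { v[-s_j][1] <- 0.9; v[s_j] <- 5 }
      if (p == "hi") { v[s_j] <- 2 }
      if (p == "lo") { v[-s_j][1] <- 1.5; v[s_j] <- 8 }
      fpkm[decoy_rows[i], ] <- v
    }
  }

  truth_pairs <- host_pairs
  if (nrow(truth_pairs)) truth_pairs$true_rho <- spec$rho

  structure(
    list(
      genome = genome,
      coding_exons = coding,
      annotation = genome_annotation(coding),
      lnc_exons = validate_exons(lnc_exons),
      fpkm = fpkm,
      evidence = evidence,
      truth = list(
        class = truth_class,
        filter = truth_filter,
        orf = truth_orf,
        specific = truth_specific,
        pairs = truth_pairs
      ),
      spec = spec
    ),
    class = "fixture_set"
  )
}

#' Write a fixture set to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `lnc.gtf`, `fpkm.tsv`, evidence
#' lists (`evidence_<label>.txt`) and the truth tables
#' (`truth_<name>.tsv`), all plain text, parseable by the package readers.
#'
#' @param fx a `fixture_set` from [generate_fixtures()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(fx, dir) {
  abort_if(!inherits(fx, "fixture_set"), "fx must be a fixture_set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(fx$genome, file.path(dir, "genome.fa"), width = 80L)
  write_gff3(fx$coding_exons, file.path(dir, "annotation.gff3"))
  write_gtf(fx$lnc_exons, file.path(dir, "lnc.gtf"))
  fp <- data.frame(id = rownames(fx$fpkm), fx$fpkm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(fp, file.path(dir, "fpkm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (label in names(fx$evidence)) {
    writeLines(fx$evidence[[label]], file.path(dir, sprintf("evidence_%s.txt", label)))
  }
  for (nm in names(fx$truth)) {
    write.table(fx$truth[[nm]], file.path(dir, sprintf("truth_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write a gene -> mRNA -> exon annotation as GFF3
#'
#' @param exons exon table of the reference annotation (one or more
#'   transcripts per gene).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(exons, path) {
  exons <- validate_exons(exons)
  lines <- "##gff-version 3"
  for (gid in unique(exons$gene_id)) {
    g <- exons[exons$gene_id == gid, , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tlncloc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom[1], min(g$start) + 1L, max(g$end), g$strand[1], gid
    ))
    for (tid in unique(g$transcript_id)) {
      t <- g[g$transcript_id == tid, , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s\tlncloc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        t$chrom[1], min(t$start) + 1L, max(t$end), t$strand[1], tid, gid
      ))
      lines <- c(lines, sprintf(
        "%s\tlncloc\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        t$chrom, t$start + 1L, t$end, t$strand, tid, seq_len(nrow(t)), tid
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an FPKM matrix with planted sample-specific rows
#'
#' Background rows are lognormal noise; `n_specific` rows are overwritten
#' with a clean specific pattern (one sample between 4.6 and 9 FPKM, the
#' rest below 0.45); `n_decoys` rows fail exactly one of the three
#' specificity clauses and must not be called.
#'
#' @param n_rows,n_samples matrix dimensions.
#' @param n_specific,n_decoys planted and near-miss row counts.
#' @param sigma log2-scale noise sd for background rows.
#' @param seed RNG seed.
#' @return list with `m` (matrix), `truth` (data.frame `transcript_id`,
#'   `sample_id` of planted specific rows).
#' @export
simulate_specific_matrix <- function(n_rows = 1000L, n_samples = 6L,
                                     n_specific = 50L, n_decoys = 30L,
                                     sigma = 0.5, seed) {
  abort_if(missing(seed), "seed is mandatory")
  abort_if(n_specific + n_decoys > n_rows, "planted rows exceed n_rows")
  with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_rows))
    mu <- rnorm(n_rows, 5, 1.5)
    m <- 2^(mu + matrix(rnorm(n_rows * n_samples, 0, sigma), n_rows))
    dimnames(m) <- list(ids, sprintf("S%02d", seq_len(n_samples)))
    pick <- sample(n_rows, n_specific + n_decoys)
    sp <- pick[seq_len(n_specific)]
    dc <- pick[-seq_len(n_specific)]
    truth <- data.frame(transcript_id = character(), sample_id = character(),
                        stringsAsFactors = FALSE)
    for (i in seq_along(sp)) {
      j <- (i - 1L) %% n_samples + 1L
      m[sp[i], ] <- runif(n_samples, 0.05, 0.45)
      m[sp[i], j] <- runif(1, 4.6, 9)
      truth[i, ] <- list(ids[sp[i]], sprintf("S%02d", j))
    }
    patterns <- c("fold", "hi", "lo")
    for (i in seq_along(dc)) {
      j <- (i - 1L) %% n_samples + 1L
      v <- runif(n_samples, 0.05, 0.45)
      p <- patterns[(i - 1L) %% 3L + 1L]
      if (p == "fold") { v[-j][1] <- 0.9; v[j] <- 5 }
      if (p == "hi") { v[j] <- 2 }
      if (p == "lo") { v[-j][1] <- 1.5; v[j] <- 8 }
      m[dc[i], ] <- v
    }
    list(m = m, truth = truth)
  })
}

#' Simulate a two-group FPKM matrix with planted fold shifts
#'
#' Per-transcript baselines are drawn once, replicate noise is lognormal,
#' and the first `n_shifted` transcripts are multiplied by `fold` in the
#' second group. With `n_shifted = 0` the matrix is a pure null for
#' calibrating the differential caller.
#'
#' @param n_transcripts rows.
#' @param n_per_group replicate columns per group (two groups).
#' @param n_shifted planted differential rows.
#' @param fold expression ratio planted in group B.
#' @param sigma log2-scale replicate noise sd.
#' @param seed RNG seed.
#' @return list with `m`, `groups` (named vector column -> group) and
#'   `truth` (shifted transcript ids).
#' @export
simulate_diff_matrix <- function(n_transcripts = 2000L, n_per_group = 3L,
                                 n_shifted = 50L, fold = 8, sigma = 0.1, seed) {
  abort_if(missing(seed), "seed is mandatory")
  with_seed(seed, {
    ids <- sprintf("T%05d", seq_len(n_transcripts))
    cols <- c(sprintf("A%d", seq_len(n_per_group)), sprintf("B%d", seq_len(n_per_group)))
    mu <- rnorm(n_transcripts, 5, 1.5)
    x <- mu + matrix(rnorm(n_transcripts * 2L * n_per_group, 0, sigma), n_transcripts)
    if (n_shifted > 0L) {
      x[seq_len(n_shifted), n_per_group + seq_len(n_per_group)] <-
        x[seq_len(n_shifted), n_per_group + seq_len(n_per_group)] + log2(fold)
    }
    m <- 2^x
    dimnames(m) <- list(ids, cols)
    groups <- setNames(rep(c("A", "B"), each = n_per_group), cols)
    list(m = m, groups = groups, truth = head(ids, n_shifted))
  })
}

#' Simulate an expression fixture for the co-expression test
#'
#' `n_pairs` (lncRNA, gene) pairs share a latent factor giving log-scale
#' correlation `rho`; a pool of `n_pool` independent genes provides the
#' random-pair null.
#'
#' @param n_pairs neighbour pairs.
#' @param n_pool unrelated pool genes for the null.
#' @param n_samples expression samples.
#' @param rho planted log-scale correlation within pairs.
#' @param seed RNG seed.
#' @return list with `m`, `pairs` (data.frame `lnc_id`, `gene_id`) and
#'   `gene_pool` (ids).
#' @export
simulate_coexpression_fixture <- function(n_pairs = 60L, n_pool = 150L,
                                          n_samples = 12L, rho = 0.5, seed) {
  abort_if(missing(seed), "seed is mandatory")
  abort_if(rho < 0 || rho >= 1, "rho must be in [0, 1)")
  with_seed(seed, {
    lnc_ids <- sprintf("L%03d", seq_len(n_pairs))
    gene_ids <- sprintf("G%03d", seq_len(n_pairs))
    pool_ids <- sprintf("P%03d", seq_len(n_pool))
    z <- matrix(rnorm(n_pairs * n_samples), n_pairs)
    xl <- 5 + sqrt(rho) * z + sqrt(1 - rho) * matrix(rnorm(n_pairs * n_samples), n_pairs)
    xg <- 5 + sqrt(rho) * z + sqrt(1 - rho) * matrix(rnorm(n_pairs * n_samples), n_pairs)
    xp <- 5 + matrix(rnorm(n_pool * n_samples), n_pool)
    m <- 2^rbind(xl, xg, xp)
    rownames(m) <- c(lnc_ids, gene_ids, pool_ids)
    colnames(m) <- sprintf("S%02d", seq_len(n_samples))
    list(
      m = m,
      pairs = data.frame(lnc_id = lnc_ids, gene_id = gene_ids,
                         stringsAsFactors = FALSE),
      gene_pool = pool_ids
    )
  })
}
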