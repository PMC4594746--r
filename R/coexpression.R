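#' Nearest protein-coding gene for each lncRNA
#'
#' For every transcript, the reference gene minimising the span-to-span gap
#' on the same chromosome, ignoring strand. Distance is 0 when the spans
#' overlap; ties go to the smallest `gene_id`. Distances are binned as:
#' `overlap` (span overlap), `lt5k` (gap < 5 kb), `lt10k` (5 kb <= gap <
#' 10 kb), `ge10k` (gap >= 10 kb). Transcripts on a chromosome with no
#' gene get distance `Inf`, bin `ge10k`, and are flagged.
#'
#' @param exons exon table of lncRNA transcripts.
#' @param ann a [genome_annotation()].
#' @return data.frame with columns `lnc_id`, `nearest_gene_id`, `distance`,
#'   `bin`, `no_gene_on_chrom`.
#' @export
nearest_genes <- function(exons, ann) {
  exons <- validate_exons(exons)
  abort_if(!inherits(ann, "genome_annotation"), "ann must be a genome_annotation")
  spans <- transcript_spans(exons)
  lv <- union(unique(spans$chrom), unique(ann$genes$chrom))
  sp_gr <- GenomicRanges::GRanges(
    factor(spans$chrom, lv), IRanges::IRanges(spans$start + 1L, spans$end)
  )
  genes_gr <- GenomicRanges::GRanges(
    factor(ann$genes$chrom, lv),
    IRanges::IRanges(ann$genes$start + 1L, ann$genes$end)
  )
  hits <- GenomicRanges::distanceToNearest(sp_gr, genes_gr,
                                           ignore.strand = TRUE, select = "all")
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  nearest <- rep(NA_character_, nrow(spans))
  dist <- rep(Inf, nrow(spans))
  if (length(q)) {
    # ties: smallest gene_id
    ord <- order(q, ann$genes$gene_id[s])
    q <- q[ord]; s <- s[ord]; d <- d[ord]
    first <- !duplicated(q)
    nearest[q[first]] <- ann$genes$gene_id[s[first]]
    dist[q[first]] <- d[first]
  }
  overlaps <- GenomicRanges::countOverlaps(sp_gr, genes_gr, ignore.strand = TRUE) > 0L
  bin <- ifelse(overlaps, "overlap",
                ifelse(dist < 5000, "lt5k",
                       ifelse(dist < 10000, "lt10k", "ge10k")))
  data.frame(
    lnc_id = spans$transcript_id,
    nearest_gene_id = nearest,
    distance = dist,
    bin = bin,
    no_gene_on_chrom = is.na(nearest),
    stringsAsFactors = FALSE
  )
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation of two expression vectors, with the
#' degenerate cases rejected explicitly.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  abort_if(length(x) != length(y), "vectors differ in length")
  abort_if(length(x) < 3L, "need >= 3 paired observations")
  abort_if(stats::sd(x) == 0 || stats::sd(y) == 0,
           "correlation undefined for a constant vector")
  cor(x, y, method = "pearson")
}

#' Neighbour co-expression versus a random-pair null
#'
#' Computes the Pearson correlation of each (lncRNA, neighbouring gene)
#' expression pair, draws `n_random` random (lncRNA, non-neighbour gene)
#' pairs as a null, and compares the two correlation distributions with a
#' Welch two-sample t-test. Pairs whose `|r|` exceeds `strong_cut`
#' (default 0.8) are flagged as strongly correlated. The null never draws
#' a lncRNA's own neighbour gene(s). Results are reproducible
#' bit-for-bit under a fixed `seed`.
#'
#' @param pairs data.frame with columns `lnc_id`, `gene_id` (neighbour
#'   pairs, e.g. from [nearest_genes()]).
#' @param m FPKM matrix containing both lncRNA and gene rows.
#' @param n_random number of null pairs (must be >= `nrow(pairs)`).
#' @param seed RNG seed.
#' @param gene_pool candidate gene ids for the null; defaults to all
#'   neighbour gene ids in `pairs` plus any row of `m` not used as a
#'   lncRNA.
#' @param strong_cut threshold on `|r|` for the strong-correlation flag.
#' @return object of class `coexpression_result`: list with `pair_r`
#'   (per-pair data.frame with `r` and `strong`), `null_r`,
#'   `observed_mean_r`, `null_mean_r`, `statistic`, `p_value`,
#'   `strong_pairs`, `n_dropped` (pairs lost to missing ids or constant
#'   rows).
#' @export
coexpression_test <- function(pairs, m, n_random = 1000L, seed = 1L,
                              gene_pool = NULL, strong_cut = 0.8) {
  abort_if(!all(c("lnc_id", "gene_id") %in% names(pairs)),
           "pairs needs columns lnc_id and gene_id")
  abort_if(nrow(pairs) == 0L, "no neighbour pairs supplied")
  abort_if(n_random < nrow(pairs),
           "n_random (%d) must be >= the number of neighbour pairs (%d)",
           n_random, nrow(pairs))
  present <- pairs$lnc_id %in% rownames(m) & pairs$gene_id %in% rownames(m)
  n_dropped <- sum(!present)
  pairs <- pairs[present, , drop = FALSE]
  abort_if(nrow(pairs) == 0L, "no neighbour pair has both members in the matrix")

  # standardised rows: r(a, b) = sum(z_a * z_b) / (n - 1); constant rows
  # are dropped from both observed and null pairs
  sds <- apply(m, 1L, stats::sd)
  usable <- rownames(m)[sds > 0]
  const_pairs <- !(pairs$lnc_id %in% usable & pairs$gene_id %in% usable)
  n_dropped <- n_dropped + sum(const_pairs)
  pairs <- pairs[!const_pairs, , drop = FALSE]
  abort_if(nrow(pairs) == 0L, "all neighbour pairs dropped (constant rows?)")
  z <- t(scale(t(m[usable, , drop = FALSE])))
  r_of <- function(a, b) rowSums(z[a, , drop = FALSE] * z[b, , drop = FALSE]) / (ncol(m) - 1)

  r_obs <- unname(r_of(pairs$lnc_id, pairs$gene_id))

  if (is.null(gene_pool)) {
    gene_pool <- union(unique(pairs$gene_id), setdiff(rownames(m), pairs$lnc_id))
  }
  gene_pool <- intersect(gene_pool, usable)
  neighbours_of <- split(pairs$gene_id, pairs$lnc_id)
  lnc_ids <- unique(pairs$lnc_id)
  abort_if(length(gene_pool) < 2L, "gene pool too small for a null")

  null_pairs <- with_seed(seed, {
    ln <- sample(lnc_ids, n_random, replace = TRUE)
    gn <- sample(gene_pool, n_random, replace = TRUE)
    # resample draws that hit the lncRNA's own neighbours or itself
    repeat {
      bad <- mapply(function(l, g) g %in% neighbours_of[[l]] || g == l, ln, gn)
      if (!any(bad)) break
      gn[bad] <- sample(gene_pool, sum(bad), replace = TRUE)
    }
    data.frame(lnc_id = ln, gene_id = gn, stringsAsFactors = FALSE)
  })
  r_null <- unname(r_of(null_pairs$lnc_id, null_pairs$gene_id))

  if (length(r_obs) >= 2L && length(r_null) >= 2L) {
    tt <- t.test(r_obs, r_null)
  } else {
    message("fewer than two observed pairs: observed-vs-null test not performed")
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  }
  pair_r <- data.frame(
    lnc_id = pairs$lnc_id, gene_id = pairs$gene_id,
    r = r_obs, strong = abs(r_obs) > strong_cut,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      pair_r = pair_r,
      null_r = r_null,
      observed_mean_r = mean(r_obs),
      null_mean_r = mean(r_null),
      statistic = unname(tt$statistic),
      p_value = tt$p.value,
      strong_pairs = pair_r[pair_r$strong, , drop = FALSE],
      n_dropped = n_dropped
    ),
    class = "coexpression_result"
  )
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "coexpression_result: %d neighbour pairs vs %d random pairs\n",
      "  mean r (neighbours): %.3f; mean r (random): %.3f\n",
      "  Welch t = %.2f, p = %.3g; %d strong pair(s) (|r| > cutoff)\n"
    ),
    nrow(x$pair_r), length(x$null_r), x$observed_mean_r, x$null_mean_r,
    x$statistic, x$p_value, nrow(x$strong_pairs)
  ))
  invisible(x)
}
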