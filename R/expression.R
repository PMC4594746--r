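#' Read an FPKM expression matrix
#'
#' Tab-separated file with a header row of sample names and a first column
#' of transcript/gene ids. Missing cells are imputed as 0 with a message
#' reporting the imputation count; negative values are rejected.
#'
#' @param path TSV path.
#' @return numeric matrix, rows named by id, columns by sample.
#' @export
read_fpkm <- function(path) {
  abort_if(!file.exists(path), "FPKM file not found: %s", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 2L, "FPKM table needs an id column plus >= 1 sample")
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1]])
  n_na <- sum(is.na(m))
  if (n_na > 0L) {
    message(sprintf("imputed %d missing FPKM cell(s) as 0", n_na))
    m[is.na(m)] <- 0
  }
  abort_if(any(m < 0), "negative FPKM values")
  m
}

#' Call specifically-expressed transcripts
#'
#' A transcript is specifically expressed in sample `s` when all three
#' clauses hold: its FPKM in `s` exceeds `hi`; its FPKM in every other
#' sample is below `lo`; and its FPKM in `s` is at least `fold` times the
#' maximum over the other samples. With `hi >= lo` a transcript can be
#' specific in at most one sample. Defaults are the standard rule:
#' > 3 FPKM in one sample, < 1 FPKM elsewhere, >= 10-fold higher.
#'
#' @param m FPKM matrix (rows transcripts, columns samples).
#' @param hi expressed threshold (exclusive), default 3 FPKM.
#' @param lo silent threshold (exclusive) for the other samples, default 1.
#' @param fold minimum ratio to the strongest other sample, default 10.
#' @param compare compare the fold rule against the `"max"` (default,
#'   stricter) or the `"mean"` of the other samples.
#' @return data.frame with columns `transcript_id`, `sample_id`, `fpkm`,
#'   one row per specific call.
#' @export
call_specific <- function(m, hi = 3, lo = 1, fold = 10,
                          compare = c("max", "mean")) {
  compare <- match.arg(compare)
  abort_if(!is.matrix(m) || ncol(m) < 2L, "need a matrix with >= 2 samples")
  abort_if(any(m < 0), "negative FPKM values")
  top_j <- max.col(m, ties.method = "first")
  n <- nrow(m)
  top <- m[cbind(seq_len(n), top_j)]
  others_max <- numeric(n)
  others_stat <- numeric(n)
  for (i in seq_len(n)) {
    rest <- m[i, -top_j[i]]
    others_max[i] <- max(rest)
    others_stat[i] <- if (compare == "max") max(rest) else mean(rest)
  }
  ok <- top > hi & others_max < lo & top >= fold * others_stat
  out <- data.frame(
    transcript_id = rownames(m)[ok] %||% as.character(which(ok)),
    sample_id = colnames(m)[top_j[ok]] %||% as.character(top_j[ok]),
    fpkm = unname(top[ok]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# vectorised Welch two-sample t-test on the rows of two matrices
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  # degenerate variance: identical values give p = 1, se = 0 with a real
  # difference gives p = 0
  zero_se <- se2 == 0
  p[zero_se] <- ifelse(m1[zero_se] == m2[zero_se], 1, 0)
  list(statistic = tt, df = df, p = p, lfc = m1 - m2)
}

#' Call differentially-expressed transcripts between two groups
#'
#' Welch's two-sample t-test on `log2(FPKM + 1)` per transcript, with
#' Benjamini--Hochberg correction over all tested transcripts. A call
#' requires `p < p_cut` and `q < q_cut` (defaults p < 0.01, q < 0.05).
#' Both groups need at least two replicate columns; with single-replicate
#' groups only the log2 fold-change ranking is returned (no p-values),
#' with a warning.
#'
#' @param m FPKM matrix.
#' @param groups named character vector mapping each column name of `m` to
#'   one of exactly two group labels.
#' @param p_cut,q_cut significance cutoffs.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `log2fc` (group1 - group2 on the transformed scale), `p_value`,
#'   `q_value`, `called`; attribute `contrast` gives the group pair.
#' @export
call_differential <- function(m, groups, p_cut = 0.01, q_cut = 0.05) {
  abort_if(!is.matrix(m) || is.null(colnames(m)), "m must be a matrix with sample names")
  abort_if(is.null(names(groups)) || !all(colnames(m) %in% names(groups)),
           "groups must map every column of m to a group label")
  groups <- groups[colnames(m)]
  lev <- unique(groups)
  abort_if(length(lev) != 2L, "exactly two groups are required, got %d", length(lev))
  c1 <- which(groups == lev[1]); c2 <- which(groups == lev[2])
  abort_if(length(c1) == 0L || length(c2) == 0L, "a group has zero columns")
  lg <- log2(m + 1)
  if (length(c1) < 2L || length(c2) < 2L) {
    warning("a group has no replicates; returning fold-change ranking only (no test)",
            call. = FALSE)
    out <- data.frame(
      transcript_id = rownames(m) %||% as.character(seq_len(nrow(m))),
      log2fc = rowMeans(lg[, c1, drop = FALSE]) - rowMeans(lg[, c2, drop = FALSE]),
      p_value = NA_real_, q_value = NA_real_, called = FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    w <- welch_rows(lg[, c1, drop = FALSE], lg[, c2, drop = FALSE])
    q <- p.adjust(w$p, method = "BH")
    out <- data.frame(
      transcript_id = rownames(m) %||% as.character(seq_len(nrow(m))),
      log2fc = unname(w$lfc),
      p_value = unname(w$p),
      q_value = unname(q),
      called = unname(w$p < p_cut & q < q_cut),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  attr(out, "contrast") <- c(lev[1], lev[2])
  out
}

#' Average-linkage clustering of expression profiles
#'
#' Agglomerative UPGMA clustering of matrix rows on the distance
#' `1 - Pearson r` between expression profiles. Rows are ordered by row
#' name before clustering so that ties resolve deterministically by id.
#' Constant rows have undefined correlation; their r is treated as 0
#' (distance 1) and reported via a message.
#'
#' @param m expression matrix with >= 2 rows and row names.
#' @return list with `hclust` (the [stats::hclust] tree), `order` (leaf
#'   ids left to right) and `merge_heights`.
#' @export
cluster_expression <- function(m) {
  abort_if(!is.matrix(m) || nrow(m) < 2L, "need a matrix with >= 2 rows")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  const <- apply(m, 1L, function(r) stats::sd(r) == 0)
  r <- suppressWarnings(cor(t(m)))
  if (any(const)) {
    message(sprintf("%d constant row(s): correlation undefined, treated as 0", sum(const)))
  }
  r[is.na(r)] <- 0
  d <- 1 - r
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  list(
    hclust = hc,
    order = rownames(m)[hc$order],
    merge_heights = hc$height
  )
}
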