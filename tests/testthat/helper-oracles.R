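# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's vectorised/indexed code paths.

# six-frame longest ORF by walking codons from every ATG
oracle_longest_orf <- function(seq, both_strands = TRUE) {
  seq <- toupper(seq)
  rc <- lncloc::rev_comp(seq)
  strands <- if (both_strands) c(seq, rc) else seq
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in strands) {
    n <- nchar(s)
    for (i in seq_len(max(0L, n - 5L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i + 3L
      while (j + 2L <= n) {
        cod <- substr(s, j, j + 2L)
        if (cod %in% stops) {
          best <- max(best, j + 2L - i + 1L)
          break
        }
        j <- j + 3L
      }
    }
  }
  as.integer(best)
}

# simple per-transcript representation: list of (chrom, strand, exon matrix)
tx_list <- function(exons) {
  lapply(split(exons, exons$transcript_id), function(t) {
    t <- t[order(t$start), ]
    list(chrom = t$chrom[1], strand = t$strand[1],
         ex = cbind(t$start, t$end))
  })
}

iv_overlap <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

# exhaustive-rule location classifier: tests every rule against every gene
oracle_classify <- function(lnc_exons, ref_exons) {
  lncs <- tx_list(lnc_exons)
  genes <- split(ref_exons, ref_exons$gene_id)
  gene_info <- lapply(genes, function(g) {
    g <- g[order(g$start), ]
    introns <- NULL
    for (tid in unique(g$transcript_id)) {
      t <- g[g$transcript_id == tid, ]
      if (nrow(t) > 1L) {
        introns <- rbind(introns, cbind(t$end[-nrow(t)], t$start[-1]))
      }
    }
    list(chrom = g$chrom[1], strand = g$strand[1],
         ex = cbind(g$start, g$end), introns = introns,
         span = c(min(g$start), max(g$end)))
  })
  out <- data.frame(transcript_id = names(lncs),
                    lnc_class = NA_character_,
                    partner_gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  precedence <- c("JUNCTION_SHARED", "EXONIC_SENSE", "EXONIC_ANTISENSE",
                  "INTRONIC_SENSE", "INTRONIC_ANTISENSE")
  for (i in seq_along(lncs)) {
    t <- lncs[[i]]
    tspan <- c(min(t$ex[, 1]), max(t$ex[, 2]))
    tintrons <- if (nrow(t$ex) > 1L) cbind(t$ex[-nrow(t$ex), 2], t$ex[-1, 1]) else NULL
    span_overlap <- FALSE
    elig <- list()
    exbp <- list()
    for (gid in names(gene_info)) {
      g <- gene_info[[gid]]
      if (g$chrom != t$chrom) next
      if (iv_overlap(tspan[1], tspan[2], g$span[1], g$span[2]) > 0L) span_overlap <- TRUE
      # total exon-exon overlap
      bp <- 0L
      for (a in seq_len(nrow(t$ex))) for (b in seq_len(nrow(g$ex))) {
        bp <- bp + iv_overlap(t$ex[a, 1], t$ex[a, 2], g$ex[b, 1], g$ex[b, 2])
      }
      exbp[[gid]] <- bp
      same <- t$strand == g$strand
      opp <- (t$strand == "+" && g$strand == "-") || (t$strand == "-" && g$strand == "+")
      if (same && !is.null(tintrons) && !is.null(g$introns)) {
        for (a in seq_len(nrow(tintrons))) for (b in seq_len(nrow(g$introns))) {
          if (all(tintrons[a, ] == g$introns[b, ])) {
            elig$JUNCTION_SHARED <- c(elig$JUNCTION_SHARED, gid)
          }
        }
      }
      if (same && bp > 0L) elig$EXONIC_SENSE <- c(elig$EXONIC_SENSE, gid)
      if (opp && bp > 0L) elig$EXONIC_ANTISENSE <- c(elig$EXONIC_ANTISENSE, gid)
      if (same && !is.null(g$introns)) {
        for (b in seq_len(nrow(g$introns))) {
          if (tspan[1] >= g$introns[b, 1] && tspan[2] <= g$introns[b, 2]) {
            elig$INTRONIC_SENSE <- c(elig$INTRONIC_SENSE, gid)
          }
        }
      }
      if (opp && bp == 0L && !is.null(g$introns)) {
        hit <- FALSE
        for (a in seq_len(nrow(t$ex))) for (b in seq_len(nrow(g$introns))) {
          if (iv_overlap(t$ex[a, 1], t$ex[a, 2], g$introns[b, 1], g$introns[b, 2]) > 0L) hit <- TRUE
        }
        if (hit) elig$INTRONIC_ANTISENSE <- c(elig$INTRONIC_ANTISENSE, gid)
      }
    }
    cls <- NA_character_
    partner <- NA_character_
    if (t$strand == "*") {
      cls <- if (span_overlap) "UNCLASSIFIED" else "INTERGENIC"
    } else {
      for (cl in precedence) {
        gids <- unique(elig[[cl]])
        if (length(gids)) {
          cls <- cl
          bps <- unlist(exbp[gids])
          gids <- gids[bps == max(bps)]
          partner <- sort(gids)[1]
          break
        }
      }
      if (is.na(cls)) cls <- if (span_overlap) "UNCLASSIFIED" else "INTERGENIC"
    }
    out$lnc_class[i] <- cls
    out$partner_gene_id[i] <- partner
  }
  out
}

# O(n^2) union-find locus grouping
oracle_loci <- function(exons) {
  txs <- tx_list(exons)
  ids <- names(txs)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- txs[[i]]; b <- txs[[j]]
    if (a$chrom != b$chrom || a$strand != b$strand) next
    ov <- FALSE
    for (p in seq_len(nrow(a$ex))) for (q in seq_len(nrow(b$ex))) {
      if (iv_overlap(a$ex[p, 1], a$ex[p, 2], b$ex[q, 1], b$ex[q, 2]) > 0L) ov <- TRUE
    }
    if (ov) parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_along(ids), find, 0L)
  split(ids, comp)
}

# naive O(n^3) UPGMA on a distance matrix; returns sorted merge heights
oracle_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  active <- rep(TRUE, length(clusters))
  heights <- numeric(0)
  dist_cc <- function(a, b) mean(d[a, b])
  while (sum(active) > 1L) {
    best <- Inf; bi <- bj <- NA
    idx <- which(active)
    for (i in idx) for (j in idx) {
      if (i < j) {
        dd <- dist_cc(clusters[[i]], clusters[[j]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    active[bj] <- FALSE
  }
  sort(heights)
}

# all-pairs span-to-span nearest gene
oracle_nearest <- function(lnc_exons, ref_exons) {
  lspans <- lapply(tx_list(lnc_exons), function(t)
    list(chrom = t$chrom, s = min(t$ex[, 1]), e = max(t$ex[, 2])))
  gspans <- lapply(split(ref_exons, ref_exons$gene_id), function(g)
    list(chrom = g$chrom[1], s = min(g$start), e = max(g$end)))
  out <- data.frame(lnc_id = names(lspans), nearest_gene_id = NA_character_,
                    distance = Inf, stringsAsFactors = FALSE)
  for (i in seq_along(lspans)) {
    l <- lspans[[i]]
    for (gid in sort(names(gspans))) {
      g <- gspans[[gid]]
      if (g$chrom != l$chrom) next
      d <- max(0L, max(l$s, g$s) - min(l$e, g$e))
      if (d < out$distance[i]) {
        out$distance[i] <- d
        out$nearest_gene_id[i] <- gid
      }
    }
  }
  out
}

# compact exon-table builder: list of c(start, end) per transcript
mk_tx <- function(id, chrom, strand, ..., gene_id = id) {
  ex <- list(...)
  data.frame(
    transcript_id = id, gene_id = gene_id, chrom = chrom, strand = strand,
    start = vapply(ex, `[`, 0, 1), end = vapply(ex, `[`, 0, 2),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# random multi-exon transcript set for locus-grouping tests
make_random_tx_set <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    n_ex <- sample(1:3, 1)
    s <- sort(sample(seq(0, 4000, by = 20), n_ex))
    e <- s + sample(10:120, n_ex, replace = TRUE)
    e <- pmin(e, c(s[-1], Inf) - 1)
    data.frame(transcript_id = sprintf("t%03d", i), gene_id = sprintf("t%03d", i),
               chrom = sample(c("chr1", "chr2"), 1), strand = sample(c("+", "-"), 1),
               start = s, end = e, stringsAsFactors = FALSE)
  }))
}
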