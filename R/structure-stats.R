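#' Structural feature summary of a transcript set
#'
#' Summarises exon-count distribution, transcript/exon/intron lengths and,
#' when a locus table is supplied, the alternative-splicing fraction (the
#' share of loci with at least two isoforms) and the loci with the most
#' isoforms.
#'
#' Exon and intron means are computed per exon / per intron by default
#' (every interval weighs equally); `per_transcript = TRUE` instead
#' averages per-transcript means.
#'
#' @param exons exon table.
#' @param loci optional output of [group_loci()] over the same transcripts.
#' @param per_transcript average exon/intron lengths within transcripts
#'   first (default `FALSE`).
#' @return an object of class `structure_summary`: list with
#'   `exon_count_hist` (named integer vector), `exon_count_pct`,
#'   `n_transcripts`, `mean_transcript_length`, `median_transcript_length`,
#'   `mean_exon_length`, `mean_intron_length` (`NaN` when intron-free),
#'   `as_fraction` and `max_isoform_loci` (`NULL` without `loci`).
#' @export
structure_summary <- function(exons, loci = NULL, per_transcript = FALSE) {
  abort_if(is.null(exons) || nrow(exons) == 0L, "empty transcript set")
  exons <- validate_exons(exons)
  lens <- transcript_length(exons)
  n_ex <- table(exons$transcript_id)[lens$transcript_id]
  hist <- table(as.integer(n_ex))
  hist <- setNames(as.integer(hist), names(hist))
  introns <- transcript_introns(exons)
  if (per_transcript) {
    mean_exon <- mean(tapply(exons$end - exons$start, exons$transcript_id, mean))
    mean_intron <- if (nrow(introns)) {
      mean(tapply(introns$end - introns$start, introns$transcript_id, mean))
    } else {
      NaN
    }
  } else {
    mean_exon <- mean(exons$end - exons$start)
    mean_intron <- if (nrow(introns)) mean(introns$end - introns$start) else NaN
  }
  as_fraction <- NULL
  max_isoform_loci <- NULL
  if (!is.null(loci)) {
    abort_if(!setequal(loci$transcript_id, lens$transcript_id),
             "loci must partition exactly the supplied transcripts")
    sizes <- table(loci$locus_id)
    as_fraction <- sum(sizes >= 2L) / length(sizes)
    mx <- max(sizes)
    max_isoform_loci <- data.frame(
      locus_id = names(sizes)[sizes == mx],
      n_isoforms = as.integer(mx),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      exon_count_hist = hist,
      exon_count_pct = round_half_up(100 * hist / sum(hist), 2),
      n_transcripts = nrow(lens),
      mean_transcript_length = mean(lens$length),
      median_transcript_length = median(lens$length),
      mean_exon_length = mean_exon,
      mean_intron_length = mean_intron,
      as_fraction = as_fraction,
      max_isoform_loci = max_isoform_loci
    ),
    class = "structure_summary"
  )
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "structure_summary: %d transcripts\n",
      "  mean/median transcript length: %.1f / %.1f nt\n",
      "  mean exon length: %.1f nt; mean intron length: %.1f nt\n"
    ),
    x$n_transcripts, x$mean_transcript_length, x$median_transcript_length,
    x$mean_exon_length, x$mean_intron_length
  ))
  if (!is.null(x$as_fraction)) {
    cat(sprintf("  alternative splicing fraction: %.3f\n", x$as_fraction))
  }
  invisible(x)
}

#' Side-by-side comparison of two structure summaries
#'
#' Pairs the scalar fields of two [structure_summary()] objects (e.g.
#' lncRNA vs protein-coding transcripts) and reports their difference.
#'
#' @param a,b `structure_summary` objects.
#' @param labels column labels for the two groups.
#' @return data.frame with columns `metric`, the two group values, and
#'   `delta` (a - b).
#' @export
compare_groups <- function(a, b, labels = c("a", "b")) {
  abort_if(!inherits(a, "structure_summary") || !inherits(b, "structure_summary"),
           "both arguments must be structure_summary objects")
  fields <- c(
    "n_transcripts", "mean_transcript_length", "median_transcript_length",
    "mean_exon_length", "mean_intron_length"
  )
  va <- vapply(fields, function(f) as.numeric(a[[f]]), 0)
  vb <- vapply(fields, function(f) as.numeric(b[[f]]), 0)
  if (!is.null(a$as_fraction) && !is.null(b$as_fraction)) {
    fields <- c(fields, "as_fraction")
    va <- c(va, a$as_fraction)
    vb <- c(vb, b$as_fraction)
  }
  out <- data.frame(metric = fields, va, vb, delta = va - vb,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- labels
  rownames(out) <- NULL
  out
}

#' Binned length distribution
#'
#' Histogram counts of interval lengths on a fixed grid — the computational
#' half of the density panels (plotting left to the caller).
#'
#' @param lengths numeric vector of lengths (nt).
#' @param breaks bin breakpoints; defaults to 50 equal bins over the range.
#' @return data.frame with `bin_start`, `bin_end`, `count`, `density`.
#' @export
length_bins <- function(lengths, breaks = NULL) {
  abort_if(length(lengths) == 0L, "no lengths supplied")
  if (is.null(breaks)) {
    breaks <- seq(min(lengths), max(lengths) + 1, length.out = 51L)
  }
  h <- graphics::hist(lengths, breaks = breaks, plot = FALSE)
  data.frame(
    bin_start = h$breaks[-length(h$breaks)],
    bin_end = h$breaks[-1],
    count = h$counts,
    density = h$density
  )
}
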