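test_that("GTF reading converts coordinates and sorts exons", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t100\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tx\texon\t500\t600\t.\t+\t.\ttranscript_id "t2"; gene_id "g2";',
    'chr1\tx\texon\t300\t400\t.\t+\t.\ttranscript_id "t2"; gene_id "g2";'
  ), gtf)
  ex <- read_gtf(gtf)
  t1 <- ex[ex$transcript_id == "t1", ]
  expect_equal(c(t1$start, t1$end), c(99, 200))
  expect_equal(transcript_length(ex)$length, c(101L, 202L))
  t2 <- ex[ex$transcript_id == "t2", ]
  expect_equal(t2$start, c(299, 499)) # sorted ascending
})

test_that("malformed GTF lines are rejected with a line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t100\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    "chr1\tonly three fields"
  ), gtf)
  expect_error(read_gtf(gtf), "line 2")
  writeLines(c(
    'chr1\tx\texon\t300\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";'
  ), gtf)
  expect_error(read_gtf(gtf), "end.*start")
})

test_that("duplicate transcript ids across chromosomes are an error", {
  ex <- rbind(
    mk_tx("t1", "chr1", "+", c(0, 100)),
    mk_tx("t1", "chr2", "+", c(0, 100))
  )
  expect_error(write_gtf(ex, tempfile()), "chromosomes")
})

test_that("unknown strand warns on assembled input and fails for references", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(
    'chr1\tx\texon\t100\t200\t.\t.\t.\ttranscript_id "t1"; gene_id "g1";',
    gtf
  )
  expect_warning(ex <- read_gtf(gtf), "unknown strand")
  expect_equal(ex$strand, "*")
  expect_error(suppressWarnings(read_annotation(gtf, format = "gtf")), "strand")
})

test_that("GTF round-trip preserves models and exon counts match a line-count oracle", {
  exs <- do.call(rbind, lapply(1:5, function(i) {
    n_ex <- c(3, 2, 1, 4, 2)[i]
    starts <- seq(0, by = 500, length.out = n_ex) + (i - 1) * 10000
    data.frame(transcript_id = sprintf("t%d", i), gene_id = sprintf("g%d", i),
               chrom = "chr1", strand = c("+", "-", "+", "+", "-")[i],
               start = starts, end = starts + 100 + 7 * i,
               stringsAsFactors = FALSE)
  }))
  p1 <- tempfile(fileext = ".gtf"); p2 <- tempfile(fileext = ".gtf")
  write_gtf(exs, p1)
  r1 <- read_gtf(p1)
  write_gtf(r1, p2)
  r2 <- read_gtf(p2)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 12L)
  # line-count oracle over the raw file
  lines <- readLines(p1)
  counts <- table(sub('.*transcript_id "([^"]+)".*', "\\1", lines))
  expect_equal(as.integer(counts[sprintf("t%d", 1:5)]),
               as.integer(table(r1$transcript_id)[sprintf("t%d", 1:5)]))
})

test_that("transcript length equals a per-base bitmask oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n_ex <- sample(1:5, 1)
    starts <- sort(sample(0:900, n_ex)) * 10
    ends <- starts + sample(10:200, n_ex)
    ends <- pmin(ends, c(starts[-1], Inf) - 1)
    ex <- data.frame(transcript_id = "t", gene_id = "t", chrom = "c", strand = "+",
                     start = starts, end = ends, stringsAsFactors = FALSE)
    mask <- logical(20000)
    for (i in seq_len(n_ex)) mask[(starts[i] + 1):ends[i]] <- TRUE
    expect_equal(transcript_length(ex)$length, sum(mask))
  }
})

test_that("introns are the exon gaps and tile the span with exons", {
  ex <- mk_tx("t", "chr1", "+", c(0, 100), c(200, 300))
  intr <- transcript_introns(ex)
  expect_equal(c(intr$start, intr$end), c(100, 200))
  expect_equal(nrow(transcript_introns(mk_tx("s", "chr1", "+", c(0, 100)))), 0L)

  four <- mk_tx("t4", "chr1", "-", c(10, 50), c(90, 140), c(200, 260), c(400, 430))
  intr4 <- transcript_introns(four)
  expect_equal(nrow(intr4), 3L)
  # tiling oracle: exons + introns cover the span exactly once
  span <- c(min(four$start), max(four$end))
  covered <- integer(0)
  for (i in seq_len(nrow(four))) covered <- c(covered, (four$start[i] + 1):four$end[i])
  for (i in seq_len(nrow(intr4))) covered <- c(covered, (intr4$start[i] + 1):intr4$end[i])
  expect_equal(sort(covered), (span[1] + 1):span[2])
  # invariant: transcript length + intron lengths = span length
  expect_equal(transcript_length(four)$length + sum(intr4$end - intr4$start),
               span[2] - span[1])
})

test_that("locus grouping matches the pairwise union-find oracle", {
  two <- rbind(mk_tx("a", "chr1", "+", c(0, 100)),
               mk_tx("b", "chr1", "+", c(50, 150)))
  expect_equal(length(unique(group_loci(two)$locus_id)), 1L)
  opp <- rbind(mk_tx("a", "chr1", "+", c(0, 100)),
               mk_tx("b", "chr1", "-", c(0, 100)))
  expect_equal(length(unique(group_loci(opp)$locus_id)), 2L)

  ex <- make_random_tx_set(50, seed = 13)
  got <- group_loci(ex)
  partition <- unname(lapply(split(got$transcript_id, got$locus_id), sort))
  want <- unname(lapply(oracle_loci(ex), sort))
  expect_setequal(
    vapply(partition, paste, "", collapse = ","),
    vapply(want, paste, "", collapse = ",")
  )
})

test_that("locus grouping is invariant to input order", {
  ex <- make_random_tx_set(40, seed = 5)
  base <- group_loci(ex)
  key <- function(g) sort(vapply(split(g$transcript_id, g$locus_id),
                                 function(v) paste(sort(v), collapse = ","), ""))
  for (s in 1:3) {
    set.seed(s)
    perm <- ex[sample(nrow(ex)), ]
    expect_equal(key(group_loci(perm)), key(base))
  }
})
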