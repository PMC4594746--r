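test_that("longest_orf handles the canonical cases", {
  expect_equal(longest_orf("ATGAAATAA"), 9L)      # single complete ORF
  expect_equal(longest_orf("CCCCCC"), 0L)         # no start codon
  expect_equal(longest_orf("ATGAAAAAA"), 0L)      # truncated: no stop
  # codons containing N are neither start nor stop, but the walk continues
  expect_equal(longest_orf("ATGNAATAA"), 9L)      # N mid-ORF is tolerated
  expect_equal(longest_orf("NTGAAATAA"), 0L)      # N kills the start codon
  expect_equal(longest_orf("ATGAATNAA"), 0L)      # N kills the stop codon
  # reverse-strand ORF is found
  expect_equal(longest_orf(rev_comp("ATGAAATAA")), 9L)
  # forward-only mode misses it
  expect_equal(longest_orf(rev_comp("ATGAAATAA"), both_strands = FALSE), 0L)
})

test_that("longest_orf equals the exhaustive per-ATG scanner on random sequences", {
  set.seed(20)
  for (i in 1:40) {
    s <- random_dna(sample(50:400, 1))
    expect_equal(longest_orf(s), oracle_longest_orf(s), info = s)
  }
})

test_that("longest_orf is symmetric under reverse complement", {
  set.seed(33)
  for (i in 1:20) {
    s <- random_dna(300)
    expect_equal(longest_orf(s), longest_orf(rev_comp(s)))
  }
})

test_that("spliced_sequence extracts and orients exon sequence", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTTACGTACGTAAGG"))
  plus <- mk_tx("p", "chr1", "+", c(2, 8))
  expect_equal(spliced_sequence(plus, genome), "CCGGTT")
  minus <- mk_tx("m", "chr1", "-", c(2, 8))
  expect_equal(spliced_sequence(minus, genome), rev_comp("CCGGTT"))
  # two-exon minus strand: reverse complement of the genomic concatenation
  m2 <- mk_tx("m2", "chr1", "-", c(0, 4), c(10, 16))
  seqs <- substr("AACCGGTTACGTACGTAAGG", 1, 4)
  seqs2 <- substr("AACCGGTTACGTACGTAAGG", 11, 16)
  expect_equal(spliced_sequence(m2, genome), rev_comp(paste0(seqs, seqs2)))
  # out-of-bounds exon
  expect_error(spliced_sequence(mk_tx("x", "chr1", "+", c(10, 99)), genome), "bounds")
})

test_that("size rule removes short and single-exon transcripts", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 500), collapse = "")))
  ex <- rbind(
    mk_tx("short", "chr1", "+", c(0, 70), c(100, 180)),      # 150 nt, 2 exons
    mk_tx("single", "chr1", "+", c(200, 700)),               # 500 nt, 1 exon
    mk_tx("keep", "chr1", "+", c(800, 950), c(1000, 1100))   # 250 nt, 2 exons
  )
  res <- run_cascade(ex, genome, cfg = filter_config(max_orf = Inf))
  expect_setequal(res$survivor_ids, "keep")
  expect_equal(res$report$removed[res$report$step == "length_exons"], 2L)
})

test_that("cascade survivors equal the independent set-algebra oracle", {
  sp <- fixture_spec(
    seed = 404, lnc_counts = c(INTERGENIC = 20L, EXONIC_SENSE = 6L, INTRONIC_SENSE = 6L),
    n_short = 4L, n_single_exon = 4L, n_orf = 4L,
    n_evidence = c(protein_hit = 3L, utr_fragment = 2L, coding_potential = 2L,
                   pfam_domain = 1L, structural_ncrna = 1L)
  )
  fx <- generate_fixtures(sp)
  res <- run_cascade(fx$lnc_exons, fx$genome, fx$evidence)

  # oracle: apply each rule independently with plain arithmetic, intersect
  ex <- fx$lnc_exons
  ids <- unique(ex$transcript_id)
  chr_str <- as.character(fx$genome)
  pass <- vapply(ids, function(id) {
    t <- ex[ex$transcript_id == id, ]
    t <- t[order(t$start), ]
    if (sum(t$end - t$start) < 200 || nrow(t) < 2) return(FALSE)
    s <- paste(substring(chr_str[[t$chrom[1]]], t$start + 1, t$end), collapse = "")
    if (t$strand[1] == "-") s <- rev_comp(s)
    if (oracle_longest_orf(s) >= 300) return(FALSE)
    !id %in% unlist(fx$evidence)
  }, TRUE)
  expect_setequal(res$survivor_ids, ids[pass])

  # report telescopes and matches the planted truth
  expect_true(all(res$report$input - res$report$removed == res$report$surviving))
  expect_equal(res$report$surviving[nrow(res$report)], sum(pass))
  tr <- fx$truth$filter
  expect_setequal(res$survivor_ids, tr$transcript_id[tr$fate == "survivor"])
  expect_equal(res$report$removed[res$report$step == "orf"], 4L)
})

test_that("survivors satisfy every rule regardless of cascade bookkeeping", {
  sp <- fixture_spec(seed = 77, lnc_counts = c(INTERGENIC = 15L), n_orf = 3L,
                     n_evidence = c(protein_hit = 2L))
  fx <- generate_fixtures(sp)
  res <- run_cascade(fx$lnc_exons, fx$genome, fx$evidence)
  surv <- res$survivors
  lens <- transcript_length(surv)
  expect_true(all(lens$length >= 200))
  expect_true(all(table(surv$transcript_id) >= 2))
  orfs <- vapply(spliced_sequences(surv, fx$genome), longest_orf, 0L)
  expect_true(all(orfs < 300))
  expect_false(any(res$survivor_ids %in% unlist(fx$evidence)))
})

test_that("stale evidence ids are warned about, not fatal", {
  ex <- mk_tx("keep", "chr1", "+", c(0, 150), c(300, 500))
  expect_warning(
    res <- run_cascade(ex, evidence = list(protein_hit = c("ghost")),
                       cfg = filter_config(max_orf = Inf)),
    "stale"
  )
  expect_equal(res$stale_evidence$protein_hit, "ghost")
  expect_setequal(res$survivor_ids, "keep")
})

test_that("tabular BLAST parsing applies the e-value cutoff", {
  p <- tempfile()
  writeLines(c(
    "t1\tsp1\t90\t100\t0\t0\t1\t100\t1\t100\t1e-10\t200",
    "t2\tsp2\t88\t100\t0\t0\t1\t100\t1\t100\t0.5\t50",
    "t3\tsp3\t88\t100\t0\t0\t1\t100\t1\t100\t9e-4\t50"
  ), p)
  expect_setequal(read_blast_outfmt6(p), c("t1", "t3"))
  expect_setequal(read_blast_outfmt6(p, max_evalue = 1e-6), "t1")
})
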