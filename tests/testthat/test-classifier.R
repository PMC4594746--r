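# a compact hand-built reference: one gene per strand with 3 exons each
ref_two_genes <- function() {
  rbind(
    mk_tx("gA.t1", "chr1", "+", c(1000, 1200), c(2000, 2300), c(5000, 5400),
          gene_id = "gA"),
    mk_tx("gB.t1", "chr1", "-", c(20000, 20500), c(24000, 24800),
          gene_id = "gB")
  )
}

test_that("each location rule fires on its canonical configuration", {
  ann <- genome_annotation(ref_two_genes())
  cases <- list(
    # entirely inside intron 1 of gA, same strand
    list(mk_tx("t", "chr1", "+", c(1300, 1450), c(1600, 1750)), "INTRONIC_SENSE", "gA"),
    # same span, opposite strand, exons only in the intron
    list(mk_tx("t", "chr1", "-", c(1300, 1450), c(1600, 1750)), "INTRONIC_ANTISENSE", "gA"),
    # exon overlaps gA exon 2 on the same strand (junction not shared)
    list(mk_tx("t", "chr1", "+", c(2100, 2400), c(2600, 2800)), "EXONIC_SENSE", "gA"),
    # same structure, opposite strand
    list(mk_tx("t", "chr1", "-", c(2100, 2400), c(2600, 2800)), "EXONIC_ANTISENSE", "gA"),
    # shares gA's intron 2 exactly: junction beats the exonic overlap
    list(mk_tx("t", "chr1", "+", c(2200, 2300), c(5000, 5100)), "JUNCTION_SHARED", "gA"),
    # far from every gene
    list(mk_tx("t", "chr1", "+", c(40000, 40200), c(40400, 40600)), "INTERGENIC", NA),
    # same strand, exons in intron but span not within it (residual)
    list(mk_tx("t", "chr1", "+", c(900, 950), c(1300, 1400)), NA, NA)
  )
  for (i in seq_along(cases)) {
    got <- classify_transcripts(cases[[i]][[1]], ann)
    if (!is.na(cases[[i]][[2]])) {
      expect_equal(got$lnc_class, cases[[i]][[2]], info = paste("case", i))
    }
    if (!is.na(cases[[i]][[3]])) {
      expect_equal(got$partner_gene_id, cases[[i]][[3]], info = paste("case", i))
    }
  }
  # the residual case: exon overlaps gA's first exon? no -- (900,950) is
  # upstream of gA, (1300,1400) inside intron 1; span overlaps the gene but
  # no rule fires
  got <- classify_transcripts(cases[[7]][[1]], ann)
  expect_equal(got$lnc_class, "UNCLASSIFIED")
  expect_true(is.na(got$partner_gene_id))
})

test_that("unstranded transcripts are unclassified only when they touch a gene", {
  ann <- genome_annotation(ref_two_genes())
  inside <- mk_tx("u1", "chr1", "*", c(1300, 1450), c(1600, 1750))
  away <- mk_tx("u2", "chr1", "*", c(40000, 40200), c(40400, 40600))
  expect_equal(classify_transcripts(inside, ann)$lnc_class, "UNCLASSIFIED")
  expect_equal(classify_transcripts(away, ann)$lnc_class, "INTERGENIC")
})

test_that("a chromosome absent from the annotation is intergenic with a warning", {
  ann <- genome_annotation(ref_two_genes())
  t <- mk_tx("t", "chrUn", "+", c(100, 300), c(500, 700))
  expect_warning(got <- classify_transcripts(t, ann), "absent")
  expect_equal(got$lnc_class, "INTERGENIC")
})

test_that("classification is strand-flip symmetric", {
  flip <- function(ex) {
    ex$strand <- ifelse(ex$strand == "+", "-", ifelse(ex$strand == "-", "+", "*"))
    ex
  }
  ref <- ref_two_genes()
  ts <- rbind(
    mk_tx("a", "chr1", "+", c(1300, 1450), c(1600, 1750)),
    mk_tx("b", "chr1", "-", c(2100, 2400), c(2600, 2800)),
    mk_tx("c", "chr1", "+", c(40000, 40200), c(40500, 40800))
  )
  r1 <- classify_transcripts(ts, genome_annotation(ref))
  r2 <- classify_transcripts(flip(ts), genome_annotation(flip(ref)))
  expect_equal(r1$lnc_class, r2$lnc_class)
  expect_equal(r1$partner_gene_id, r2$partner_gene_id)
})

test_that("planted fixture classes are fully recovered and agree with the exhaustive oracle", {
  sp <- fixture_spec(
    seed = 501,
    lnc_counts = c(INTERGENIC = 10L, INTRONIC_SENSE = 6L, INTRONIC_ANTISENSE = 6L,
                   EXONIC_SENSE = 6L, EXONIC_ANTISENSE = 6L, JUNCTION_SHARED = 6L,
                   UNCLASSIFIED = 6L),
    as_fraction = 0
  )
  fx <- generate_fixtures(sp)
  got <- classify_transcripts(fx$lnc_exons, fx$annotation)
  tr <- fx$truth$class
  m <- match(tr$transcript_id, got$transcript_id)
  expect_equal(got$lnc_class[m], tr$true_class)
  ok <- is.na(tr$true_partner) | got$partner_gene_id[m] == tr$true_partner
  expect_true(all(ok))
  orc <- oracle_classify(fx$lnc_exons, fx$coding_exons)
  m2 <- match(orc$transcript_id, got$transcript_id)
  expect_equal(got$lnc_class[m2], orc$lnc_class)
  expect_equal(got$partner_gene_id[m2], orc$partner_gene_id)
})

test_that("every transcript gets exactly one class and moving far away gives intergenic", {
  ann <- genome_annotation(ref_two_genes())
  t <- mk_tx("t", "chr1", "+", c(2100, 2400), c(2600, 2800))
  got <- classify_transcripts(t, ann)
  expect_equal(nrow(got), 1L)
  shifted <- t
  shifted$start <- shifted$start + 10^6
  shifted$end <- shifted$end + 10^6
  expect_equal(classify_transcripts(shifted, ann)$lnc_class, "INTERGENIC")
})

test_that("naming follows the gene-set scheme with collision and isoform suffixes", {
  # two intergenic loci, one antisense, two sense-exonic loci on one gene,
  # and an unclassified locus with 10 isoforms
  ann <- genome_annotation(ref_two_genes())
  ex <- rbind(
    mk_tx("i1", "chr1", "+", c(30000, 30200), c(30400, 30600)),
    mk_tx("i2", "chr1", "+", c(32000, 32200), c(32400, 32600)),
    mk_tx("as1", "chr1", "-", c(2100, 2400), c(2600, 2800)),
    mk_tx("ot1", "chr1", "+", c(2100, 2400), c(2600, 2800)),
    mk_tx("ot2", "chr1", "+", c(5300, 5600), c(5800, 6000)),
    do.call(rbind, lapply(1:10, function(k) {
      mk_tx(sprintf("u%02d", k), "chr1", "*", c(1300, 1500), c(1600, 1700 + 10 * k))
    }))
  )
  recs <- classify_transcripts(ex, ann)
  named <- assign_names(recs, group_loci(ex), prefix = "BPH")
  nm <- setNames(named$assigned_name, named$transcript_id)
  expect_equal(unname(nm["i1"]), "BPHLINC1")
  expect_equal(unname(nm["i2"]), "BPHLINC2")
  expect_equal(unname(nm["as1"]), "gA-AS")
  # two distinct sense loci on gA collide on the base name
  expect_setequal(unname(nm[c("ot1", "ot2")]), c("gA-OT", "gA-OT2"))
  # ten unclassified isoforms of one locus: -RA ... -RJ
  expect_setequal(unname(nm[sprintf("u%02d", 1:10)]),
                  paste0("BPHLNC-unc1-R", LETTERS[1:10]))
  expect_equal(sum(named$isoform_suffix != ""), 10L)
})

test_that("intronic names use -IT for sense and -AS for antisense by default", {
  ann <- genome_annotation(ref_two_genes())
  ex <- rbind(
    mk_tx("itx", "chr1", "+", c(1300, 1450), c(1600, 1750)),
    mk_tx("asx", "chr1", "-", c(3000, 3200), c(3400, 3600))
  )
  recs <- classify_transcripts(ex, ann)
  named <- assign_names(recs, group_loci(ex))
  nm <- setNames(named$assigned_name, named$transcript_id)
  expect_equal(unname(nm["itx"]), "gA-IT")
  expect_equal(unname(nm["asx"]), "gA-AS")
  named2 <- assign_names(recs, group_loci(ex), intronic_antisense_suffix = "IT")
  expect_equal(named2$assigned_name[named2$transcript_id == "asx"], "gA-IT2")
})

test_that("class tables reproduce the published arithmetic", {
  counts <- c(
    INTERGENIC = 853, INTRONIC_SENSE = 80, INTRONIC_ANTISENSE = 5,
    EXONIC_SENSE = 385, EXONIC_ANTISENSE = 211, JUNCTION_SHARED = 264,
    UNCLASSIFIED = 641
  )
  ct <- class_table(counts)
  expect_equal(attr(ct, "total"), 2439)
  expect_equal(ct$percentage[ct$lnc_class == "INTERGENIC"], 34.97)
  expect_equal(ct$percentage[ct$lnc_class == "INTRONIC_SENSE"], 3.28)
  expect_equal(ct$percentage[ct$lnc_class == "INTRONIC_ANTISENSE"], 0.21)
  expect_equal(ct$percentage[ct$lnc_class == "EXONIC_SENSE"], 15.79)
  expect_equal(ct$percentage[ct$lnc_class == "EXONIC_ANTISENSE"], 8.65)
  expect_equal(ct$percentage[ct$lnc_class == "UNCLASSIFIED"], 26.28)
  expect_lt(abs(sum(ct$percentage) - 100), 0.02 + 1e-9)
})

test_that("single-class input yields 100.00 percent and empty input an empty table", {
  one <- data.frame(lnc_class = rep("INTERGENIC", 7), stringsAsFactors = FALSE)
  ct <- class_table(one)
  expect_equal(ct$percentage[ct$lnc_class == "INTERGENIC"], 100)
  empty <- class_table(data.frame(lnc_class = character()))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "total"), 0L)
})
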