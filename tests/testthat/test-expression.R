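test_that("FPKM reading imputes missing cells and round-trips", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "t1\t1.5\t2.5", "t2\t\t0.1"), p)
  expect_message(m <- read_fpkm(p), "imputed 1")
  expect_equal(m["t2", "S1"], 0)
  expect_equal(m["t1", ], c(S1 = 1.5, S2 = 2.5))
})

test_that("the specificity rule is a strict conjunction of its three clauses", {
  m <- rbind(
    fold_fails = c(5.0, 0.8, 0.2),   # 5 < 10 * 0.8 -> no call
    all_pass = c(5.0, 0.45, 0.2),    # 5 > 3; others < 1; 5 >= 4.5
    hi_fails = c(2.5, 0.1, 0.05),
    lo_fails = c(9.0, 1.2, 0.1)
  )
  colnames(m) <- c("A", "B", "C")
  calls <- call_specific(m)
  expect_equal(calls$transcript_id, "all_pass")
  expect_equal(calls$sample_id, "A")
  # a 12.5-fold case passes all three clauses
  one <- matrix(c(5.0, 0.4, 0.2), 1, dimnames = list("t", c("A", "B", "C")))
  expect_equal(call_specific(one)$sample_id, "A")
  expect_error(call_specific(m[, 1, drop = FALSE]), "2 samples")
})

test_that("planted specific rows are recovered exactly, decoys excluded", {
  sim <- simulate_specific_matrix(n_rows = 200, n_samples = 6, n_specific = 15,
                                  n_decoys = 12, seed = 9)
  calls <- call_specific(sim$m)
  got <- calls[order(calls$transcript_id), ]
  want <- sim$truth[order(sim$truth$transcript_id), ]
  expect_equal(got$transcript_id, want$transcript_id)
  expect_equal(got$sample_id, want$sample_id)
  # brute-force per-cell rule evaluation agrees
  brute <- do.call(rbind, lapply(rownames(sim$m), function(id) {
    v <- sim$m[id, ]
    for (j in seq_along(v)) {
      if (v[j] > 3 && all(v[-j] < 1) && v[j] >= 10 * max(v[-j])) {
        return(data.frame(transcript_id = id, sample_id = colnames(sim$m)[j]))
      }
    }
    NULL
  }))
  expect_equal(got$transcript_id, brute$transcript_id[order(brute$transcript_id)])
})

test_that("specific calls are invariant under joint rescaling of matrix and thresholds", {
  sim <- simulate_specific_matrix(n_rows = 100, n_samples = 5, n_specific = 10,
                                  n_decoys = 6, seed = 3)
  base <- call_specific(sim$m)
  for (c_scale in c(0.2, 7)) {
    scaled <- call_specific(sim$m * c_scale, hi = 3 * c_scale, lo = 1 * c_scale)
    expect_equal(scaled$transcript_id, base$transcript_id)
    expect_equal(scaled$sample_id, base$sample_id)
  }
})

test_that("differential calls match a per-row t.test oracle on a worked matrix", {
  set.seed(12)
  m <- matrix(2^rnorm(30, 4), 5,
              dimnames = list(sprintf("t%d", 1:5), sprintf("s%d", 1:6)))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  got <- call_differential(m, groups)
  lg <- log2(m + 1)
  for (i in 1:5) {
    tt <- t.test(lg[i, 1:3], lg[i, 4:6])
    expect_equal(got$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(got$log2fc[i], unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-12)
  }
  expect_equal(got$q_value, p.adjust(got$p_value, "BH"))
})

test_that("identical groups give p = 1 and no calls; q is monotone in p rank", {
  m <- matrix(rep(c(2, 2, 2, 2), each = 3), nrow = 3, byrow = FALSE,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  groups <- setNames(rep(c("A", "B"), each = 2), colnames(m))
  got <- call_differential(m, groups)
  expect_true(all(got$p_value == 1))
  expect_false(any(got$called))

  sim <- simulate_diff_matrix(n_transcripts = 300, n_shifted = 20, seed = 5)
  res <- call_differential(sim$m, sim$groups)
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_true(all(res$p_value[res$called] < 0.01))
})

test_that("planted fold shifts are recalled and a no-replicate design degrades gracefully", {
  sim <- simulate_diff_matrix(n_transcripts = 1000, n_shifted = 30, fold = 8, seed = 21)
  res <- call_differential(sim$m, sim$groups)
  recall <- mean(sim$truth %in% res$transcript_id[res$called])
  expect_gte(recall, 0.9)

  m1 <- sim$m[, c(1, 4), drop = FALSE]
  expect_warning(
    r1 <- call_differential(m1, setNames(c("A", "B"), colnames(m1))),
    "no replicates"
  )
  expect_true(all(is.na(r1$p_value)))
  expect_false(any(r1$called))
})

test_that("UPGMA clustering on correlation distance matches the naive oracle", {
  # two identical rows merge first at height 0
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  cl <- cluster_expression(m)
  expect_equal(cl$merge_heights[1], 0)            # r(a, b) = 1
  expect_setequal(-cl$hclust$merge[1, ], c(1, 2)) # a and b merge first

  set.seed(8)
  m12 <- matrix(rnorm(12 * 6), 12, dimnames = list(sprintf("r%02d", 1:12), NULL))
  cl12 <- cluster_expression(m12)
  d <- 1 - cor(t(m12[order(rownames(m12)), ]))
  expect_equal(sort(cl12$merge_heights), oracle_upgma_heights(d), tolerance = 1e-10)
})

test_that("clustering is invariant to row permutation and tolerates constant rows", {
  set.seed(30)
  m <- matrix(rnorm(8 * 5), 8, dimnames = list(sprintf("r%d", 1:8), NULL))
  h1 <- cluster_expression(m)$merge_heights
  h2 <- cluster_expression(m[sample(8), ])$merge_heights
  expect_equal(h1, h2, tolerance = 1e-12)

  mc <- rbind(m, const = rep(3, 5))
  expect_message(clc <- cluster_expression(mc), "constant")
  expect_equal(length(clc$order), 9L)
})
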