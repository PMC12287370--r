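test_that("CPM, MC and L2FC follow their defining arithmetic", {
  expect_equal(cpm(c(5, 15, 80), 100), c(50000, 150000, 800000))
  expect_equal(cpm(0, 10), 0)
  expect_equal(cpm(100, 100), 1e6)
  expect_error(cpm(1:3, 0), "positive")

  expect_equal(mean_counts(10, 20), 15)
  expect_equal(mean_counts(0, 0), 0)
  expect_equal(mean_counts(9, 10), 9.5)  # fails MC >= 10 by construction

  expect_equal(log2_fc(3, 31), 3)
  expect_equal(log2_fc(7, 7), 0)
  expect_equal(log2_fc(0, 0), 0)  # +1 pseudocount prevents -Inf
})

test_that("CPM vectors of a condition sum to one million", {
  set.seed(3)
  counts <- rpois(500, 50)
  expect_equal(sum(cpm(counts, sum(counts))), 1e6, tolerance = 1e-9)
})

# A 5-transcript matrix engineered so exactly 2 transcripts pass all
# three clauses and each of three others fails exactly one clause.
engineered_matrix <- function() {
  # collapsed (replicate-average) parental / resistant counts:
  #   t1: strong up, passes everything
  #   t2: strong up, dominates both libraries, passes everything
  #   t3: fails only MC (9.5 < 10)
  #   t4: fails only |L2FC| (log2 ratio exactly 1 < 2)
  #   t5: fails only CPM (<= 0.5 in both conditions thanks to t2's bulk)
  par_c <- c(t1 = 20, t2 = 4e6, t3 = 3, t4 = 500, t5 = 1)
  res_c <- c(t1 = 200, t2 = 1e8, t3 = 16, t4 = 1001, t5 = 20)
  # duplicate as two identical replicates so averaging is exercised
  counts <- cbind(par_c, par_c, res_c, res_c)
  rownames(counts) <- names(par_c)
  samples <- data.frame(
    sample = c("L_parental_1", "L_parental_2", "L_resistant_1", "L_resistant_2"),
    line = "L", state = rep(c("parental", "resistant"), each = 2),
    replicate = c(1:2, 1:2), stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample
  count_matrix(counts, samples)
}

test_that("each filter clause excludes exactly the transcript engineered to fail it", {
  m <- engineered_matrix()
  res <- altered_transcripts(m, "L")
  tab <- res$table
  expect_setequal(res$altered, c("t1", "t2"))

  # verify each exclusion is attributable to exactly one clause
  t3 <- tab[tab$transcript_id == "t3", ]
  expect_lt(t3$mc, 10)
  expect_gt(abs(t3$l2fc), 2)
  expect_gt(max(t3$cpm_parental, t3$cpm_resistant), 0.5)

  t4 <- tab[tab$transcript_id == "t4", ]
  expect_lte(abs(t4$l2fc), 2)
  expect_gte(t4$mc, 10)
  expect_gt(max(t4$cpm_parental, t4$cpm_resistant), 0.5)

  t5 <- tab[tab$transcript_id == "t5", ]
  expect_lte(max(t5$cpm_parental, t5$cpm_resistant), 0.5)
  expect_gte(t5$mc, 10)
  expect_gt(abs(t5$l2fc), 2)
})

test_that("threshold inequalities are strict/non-strict exactly as specified", {
  m <- engineered_matrix()
  tab <- altered_transcripts(m, "L")$table
  # MC >= 10 is non-strict: t3 at exactly 9.5 fails, a 10 would pass
  expect_equal(tab$mc[tab$transcript_id == "t3"], 9.5)
  # |L2FC| > 2 is strict: t4 sits at exactly 1.0 (log2(1002/501))
  expect_equal(tab$l2fc[tab$transcript_id == "t4"], 1)
  # raising any threshold never increases the altered count
  base <- length(altered_transcripts(m, "L")$altered)
  for (th in list(diff_thresholds(cpm_min = 5),
                  diff_thresholds(mc_min = 100),
                  diff_thresholds(l2fc_min = 4))) {
    expect_lte(length(altered_transcripts(m, "L", th)$altered), base)
  }
})

test_that("identical parental and resistant columns yield no altered transcripts", {
  counts <- matrix(rpois(40, 100), 10, 4,
                   dimnames = list(sprintf("t%02d", 1:10), NULL))
  counts[, 3:4] <- counts[, 1:2]
  samples <- data.frame(sample = paste0("s", 1:4), line = "L",
                        state = rep(c("parental", "resistant"), each = 2),
                        replicate = c(1:2, 1:2), stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample
  m <- count_matrix(counts, samples)
  expect_length(altered_transcripts(m, "L")$altered, 0)
})

test_that("the filter is idempotent on its own output", {
  cm <- simulate_counts(n_transcripts = 800, n_spiked = 10, seed = 21)
  r1 <- altered_transcripts(cm, "SIM")
  keep <- r1$table$transcript_id[r1$table$altered]
  if (length(keep) >= 1) {
    sub <- count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
    r2 <- altered_transcripts(sub, "SIM")
    # L2FC and MC are per-transcript and unchanged; CPM can only grow
    # when the library shrinks, so the altered set is preserved
    expect_setequal(r2$altered, keep)
  }
})

test_that("count matrices round-trip through the TSV layout", {
  cm <- simulate_counts(n_transcripts = 50, n_spiked = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_count_matrix(path)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$samples$state, cm$samples$state)
  expect_equal(back$samples$line, rep("SIM", 4))
})

test_that("venn arithmetic satisfies inclusion-exclusion", {
  v <- venn(c("a", "b"), c("c"))
  expect_equal(v$union, 2 + 1)
  expect_equal(v$both, 0)
  v2 <- venn(letters[1:5], letters[1:5])
  expect_equal(v2$only_a, 0)
  expect_equal(v2$only_b, 0)
  expect_equal(v2$union, 5)
  set.seed(17)
  for (i in 1:50) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    v <- venn(a, b)
    expect_equal(v$union, length(unique(c(a, b))))
    expect_equal(v$union, v$only_a + v$only_b + v$both)
    expect_equal(v$both, sum(unique(a) %in% b))
  }
})
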