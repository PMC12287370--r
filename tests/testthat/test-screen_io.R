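test_that("screen tables round-trip through CSV with headers normalized", {
  path <- withr::local_tempfile(fileext = ".csv")
  toy_screen_csv(path)
  tab <- read_screen_table(path)
  expect_s3_class(tab, "screen_table")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$signal, c(8000, 6000, 3000, 2200, 10000, 2000))

  # capitalized headers give the identical result
  caps <- withr::local_tempfile(fileext = ".csv")
  toy_screen_csv(caps,
    header = "Sample_ID,Treatment_ID,Treatment_Type,Concentration_nM,Replicate,Signal,Well_Role")
  expect_identical(read_screen_table(caps), tab)

  # write/read reproduces all numeric fields to full precision
  out <- withr::local_tempfile(fileext = ".csv")
  tab2 <- tab
  tab2$signal[1] <- 8000 + pi * 1e-8
  write_screen_table(tab2, out)
  back <- read_screen_table(out)
  expect_identical(back$signal, tab2$signal)
  expect_identical(back$concentration_nM, tab2$concentration_nM)
})

test_that("schema and parse errors name the offending column or line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,treatment_id,treatment_type,concentration_nM,replicate,signal",
               "S1,drugA,single,10,1,8000"), path)
  expect_error(read_screen_table(path), "well_role")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,treatment_id,treatment_type,concentration_nM,replicate,signal,well_role",
               "S1,drugA,single,10,1,oops,compound",
               "S1,,,,1,10000,neg_ctrl",
               "S1,,,,1,2000,pos_ctrl"), bad)
  expect_error(read_screen_table(bad), "line.*2")
})

test_that("viability normalization maps controls to 100/0 and is affine-invariant", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- read_screen_table(toy_screen_csv(path))

  # signal equal to mean_neg -> 100; equal to mean_pos -> 0; midpoint arithmetic
  tab2 <- tab
  tab2$signal[tab2$well_role == "compound"] <- c(10000, 2000, 6000, 6000)
  nv <- normalize_viability(tab2, "S1")
  expect_equal(nv$viability_pct, c(100, 0, 50, 50))
  expect_equal(nv$n_replicates, rep(1L, 4))

  # scaling every signal by k > 0 leaves viability unchanged
  tab3 <- tab
  tab3$signal <- tab3$signal * 3.7
  expect_equal(normalize_viability(tab3, "S1")$viability_pct,
               normalize_viability(tab, "S1")$viability_pct)
})

test_that("replicate-mean viability equals viability of the replicate-mean signal", {
  sig <- c(7000, 5000, 6600)
  tab <- data.frame(
    sample_id = "S1", treatment_id = c(rep("d", 3), "", ""),
    treatment_type = c(rep("single", 3), "", ""),
    concentration_nM = c(rep(100, 3), NA, NA),
    replicate = c(1:3, 1, 1),
    signal = c(sig, 10000, 2000),
    well_role = c(rep("compound", 3), "neg_ctrl", "pos_ctrl"),
    stringsAsFactors = FALSE)
  nv <- normalize_viability(validate_screen_table(tab), "S1")
  expect_equal(nv$viability_pct, 100 * (mean(sig) - 2000) / 8000)
  expect_equal(nv$n_replicates, 3L)
  expect_equal(nv$viability_sd, sd(100 * (sig - 2000) / 8000))
})

test_that("degenerate controls and missing samples raise errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- read_screen_table(toy_screen_csv(path))
  expect_error(normalize_viability(tab, "nope"), "not present")
  swapped <- tab
  swapped$signal[swapped$well_role == "neg_ctrl"] <- 1500  # below pos ctrl
  expect_error(normalize_viability(swapped, "S1"), "degenerate")
})

test_that("treatment libraries parse components, targets and series", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lib <- read_treatment_library(toy_library_tsv(path))
  expect_s3_class(lib, "treatment_library")
  ixa <- lib[lib$treatment_id == "ixazomib", ]
  expect_equal(ixa$series[[1]], c(1, 10, 100, 1000, 10000))
  expect_equal(ixa$targets[[1]], "PSMB5")
  expect_equal(lib$targets[lib$treatment_id == "venetoclax"][[1]],
               c("BCL2", "BCL2L1"))
  expect_equal(lib$components[lib$treatment_id == "ven_ixa"][[1]],
               c("venetoclax", "ixazomib"))

  dup <- withr::local_tempfile(fileext = ".tsv")
  toy_library_tsv(dup, "ixazomib\tsingle\tixazomib\tPSMB5\t1;10")
  expect_error(read_treatment_library(dup), "duplicate")

  noser <- withr::local_tempfile(fileext = ".tsv")
  toy_library_tsv(noser, "empty\tsingle\tempty\tX\t")
  expect_error(read_treatment_library(noser), "series")
})
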