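# Shared fixtures and independent oracles, built in code at test time.

# Closed-form logistic, written out independently of the package path.
logistic_ref <- function(x, top, bottom, e, h) {
  bottom + (top - bottom) / (1 + 10^(h * (x - e)))
}

# Independent DSS oracle: dense trapezoid on the clipped inhibition
# curve (10,001-point grid by default).
dss_trapezoid <- function(top, bottom, e, h, x_min, x_max,
                          floor = 10, n = 10001) {
  x <- seq(x_min, x_max, length.out = n)
  v <- logistic_ref(x, top, bottom, e, h)
  y <- pmin(pmax(100 - v, 0), 100 - floor)
  auc <- sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
  100 * auc / ((100 - floor) * (x_max - x_min))
}

# Minimal valid screen table: one compound series plus controls.
toy_screen_csv <- function(path,
                           header = "sample_id,treatment_id,treatment_type,concentration_nM,replicate,signal,well_role") {
  writeLines(c(
    header,
    "S1,drugA,single,10,1,8000,compound",
    "S1,drugA,single,100,1,6000,compound",
    "S1,drugA,single,1000,1,3000,compound",
    "S1,drugA,single,10000,1,2200,compound",
    "S1,,,,1,10000,neg_ctrl",
    "S1,,,,1,2000,pos_ctrl"
  ), path)
  path
}

toy_library_tsv <- function(path, extra_rows = character()) {
  writeLines(c(
    "treatment_id\ttype\tcomponents\ttargets\tseries",
    "ixazomib\tsingle\tixazomib\tPSMB5\t1;10;100;1000;10000",
    "venetoclax\tsingle\tvenetoclax\tBCL2;BCL2L1\t1;10;100;1000;10000",
    "ven_ixa\tcombination\tvenetoclax;ixazomib\tBCL2;PSMB5\t1;10;100;1000;10000",
    extra_rows
  ), path)
  path
}

# A dss_table-shaped summary data frame for TAS tests.
dss_summary_df <- function(treatment_id, dss_mean, sample_id = "S1") {
  data.frame(sample_id = sample_id, treatment_id = treatment_id,
             n_experiments = 1L, dss_mean = dss_mean, dss_sd = NA_real_,
             stringsAsFactors = FALSE)
}

# Small treatment library built directly (no file round-trip).
library_from_targets <- function(targets_by_treatment,
                                 series = 10^(0:4)) {
  ids <- names(targets_by_treatment)
  lib <- data.frame(treatment_id = ids,
                    type = "single", stringsAsFactors = FALSE)
  lib$components <- as.list(ids)
  lib$targets <- lapply(targets_by_treatment, function(x) sort(unique(x)))
  lib$series <- rep(list(series), length(ids))
  validate_treatment_library(lib)
}
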