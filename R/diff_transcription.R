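# Count-based differential-transcription filter for paired
# parental/resistant cell lines: CPM > 0.5, MC >= 10, |L2FC| > 2 with a
# +1 pseudocount, applied per line, plus Venn summarization of the
# altered sets across lines.

#' Counts per million
#'
#' \eqn{CPM_i = counts_i / librarySum \times 10^6}.
#'
#' @param counts Non-negative count vector.
#' @param library_sum Positive library size (sum of counts of the
#'   condition the vector belongs to). Defaults to \code{sum(counts)}.
#' @return Numeric vector of CPM values.
#' @export
cpm <- function(counts, library_sum = sum(counts)) {
  if (!is.finite(library_sum) || library_sum <= 0) {
    stop("library_sum must be positive")
  }
  counts / library_sum * 1e6
}

#' Mean of counts between the paired conditions
#'
#' @param parental,resistant Non-negative counts.
#' @return \code{(parental + resistant) / 2}.
#' @export
mean_counts <- function(parental, resistant) {
  (parental + resistant) / 2
}

#' Log2 fold change with a +1 pseudocount
#'
#' Resistant over parental: \eqn{\log_2(resistant + 1) -
#' \log_2(parental + 1)}; the pseudocount keeps zero counts finite.
#'
#' @param parental,resistant Non-negative counts.
#' @return Numeric log2 fold change.
#' @export
log2_fc <- function(parental, resistant) {
  log2(resistant + 1) - log2(parental + 1)
}

#' Thresholds and conventions for the differential filter
#'
#' @param cpm_min CPM threshold (strict: CPM must exceed it).
#' @param mc_min Mean-of-counts threshold (non-strict: MC >= mc_min).
#' @param l2fc_min Absolute log2-fold-change threshold (strict).
#' @param cpm_rule Whether the CPM clause must hold in \code{"either"}
#'   condition (default, the permissive standard for expression
#'   filters) or in \code{"both"}.
#' @param replicates How replicate counts are collapsed to one value
#'   per condition before CPM/MC/L2FC: \code{"average"} (default) or
#'   \code{"sum"}.
#' @return A list of class \code{"diff_thresholds"}.
#' @export
diff_thresholds <- function(cpm_min = 0.5, mc_min = 10, l2fc_min = 2,
                            cpm_rule = c("either", "both"),
                            replicates = c("average", "sum")) {
  structure(list(cpm_min = cpm_min, mc_min = mc_min, l2fc_min = l2fc_min,
                 cpm_rule = match.arg(cpm_rule),
                 replicates = match.arg(replicates)),
            class = "diff_thresholds")
}

#' Construct a transcript count matrix with sample annotations
#'
#' @param counts Non-negative integer matrix, transcripts x samples,
#'   with transcript ids as row names.
#' @param samples Data frame with one row per column of \code{counts}:
#'   \code{sample}, \code{line}, \code{state} (\code{"parental"} or
#'   \code{"resistant"}), \code{replicate}.
#' @return An object of class \code{"count_matrix"}.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have transcript row names")
  if (nrow(samples) != ncol(counts)) {
    stop("samples must describe every column of counts")
  }
  stopifnot(all(c("sample", "line", "state", "replicate") %in% names(samples)))
  if (any(!samples$state %in% c("parental", "resistant"))) {
    stop("state must be 'parental' or 'resistant'")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  structure(list(counts = counts, samples = as.data.frame(samples)),
            class = "count_matrix")
}

#' Read a transcript count matrix from TSV
#'
#' First column \code{transcript_id}; remaining column headers encode
#' \code{line_state_replicate} (e.g. \code{KARPAS1718_parental_1}).
#'
#' @param path Path to the TSV file.
#' @return A \code{"count_matrix"}.
#' @export
read_count_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- raw[[1]]
  hdr <- colnames(counts)
  parts <- regmatches(hdr, regexec("^(.*)_(parental|resistant)_([0-9]+)$", hdr))
  bad <- vapply(parts, length, 1L) != 4
  if (any(bad)) {
    stop("cannot parse sample header(s): ",
         paste(sQuote(hdr[bad]), collapse = ", "),
         " (expected line_state_replicate)")
  }
  samples <- data.frame(
    sample = hdr,
    line = vapply(parts, `[`, "", 2),
    state = vapply(parts, `[`, "", 3),
    replicate = as.integer(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, samples)
}

#' Apply the differential-transcription filter to one cell line
#'
#' Collapses replicate counts to one parental and one resistant value
#' per transcript (average by default), computes CPM against the
#' collapsed library sum of each condition, MC as the mean of the two
#' condition values, and L2FC with the +1 pseudocount, then flags a
#' transcript as altered iff CPM exceeds \code{cpm_min} (in at least
#' one condition by default), MC >= \code{mc_min}, and |L2FC| >
#' \code{l2fc_min} - the inequalities strict/non-strict exactly as
#' listed.
#'
#' @param m A \code{"count_matrix"}.
#' @param line Cell line to analyze (lines are analyzed separately).
#' @param thresholds A [diff_thresholds()].
#' @return An object of class \code{"diff_result"}: list with
#'   \code{table} (per-transcript data frame: counts, CPM per
#'   condition, \code{mc}, \code{l2fc}, \code{altered}),
#'   \code{altered} (character vector of transcript ids) and
#'   \code{line}.
#' @export
altered_transcripts <- function(m, line, thresholds = diff_thresholds()) {
  stopifnot(inherits(m, "count_matrix"), inherits(thresholds, "diff_thresholds"))
  sel <- m$samples$line == line
  if (!any(sel)) stop("line ", sQuote(line), " not present")
  collapse <- function(state) {
    cols <- which(sel & m$samples$state == state)
    if (length(cols) == 0) {
      stop("line ", sQuote(line), " lacks ", state, " samples")
    }
    mat <- m$counts[, cols, drop = FALSE]
    if (thresholds$replicates == "average") rowMeans(mat) else rowSums(mat)
  }
  par_c <- collapse("parental")
  res_c <- collapse("resistant")

  cpm_p <- cpm(par_c, sum(par_c))
  cpm_r <- cpm(res_c, sum(res_c))
  mc <- mean_counts(par_c, res_c)
  l2fc <- log2_fc(par_c, res_c)

  cpm_pass <- if (thresholds$cpm_rule == "either") {
    pmax(cpm_p, cpm_r) > thresholds$cpm_min
  } else {
    pmin(cpm_p, cpm_r) > thresholds$cpm_min
  }
  altered <- cpm_pass & (mc >= thresholds$mc_min) &
    (abs(l2fc) > thresholds$l2fc_min)

  tab <- data.frame(
    transcript_id = rownames(m$counts),
    count_parental = unname(par_c),
    count_resistant = unname(res_c),
    cpm_parental = unname(cpm_p),
    cpm_resistant = unname(cpm_r),
    mc = unname(mc),
    l2fc = unname(l2fc),
    altered = unname(altered),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, altered = tab$transcript_id[tab$altered],
                 line = line, thresholds = thresholds),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("Differential-transcription filter [%s]: %d of %d transcripts altered\n",
              x$line, length(x$altered), nrow(x$table)))
  invisible(x)
}

#' Run the filter on two lines and summarize the overlap
#'
#' Applies [altered_transcripts()] to each line separately and returns
#' the Venn summary of the two altered sets together with the per-line
#' results.
#'
#' @param m A \code{"count_matrix"} containing both lines.
#' @param line_a,line_b The two cell lines to compare.
#' @param thresholds A [diff_thresholds()].
#' @return List with \code{a}, \code{b} (the two
#'   \code{"diff_result"}s) and \code{venn} (a
#'   \code{"venn_summary"}).
#' @export
diff_venn <- function(m, line_a, line_b, thresholds = diff_thresholds()) {
  a <- altered_transcripts(m, line_a, thresholds)
  b <- altered_transcripts(m, line_b, thresholds)
  list(a = a, b = b, venn = venn(a$altered, b$altered))
}

#' Venn summary of two altered-transcript sets
#'
#' @param set_a,set_b Character vectors of transcript ids (duplicates
#'   ignored).
#' @return An object of class \code{"venn_summary"}: list with
#'   \code{only_a}, \code{only_b}, \code{both} and \code{union}
#'   (\code{union = only_a + only_b + both}).
#' @export
venn <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  both <- length(intersect(a, b))
  structure(list(only_a = length(a) - both, only_b = length(b) - both,
                 both = both, union = length(union(a, b))),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("Venn: only A %d | both %d | only B %d (union %d)\n",
              x$only_a, x$both, x$only_b, x$union))
  invisible(x)
}
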