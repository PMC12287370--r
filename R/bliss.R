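# Bliss independence synergy scoring of combination dose-response
# surfaces (full matrices and 1:1 fixed-molar diagonals), with the
# -10/+10 classification bounds.

#' Construct a combination dose-response matrix
#'
#' @param doses_a,doses_b Ascending dose vectors in nM, each beginning
#'   with 0 (the monotherapy row/column of the other drug).
#' @param viability Viability matrix (\%), \code{length(doses_a)} rows x
#'   \code{length(doses_b)} columns; cell [1, 1] is the untreated well
#'   and is renormalized to exactly 100 to define the zero-inhibition
#'   baseline.
#' @return An object of class \code{"combination_matrix"}.
#' @export
combination_matrix <- function(doses_a, doses_b, viability) {
  viability <- as.matrix(viability)
  if (length(doses_a) != nrow(viability) ||
      length(doses_b) != ncol(viability)) {
    stop("viability must be length(doses_a) x length(doses_b)")
  }
  if (doses_a[1] != 0 || doses_b[1] != 0) {
    stop("dose vectors must start with 0 (monotherapy row/column)")
  }
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE)) {
    stop("doses must be strictly ascending")
  }
  if (any(!is.finite(viability))) stop("viability must be finite")
  viability[1, 1] <- 100
  dimnames(viability) <- list(doses_a, doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 viability = viability),
            class = "combination_matrix")
}

#' Read a combination matrix from TSV
#'
#' Expects the layout used for dose-response matrices: first row and
#' first column hold the doses in nM (including 0), the body holds
#' viability in \%.
#'
#' @param path Path to the TSV file.
#' @return A \code{"combination_matrix"}.
#' @export
read_combination_matrix <- function(path) {
  raw <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  doses_a <- as.numeric(raw[-1, 1])
  doses_b <- as.numeric(raw[1, -1])
  v <- matrix(as.numeric(raw[-1, -1]), nrow = length(doses_a))
  combination_matrix(doses_a, doses_b, v)
}

#' Write a combination matrix to TSV
#'
#' @param m A \code{"combination_matrix"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_combination_matrix <- function(m, path) {
  body <- rbind(c(NA, m$doses_b), cbind(m$doses_a, m$viability))
  utils::write.table(body, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

.classify_bliss_levels <- c("antagonistic", "additive", "synergistic")

#' Classify a Bliss synergy score
#'
#' Scores below -10 are antagonistic, from -10 to 10 (boundaries
#' inclusive) additive, above 10 synergistic.
#'
#' @param score Finite numeric score (percentage-point excess).
#' @return One of \code{"antagonistic"}, \code{"additive"},
#'   \code{"synergistic"}.
#' @export
classify_bliss <- function(score) {
  if (length(score) != 1 || !is.finite(score)) {
    stop("score must be a single finite number")
  }
  if (score < -10) "antagonistic"
  else if (score > 10) "synergistic"
  else "additive"
}

.bliss_result <- function(excess, score, n_cells) {
  structure(list(excess = excess, score = score,
                 call = classify_bliss(score), n_cells = n_cells),
            class = "bliss_result")
}

#' Bliss excess of a full combination matrix
#'
#' Converts viability to inhibition fractions clipped to [0, 1],
#' \eqn{f = \mathrm{clip}((100 - v)/100, 0, 1)}, computes the Bliss
#' independence expectation from the monotherapy row/column,
#' \eqn{E_{ij} = f_{i0} + f_{0j} - f_{i0} f_{0j}}, and reports the
#' observed-minus-expected excess in percentage points per cell. The
#' summary score is the arithmetic mean of the excess over combination
#' cells only (both doses > 0).
#'
#' @param m A \code{"combination_matrix"}.
#' @return An object of class \code{"bliss_result"} with \code{excess}
#'   (matrix over combination cells), \code{score}, \code{call} and
#'   \code{n_cells}.
#' @export
bliss_matrix <- function(m) {
  stopifnot(inherits(m, "combination_matrix"))
  if (length(m$doses_a) < 2 || length(m$doses_b) < 2) {
    stop("matrix must contain at least one combination cell")
  }
  f <- pmin(pmax((100 - m$viability) / 100, 0), 1)
  fa <- f[, 1]   # monotherapy of drug A (dose_b = 0)
  fb <- f[1, ]   # monotherapy of drug B (dose_a = 0)
  expected <- outer(fa, fb, function(a, b) a + b - a * b)
  excess <- (f - expected) * 100
  combo <- excess[-1, -1, drop = FALSE]
  dimnames(combo) <- list(m$doses_a[-1], m$doses_b[-1])
  .bliss_result(combo, mean(combo), length(combo))
}

#' Bliss excess along a 1:1 fixed-molar diagonal design
#'
#' Both drugs share one concentration series; at each concentration the
#' expectation is formed from the two monotherapy viabilities at that
#' same concentration, and the excess is the observed combination
#' inhibition minus the expectation, in percentage points.
#'
#' @param doses Shared concentration series, nM (> 0).
#' @param mono_a,mono_b Monotherapy viabilities (\%) at \code{doses}.
#' @param combo Combination viabilities (\%) at \code{doses}.
#' @return A \code{"bliss_result"} with an excess vector named by dose;
#'   the score is the mean excess over doses > 0.
#' @export
bliss_diagonal <- function(doses, mono_a, mono_b, combo) {
  n <- length(doses)
  if (length(mono_a) != n || length(mono_b) != n || length(combo) != n) {
    stop("doses, mono_a, mono_b and combo must have equal length")
  }
  if (any(!is.finite(c(doses, mono_a, mono_b, combo)))) {
    stop("inputs must be finite")
  }
  clip01 <- function(v) pmin(pmax((100 - v) / 100, 0), 1)
  fa <- clip01(mono_a)
  fb <- clip01(mono_b)
  fc <- clip01(combo)
  expected <- fa + fb - fa * fb
  excess <- (fc - expected) * 100
  names(excess) <- doses
  keep <- doses > 0
  if (!any(keep)) stop("no positive-dose cells to score")
  .bliss_result(excess[keep], mean(excess[keep]), sum(keep))
}

#' @export
print.bliss_result <- function(x, ...) {
  cat(sprintf("Bliss synergy score: %.2f (%s) over %d combination cells\n",
              x$score, x$call, x$n_cells))
  invisible(x)
}
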