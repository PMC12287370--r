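# Modified DSS3 drug sensitivity score: normalized area under the
# inhibition curve on log10-dose, restricted to the 10-100% viability
# activity band, over the tested dose window. Omits the DSS2-style
# division by log10 of the upper asymptote.

#' DSS configuration
#'
#' @param viability_floor Activity-window floor in viability \%
#'   (default 10): inhibition is only credited down to this viability,
#'   i.e. the integrand is capped at \code{100 - viability_floor}
#'   percentage points.
#' @param apply_window_factor If \code{TRUE}, additionally rescale the
#'   score by the responsive fraction of the dose window,
#'   \code{(x_stop - x_min) / (x_max - x_min)}, where \code{x_stop} is
#'   the dose at which viability first reaches the floor (the literal
#'   dose-window truncation variant). Off by default; see the methods
#'   vignette for why.
#' @param quadrature_tol Relative tolerance of the adaptive quadrature.
#' @return A list of class \code{"dss_config"}.
#' @export
dss_config <- function(viability_floor = 10, apply_window_factor = FALSE,
                       quadrature_tol = 1e-8) {
  if (!is.finite(viability_floor) || viability_floor <= 0 ||
      viability_floor >= 100) {
    stop("viability_floor must lie strictly between 0 and 100")
  }
  structure(list(viability_floor = viability_floor,
                 inhibition_cap = 100 - viability_floor,
                 apply_window_factor = apply_window_factor,
                 quadrature_tol = quadrature_tol),
            class = "dss_config")
}

# x where the (monotone, hill >= 0) fitted curve crosses viability level,
# or NA when the level is not crossed.
.logistic_crossing <- function(fit, level) {
  top <- fit$top; bottom <- fit$bottom
  if (fit$hill <= 0 || top <= bottom) return(NA_real_)
  if (level >= top || level <= bottom) return(NA_real_)
  fit$log10_ic50 + log10((top - level) / (level - bottom)) / fit$hill
}

#' Drug sensitivity score (modified DSS3) of a fitted curve
#'
#' Integrates the inhibition curve \eqn{y(x) = 100 - v(x)}, clipped to
#' the activity band \eqn{[0, 100 - t_v]} (default \eqn{t_v} = 10\%
#' viability), over the tested log10-dose window
#' \eqn{[x_{min}, x_{max}]}, and normalizes by the maximal attainable
#' area:
#' \deqn{DSS = 100 \cdot AUC / ((100 - t_v)(x_{max} - x_{min}))}
#' so a curve pinned at 100\% viability scores 0 and complete kill
#' across the window scores 100. Viability above 100\% contributes zero
#' area (never negative). The integral is adaptive quadrature split at
#' the curve's closed-form crossings of the band edges.
#'
#' @param fit A \code{"logistic_fit"}.
#' @param config A [dss_config()].
#' @return An object of class \code{"dss_result"}: list with
#'   \code{sample_id}, \code{treatment_id}, \code{experiment},
#'   \code{dss} (in [0, 100]), \code{auc} (\%·log10 nM),
#'   \code{x_stop} (log10 nM where viability first reaches the floor,
#'   \code{x_max} if never) and \code{metric_label}.
#' @export
dss_score <- function(fit, config = dss_config()) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(config, "dss_config"))
  x_min <- fit$x_min
  x_max <- fit$x_max
  if (!is.finite(x_min) || !is.finite(x_max) || x_max <= x_min) {
    stop("fit dose window is degenerate (x_max <= x_min)")
  }
  t_v <- config$viability_floor
  y_cap <- config$inhibition_cap

  integrand <- function(x) {
    y <- 100 - predict(fit, log10_conc = x)
    pmin(pmax(y, 0), y_cap)
  }
  # split at the closed-form band crossings (v = 100 and v = t_v)
  cuts <- c(.logistic_crossing(fit, 100), .logistic_crossing(fit, t_v))
  cuts <- sort(cuts[!is.na(cuts) & cuts > x_min & cuts < x_max])
  edges <- c(x_min, cuts, x_max)
  auc <- 0
  for (k in seq_len(length(edges) - 1)) {
    auc <- auc + stats::integrate(integrand, edges[k], edges[k + 1],
                                  rel.tol = config$quadrature_tol,
                                  abs.tol = config$quadrature_tol,
                                  subdivisions = 200L)$value
  }
  dss <- 100 * auc / (y_cap * (x_max - x_min))

  cross_floor <- .logistic_crossing(fit, t_v)
  x_stop <- if (predict(fit, log10_conc = x_min) <= t_v) x_min
            else if (!is.na(cross_floor) && cross_floor <= x_max) cross_floor
            else x_max
  label <- "DSS3m"
  if (config$apply_window_factor) {
    dss <- dss * (x_stop - x_min) / (x_max - x_min)
    label <- "DSS3m+window"
  }
  structure(list(sample_id = fit$sample_id, treatment_id = fit$treatment_id,
                 experiment = fit$experiment,
                 dss = min(max(dss, 0), 100), auc = auc, x_stop = x_stop,
                 metric_label = label),
            class = "dss_result")
}

#' @export
print.dss_result <- function(x, ...) {
  id <- paste(stats::na.omit(c(x$sample_id, x$treatment_id)), collapse = " / ")
  cat(sprintf("%s = %.2f%s (AUC %.3g, x_stop %.3g)\n", x$metric_label,
              x$dss, if (nzchar(id)) paste0(" [", id, "]") else "",
              x$auc, x$x_stop))
  invisible(x)
}

#' Tabulate DSS across fits and independent experiments
#'
#' Scores every fit, then summarizes per (sample, treatment) across
#' independent experiments: per-experiment scores plus their mean and
#' SD (SD is NA for a single experiment). Combination treatments are
#' scored identically to single agents, using the shared 1:1 series
#' concentration as the dose axis.
#'
#' @param fits A list of \code{"logistic_fit"} objects (e.g. from
#'   [fit_screen()]).
#' @param config A [dss_config()].
#' @return An object of class \code{"dss_table"}: list with
#'   \code{scores} (one row per fit: sample_id, treatment_id,
#'   experiment, dss) and \code{summary} (one row per sample x
#'   treatment: n_experiments, dss_mean, dss_sd).
#' @export
dss_table <- function(fits, config = dss_config()) {
  if (length(fits) == 0) {
    scores <- data.frame(sample_id = character(), treatment_id = character(),
                         experiment = character(), dss = numeric(),
                         stringsAsFactors = FALSE)
    summ <- data.frame(sample_id = character(), treatment_id = character(),
                       n_experiments = integer(), dss_mean = numeric(),
                       dss_sd = numeric(), stringsAsFactors = FALSE)
    return(structure(list(scores = scores, summary = summ),
                     class = "dss_table"))
  }
  rows <- lapply(fits, function(f) {
    r <- dss_score(f, config)
    data.frame(sample_id = r$sample_id, treatment_id = r$treatment_id,
               experiment = r$experiment, dss = r$dss,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  key <- paste(scores$sample_id, scores$treatment_id, sep = "\r")
  summ <- do.call(rbind, lapply(split(scores, key), function(g) {
    data.frame(sample_id = g$sample_id[1], treatment_id = g$treatment_id[1],
               n_experiments = nrow(g), dss_mean = mean(g$dss),
               dss_sd = if (nrow(g) >= 2) stats::sd(g$dss) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$sample_id, summ$treatment_id), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(scores = scores, summary = summ), class = "dss_table")
}

#' @export
print.dss_table <- function(x, ...) {
  cat("DSS table:", nrow(x$scores), "scored fits,",
      nrow(x$summary), "sample x treatment groups\n")
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("...\n")
  invisible(x)
}
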