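# Four-parameter logistic dose-response fitting on log10(concentration).
# The curve is parameterized so hill >= 0 always gives a monotone
# non-increasing kill curve, the geometry the sensitivity score assumes.

.logistic4 <- function(x, top, bottom, log10_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (x - log10_ic50)))
}

#' Default parameter bounds for logistic fitting
#'
#' @param top_max Upper bound for the top (and bottom) asymptote, \%.
#'   Defaults to 120 because normalized viability legitimately
#'   overshoots 100\%.
#' @param hill_max Upper bound for the Hill slope.
#' @param ic50_pad Log10 units the IC50 may sit outside the tested
#'   range.
#' @return A list of bounds used by [fit_logistic()].
#' @export
logistic_bounds <- function(top_max = 120, hill_max = 10, ic50_pad = 2) {
  stopifnot(top_max > 0, hill_max > 0, ic50_pad >= 0)
  list(top_max = top_max, hill_max = hill_max, ic50_pad = ic50_pad)
}

#' Fit a four-parameter logistic viability curve
#'
#' Least-squares fit of
#' \deqn{v(x) = bottom + (top - bottom) / (1 + 10^{hill (x - log10IC50)})}
#' with \eqn{x = \log_{10}(\mathrm{conc}\ \mathrm{nM})}, under the box
#' constraints \eqn{0 \le bottom \le top \le top_{max}},
#' \eqn{0 \le hill \le hill_{max}} and log10IC50 within the tested range
#' padded by \code{ic50_pad}. Optimization is a deterministic multi-start
#' (5 x 5 grid over log10IC50 and hill, L-BFGS-B refinement, best
#' residual sum of squares wins); a flat curve at the mean viability is
#' always among the candidates, so the returned fit never has a larger
#' RSS than the flat fallback. If every refinement fails the flat fit is
#' returned with \code{converged = FALSE} rather than erroring, so one
#' bad well series cannot abort a screen.
#'
#' @param concentration Positive concentrations in nM (>= 2 distinct).
#' @param viability Finite viability percentages, same length.
#' @param bounds Output of [logistic_bounds()].
#' @param sample_id,treatment_id,experiment Optional identifiers carried
#'   on the fit for downstream score tables.
#' @return An object of class \code{"logistic_fit"}: a list with
#'   elements \code{top}, \code{bottom}, \code{log10_ic50}, \code{hill},
#'   \code{rss}, \code{converged}, \code{x_min}, \code{x_max} (log10 nM
#'   of the tested range), \code{data}, and the identifiers.
#' @examples
#' conc <- 10^(0:4)
#' v <- 100 / (1 + 10^((0:4) - 2))
#' fit <- fit_logistic(conc, v)
#' coef(fit)
#' predict(fit, concentration = 100)  # midpoint: (top + bottom) / 2
#' @export
fit_logistic <- function(concentration, viability, bounds = logistic_bounds(),
                         sample_id = NA_character_,
                         treatment_id = NA_character_,
                         experiment = NA_character_) {
  if (length(concentration) != length(viability)) {
    stop("concentration and viability must have equal length")
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be positive and finite")
  }
  if (any(!is.finite(viability))) {
    stop("viabilities must be finite")
  }
  if (length(unique(concentration)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  ord <- order(concentration)
  x <- log10(concentration)[ord]
  v <- viability[ord]
  x_min <- min(x)
  x_max <- max(x)
  tmax <- bounds$top_max
  hmax <- bounds$hill_max
  e_lo <- x_min - bounds$ic50_pad
  e_hi <- x_max + bounds$ic50_pad

  # theta = (top, bottom_frac, log10_ic50, hill); bottom = bottom_frac * top
  # keeps 0 <= bottom <= top as plain box constraints.
  rss_fun <- function(theta) {
    pred <- .logistic4(x, theta[1], theta[2] * theta[1], theta[3], theta[4])
    sum((v - pred)^2)
  }
  lower <- c(0, 0, e_lo, 0)
  upper <- c(tmax, 1, e_hi, hmax)

  clip <- function(z, lo, hi) pmin(pmax(z, lo), hi)
  top0 <- clip(max(v), 1e-6, tmax)
  bfrac0 <- clip(min(v) / top0, 0, 1)

  # flat fallback candidate: constant curve at the (clipped) mean
  flat_level <- clip(mean(v), 0, tmax)
  flat <- list(par = c(flat_level, 1, (x_min + x_max) / 2, 0),
               rss = sum((v - flat_level)^2), converged = TRUE)

  best <- flat
  any_converged <- FALSE
  for (e0 in seq(x_min - 1, x_max + 1, length.out = 5)) {
    for (h0 in c(0.25, 0.5, 1, 2, 4)) {
      start <- c(top0, bfrac0, clip(e0, e_lo, e_hi), min(h0, hmax))
      res <- tryCatch(
        stats::optim(start, rss_fun, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(res)) next
      any_converged <- any_converged || res$convergence == 0
      if (res$value < best$rss - 1e-12 ||
          (res$value < best$rss && res$convergence == 0)) {
        best <- list(par = res$par, rss = res$value,
                     converged = res$convergence == 0)
      }
    }
  }
  converged <- if (identical(best$rss, flat$rss) && !any_converged) FALSE
               else best$converged || identical(best$par, flat$par)

  structure(list(
    top = best$par[1],
    bottom = best$par[2] * best$par[1],
    log10_ic50 = best$par[3],
    hill = best$par[4],
    rss = best$rss,
    converged = converged,
    x_min = x_min,
    x_max = x_max,
    data = data.frame(log10_conc = x, viability = v),
    sample_id = sample_id,
    treatment_id = treatment_id,
    experiment = experiment
  ), class = "logistic_fit")
}

#' Construct a logistic curve object from known parameters
#'
#' Builds a \code{"logistic_fit"} directly, without fitting - useful to
#' score curves with known parameters (e.g. simulated ground truth)
#' with [dss_score()].
#'
#' @param top,bottom Asymptotes, \% (\code{bottom <= top}).
#' @param log10_ic50 Inflection point, log10(nM).
#' @param hill Hill slope, >= 0.
#' @param x_min,x_max Tested dose window, log10(nM).
#' @param sample_id,treatment_id,experiment Optional identifiers.
#' @return A \code{"logistic_fit"} with \code{rss = NA} and no data.
#' @export
logistic_fit <- function(top, bottom, log10_ic50, hill, x_min, x_max,
                         sample_id = NA_character_,
                         treatment_id = NA_character_,
                         experiment = NA_character_) {
  if (bottom > top) stop("bottom must not exceed top")
  if (hill < 0) stop("hill must be non-negative")
  if (x_max <= x_min) stop("x_max must exceed x_min")
  structure(list(top = top, bottom = bottom, log10_ic50 = log10_ic50,
                 hill = hill, rss = NA_real_, converged = TRUE,
                 x_min = x_min, x_max = x_max,
                 data = data.frame(log10_conc = numeric(),
                                   viability = numeric()),
                 sample_id = sample_id, treatment_id = treatment_id,
                 experiment = experiment),
            class = "logistic_fit")
}

#' Evaluate a fitted logistic curve at given concentrations
#'
#' @param fit A \code{"logistic_fit"}.
#' @param concentration Positive concentrations in nM.
#' @return Predicted viability, \%.
#' @export
predict_viability <- function(fit, concentration) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration must be positive and finite")
  }
  .logistic4(log10(concentration), fit$top, fit$bottom,
             fit$log10_ic50, fit$hill)
}

#' @export
predict.logistic_fit <- function(object, concentration = NULL,
                                 log10_conc = NULL, ...) {
  if (is.null(concentration) && is.null(log10_conc)) {
    log10_conc <- object$data$log10_conc
  }
  if (!is.null(concentration)) {
    return(predict_viability(object, concentration))
  }
  .logistic4(log10_conc, object$top, object$bottom,
             object$log10_ic50, object$hill)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    log10_ic50 = object$log10_ic50, hill = object$hill)
}

#' @export
fitted.logistic_fit <- function(object, ...) {
  predict(object, log10_conc = object$data$log10_conc)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$data$viability - fitted(object)
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  id <- paste(stats::na.omit(c(x$sample_id, x$treatment_id)), collapse = " / ")
  cat("4-parameter logistic dose-response fit",
      if (nzchar(id)) paste0(" [", id, "]"), "\n", sep = "")
  cat(sprintf("  top %.*g%%  bottom %.*g%%  log10(IC50/nM) %.*g  hill %.*g\n",
              digits, x$top, digits, x$bottom, digits, x$log10_ic50,
              digits, x$hill))
  cat(sprintf("  n = %d points on log10(nM) in [%.3g, %.3g], rss = %.*g%s\n",
              nrow(x$data), x$x_min, x$x_max, digits, x$rss,
              if (!x$converged) " (not converged: flat fallback)" else ""))
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  out <- list(coef = coef(object), rss = object$rss,
              n = nrow(object$data), converged = object$converged,
              ic50_nM = 10^object$log10_ic50,
              residuals = residuals(object))
  class(out) <- "summary.logistic_fit"
  out
}

#' @export
print.summary.logistic_fit <- function(x, digits = 4, ...) {
  cat("Coefficients:\n")
  print(round(x$coef, digits))
  cat(sprintf("IC50 = %.4g nM; RSS = %.4g over %d points; converged: %s\n",
              x$ic50_nM, x$rss, x$n, x$converged))
  invisible(x)
}

#' @export
plot.logistic_fit <- function(x, n_grid = 200, ...) {
  grid <- seq(x$x_min, x$x_max, length.out = n_grid)
  graphics::plot(x$data$log10_conc, x$data$viability,
                 xlab = "log10(concentration, nM)", ylab = "viability (%)",
                 ylim = range(0, 100, x$data$viability), ...)
  graphics::lines(grid, predict(x, log10_conc = grid))
  graphics::abline(v = x$log10_ic50, lty = 3)
  invisible(x)
}

#' Fit logistic curves for every (treatment, experiment) of a sample
#'
#' Convenience wrapper: splits a normalized response table (the output
#' of [normalize_viability()], optionally with an \code{experiment}
#' column) and fits one curve per group.
#'
#' @param normalized Data frame with \code{sample_id},
#'   \code{treatment_id}, \code{concentration_nM}, \code{viability_pct}
#'   and optionally \code{experiment}.
#' @param bounds Passed to [fit_logistic()].
#' @return A list of \code{"logistic_fit"} objects.
#' @export
fit_screen <- function(normalized, bounds = logistic_bounds()) {
  if (!"experiment" %in% names(normalized)) {
    normalized$experiment <- NA_character_
  }
  key <- paste(normalized$sample_id, normalized$treatment_id,
               normalized$experiment, sep = "\r")
  lapply(split(normalized, key), function(g) {
    fit_logistic(g$concentration_nM, g$viability_pct, bounds = bounds,
                 sample_id = g$sample_id[1], treatment_id = g$treatment_id[1],
                 experiment = as.character(g$experiment[1]))
  })
}
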