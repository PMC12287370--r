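# Target addiction scoring: deconvolve per-sample drug sensitivities
# into per-protein-target scores by averaging the DSS of every
# annotated treatment (single agents and combinations alike).

#' Compute target addiction scores for one sample
#'
#' For each protein target annotated in the treatment library, the
#' target addiction score (TAS) is the arithmetic mean of the
#' (experiment-mean) DSS of every scored treatment - single agent or
#' combination - whose target set contains that target. Treatments
#' without a score for the sample are excluded from the mean, never
#' imputed; targets with no scored annotated treatment are absent from
#' the result rather than reported as zero. Higher TAS indicates a
#' stronger functional dependence of the sample on that target.
#'
#' @param dss A \code{"dss_table"} (from [dss_table()]) or a data frame
#'   with columns \code{sample_id}, \code{treatment_id},
#'   \code{dss_mean}.
#' @param library A \code{"treatment_library"}.
#' @param sample_id Sample to score.
#' @return A \code{data.frame} of class \code{"tas_table"}: one row per
#'   target with \code{target}, \code{tas} (in [0, 100]),
#'   \code{n_treatments} and \code{treatments} (semicolon-separated
#'   contributing treatment ids), sorted by target name.
#' @export
compute_tas <- function(dss, library, sample_id) {
  summ <- if (inherits(dss, "dss_table")) dss$summary else dss
  stopifnot(all(c("sample_id", "treatment_id", "dss_mean") %in% names(summ)))
  summ <- summ[summ$sample_id == sample_id, , drop = FALSE]
  if (nrow(summ) == 0) {
    stop("sample ", sQuote(sample_id), " has no scored treatments")
  }
  score_of <- stats::setNames(summ$dss_mean, summ$treatment_id)

  pairs <- do.call(rbind, lapply(seq_len(nrow(library)), function(i) {
    tid <- library$treatment_id[i]
    tg <- library$targets[[i]]
    if (length(tg) == 0 || !tid %in% names(score_of)) return(NULL)
    data.frame(target = tg, treatment_id = tid, dss = unname(score_of[tid]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    out <- data.frame(target = character(), tas = numeric(),
                      n_treatments = integer(), treatments = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("tas_table", class(out))
    return(out)
  }
  out <- do.call(rbind, lapply(split(pairs, pairs$target), function(g) {
    data.frame(target = g$target[1], tas = mean(g$dss),
               n_treatments = nrow(g),
               treatments = paste(sort(g$treatment_id), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  class(out) <- c("tas_table", class(out))
  out
}

#' Rank protein targets by addiction score
#'
#' @param tas A \code{"tas_table"}.
#' @param top_k How many top targets to return (>= 1).
#' @return Character vector of target names, sorted by TAS descending
#'   with deterministic alphabetical tie-break.
#' @export
rank_targets <- function(tas, top_k = nrow(tas)) {
  if (nrow(tas) == 0) stop("empty TAS table")
  if (!is.finite(top_k) || top_k < 1) stop("top_k must be >= 1")
  ord <- order(-tas$tas, tas$target)
  utils::head(tas$target[ord], top_k)
}

#' @export
print.tas_table <- function(x, ...) {
  sid <- attr(x, "sample_id")
  cat("Target addiction scores",
      if (!is.null(sid)) paste0(" [", sid, "]"), ": ",
      nrow(x), " targets\n", sep = "")
  ord <- order(-x$tas, x$target)
  print.data.frame(utils::head(x[ord, c("target", "tas", "n_treatments")], 10),
                   row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
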