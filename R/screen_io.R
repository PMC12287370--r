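# Reading, validation and control-normalization of plate-based viability
# screen tables, plus the treatment (drug/combination) annotation library.

.SCREEN_COLUMNS <- c("sample_id", "treatment_id", "treatment_type",
                     "concentration_nM", "replicate", "signal", "well_role")
.WELL_ROLES <- c("compound", "neg_ctrl", "pos_ctrl")

#' Read a long-format drug screen table
#'
#' Reads a CSV/TSV export of a viability screen with one row per well.
#' Required columns (header match is case-insensitive):
#' \code{sample_id}, \code{treatment_id}, \code{treatment_type},
#' \code{concentration_nM}, \code{replicate}, \code{signal},
#' \code{well_role}. Control wells (\code{neg_ctrl}: DMSO vehicle,
#' \code{pos_ctrl}: benzethonium-chloride full kill) may leave the
#' treatment fields blank.
#'
#' @param path Path to an existing CSV or TSV file.
#' @param sep Field separator. Defaults to \code{","} for \code{.csv}
#'   files and \code{"\t"} otherwise.
#' @return A \code{data.frame} of class \code{"screen_table"} with the
#'   canonical column names, row order preserved from the file.
#' @seealso [normalize_viability()], [write_screen_table()]
#' @export
read_screen_table <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop("screen table not found: ", path)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  hdr <- tolower(trimws(names(raw)))
  idx <- match(tolower(.SCREEN_COLUMNS), hdr)
  if (anyNA(idx)) {
    stop("schema error: missing column(s): ",
         paste(sQuote(.SCREEN_COLUMNS[is.na(idx)]), collapse = ", "))
  }
  raw <- raw[idx]
  names(raw) <- .SCREEN_COLUMNS
  # header line is line 1, so data row i sits on file line i + 1
  line_no <- seq_len(nrow(raw)) + 1L

  conc <- suppressWarnings(as.numeric(raw$concentration_nM))
  sig <- suppressWarnings(as.numeric(raw$signal))
  rep <- suppressWarnings(as.integer(raw$replicate))
  role <- tolower(trimws(raw$well_role))
  is_compound <- role == "compound"

  bad_sig <- which(is.na(sig) & nzchar(raw$signal))
  bad_conc <- which(is_compound & is.na(conc))
  if (length(bad_sig) > 0 || length(bad_conc) > 0) {
    stop("parse error: non-numeric signal at line(s) ",
         paste(line_no[bad_sig], collapse = ", "),
         if (length(bad_conc) > 0)
           paste0("; non-numeric concentration at line(s) ",
                  paste(line_no[bad_conc], collapse = ", ")))
  }
  bad_role <- which(!role %in% .WELL_ROLES)
  if (length(bad_role) > 0) {
    stop("parse error: unknown well_role at line(s) ",
         paste(line_no[bad_role], collapse = ", "))
  }

  out <- data.frame(
    sample_id = trimws(raw$sample_id),
    treatment_id = trimws(raw$treatment_id),
    treatment_type = trimws(raw$treatment_type),
    concentration_nM = conc,
    replicate = rep,
    signal = sig,
    well_role = role,
    stringsAsFactors = FALSE
  )
  validate_screen_table(out)
}

#' Validate a screen table
#'
#' Checks the invariants a screen table must satisfy: non-negative
#' signals, positive concentrations on compound wells, and at least one
#' negative and one positive control well per sample.
#'
#' @param x A \code{data.frame} with the screen-table columns.
#' @return \code{x}, classed \code{"screen_table"}, invisibly validated.
#' @export
validate_screen_table <- function(x) {
  stopifnot(is.data.frame(x))
  missing <- setdiff(.SCREEN_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ",
         paste(sQuote(missing), collapse = ", "))
  }
  if (any(!x$well_role %in% .WELL_ROLES)) {
    stop("well_role must be one of ", paste(.WELL_ROLES, collapse = ", "))
  }
  if (any(!is.finite(x$signal)) || any(x$signal < 0)) {
    stop("signal must be finite and non-negative")
  }
  cmp <- x[x$well_role == "compound", , drop = FALSE]
  if (nrow(cmp) > 0 &&
      (any(!is.finite(cmp$concentration_nM)) || any(cmp$concentration_nM <= 0))) {
    stop("compound wells must have concentration_nM > 0")
  }
  for (s in unique(x$sample_id)) {
    roles <- x$well_role[x$sample_id == s]
    if (!any(roles == "neg_ctrl") || !any(roles == "pos_ctrl")) {
      stop("sample ", sQuote(s),
           " lacks a negative and/or positive control well")
    }
  }
  class(x) <- unique(c("screen_table", class(x)))
  x
}

#' Write a screen table
#'
#' Writes a screen table back to CSV/TSV with full numeric precision, so
#' that \code{read_screen_table(write_screen_table(x))} round-trips.
#'
#' @param x A \code{"screen_table"}.
#' @param path Output file path; extension selects the separator.
#' @param sep Optional explicit separator.
#' @return \code{path}, invisibly.
#' @export
write_screen_table <- function(x, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  out <- as.data.frame(x)[.SCREEN_COLUMNS]
  out$concentration_nM <- formatC(out$concentration_nM, digits = 17,
                                  format = "g")
  out$concentration_nM[out$concentration_nM == "NA"] <- ""
  out$signal <- formatC(out$signal, digits = 17, format = "g")
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normalize raw viability signals to plate controls
#'
#' Rescales luminescence so that the mean negative (DMSO) control maps to
#' 100\% viability and the mean positive (benzethonium chloride) control
#' maps to 0\%:
#' \deqn{viability = 100 (signal - \bar{pos}) / (\bar{neg} - \bar{pos})}
#' Each well is normalized individually against its own sample's pooled
#' controls, then replicate wells are averaged per (treatment,
#' concentration). Values are deliberately not clipped to [0, 100]:
#' slight overshoot is legitimate assay noise and is handled downstream
#' where a formula requires a bounded range.
#'
#' @param table A \code{"screen_table"}.
#' @param sample_id Sample to normalize.
#' @param control_stat Summary for the control wells, \code{"mean"}
#'   (default, matches the linear formula) or \code{"median"}.
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{treatment_id}, \code{concentration_nM}, \code{viability_pct},
#'   \code{n_replicates}, \code{viability_sd} (NA when a single
#'   replicate), ordered by treatment then ascending concentration.
#' @export
normalize_viability <- function(table, sample_id,
                                control_stat = c("mean", "median")) {
  control_stat <- match.arg(control_stat)
  stat <- if (control_stat == "mean") mean else stats::median
  x <- table[table$sample_id == sample_id, , drop = FALSE]
  if (nrow(x) == 0) {
    stop("sample ", sQuote(sample_id), " not present in screen table")
  }
  neg <- x$signal[x$well_role == "neg_ctrl"]
  pos <- x$signal[x$well_role == "pos_ctrl"]
  if (length(neg) == 0 || length(pos) == 0) {
    stop("sample ", sQuote(sample_id), " lacks control wells")
  }
  m_neg <- stat(neg)
  m_pos <- stat(pos)
  if (m_neg <= m_pos) {
    stop("degenerate controls for sample ", sQuote(sample_id),
         ": negative-control signal (", signif(m_neg, 6),
         ") does not exceed positive-control signal (",
         signif(m_pos, 6), "); assay failure")
  }
  cmp <- x[x$well_role == "compound", , drop = FALSE]
  empty <- data.frame(sample_id = character(), treatment_id = character(),
                      concentration_nM = numeric(), viability_pct = numeric(),
                      n_replicates = integer(), viability_sd = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(cmp) == 0) {
    warning("sample ", sQuote(sample_id), " has no compound wells")
    return(empty)
  }
  v_well <- 100 * (cmp$signal - m_pos) / (m_neg - m_pos)
  key <- interaction(cmp$treatment_id, cmp$concentration_nM, drop = TRUE)
  agg <- lapply(split(seq_along(v_well), key), function(i) {
    data.frame(
      sample_id = sample_id,
      treatment_id = cmp$treatment_id[i[1]],
      concentration_nM = cmp$concentration_nM[i[1]],
      viability_pct = mean(v_well[i]),
      n_replicates = length(i),
      viability_sd = if (length(i) >= 2) stats::sd(v_well[i]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$treatment_id, out$concentration_nM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a treatment annotation library
#'
#' Parses the TSV mirror of the screen's treatment annotation tables:
#' columns \code{treatment_id}, \code{type} (\code{single} or
#' \code{combination}), \code{components} (semicolon-separated drug
#' names), \code{targets} (semicolon-separated protein targets; may be
#' empty), \code{series} (semicolon-separated ascending concentrations
#' in nM).
#'
#' @param path Path to the TSV file.
#' @return A \code{data.frame} of class \code{"treatment_library"} with
#'   list-columns \code{components}, \code{targets} (character vectors)
#'   and \code{series} (numeric, strictly ascending).
#' @export
read_treatment_library <- function(path) {
  if (!file.exists(path)) {
    stop("treatment library not found: ", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  names(raw) <- tolower(trimws(names(raw)))
  need <- c("treatment_id", "type", "components", "targets", "series")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ",
         paste(sQuote(missing), collapse = ", "))
  }
  split_field <- function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  }
  lib <- data.frame(treatment_id = trimws(raw$treatment_id),
                    type = tolower(trimws(raw$type)),
                    stringsAsFactors = FALSE)
  lib$components <- lapply(raw$components, split_field)
  lib$targets <- lapply(raw$targets, function(s) sort(unique(split_field(s))))
  lib$series <- lapply(raw$series, function(s) as.numeric(split_field(s)))
  validate_treatment_library(lib)
}

#' Validate a treatment library
#'
#' @param lib A \code{data.frame} with columns \code{treatment_id},
#'   \code{type} and list-columns \code{components}, \code{targets},
#'   \code{series}.
#' @return \code{lib}, classed \code{"treatment_library"}.
#' @export
validate_treatment_library <- function(lib) {
  dup <- lib$treatment_id[duplicated(lib$treatment_id)]
  if (length(dup) > 0) {
    stop("duplicate treatment_id: ", paste(sQuote(unique(dup)), collapse = ", "))
  }
  if (any(!lib$type %in% c("single", "combination"))) {
    stop("type must be 'single' or 'combination'")
  }
  for (i in seq_len(nrow(lib))) {
    ser <- lib$series[[i]]
    if (length(ser) == 0 || any(is.na(ser))) {
      stop("treatment ", sQuote(lib$treatment_id[i]),
           ": empty or non-numeric concentration series")
    }
    if (any(ser <= 0) || is.unsorted(ser, strictly = TRUE)) {
      stop("treatment ", sQuote(lib$treatment_id[i]),
           ": series must be positive and strictly ascending")
    }
    if (lib$type[i] == "combination" && length(lib$components[[i]]) < 2) {
      stop("combination ", sQuote(lib$treatment_id[i]),
           " must list at least 2 component drugs")
    }
  }
  class(lib) <- unique(c("treatment_library", class(lib)))
  lib
}
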