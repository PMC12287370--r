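# Synthetic-data generators emulating the screen's assays: logistic
# viability plates with plate controls, Bliss-independent (or
# synergy-injected) combination surfaces, and negative-binomial count
# matrices with spiked fold-changes. All generators are pure functions
# of (parameters, seed): the caller's RNG state is saved and restored.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.finite(seed)) stop("seed must be a finite integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Build a synthetic treatment library
#'
#' Emulates the screen's design: single agents on a shared 5-point
#' log-spaced concentration series plus 1:1 fixed-molar diagonal
#' combinations of pairs of them, each treatment annotated to protein
#' targets drawn from a pool (combinations inherit the union of their
#' components' targets).
#'
#' @param n_single Number of single agents (default 93, the screen's
#'   library size).
#' @param n_combination Number of pairwise combinations (default 87).
#' @param series Shared ascending concentration series, nM.
#' @param target_pool Protein-target names to cycle over the single
#'   agents.
#' @param seed RNG seed for the combination pairing.
#' @return A \code{"treatment_library"}.
#' @export
synthetic_treatment_library <- function(n_single = 93, n_combination = 87,
                                        series = 10^(0:4),
                                        target_pool = c("BCL2", "HDAC1",
                                                        "PSMB5", "BTK",
                                                        "PIK3CD", "MTOR",
                                                        "CDK9", "BCL2L1",
                                                        "MCL1", "XPO1"),
                                        seed = 1) {
  stopifnot(n_single >= 1, n_combination >= 0)
  .with_seed(seed, {
    singles <- data.frame(
      treatment_id = sprintf("drug%03d", seq_len(n_single)),
      type = "single", stringsAsFactors = FALSE)
    singles$components <- as.list(singles$treatment_id)
    singles$targets <- lapply(seq_len(n_single), function(i) {
      target_pool[1 + (i - 1) %% length(target_pool)]
    })
    singles$series <- rep(list(series), n_single)

    combos <- NULL
    if (n_combination > 0) {
      pair <- t(vapply(seq_len(n_combination),
                       function(i) sample.int(n_single, 2), integer(2)))
      combos <- data.frame(
        treatment_id = sprintf("combo%03d", seq_len(n_combination)),
        type = "combination", stringsAsFactors = FALSE)
      combos$components <- lapply(seq_len(n_combination), function(i) {
        singles$treatment_id[pair[i, ]]
      })
      combos$targets <- lapply(seq_len(n_combination), function(i) {
        sort(unique(unlist(singles$targets[pair[i, ]])))
      })
      combos$series <- rep(list(series), n_combination)
    }
    validate_treatment_library(rbind(singles, combos))
  })
}

#' Draw a random admissible screen ground truth
#'
#' One logistic parameter set per treatment of the library, for one
#' sample: top fixed at 100\%, bottom uniform on \code{bottom_range},
#' log10(IC50) uniform on \code{ic50_range} (log10 nM, inside the
#' tested window so the series brackets the IC50, as screen series are
#' designed to), Hill slope uniform on \code{hill_range}.
#'
#' @param library A \code{"treatment_library"}.
#' @param sample_id Sample identifier.
#' @param ic50_range,hill_range,bottom_range Uniform sampling ranges.
#' @param top Upper asymptote, \%.
#' @param seed RNG seed.
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{treatment_id}, \code{top}, \code{bottom},
#'   \code{log10_ic50}, \code{hill}.
#' @export
random_screen_truth <- function(library, sample_id = "S1",
                                ic50_range = c(1, 3),
                                hill_range = c(1, 2.5),
                                bottom_range = c(0, 20),
                                top = 100, seed = 1) {
  n <- nrow(library)
  .with_seed(seed, data.frame(
    sample_id = sample_id,
    treatment_id = library$treatment_id,
    top = rep(top, n),
    bottom = stats::runif(n, bottom_range[1], bottom_range[2]),
    log10_ic50 = stats::runif(n, ic50_range[1], ic50_range[2]),
    hill = stats::runif(n, hill_range[1], hill_range[2]),
    stringsAsFactors = FALSE
  ))
}

#' Simulate a raw viability screen table
#'
#' Emits one luminescence signal per well such that control
#' normalization recovers \code{logistic(truth) + noise}: compound-well
#' signal is \code{pos + v/100 (neg - pos)} with additive Gaussian
#' viability noise (sd \code{noise_sd} \%), plus negative- and
#' positive-control wells at the configured separation with matching
#' signal-scale noise. Signals are truncated at 0. With
#' \code{noise_sd = 0} the construction is exactly invertible.
#'
#' @param truth Ground-truth data frame from [random_screen_truth()]
#'   (columns \code{sample_id}, \code{treatment_id}, \code{top},
#'   \code{bottom}, \code{log10_ic50}, \code{hill}).
#' @param library A \code{"treatment_library"} supplying each
#'   treatment's concentration series.
#' @param n_replicates Compound wells per (treatment, concentration).
#' @param noise_sd Additive viability noise sd, \% (default 5,
#'   resembling triplicate luminescence scatter).
#' @param neg_level,pos_level Mean control signals, AU (negative =
#'   vehicle = 100\% viability; positive = full kill = 0\%).
#' @param n_control_wells Control wells of each kind per sample.
#' @param seed RNG seed.
#' @return A \code{"screen_table"}.
#' @export
simulate_screen <- function(truth, library, n_replicates = 3, noise_sd = 5,
                            neg_level = 1e5, pos_level = 2e3,
                            n_control_wells = 16, seed = 1) {
  stopifnot(all(c("sample_id", "treatment_id", "top", "bottom",
                  "log10_ic50", "hill") %in% names(truth)))
  if (any(truth$bottom > truth$top) || any(truth$hill < 0)) {
    stop("inadmissible ground-truth parameters (need bottom <= top, hill >= 0)")
  }
  if (neg_level <= pos_level) stop("neg_level must exceed pos_level")
  missing <- setdiff(truth$treatment_id, library$treatment_id)
  if (length(missing) > 0) {
    stop("treatments absent from library: ",
         paste(sQuote(missing), collapse = ", "))
  }
  series_of <- stats::setNames(library$series, library$treatment_id)
  type_of <- stats::setNames(library$type, library$treatment_id)
  span <- neg_level - pos_level
  sig_sd <- noise_sd / 100 * span

  .with_seed(seed, {
    rows <- vector("list", nrow(truth) + 2 * length(unique(truth$sample_id)))
    k <- 0
    for (i in seq_len(nrow(truth))) {
      conc <- series_of[[truth$treatment_id[i]]]
      grid <- expand.grid(concentration_nM = conc,
                          replicate = seq_len(n_replicates))
      v <- .logistic4(log10(grid$concentration_nM), truth$top[i],
                      truth$bottom[i], truth$log10_ic50[i], truth$hill[i])
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      k <- k + 1
      rows[[k]] <- data.frame(
        sample_id = truth$sample_id[i],
        treatment_id = truth$treatment_id[i],
        treatment_type = unname(type_of[truth$treatment_id[i]]),
        concentration_nM = grid$concentration_nM,
        replicate = grid$replicate,
        signal = pmax(pos_level + v / 100 * span, 0),
        well_role = "compound", stringsAsFactors = FALSE)
    }
    for (s in unique(truth$sample_id)) {
      ctrl <- function(level, role) {
        sig <- rep(level, n_control_wells)
        if (noise_sd > 0) sig <- sig + stats::rnorm(n_control_wells, 0, sig_sd)
        data.frame(sample_id = s, treatment_id = "", treatment_type = "",
                   concentration_nM = NA_real_,
                   replicate = seq_len(n_control_wells),
                   signal = pmax(sig, 0), well_role = role,
                   stringsAsFactors = FALSE)
      }
      k <- k + 1; rows[[k]] <- ctrl(neg_level, "neg_ctrl")
      k <- k + 1; rows[[k]] <- ctrl(pos_level, "pos_ctrl")
    }
    validate_screen_table(do.call(rbind, rows[seq_len(k)]))
  })
}

#' Simulate a combination surface and its 1:1 diagonal
#'
#' Monotherapy viabilities follow each drug's logistic curve; the
#' combination inhibition fraction is
#' \code{clip(fA + fB - fA fB + delta + noise, 0, 1)}, so
#' \code{delta = 0} yields a Bliss-independent surface and a nonzero
#' \code{delta} injects that much synergy (antagonism if negative)
#' before clipping. Gaussian noise (sd \code{noise_sd} \%) is added on
#' the viability scale to every measured cell; the untreated cell is
#' exactly 100.
#'
#' @param params_a,params_b Named vectors \code{c(top, bottom,
#'   log10_ic50, hill)} for the two drugs.
#' @param delta Injected Bliss excess as an inhibition fraction,
#'   |delta| <= 1.
#' @param doses Positive shared concentration series, nM.
#' @param noise_sd Viability noise sd, \%.
#' @param seed RNG seed.
#' @return List with \code{matrix} (a \code{"combination_matrix"} over
#'   \code{c(0, doses)}) and \code{diagonal} (list with \code{doses},
#'   \code{mono_a}, \code{mono_b}, \code{combo} viabilities).
#' @export
simulate_combination <- function(params_a, params_b, delta = 0,
                                 doses = 10^(0:4), noise_sd = 0, seed = 1) {
  if (abs(delta) > 1) stop("|delta| must not exceed 1")
  if (any(doses <= 0)) {
    stop("doses must be positive; the zero dose is added automatically")
  }
  lg <- function(p, x) .logistic4(x, p["top"], p["bottom"],
                                  p["log10_ic50"], p["hill"])
  x <- log10(doses)
  n <- length(doses)
  .with_seed(seed, {
    noise <- function(m) if (noise_sd > 0) stats::rnorm(m, 0, noise_sd) else 0
    va <- lg(params_a, x) + noise(n)
    vb <- lg(params_b, x) + noise(n)
    fa <- pmin(pmax((100 - va) / 100, 0), 1)
    fb <- pmin(pmax((100 - vb) / 100, 0), 1)
    f_combo <- outer(fa, fb, function(a, b) a + b - a * b) + delta
    v_combo <- 100 * (1 - f_combo) + noise(n * n)
    v_combo <- 100 * (1 - pmin(pmax((100 - v_combo) / 100, 0), 1))

    v <- matrix(NA_real_, n + 1, n + 1)
    v[1, 1] <- 100
    v[-1, 1] <- va
    v[1, -1] <- vb
    v[-1, -1] <- v_combo
    m <- combination_matrix(c(0, doses), c(0, doses), v)

    diag_combo <- diag(v_combo)
    list(matrix = m,
         diagonal = list(doses = doses, mono_a = va, mono_b = vb,
                         combo = diag_combo))
  })
}

#' Simulate a paired parental/resistant transcript count matrix
#'
#' Baseline per-transcript means are log-normal; parental replicates
#' are negative-binomial around the baseline, resistant replicates
#' around \code{baseline x fold_change} for the spiked transcripts and
#' around the baseline otherwise.
#'
#' @param n_transcripts Number of transcripts.
#' @param meanlog,sdlog Log-normal parameters of the baseline mean
#'   (defaults give a median of 200 counts with realistic spread).
#' @param dispersion Negative-binomial dispersion (> 0); variance is
#'   \code{mu + dispersion mu^2}.
#' @param n_spiked Number of transcripts given a true fold-change.
#' @param fold_change Fold-change of spiked transcripts (> 0; values
#'   < 1 are down-regulation).
#' @param n_replicates Replicates per condition (default 2, matching
#'   paired biological duplicates).
#' @param line Cell-line label for the synthetic samples.
#' @param seed RNG seed.
#' @return A \code{"count_matrix"} whose \code{"ground_truth"}
#'   attribute records the baseline means, spiked ids and fold-change.
#' @export
simulate_counts <- function(n_transcripts = 5000, meanlog = log(200),
                            sdlog = 1, dispersion = 0.05, n_spiked = 25,
                            fold_change = 8, n_replicates = 2,
                            line = "SIM", seed = 1) {
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("dispersion must be positive")
  }
  if (fold_change <= 0) stop("fold_change must be positive")
  if (n_spiked > n_transcripts) stop("n_spiked exceeds n_transcripts")
  .with_seed(seed, {
    ids <- sprintf("tx%05d", seq_len(n_transcripts))
    base <- stats::rlnorm(n_transcripts, meanlog, sdlog)
    spiked <- sort(sample(ids, n_spiked))
    fc <- stats::setNames(rep(1, n_transcripts), ids)
    fc[spiked] <- fold_change
    size <- 1 / dispersion
    draw <- function(mu) {
      matrix(stats::rnbinom(length(mu) * n_replicates, mu = mu, size = size),
             nrow = length(mu))
    }
    counts <- cbind(draw(base), draw(base * fc))
    rownames(counts) <- ids
    samples <- data.frame(
      sample = c(sprintf("%s_parental_%d", line, seq_len(n_replicates)),
                 sprintf("%s_resistant_%d", line, seq_len(n_replicates))),
      line = line,
      state = rep(c("parental", "resistant"), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      stringsAsFactors = FALSE)
    colnames(counts) <- samples$sample
    out <- count_matrix(counts, samples)
    attr(out, "ground_truth") <- list(base_mean = stats::setNames(base, ids),
                                      spiked = spiked,
                                      fold_change = fold_change)
    out
  })
}
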