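# Experimental designs, the forward simulator, trial-table IO and filtering.

TRIAL_COLUMNS <- c("subject_id", "experiment_id", "trial_index", "theta_deg",
                   "noise_level", "sigma_s_deg", "true_category", "choice",
                   "choice_correct", "estimate_deg", "consistent",
                   "m", "m_m", "n_draws")
MANDATORY_COLUMNS <- setdiff(TRIAL_COLUMNS, c("m", "m_m", "n_draws"))

#' Experimental design
#'
#' Builds the full-factorial trial list of one of the two orientation
#' judgment experiments. Experiment 1 uses a symmetric orientation range
#' (-21 to 21 deg in steps of 3; stimulus noise SDs 3 and 18 deg); Experiment
#' 2 an asymmetric one (-12 to 0 in steps of 2 on the ccw side, 0 to 30 in
#' steps of 5 on the cw side, 0 counted once; SDs 6 and 18 deg). Every
#' (orientation, noise) condition is repeated `repetitions` times (default 70,
#' giving 2100 / 1820 trials).
#'
#' @param experiment_id `"exp1"` or `"exp2"`.
#' @param repetitions Repetitions per condition (>= 1).
#' @param seed Optional integer; when given, the trial order is shuffled
#'   reproducibly, otherwise trials are in factorial order.
#' @return Object of class `experiment_design`: list with `experiment_id`,
#'   `orientations`, `noise_sigmas` (named `low`/`high`), `repetitions`, and
#'   `trials`, a data frame with one row per trial (`theta_deg`,
#'   `noise_level`, `sigma_s_deg`).
#' @examples
#' d <- build_design("exp1", repetitions = 70, seed = 1)
#' nrow(d$trials)
#' @export
build_design <- function(experiment_id = c("exp1", "exp2"), repetitions = 70,
                         seed = NULL) {
  experiment_id <- match.arg(experiment_id)
  stopifnot(repetitions >= 1)
  if (experiment_id == "exp1") {
    orientations <- seq(-21, 21, by = 3)
    noise_sigmas <- c(low = 3, high = 18)
  } else {
    orientations <- c(seq(-12, 0, by = 2), seq(5, 30, by = 5))
    noise_sigmas <- c(low = 6, high = 18)
  }
  cells <- expand.grid(theta_deg = orientations,
                       noise_level = c("low", "high"),
                       rep = seq_len(repetitions),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$sigma_s_deg <- noise_sigmas[cells$noise_level]
  if (!is.null(seed)) {
    ord <- local({set.seed(seed); sample.int(nrow(cells))})
    cells <- cells[ord, ]
  }
  rownames(cells) <- NULL
  structure(
    list(experiment_id = experiment_id, orientations = orientations,
         noise_sigmas = noise_sigmas, repetitions = repetitions,
         trials = cells[, c("theta_deg", "noise_level", "sigma_s_deg")]),
    class = "experiment_design"
  )
}

#' Simulate a synthetic subject
#'
#' Forward pass of the generative observer: per trial a measurement
#' \eqn{m \sim N(\theta, \sigma_s)} is drawn, categorized by the threshold
#' decision rule, and 100%-valid feedback is delivered. On correct trials the
#' memory sample is plain noisy recall \eqn{m_m \sim N(m, \sigma_m)} and the
#' estimate is the posterior mean conditioned on the choice; on incorrect
#' trials the observer switches to the feedback-corrected category, with
#' memory recall either plain (`"selfconsistent"` generator, the decision-flip
#' behavior) or feedback-consistent truncated resampling (`"2b-resampled"`).
#' Motor noise \eqn{N(0, \sigma_0)} is added to every estimate; with
#' probability `lapse` the estimate is replaced by a uniform draw over the
#' design's orientation range.
#'
#' @param params An [observer_params()] object (generating truth).
#' @param design An [build_design()] object.
#' @param generating_model `"selfconsistent"` or `"2b-resampled"`.
#' @param seed Integer seed; the whole table is a deterministic function of
#'   (params, design, generating_model, seed).
#' @param subject_id Subject label stored in the table.
#' @return A `trial_table`: data frame with one row per trial (subject,
#'   experiment, trial index, orientation, noise level and SD, true category,
#'   choice, feedback correctness, estimate, consistency flag, and the
#'   generator fields `m`, `m_m`, `n_draws`) plus attributes `params`,
#'   `design`, `generating_model`, `seed`.
#' @examples
#' p <- observer_params(3, 18, 4, alpha_cw = 21, beta = 8, sigma_0 = 2)
#' tab <- simulate_subject(p, build_design("exp1", 2), seed = 1)
#' @export
simulate_subject <- function(params, design,
                             generating_model = c("selfconsistent",
                                                  "2b-resampled"),
                             seed, subject_id = "S1") {
  generating_model <- match.arg(generating_model)
  stopifnot(inherits(params, "observer_params"),
            inherits(design, "experiment_design"))
  model <- observer_model(params)
  tr <- design$trials
  n <- nrow(tr)
  # the observer's sensory noise for each trial's stimulus-noise condition
  # (the design's sigma_s_deg column only labels the stimulus condition)
  sig_s <- ifelse(tr$noise_level == "low", params$sigma_s_low,
                  params$sigma_s_high)
  set.seed(seed)
  m <- stats::rnorm(n, tr$theta_deg, sig_s)
  mstar <- model$criteria[tr$noise_level]
  choice <- ifelse(m > mstar, "cw", "ccw")
  at_star <- m == mstar
  if (any(at_star))
    choice[at_star] <- sample(CATEGORIES, sum(at_star), replace = TRUE)
  true_cat <- sign_category(tr$theta_deg)
  zero <- is.na(true_cat)
  true_cat[zero] <- sample(CATEGORIES, sum(zero), replace = TRUE)
  correct <- choice == true_cat
  # feedback-corrected category: choice on correct trials, its flip otherwise
  est_cat <- true_cat
  m_m <- m + stats::rnorm(n, 0, params$sigma_m)
  n_draws <- rep(NA_integer_, n)
  if (generating_model == "2b-resampled") {
    for (i in which(!correct)) {
      rs <- resample_memory(m[i], sig_s[i], params$sigma_m,
                            est_cat[i])
      m_m[i] <- rs$m_m
      n_draws[i] <- rs$n_draws
    }
  }
  # exact posterior-mean estimate per trial
  est <- numeric(n)
  for (cat in CATEGORIES) {
    for (nl in c("low", "high")) {
      sel <- est_cat == cat & tr$noise_level == nl
      if (!any(sel)) next
      est[sel] <- .posterior_mean_batch(m_m[sel], model$sigma_like[[nl]],
                                        model$priors[[cat]], model$grid)
    }
  }
  est <- est + stats::rnorm(n, 0, params$sigma_0)
  if (params$lapse > 0) {
    lap <- stats::runif(n) < params$lapse
    est[lap] <- stats::runif(sum(lap), min(design$orientations),
                             max(design$orientations))
  }
  fb_cat <- est_cat
  consistent <- est == 0 | sign_category(est) == fb_cat
  consistent[is.na(consistent)] <- TRUE
  out <- data.frame(
    subject_id = subject_id, experiment_id = design$experiment_id,
    trial_index = seq_len(n), theta_deg = tr$theta_deg,
    noise_level = tr$noise_level, sigma_s_deg = tr$sigma_s_deg,
    true_category = true_cat, choice = choice, choice_correct = correct,
    estimate_deg = est, consistent = consistent,
    m = m, m_m = m_m, n_draws = n_draws,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  attr(out, "design") <- design
  attr(out, "generating_model") <- generating_model
  attr(out, "seed") <- seed
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write / read a trial table
#'
#' Plain UTF-8 comma-separated files with the exact trial-record header;
#' booleans as `true`/`false`, missing generator fields empty. Real-data
#' files may omit the generator columns (`m`, `m_m`, `n_draws`), which then
#' load as `NA`.
#'
#' @param table A `trial_table` (or compatible data frame).
#' @param path File path.
#' @return `read_trials` returns a `trial_table`; `write_trials` returns
#'   `path` invisibly.
#' @export
write_trials <- function(table, path) {
  stopifnot(all(MANDATORY_COLUMNS %in% names(table)))
  out <- as.data.frame(table)[, intersect(TRIAL_COLUMNS, names(table))]
  for (cl in c("choice_correct", "consistent"))
    out[[cl]] <- ifelse(out[[cl]], "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("trial file schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cl in c("theta_deg", "sigma_s_deg", "estimate_deg")) {
    bad <- which(!is.na(raw[[cl]]) & is.na(suppressWarnings(as.numeric(raw[[cl]]))))
    if (length(bad) > 0)
      stop("non-numeric ", cl, " in row(s) ", paste(utils::head(bad, 5),
                                                    collapse = ", "))
    raw[[cl]] <- as.numeric(raw[[cl]])
  }
  for (cl in c("choice_correct", "consistent")) {
    v <- tolower(as.character(raw[[cl]]))
    if (!all(v %in% c("true", "false")))
      stop("column ", cl, " must be true/false")
    raw[[cl]] <- v == "true"
  }
  for (cl in c("m", "m_m", "n_draws")) {
    if (is.null(raw[[cl]])) raw[[cl]] <- NA_real_
    raw[[cl]] <- as.numeric(raw[[cl]])
  }
  stopifnot(all(raw$true_category %in% CATEGORIES),
            all(raw$choice %in% CATEGORIES))
  raw <- raw[, TRIAL_COLUMNS]
  class(raw) <- c("trial_table", "data.frame")
  raw
}

#' Split trials by feedback and filter inconsistent estimates
#'
#' Splits a trial table into correct and incorrect trials (by the categorical
#' feedback) and excludes inconsistent trials: trials whose estimate lies on
#' the side of the reference conflicting with the feedback-corrected category
#' (the choice on correct trials, its flip on incorrect trials). An estimate
#' of exactly 0 is never flagged.
#'
#' @param table A `trial_table`.
#' @return List with `correct`, `incorrect`, `excluded` (trial tables) and
#'   `report` (list: `n_total`, `n_excluded`, `excluded_fraction`).
#' @export
split_and_filter <- function(table) {
  stopifnot(all(MANDATORY_COLUMNS %in% names(table)))
  fb_cat <- ifelse(table$choice_correct, table$choice,
                   flip_category(table$choice))
  ok <- table$estimate_deg == 0 |
    sign_category(table$estimate_deg) == fb_cat
  excluded <- table[!ok, , drop = FALSE]
  kept <- table[ok, , drop = FALSE]
  list(
    correct = kept[kept$choice_correct, , drop = FALSE],
    incorrect = kept[!kept$choice_correct, , drop = FALSE],
    excluded = excluded,
    report = list(n_total = nrow(table), n_excluded = nrow(excluded),
                  excluded_fraction = nrow(excluded) / nrow(table))
  )
}
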