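# Synthetic trial-sequence generator.
#
# The generative model mirrors a near-threshold orientation-discrimination
# session: on every trial an equiprobable left/right Gabor is judged from a
# single Gaussian evidence sample, awareness is an exogenous Bernoulli state
# that sets the effective sensitivity, confidence thresholds the absolute
# evidence, and the *prospective* decision made before the trial is a
# Bernoulli draw whose log-odds are a linear function of correctness,
# awareness and confidence on the preceding 1..4 trials.

#' Default lagged log-odds weights
#'
#' A 4 x 4 matrix of log-odds weights (rows = lags 1..4; columns =
#' `correctness`, `awareness`, `confidence`, `prospective`) used by
#' [generator_config()]. Lag-1 awareness and confidence carry weight
#' `log(3)` (an odds ratio of 3), correctness a much smaller `log(1.2)`,
#' and weights decay geometrically by 1/2 per additional lag so that
#' decodability falls off with lag. The `prospective` column (an
#' autoregressive term on the decision itself) defaults to zero.
#'
#' @param decay geometric decay factor applied per additional lag.
#' @return numeric matrix with dimnames `lag1..lag4` x feature names.
#' @export
default_lag_weights <- function(decay = 0.5) {
  lag1 <- c(correctness = log(1.2), awareness = log(3), confidence = log(3),
            prospective = 0)
  w <- outer(decay^(0:3), lag1)
  dimnames(w) <- list(paste0("lag", 1:4), names(lag1))
  w
}

#' Configuration of the synthetic trial-sequence generator
#'
#' Bundles the full generative parameterization: session geometry, the
#' type-1 signal-detection evidence model, the confidence model, and the
#' lagged logistic weights driving the prospective decision. The defaults
#' are calibrated to the belief-of-success experiment: 15 subjects of 12
#' blocks x 50 trials, awareness held at 0.5 (as a luminance staircase
#' would), sensitivity 1.2 on aware and 0.3 on unaware trials, and a
#' confidence model (`conf_threshold = 0.95`, `conf_noise_sd = 0.3`,
#' `conf_aware_shift = 0.3`) tuned so the three pairwise phi correlations
#' between correctness, awareness and confidence land near 0.17-0.23.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_blocks blocks per subject.
#' @param trials_per_block trials per block.
#' @param p_aware probability of an aware trial.
#' @param dprime_aware type-1 sensitivity (d') on aware trials.
#' @param dprime_unaware type-1 sensitivity on unaware trials.
#' @param type1_criterion type-1 decision criterion (evidence units).
#' @param conf_threshold evidence magnitude above which confidence is high.
#' @param conf_noise_sd SD of Gaussian noise added to the confidence signal.
#' @param conf_aware_shift reduction of the confidence threshold on aware
#'   trials; induces the awareness-confidence association.
#' @param beta0 log-odds intercept of the prospective decision.
#' @param beta 4 x 4 numeric matrix of lagged log-odds weights, rows =
#'   lags 1..4, columns `correctness`, `awareness`, `confidence`,
#'   `prospective` (see [default_lag_weights()]). Lagged predictors are
#'   centered at 0.5, so `beta0 = 0` gives a 0.5 base rate.
#' @param warmup_trials leading trials simulated then discarded so every
#'   retained trial has a full lag history; must be at least the largest
#'   lag with a nonzero weight.
#' @param experiment label attached to the generated table, `"belief"` or
#'   `"attention"`.
#' @param seed integer master seed; subject substreams are derived from it.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_subjects = 15,
                             n_blocks = 12,
                             trials_per_block = 50,
                             p_aware = 0.5,
                             dprime_aware = 1.2,
                             dprime_unaware = 0.3,
                             type1_criterion = 0,
                             conf_threshold = 0.95,
                             conf_noise_sd = 0.3,
                             conf_aware_shift = 0.3,
                             beta0 = 0,
                             beta = default_lag_weights(),
                             warmup_trials = 4,
                             experiment = c("belief", "attention"),
                             seed = 1L) {
  experiment <- match.arg(experiment)
  beta <- as.matrix(beta)
  cfg <- structure(
    list(n_subjects = n_subjects, n_blocks = n_blocks,
         trials_per_block = trials_per_block, p_aware = p_aware,
         dprime_aware = dprime_aware, dprime_unaware = dprime_unaware,
         type1_criterion = type1_criterion, conf_threshold = conf_threshold,
         conf_noise_sd = conf_noise_sd, conf_aware_shift = conf_aware_shift,
         beta0 = beta0, beta = beta, warmup_trials = warmup_trials,
         experiment = experiment, seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid generator configuration: field '", field, "' ", msg,
         call. = FALSE)
  }
  for (f in c("n_subjects", "n_blocks", "trials_per_block")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      fail(f, "must be a positive integer")
  }
  if (!is.numeric(cfg$p_aware) || cfg$p_aware < 0 || cfg$p_aware > 1)
    fail("p_aware", "must be a probability in [0, 1]")
  if (cfg$dprime_unaware < 0) fail("dprime_unaware", "must be >= 0")
  if (cfg$dprime_aware < cfg$dprime_unaware)
    fail("dprime_aware", "must be >= dprime_unaware")
  if (cfg$conf_noise_sd < 0) fail("conf_noise_sd", "must be >= 0")
  b <- cfg$beta
  if (!is.matrix(b) || nrow(b) != 4 || ncol(b) != 4 ||
      !identical(colnames(b),
                 c("correctness", "awareness", "confidence", "prospective")))
    fail("beta", paste("must be a 4 x 4 matrix with columns",
                       "correctness, awareness, confidence, prospective"))
  max_lag <- max(c(0L, which(rowSums(abs(b)) > 0)))
  if (cfg$warmup_trials < max_lag)
    fail("warmup_trials", sprintf(
      "must be >= %d, the largest lag with a nonzero weight", max_lag))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    fail("seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d subjects x %d blocks x %d trials (%s), seed %d\n",
    x$n_subjects, x$n_blocks, x$trials_per_block, x$experiment, x$seed))
  cat(sprintf("  evidence: d'_aware=%.2f d'_unaware=%.2f c=%.2f P(aware)=%.2f\n",
              x$dprime_aware, x$dprime_unaware, x$type1_criterion, x$p_aware))
  cat(sprintf("  confidence: threshold=%.2f noise=%.2f aware shift=%.2f\n",
              x$conf_threshold, x$conf_noise_sd, x$conf_aware_shift))
  cat("  lag-1 odds ratios:",
      paste(sprintf("%s=%.2f", colnames(x$beta), exp(x$beta[1, ])),
            collapse = " "), "\n")
  invisible(x)
}

#' Simulate one subject's trial sequence
#'
#' Simulates `warmup_trials + n_blocks * trials_per_block` trials from the
#' generative model and discards the warm-up so every retained trial has a
#' full lag history. Stimulus is left/right with equal probability;
#' awareness is Bernoulli(`p_aware`); a single evidence sample
#' `e ~ N(s * d/2, 1)` (with `d` the awareness-dependent sensitivity and
#' `s = +1` for left) is thresholded at the type-1 criterion for the
#' orientation response; confidence is high when
#' `|e - c| + noise > conf_threshold - awareness * conf_aware_shift`; and
#' the prospective decision is Bernoulli with log-odds
#' `beta0 + sum_k beta[k, f] * (x[f, t-k] - 0.5)` over the lagged,
#' 0.5-centered features.
#'
#' @param config a [generator_config()].
#' @param subject_id character or integer subject identifier.
#' @param substream_seed integer seed for this subject's random substream.
#' @return a trial table (see [as_trial_table()]) with
#'   `n_blocks * trials_per_block` rows.
#' @export
simulate_subject <- function(config, subject_id, substream_seed) {
  validate_generator_config(config)
  n_keep <- config$n_blocks * config$trials_per_block
  n_tot <- n_keep + config$warmup_trials
  set.seed(as.integer(substream_seed))

  s <- sample(c(1L, -1L), n_tot, replace = TRUE)         # +1 = left
  aware <- stats::rbinom(n_tot, 1L, config$p_aware)
  d <- ifelse(aware == 1L, config$dprime_aware, config$dprime_unaware)
  e <- stats::rnorm(n_tot, mean = s * d / 2, sd = 1)
  resp <- ifelse(e > config$type1_criterion, 1L, -1L)
  correct <- as.integer(resp == s)
  conf_signal <- abs(e - config$type1_criterion) +
    stats::rnorm(n_tot, 0, config$conf_noise_sd)
  confidence <- as.integer(conf_signal >
                             config$conf_threshold - aware * config$conf_aware_shift)

  # prospective decision: sequential because it may depend on its own lags
  u <- stats::runif(n_tot)
  prospective <- integer(n_tot)
  beta <- config$beta
  feats <- cbind(correctness = correct, awareness = aware,
                 confidence = confidence, prospective = prospective)
  for (t in seq_len(n_tot)) {
    lp <- config$beta0
    for (k in 1:4) {
      if (t - k >= 1) {
        feats[t - k, "prospective"] <- prospective[t - k]
        lp <- lp + sum(beta[k, ] * (feats[t - k, ] - 0.5))
      }
    }
    prospective[t] <- as.integer(u[t] < stats::plogis(lp))
  }

  keep <- (config$warmup_trials + 1):n_tot
  tbl <- tibble::tibble(
    subject = as.character(subject_id),
    experiment = config$experiment,
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    trial = rep(seq_len(config$trials_per_block), times = config$n_blocks),
    prospective = prospective[keep],
    stimulus = ifelse(s[keep] == 1L, "left", "right"),
    response = ifelse(resp[keep] == 1L, "left", "right"),
    correct = correct[keep],
    awareness = aware[keep],
    confidence = confidence[keep])
  as_trial_table(tbl)
}

#' Simulate a full multi-subject experiment
#'
#' Draws one independent substream seed per subject from the master seed
#' and concatenates [simulate_subject()] across subjects, so the same
#' `(config, seed)` pair always reproduces the identical table.
#'
#' @param config a [generator_config()].
#' @return a trial table of `n_subjects * n_blocks * trials_per_block` rows
#'   with subjects labelled `s01`, `s02`, ...
#' @export
simulate_experiment <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, config$n_subjects)
  ids <- sprintf("s%02d", seq_len(config$n_subjects))
  tabs <- lapply(seq_len(config$n_subjects), function(i)
    simulate_subject(config, ids[i], sub_seeds[i]))
  as_trial_table(dplyr::bind_rows(tabs))
}

#' Calibration summary of a trial table
#'
#' Per-subject phi correlations between the three same-trial feature pairs
#' (awareness-confidence, correctness-awareness, correctness-confidence)
#' and the per-subject proportion of high prospective decisions, summarised
#' across subjects. Because phi is bounded in \[-1, 1\], the one-sample
#' t-tests against zero are run on arc-hyperbolic-tangent (Fisher)
#' transformed values; means and SDs are reported back on the phi scale.
#' Subjects for whom a phi is undefined (a constant feature column) are
#' dropped from that pair's summary with a warning.
#'
#' @param table a trial table with at least 2 subjects.
#' @return a list of class `calibration_summary` with components
#'   `by_subject` (tibble of per-subject statistics) and `summary`
#'   (tibble: statistic, mean, sd, t, df, p_value).
#' @export
summarize_calibration <- function(table) {
  table <- as_trial_table(table)
  if (dplyr::n_distinct(table$subject) < 2)
    stop("summarize_calibration() needs at least 2 subjects", call. = FALSE)
  safe_phi <- function(x, y) tryCatch(phi_correlation(x, y),
                                      warning = function(w) NA_real_)
  by_subject <- table |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      phi_aw_conf = safe_phi(.data$awareness, .data$confidence),
      phi_corr_aw = safe_phi(.data$correct, .data$awareness),
      phi_corr_conf = safe_phi(.data$correct, .data$confidence),
      p_high_prospective = mean(.data$prospective),
      p_aware = mean(.data$awareness),
      .groups = "drop")

  one <- function(name, v) {
    dropped <- sum(is.na(v))
    if (dropped > 0)
      warning(sprintf("%s undefined for %d subject(s); excluded from summary",
                      name, dropped), call. = FALSE)
    v <- v[!is.na(v)]
    tt <- if (length(v) >= 2 && stats::sd(v) > 0) {
      z <- if (startsWith(name, "phi")) atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)) else v
      stats::t.test(z, mu = if (startsWith(name, "phi")) 0 else 0.5)
    } else NULL
    tibble::tibble(statistic = name, mean = mean(v), sd = stats::sd(v),
                   n = length(v),
                   t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                   df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                   p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  summary <- dplyr::bind_rows(
    one("phi_aw_conf", by_subject$phi_aw_conf),
    one("phi_corr_aw", by_subject$phi_corr_aw),
    one("phi_corr_conf", by_subject$phi_corr_conf),
    one("p_high_prospective", by_subject$p_high_prospective))
  structure(list(by_subject = by_subject, summary = summary),
            class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat("<calibration_summary> across", nrow(x$by_subject), "subjects\n")
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write the generator ground truth next to a trial CSV
#'
#' Saves the full generator configuration as a JSON sidecar so that
#' parameter-recovery analyses can compare estimates against the exact
#' generative weights.
#'
#' @param config a [generator_config()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(config, path) {
  validate_generator_config(config)
  out <- unclass(config)
  out$beta <- as.data.frame(out$beta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a generator configuration from YAML or JSON
#'
#' Accepts a file mirroring [generator_config()] field-for-field; `beta`
#' may be given as a 4 x 4 matrix (list of rows or data frame columns).
#' Missing fields take the package defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$beta)) raw$beta <- canonical_beta(raw$beta)
  do.call(generator_config, raw)
}

# accept a beta matrix serialized as a matrix, a data frame, a named list
# of feature columns (YAML) or a list of lag rows
canonical_beta <- function(b) {
  feats <- c("correctness", "awareness", "confidence", "prospective")
  if (is.data.frame(b)) {
    b <- as.matrix(b)
  } else if (is.list(b)) {
    b <- if (!is.null(names(b)) && all(names(b) %in% feats))
      do.call(cbind, lapply(b, unlist))
    else do.call(rbind, lapply(b, unlist))
  }
  if (!is.null(colnames(b)) && all(feats %in% colnames(b)))
    b <- b[, feats, drop = FALSE]
  matrix(as.numeric(b), nrow = 4, ncol = 4,
         dimnames = list(paste0("lag", 1:4), feats))
}
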