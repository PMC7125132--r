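# End-to-end orchestration: simulate -> validate -> decode -> SDT ->
# transfer -> report, with one mandatory master seed and a JSON manifest.

#' Full pipeline configuration
#'
#' @param generator_belief,generator_attention [generator_config()]s for
#'   the two simulated experiments. Defaults: 15 belief subjects and 16
#'   attention subjects sharing the same lagged weights.
#' @param lags lags to decode.
#' @param n_splits shuffle splits per cross-validation.
#' @param n_permutations permutation iterations per null.
#' @param test_fraction held-out fraction.
#' @param n_transfer_iterations iterations per transfer direction.
#' @param n_group_resamples sign-flip resamples for group inference.
#' @param sdt_pad,m_ratio_epsilon see [fit_meta_d()].
#' @param p_aware_floor see [validate_subjects()].
#' @param output_dir directory for all outputs.
#' @param seed mandatory master seed.
#' @param fast if `TRUE`, run with 20 splits / 20 permutations / 20
#'   transfer iterations instead of 100 each.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator_belief = NULL,
                            generator_attention = NULL,
                            lags = 1:4, n_splits = 100, n_permutations = 100,
                            test_fraction = 0.2,
                            n_transfer_iterations = 100,
                            n_group_resamples = 10000,
                            sdt_pad = 1 / 8, m_ratio_epsilon = 0.1,
                            p_aware_floor = 0.05,
                            output_dir = "metalag_results",
                            seed, fast = FALSE) {
  if (missing(seed) || is.null(seed))
    stop("pipeline_config() requires an explicit seed", call. = FALSE)
  seed <- as.integer(seed)
  if (fast) {
    n_splits <- min(n_splits, 20)
    n_permutations <- min(n_permutations, 20)
    n_transfer_iterations <- min(n_transfer_iterations, 20)
  }
  if (is.null(generator_belief))
    generator_belief <- generator_config(n_subjects = 15,
                                         experiment = "belief", seed = seed)
  if (is.null(generator_attention))
    generator_attention <- generator_config(n_subjects = 16,
                                            experiment = "attention",
                                            seed = seed + 1L)
  structure(list(generator_belief = generator_belief,
                 generator_attention = generator_attention,
                 lags = lags, n_splits = n_splits,
                 n_permutations = n_permutations,
                 test_fraction = test_fraction,
                 n_transfer_iterations = n_transfer_iterations,
                 n_group_resamples = n_group_resamples,
                 sdt_pad = sdt_pad, m_ratio_epsilon = m_ratio_epsilon,
                 p_aware_floor = p_aware_floor,
                 output_dir = output_dir, seed = seed, fast = fast),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level fields mirror [pipeline_config()]; `generator_belief` and
#' `generator_attention` are nested [generator_config()] field lists.
#'
#' @param path YAML or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  for (g in c("generator_belief", "generator_attention"))
    if (!is.null(raw[[g]])) {
      gl <- raw[[g]]
      if (!is.null(gl$beta)) gl$beta <- canonical_beta(gl$beta)
      raw[[g]] <- do.call(generator_config, gl)
    }
  do.call(pipeline_config, raw)
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[metalag %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Simulates both experiments, applies subject exclusion, runs per-subject
#' lag-wise decoding with permutation nulls, group sign-flip inference,
#' odds-ratio attribution, conditional-probability and calibration
#' summaries, the awareness x prospective SDT grid, and bidirectional
#' cross-experiment transfer; writes every table as CSV plus a JSON
#' manifest into `config$output_dir`. Re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress messages.
#' @return (invisibly) a named list with every result object and the
#'   manifest.
#' @export
run_full_analysis <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  set.seed(config$seed)
  stage_seeds <- as.list(sample.int(.Machine$integer.max, 6))
  names(stage_seeds) <- c("decode_belief", "decode_attention", "group",
                          "odds", "transfer_ba", "transfer_ab")
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  stage_msg(verbose, "simulate: %d + %d subjects",
            config$generator_belief$n_subjects,
            config$generator_attention$n_subjects)
  belief <- simulate_experiment(config$generator_belief)
  attention <- simulate_experiment(config$generator_attention)
  write_trials(belief, out("trials_belief.csv"))
  write_trials(attention, out("trials_attention.csv"))
  write_ground_truth(config$generator_belief, out("ground_truth_belief.json"))
  write_ground_truth(config$generator_attention,
                     out("ground_truth_attention.json"))

  stage_msg(verbose, "validate: exclusion rules")
  excl_belief <- validate_subjects(belief, config$p_aware_floor)
  excl_attention <- validate_subjects(attention, config$p_aware_floor)
  write_exclusion_report(excl_belief, out("exclusions_belief.json"))
  write_exclusion_report(excl_attention, out("exclusions_attention.json"))
  belief <- excl_belief$retained
  attention <- excl_attention$retained

  stage_msg(verbose, "calibration summaries")
  calib <- withCallingHandlers(
    list(belief = summarize_calibration(belief),
         attention = summarize_calibration(attention)),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(calib$belief$summary, experiment = "belief", .before = 1),
    dplyr::mutate(calib$attention$summary, experiment = "attention",
                  .before = 1)), out("calibration.csv"), progress = FALSE)

  stage_msg(verbose, "decode: %d splits x %d permutations, lags {%s}",
            config$n_splits, config$n_permutations,
            paste(config$lags, collapse = ","))
  dec <- list(
    belief = decode_table(belief, lags = config$lags,
                          n_splits = config$n_splits,
                          n_permutations = config$n_permutations,
                          test_fraction = config$test_fraction,
                          seed = stage_seeds$decode_belief),
    attention = decode_table(attention, lags = config$lags,
                             n_splits = config$n_splits,
                             n_permutations = config$n_permutations,
                             test_fraction = config$test_fraction,
                             seed = stage_seeds$decode_attention))
  decoding_csv <- dplyr::bind_rows(
    dplyr::mutate(dec$belief$summary, experiment = "belief", .before = 1),
    dplyr::mutate(dec$attention$summary, experiment = "attention",
                  .before = 1))
  readr::write_csv(decoding_csv, out("decoding.csv"), progress = FALSE)

  stage_msg(verbose, "group significance (sign-flip, %d resamples)",
            config$n_group_resamples)
  group <- dplyr::bind_rows(
    dplyr::mutate(group_significance(dec$belief, config$n_group_resamples,
                                     stage_seeds$group),
                  experiment = "belief", .before = 1),
    dplyr::mutate(group_significance(dec$attention, config$n_group_resamples,
                                     stage_seeds$group),
                  experiment = "attention", .before = 1))
  readr::write_csv(group, out("group_significance.csv"), progress = FALSE)

  stage_msg(verbose, "odds ratios (+ bootstrap CIs)")
  ors <- list(belief = odds_ratios(dec$belief, belief, seed = stage_seeds$odds),
              attention = odds_ratios(dec$attention, attention,
                                      seed = stage_seeds$odds))
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(ors$belief$group, experiment = "belief", .before = 1),
    dplyr::mutate(ors$attention$group, experiment = "attention",
                  .before = 1)), out("odds_ratios.csv"), progress = FALSE)

  stage_msg(verbose, "univariate conditional probabilities")
  cond <- dplyr::bind_rows(
    dplyr::mutate(conditional_probabilities(belief), experiment = "belief",
                  .before = 1),
    dplyr::mutate(conditional_probabilities(attention),
                  experiment = "attention", .before = 1))
  readr::write_csv(cond, out("conditional_probabilities.csv"),
                   progress = FALSE)

  stage_msg(verbose, "SDT grid (d', meta-d', M-ratio)")
  sdt <- withCallingHandlers(
    dplyr::bind_rows(
      dplyr::mutate(condition_sdt_grid(belief, config$sdt_pad,
                                       config$m_ratio_epsilon),
                    experiment = "belief", .before = 1),
      dplyr::mutate(condition_sdt_grid(attention, config$sdt_pad,
                                       config$m_ratio_epsilon),
                    experiment = "attention", .before = 1)),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  readr::write_csv(sdt, out("sdt_grid.csv"), progress = FALSE)

  stage_msg(verbose, "transfer decoding (both directions)")
  transfer_rows <- list()
  for (k in config$lags) {
    ba <- transfer_decode(belief, attention, k,
                          n_iterations = config$n_transfer_iterations,
                          n_permutations = config$n_permutations,
                          test_fraction = config$test_fraction,
                          seed = stage_seeds$transfer_ba + k)
    ab <- transfer_decode(attention, belief, k,
                          n_iterations = config$n_transfer_iterations,
                          n_permutations = config$n_permutations,
                          test_fraction = config$test_fraction,
                          seed = stage_seeds$transfer_ab + k)
    transfer_rows[[as.character(k)]] <- tibble::tibble(
      direction = c(ba$direction, ab$direction), lag = k,
      mean_auc = c(ba$mean_auc, ab$mean_auc),
      chance = c(mean(ba$null_means), mean(ab$null_means)),
      p = c(ba$p_value, ab$p_value))
  }
  transfer <- dplyr::bind_rows(transfer_rows)
  readr::write_csv(transfer, out("transfer.csv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metalag")),
    r_version = R.version.string,
    seed = config$seed, fast = config$fast,
    stage_seeds = stage_seeds,
    config = list(
      lags = config$lags, n_splits = config$n_splits,
      n_permutations = config$n_permutations,
      test_fraction = config$test_fraction,
      n_transfer_iterations = config$n_transfer_iterations,
      n_group_resamples = config$n_group_resamples,
      sdt_pad = config$sdt_pad, m_ratio_epsilon = config$m_ratio_epsilon,
      p_aware_floor = config$p_aware_floor),
    excluded_subjects = list(
      belief = excl_belief$report$subject[!excl_belief$report$retained],
      attention = excl_attention$report$subject[!excl_attention$report$retained]),
    warnings = warnings_log)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage_msg(verbose, "done: outputs in %s", config$output_dir)
  invisible(list(belief = belief, attention = attention,
                 calibration = calib, decoding = dec, group = group,
                 odds_ratios = ors, conditional = cond, sdt = sdt,
                 transfer = transfer, manifest = manifest))
}
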