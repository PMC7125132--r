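# Cross-experiment transfer decoding: train on one prospective-decision
# type (e.g. beliefs of success), test on the other (decisions to engage
# attention), on data pooled across subjects.

pooled_design <- function(table, lag, within_block = FALSE) {
  table <- as_trial_table(table)
  parts <- lapply(unique(table$subject), function(s)
    build_lagged_design(table, s, lag, within_block = within_block))
  structure(list(
    features = do.call(rbind, lapply(parts, `[[`, "features")),
    target = unlist(lapply(parts, `[[`, "target")),
    lag = as.integer(lag), subject = "pooled",
    n = sum(vapply(parts, `[[`, integer(1), "n"))),
    class = "lagged_design")
}

transfer_iterations <- function(src, tgt, n_iterations, test_fraction) {
  cell_src <- cell_index(src$features)
  cell_tgt <- cell_index(tgt$features)
  X8 <- cell_design()
  y_src <- as.integer(src$target)
  y_tgt <- as.integer(tgt$target)
  n_test <- max(1L, floor(tgt$n * test_fraction))
  n_train <- max(1L, floor(src$n * 0.8))
  vapply(seq_len(n_iterations), function(i) {
    train <- draw_split(src$n, y_src, src$n - n_train)  # held-out 20% unused
    test <- draw_split(tgt$n, y_tgt, n_test)
    fit <- fit_logistic_cells(cell_src[-train], y_src[-train], X8)
    auc_score(fit$prob[cell_tgt[test]], y_tgt[test])
  }, numeric(1))
}

#' Cross-experiment transfer decoding at one lag
#'
#' Pools the lag-k designs of all subjects within each experiment, then for
#' each of `n_iterations` draws fits the unpenalised logistic model on a
#' random 80% of the *source* rows and scores ROC AUC on a random 20% of
#' the *target* rows. Significance against chance uses the same
#' independently-shuffled permutation-null construction as within-
#' experiment decoding, applied to the pooled target design:
#' `p = (1 + #\{null mean >= observed mean\}) / (1 + n_permutations)`.
#'
#' @param source,target trial tables for the source (training) and target
#'   (testing) experiments.
#' @param lag lag k.
#' @param n_iterations transfer iterations.
#' @param n_permutations permutation iterations for the null (each re-runs
#'   `n_iterations` transfer draws on a shuffled target).
#' @param test_fraction target fraction scored per iteration.
#' @param seed integer seed.
#' @param within_block restrict lag pairs to within-block (see
#'   [build_lagged_design()]).
#' @return a `transfer_result`: list with `direction`, `lag`,
#'   `iteration_aucs`, `mean_auc`, `null_means`, `p_value`.
#' @export
transfer_decode <- function(source, target, lag, n_iterations = 100,
                            n_permutations = 100, test_fraction = 0.2,
                            seed = 1L, within_block = FALSE) {
  source <- as_trial_table(source)
  target <- as_trial_table(target)
  src <- pooled_design(source, lag, within_block)
  tgt <- pooled_design(target, lag, within_block)
  direction <- paste0(source$experiment[1], "->", target$experiment[1])
  set.seed(as.integer(seed))
  iter_seed <- sample.int(.Machine$integer.max, 1)
  perm_seeds <- sample.int(.Machine$integer.max, n_permutations)
  set.seed(iter_seed)
  aucs <- transfer_iterations(src, tgt, n_iterations, test_fraction)
  obs <- mean(aucs)
  null_means <- vapply(seq_len(n_permutations), function(p) {
    set.seed(perm_seeds[p])
    shuf <- tgt
    shuf$features <- tgt$features[sample.int(tgt$n), , drop = FALSE]
    shuf$target <- tgt$target[sample.int(tgt$n)]
    mean(transfer_iterations(src, shuf, n_iterations, test_fraction))
  }, numeric(1))
  p <- (1 + sum(null_means >= obs)) / (1 + n_permutations)
  structure(list(direction = direction, lag = as.integer(lag),
                 iteration_aucs = aucs, mean_auc = obs,
                 null_means = null_means, p_value = p),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s, lag %d: mean AUC %.3f (chance %.3f), p = %.4g\n",
              x$direction, x$lag, x$mean_auc, mean(x$null_means), x$p_value))
  invisible(x)
}
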