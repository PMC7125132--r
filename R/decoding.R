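# Lag-k history decoding: shuffle-split cross-validated logistic
# classification of the prospective decision from the (correctness,
# awareness, confidence) pattern k trials back, scored by ROC AUC, with an
# independently-shuffled permutation null, sign-flip group inference,
# odds-ratio attribution and univariate diagnostics.

feature_names <- c("correctness", "awareness", "confidence")

#' Build a single-lag design for one subject
#'
#' Pairs the binary features (correctness, awareness, confidence) of trial
#' `t - lag` with the prospective decision at trial `t`, over the subject's
#' concatenated session order. The first `lag` trials produce no rows. By
#' default block boundaries are not breaks; set `within_block = TRUE` to
#' drop pairs spanning blocks.
#'
#' @param table a `trial_table`.
#' @param subject subject identifier present in `table`.
#' @param lag k in 1..4 (any positive lag below the trial count is
#'   accepted).
#' @param within_block drop rows whose feature and target trials fall in
#'   different blocks.
#' @return a `lagged_design`: list with `features` (n x 3 integer matrix),
#'   `target` (length-n 0/1 vector), `lag`, `subject`, `n`.
#' @export
build_lagged_design <- function(table, subject, lag, within_block = FALSE) {
  table <- as_trial_table(table)
  sub <- table[table$subject == subject, ]
  if (nrow(sub) == 0)
    stop("subject '", subject, "' not present in table", call. = FALSE)
  n_trials <- nrow(sub)
  if (!is.numeric(lag) || length(lag) != 1 || lag < 1 || lag != round(lag) ||
      lag >= n_trials)
    stop("'lag' must be a positive integer below the subject's trial count (",
         n_trials, ")", call. = FALSE)
  src <- seq_len(n_trials - lag)
  tgt <- src + lag
  if (within_block) {
    keep <- sub$block[src] == sub$block[tgt]
    src <- src[keep]; tgt <- tgt[keep]
  }
  features <- cbind(correctness = sub$correct[src],
                    awareness = sub$awareness[src],
                    confidence = sub$confidence[src])
  structure(list(features = features, target = sub$prospective[tgt],
                 lag = as.integer(lag), subject = subject,
                 n = length(tgt)),
            class = "lagged_design")
}

#' ROC AUC of scores against binary labels
#'
#' Rank-based (Mann-Whitney) area under the ROC curve; tied scores
#' contribute half a concordance. Equals the probability that a random
#' positive outranks a random negative.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("auc_score() needs both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Unpenalised logistic fit on a lagged design, aggregated over the (at
# most 8) distinct binary feature patterns: maximum-likelihood equivalent
# to a row-wise fit but far cheaper inside the shuffle-split loops.
# Returns the coefficient vector (intercept + 3 features; aliased
# zero-variance columns give NA) and per-pattern fitted probabilities.
fit_logistic_cells <- function(cell, y, X8) {
  n1 <- tabulate(cell[y == 1L], nbins = 8L)
  n0 <- tabulate(cell[y == 0L], nbins = 8L)
  tot <- n1 + n0
  keep <- tot > 0
  fit <- suppressWarnings(stats::glm.fit(
    x = X8[keep, , drop = FALSE], y = n1[keep] / tot[keep],
    weights = tot[keep], family = stats::binomial(),
    control = list(epsilon = 1e-8, maxit = 100)))
  beta <- fit$coefficients
  b <- ifelse(is.na(beta), 0, beta)
  list(coef = beta, prob = as.vector(stats::plogis(X8 %*% b)))
}

cell_index <- function(features)
  1L + features[, 1L] + 2L * features[, 2L] + 4L * features[, 3L]

cell_design <- function() {
  g <- as.matrix(expand.grid(correctness = 0:1, awareness = 0:1,
                             confidence = 0:1))
  cbind(`(Intercept)` = 1, g)
}

draw_split <- function(n, target, n_test, max_attempts = 1000) {
  for (i in seq_len(max_attempts)) {
    test <- sample.int(n, n_test)
    yte <- target[test]; ytr <- target[-test]
    if (any(yte == 1) && any(yte == 0) && any(ytr == 1) && any(ytr == 0))
      return(test)
  }
  stop("could not draw a train/test split containing both classes in ",
       max_attempts, " attempts", call. = FALSE)
}

#' Shuffle-split cross-validated decoding of one lagged design
#'
#' Repeats `n_splits` times: randomly hold out `test_fraction` of the rows,
#' fit an unpenalised logistic regression (the maximum-likelihood model,
#' emulating a classifier with negligible regularisation) on the remainder,
#' and score the held-out probabilistic predictions by ROC AUC. Splits in
#' which either side lacks a target class are re-drawn (at most 1000
#' attempts).
#'
#' @param design a `lagged_design`.
#' @param n_splits number of random splits.
#' @param test_fraction held-out fraction per split.
#' @param seed integer seed for the split stream.
#' @return list with `fold_aucs` (length `n_splits`) and `coefficients`
#'   (`n_splits` x 4 matrix: intercept + the three features; `NA` for a
#'   zero-variance feature).
#' @export
cross_validated_auc <- function(design, n_splits = 100, test_fraction = 0.2,
                                seed = 1L) {
  stopifnot(inherits(design, "lagged_design"))
  y <- as.integer(design$target)
  if (!any(y == 1) || !any(y == 0))
    stop("both target classes must be present in the design", call. = FALSE)
  n <- design$n
  n_test <- max(1L, floor(n * test_fraction))
  cell <- cell_index(design$features)
  X8 <- cell_design()
  set.seed(as.integer(seed))
  fold_aucs <- numeric(n_splits)
  coefs <- matrix(NA_real_, n_splits, 4,
                  dimnames = list(NULL, c("(Intercept)", feature_names)))
  for (i in seq_len(n_splits)) {
    test <- draw_split(n, y, n_test)
    fit <- fit_logistic_cells(cell[-test], y[-test], X8)
    fold_aucs[i] <- auc_score(fit$prob[cell[test]], y[test])
    coefs[i, ] <- fit$coef
  }
  list(fold_aucs = fold_aucs, coefficients = coefs)
}

#' Permutation null for one lagged design
#'
#' Repeats the full shuffle-split cross-validation after permuting the
#' feature rows and the target entries *independently*, destroying any
#' feature-target association while preserving both marginals. The mean
#' AUC of each permutation iteration is returned; the across-iteration
#' mean is the empirical chance level.
#'
#' @inheritParams cross_validated_auc
#' @param n_permutations number of independent permutation iterations.
#' @param n_splits splits per iteration.
#' @return numeric vector of `n_permutations` mean AUCs.
#' @export
empirical_null <- function(design, n_permutations = 100, n_splits = 100,
                           test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(design, "lagged_design"))
  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max, n_permutations)
  vapply(seq_len(n_permutations), function(p) {
    set.seed(perm_seeds[p])
    d <- design
    d$features <- design$features[sample.int(design$n), , drop = FALSE]
    d$target <- design$target[sample.int(design$n)]
    cv <- cross_validated_auc(d, n_splits = n_splits,
                              test_fraction = test_fraction,
                              seed = sample.int(.Machine$integer.max, 1))
    mean(cv$fold_aucs)
  }, numeric(1))
}

#' Decode a whole experiment, per subject and lag
#'
#' Runs [build_lagged_design()], [cross_validated_auc()] and
#' [empirical_null()] for every subject x lag, and summarises each with the
#' mean decoding AUC, the empirical chance level (mean of the null), a
#' per-subject empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)` and its Bonferroni
#' correction over the number of lags.
#'
#' @param table a `trial_table`.
#' @param lags integer vector of lags.
#' @param n_splits shuffle splits per cross-validation.
#' @param n_permutations permutation iterations per null.
#' @param test_fraction held-out fraction.
#' @param seed master seed; subject/lag substreams derive from it.
#' @return a `decoding_result`: list with `summary` (tibble: subject, lag,
#'   n, mean_auc, empirical_chance, p_uncorrected, p_bonferroni) and
#'   `detail` (per subject x lag list with `fold_aucs`, `null_aucs`,
#'   `coefficients`).
#' @export
decode_table <- function(table, lags = 1:4, n_splits = 100,
                         n_permutations = 100, test_fraction = 0.2,
                         seed = 1L) {
  table <- as_trial_table(table)
  subjects <- unique(table$subject)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max,
                             2 * length(subjects) * length(lags)),
                  nrow = 2)
  detail <- list()
  rows <- list()
  idx <- 0L
  for (s in subjects) for (k in lags) {
    idx <- idx + 1L
    design <- build_lagged_design(table, s, k)
    cv <- cross_validated_auc(design, n_splits = n_splits,
                              test_fraction = test_fraction,
                              seed = seeds[1, idx])
    nulls <- empirical_null(design, n_permutations = n_permutations,
                            n_splits = n_splits,
                            test_fraction = test_fraction,
                            seed = seeds[2, idx])
    mean_auc <- mean(cv$fold_aucs)
    p <- (1 + sum(nulls >= mean_auc)) / (1 + n_permutations)
    key <- paste(s, k, sep = ".")
    detail[[key]] <- list(subject = s, lag = k, fold_aucs = cv$fold_aucs,
                          null_aucs = nulls, coefficients = cv$coefficients)
    rows[[key]] <- tibble::tibble(
      subject = s, lag = k, n = design$n, mean_auc = mean_auc,
      empirical_chance = mean(nulls), p_uncorrected = p,
      p_bonferroni = min(1, length(lags) * p))
  }
  structure(list(summary = dplyr::bind_rows(rows), detail = detail,
                 lags = lags, n_splits = n_splits,
                 n_permutations = n_permutations, seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d subject(s) x lags {%s}, %d splits, %d permutations\n",
              dplyr::n_distinct(x$summary$subject),
              paste(x$lags, collapse = ","), x$n_splits, x$n_permutations))
  agg <- x$summary |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(mean_auc = mean(.data$mean_auc),
                     chance = mean(.data$empirical_chance), .groups = "drop")
  print(as.data.frame(agg), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Group-level permutation significance per lag
#'
#' Sign-flip permutation test on the subject-level differences between the
#' decoding AUC and the empirical chance level: under the null the sign of
#' each subject's difference is exchangeable, so the observed mean
#' difference is compared with its distribution under random sign flips,
#' `p = (1 + #\{|resampled mean| >= |observed mean|\}) / (1 + n_resamples)`,
#' then Bonferroni-corrected over the number of lags.
#'
#' @param results a `decoding_result` (or its `summary` tibble).
#' @param n_resamples sign-flip resamples.
#' @param seed integer seed.
#' @return tibble: lag, n_subjects, mean_diff, p_uncorrected, p_bonferroni.
#' @export
group_significance <- function(results, n_resamples = 10000, seed = 1L) {
  summary <- if (inherits(results, "decoding_result")) results$summary else results
  lags <- sort(unique(summary$lag))
  set.seed(as.integer(seed))
  rows <- lapply(lags, function(k) {
    d <- summary$mean_auc[summary$lag == k] -
      summary$empirical_chance[summary$lag == k]
    if (length(d) < 2)
      stop("group_significance() needs >= 2 subjects per lag", call. = FALSE)
    obs <- mean(d)
    flips <- matrix(sample(c(-1, 1), length(d) * n_resamples, replace = TRUE),
                    nrow = length(d))
    null_means <- colMeans(flips * d)
    p <- (1 + sum(abs(null_means) >= abs(obs))) / (1 + n_resamples)
    tibble::tibble(lag = k, n_subjects = length(d), mean_diff = obs,
                   p_uncorrected = p,
                   p_bonferroni = min(1, length(lags) * p))
  })
  dplyr::bind_rows(rows)
}

#' Odds-ratio attribution of decoder coefficients
#'
#' For each subject x lag x feature, the odds ratio is the exponential of
#' the fold-averaged logistic coefficient; a feature with no influence on
#' the prospective decision has an odds ratio of 1. Group-level 95%
#' confidence intervals are bootstrapped across subjects (percentile
#' method). A full-data refit odds ratio (single unpenalised fit on all
#' rows) is reported alongside for comparison.
#'
#' @param results a `decoding_result`.
#' @param table the trial table the decoding ran on (for the full-data
#'   refit); `NULL` skips the refit column.
#' @param n_boot bootstrap resamples across subjects.
#' @param seed integer seed for the bootstrap.
#' @return an `odds_ratio_table`: list with `by_subject` (tibble: subject,
#'   lag, feature, odds_ratio, odds_ratio_refit) and `group` (tibble: lag,
#'   feature, odds_ratio, ci_low, ci_high).
#' @export
odds_ratios <- function(results, table = NULL, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(results, "decoding_result"))
  rows <- lapply(results$detail, function(d) {
    cm <- colMeans(d$coefficients[, feature_names, drop = FALSE], na.rm = TRUE)
    refit <- rep(NA_real_, 3)
    if (!is.null(table)) {
      des <- build_lagged_design(table, d$subject, d$lag)
      fit <- fit_logistic_cells(cell_index(des$features),
                                as.integer(des$target), cell_design())
      refit <- fit$coef[feature_names]
    }
    tibble::tibble(subject = d$subject, lag = d$lag, feature = feature_names,
                   odds_ratio = exp(unname(cm)),
                   odds_ratio_refit = exp(unname(refit)))
  })
  by_subject <- dplyr::bind_rows(rows)
  set.seed(as.integer(seed))
  keys <- dplyr::distinct(by_subject[c("lag", "feature")])
  group <- dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    sel <- by_subject$lag == keys$lag[i] & by_subject$feature == keys$feature[i]
    v <- by_subject$odds_ratio[sel]
    v <- v[!is.na(v)]
    boots <- vapply(seq_len(n_boot), function(b)
      mean(sample(v, length(v), replace = TRUE)), numeric(1))
    tibble::tibble(lag = keys$lag[i], feature = keys$feature[i],
                   odds_ratio = mean(v),
                   ci_low = stats::quantile(boots, 0.025, names = FALSE),
                   ci_high = stats::quantile(boots, 0.975, names = FALSE))
  }))
  structure(list(by_subject = by_subject, group = group),
            class = "odds_ratio_table")
}

#' @export
print.odds_ratio_table <- function(x, ...) {
  cat("<odds_ratio_table> group-level (bootstrap 95% CI):\n")
  print(as.data.frame(x$group), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Phi coefficient of two binary vectors
#'
#' Pearson correlation of two 0/1 vectors; equivalently
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` from the 2 x 2 table. A
#' constant vector makes phi undefined; `NA` is returned with a warning.
#' For inference, apply `atanh()` (the arc-hyperbolic-tangent / Fisher
#' transform) before testing.
#'
#' @param x,y equal-length binary vectors (length >= 2).
#' @return phi in \[-1, 1\], or `NA` if undefined.
#' @export
phi_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("phi undefined: constant input vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(as.numeric(x), as.numeric(y))
}

#' Conditional probability of the prospective decision given lag-1 history
#'
#' For each subject, estimates
#' `P(prospective_t = 1 | correct_(t-1) = i, aware_(t-1) = j, conf_(t-1) = k)`
#' over all eight history cells, with the number of contributing trial
#' pairs. Empty cells are reported with `n = 0` and `NA` probability.
#'
#' @param table a `trial_table`.
#' @return tibble: subject, correct, aware, conf, p_high, n.
#' @export
conditional_probabilities <- function(table) {
  table <- as_trial_table(table)
  rows <- lapply(unique(table$subject), function(s) {
    sub <- table[table$subject == s, ]
    n <- nrow(sub)
    prev <- seq_len(n - 1)
    df <- tibble::tibble(correct = sub$correct[prev],
                         aware = sub$awareness[prev],
                         conf = sub$confidence[prev],
                         y = sub$prospective[prev + 1])
    full <- tidyr::expand_grid(correct = 0:1, aware = 0:1, conf = 0:1)
    agg <- df |>
      dplyr::group_by(.data$correct, .data$aware, .data$conf) |>
      dplyr::summarise(p_high = mean(.data$y), n = dplyr::n(),
                       .groups = "drop")
    out <- dplyr::left_join(full, agg, by = c("correct", "aware", "conf"))
    out$n[is.na(out$n)] <- 0L
    dplyr::mutate(out, subject = s, .before = 1)
  })
  dplyr::bind_rows(rows)
}
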