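test_that("lagged designs pair trial t-k features with trial t targets", {
  tab <- make_table(stimulus = rep("left", 5),
                    response = c("left", "right", "left", "left", "right"),
                    awareness = c(1L, 0L, 1L, 0L, 1L),
                    confidence = c(0L, 1L, 1L, 0L, 0L),
                    prospective = c(1L, 0L, 1L, 1L, 0L))
  d <- build_lagged_design(tab, "s1", 1)
  expect_equal(d$n, 4)
  expect_equal(unname(d$features[1, ]), c(1, 1, 0))  # trial 1 features
  expect_equal(d$target[1], 0L)                      # trial 2 prospective
  expect_equal(unname(d$features[4, ]), c(1, 0, 0))
  expect_equal(d$target[4], 0L)
  # k = 4 on a 600-trial subject -> 596 rows
  big <- default_experiment()
  expect_equal(build_lagged_design(big, "s01", 4)$n, 596)
  expect_error(build_lagged_design(tab, "s1", 0), "lag")
  expect_error(build_lagged_design(tab, "s1", 5), "lag")
  expect_error(build_lagged_design(tab, "nope", 1), "not present")
})

test_that("within-block designs drop pairs spanning block boundaries", {
  tab <- default_experiment(seed = 9, n_subjects = 2)
  d_all <- build_lagged_design(tab, "s01", 2)
  d_wb <- build_lagged_design(tab, "s01", 2, within_block = TRUE)
  expect_equal(d_all$n - d_wb$n, 2 * (12 - 1))  # 2 pairs lost per boundary
})

test_that("AUC equals exhaustive concordant-pair counting", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(101)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))       # both classes present
    scores <- round(runif(n), 2)                   # induces ties
    expect_equal(auc_score(scores, labels), auc_pairs(scores, labels))
  }
})

test_that("inverting the labels maps the AUC of fixed scores to 1 - AUC", {
  set.seed(19)
  for (i in 1:5) {
    scores <- runif(40)
    labels <- c(0, 1, rbinom(38, 1, 0.5))
    expect_equal(auc_score(scores, 1 - labels), 1 - auc_score(scores, labels))
  }
  # a refit on the inverted target flips the scores too, so the
  # cross-validated AUC itself is invariant
  tab <- default_experiment(seed = 9, n_subjects = 2)
  d <- build_lagged_design(tab, "s01", 1)
  cv <- cross_validated_auc(d, n_splits = 25, seed = 3)
  d_inv <- d
  d_inv$target <- 1L - d$target
  cv_inv <- cross_validated_auc(d_inv, n_splits = 25, seed = 3)
  expect_equal(cv_inv$fold_aucs, cv$fold_aucs, tolerance = 1e-6)
})

test_that("the aggregated logistic fit equals a row-wise ML fit", {
  tab <- default_experiment(seed = 9, n_subjects = 2)
  d <- build_lagged_design(tab, "s01", 1)
  agg <- metalag:::fit_logistic_cells(metalag:::cell_index(d$features),
                                      as.integer(d$target),
                                      metalag:::cell_design())
  ref <- glm(d$target ~ d$features, family = binomial())
  expect_equal(unname(agg$coef), unname(coef(ref)), tolerance = 1e-6)
})

test_that("decoding a target unrelated to the features scores at chance", {
  set.seed(7)
  tab <- default_experiment(seed = 9, n_subjects = 2)
  d <- build_lagged_design(tab, "s01", 1)
  # fold AUCs within one draw are strongly correlated, so average over
  # several independent history-free targets
  means <- vapply(1:5, function(i) {
    d$target <- rbinom(d$n, 1, 0.5)   # independent of all features
    mean(cross_validated_auc(d, n_splits = 20, seed = 5 + i)$fold_aucs)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.04)
})

test_that("a deterministic lag-1 copy is decoded perfectly", {
  tab <- default_experiment(seed = 9, n_subjects = 2)
  tab$prospective <- c(0L, tab$confidence[-nrow(tab)])
  tab <- as_trial_table(tibble::as_tibble(tab)[-1, ])  # drop the seam row
  d <- build_lagged_design(tab[tab$subject == "s01", ], "s01", 1)
  cv <- cross_validated_auc(d, n_splits = 25, seed = 5)
  expect_gte(mean(cv$fold_aucs), 0.99)
})

test_that("zero-variance feature columns pass through the classifier", {
  tab <- default_experiment(seed = 9, n_subjects = 2)
  tab$awareness <- 1L
  d <- build_lagged_design(tab, "s01", 1)
  cv <- cross_validated_auc(d, n_splits = 10, seed = 2)
  expect_true(all(is.na(cv$coefficients[, "awareness"])))
  expect_true(all(is.finite(cv$fold_aucs)))
})

test_that("the permutation null is centered on 0.5 and seed-sensitive", {
  tab <- default_experiment(seed = 9, n_subjects = 2)
  d <- build_lagged_design(tab, "s01", 1)
  null1 <- empirical_null(d, n_permutations = 20, n_splits = 20, seed = 8)
  null2 <- empirical_null(d, n_permutations = 20, n_splits = 20, seed = 9)
  expect_lt(abs(mean(null1) - 0.5), 0.03)
  expect_lt(abs(mean(null2) - 0.5), 0.03)
  expect_false(identical(null1, null2))
  # shuffling destroys even a perfectly predictive feature
  d$target <- d$features[, "confidence"]
  null3 <- empirical_null(d, n_permutations = 20, n_splits = 20, seed = 8)
  expect_lt(abs(mean(null3) - 0.5), 0.03)
})

test_that("group significance behaves under null and strong-signal configurations", {
  fake <- tidyr::expand_grid(subject = sprintf("s%02d", 1:15), lag = 1:4)
  fake$mean_auc <- 0.5
  fake$empirical_chance <- 0.5
  g0 <- group_significance(fake, n_resamples = 2000, seed = 1)
  expect_equal(g0$p_uncorrected, rep(1, 4))
  # 15 subjects all shifted +0.2 -> p at the resolution floor
  fake$mean_auc <- 0.7
  g1 <- group_significance(fake, n_resamples = 2000, seed = 1)
  expect_true(all(g1$p_uncorrected <= 1 / 1000))
  expect_equal(g1$p_bonferroni, pmin(1, 4 * g1$p_uncorrected))
  expect_error(group_significance(fake[fake$subject == "s01", ]),
               ">= 2 subjects")
})

test_that("odds ratios recover generative weights and are 1 for idle features", {
  beta <- default_lag_weights() * 0
  beta["lag1", "confidence"] <- log(3)
  cfg <- generator_config(n_subjects = 15, beta = beta, seed = 51)
  tab <- simulate_experiment(cfg)
  dec <- decode_table(tab, lags = 1, n_splits = 20, n_permutations = 5,
                      seed = 52)
  ors <- odds_ratios(dec, tab, seed = 53)
  conf_row <- ors$group[ors$group$feature == "confidence", ]
  expect_lt(conf_row$ci_low, 3)
  expect_gt(conf_row$ci_high, 3)
  # features with no generative influence sit near an odds ratio of 1
  idle <- ors$group[ors$group$feature != "confidence", ]
  expect_true(all(abs(idle$odds_ratio - 1) < 0.15))
  # fold-averaged and full-data refit odds ratios agree
  expect_equal(ors$by_subject$odds_ratio, ors$by_subject$odds_ratio_refit,
               tolerance = 0.25)
})

test_that("phi is undefined for constant vectors and exact for matched ones", {
  x <- c(0, 1, 0, 1, 1)
  expect_equal(phi_correlation(x, x), 1)
  expect_warning(p <- phi_correlation(rep(1, 5), x), "constant")
  expect_true(is.na(p))
})

test_that("conditional probabilities follow a deterministic lag-1 rule", {
  tab <- default_experiment(seed = 9, n_subjects = 2)
  tab$prospective <- c(0L, tab$confidence[-nrow(tab)])
  tab <- as_trial_table(tibble::as_tibble(tab)[-1, ])
  cp <- conditional_probabilities(tab[tab$subject == "s01", ])
  expect_equal(nrow(cp), 8)
  expect_true(all(cp$p_high[cp$conf == 1 & cp$n > 0] == 1))
  expect_true(all(cp$p_high[cp$conf == 0 & cp$n > 0] == 0))
  expect_equal(sum(cp$n), sum(tab$subject == "s01") - 1)
})

test_that("prospective decisions driven only by awareness vary only over awareness", {
  beta <- default_lag_weights() * 0
  beta["lag1", "awareness"] <- 1.5
  cfg <- generator_config(n_subjects = 10, beta = beta, seed = 61)
  cp <- conditional_probabilities(simulate_experiment(cfg))
  agg <- dplyr::summarise(dplyr::group_by(cp, aware),
                          p = weighted.mean(p_high, n), .groups = "drop")
  expect_gt(agg$p[agg$aware == 1] - agg$p[agg$aware == 0], 0.2)
  flat <- dplyr::summarise(dplyr::group_by(cp, conf),
                           p = weighted.mean(p_high, n), .groups = "drop")
  # confidence correlates with awareness, so allow a small induced gradient
  expect_lt(abs(flat$p[flat$conf == 1] - flat$p[flat$conf == 0]), 0.12)
})
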