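test_that("type-2 counts partition the table over the awareness x prospective grid", {
  tab <- default_experiment()[default_experiment()$subject == "s03", ]
  cells <- expand.grid(a = 0:1, p = 0:1)
  totals <- vapply(seq_len(nrow(cells)), function(i)
    sum(tabulate_counts(tab, cells$a[i], cells$p[i])), numeric(1))
  expect_equal(sum(totals), nrow(tab))
  # marginalizing over confidence recovers the type-1 counts
  counts <- tabulate_counts(tab, 1, NULL)
  t1 <- type1_counts(counts)
  expect_equal(sum(t1), sum(tab$awareness == 1))
  expect_equal(unname(t1["hits"] + t1["misses"]),
               sum(tab$awareness == 1 & tab$stimulus == "left"))
  # empty selection signals a typed condition
  no_aware <- tab
  no_aware$awareness <- 0L
  expect_error(tabulate_counts(no_aware, 1, NULL),
               class = "metalag_empty_cell")
})

test_that("four trials covering all stimulus x response combinations give unit margins", {
  tab <- make_table(stimulus = c("left", "left", "right", "right"),
                    response = c("left", "right", "left", "right"))
  t1 <- type1_counts(tabulate_counts(tab))
  expect_equal(unname(t1), c(1, 1, 1, 1))
})

test_that("type-1 sensitivity matches the closed form and its symmetries", {
  expect_equal(
    unname(type1_sensitivity(c(hits = 50, misses = 50, false_alarms = 50,
                               correct_rejections = 50))),
    c(0, 0))
  # HR 0.69, FAR 0.31 -> d' = 2 * qnorm(0.69)
  est <- type1_sensitivity(c(hits = 69, misses = 31, false_alarms = 31,
                             correct_rejections = 69))
  expect_equal(unname(est["dprime"]), 2 * qnorm(0.69), tolerance = 1e-10)
  expect_equal(unname(est["dprime"]), 0.9918, tolerance = 1e-3)
  expect_equal(unname(est["criterion"]), 0)
  # swapping stimulus labels negates d'
  swapped <- type1_sensitivity(c(hits = 31, misses = 69, false_alarms = 69,
                                 correct_rejections = 31))
  expect_equal(unname(swapped["dprime"]), -unname(est["dprime"]))
  # degenerate rates are a domain error
  expect_error(type1_sensitivity(c(hits = 10, misses = 0, false_alarms = 5,
                                   correct_rejections = 5)), "exactly 0 or 1")
})

test_that("random confidence yields meta-d' near zero", {
  tab <- simulate_sdt_observer(20000, dprime = 1.5, confidence = "random",
                               seed = 11)
  est <- fit_meta_d(tabulate_counts(tab))
  expect_gt(est$dprime, 1.3)
  expect_lt(abs(est$meta_dprime), 0.1)
})

test_that("an SDT-ideal observer has meta-d' = d' and M-ratio 1", {
  tab <- simulate_sdt_observer(20000, dprime = 1.5, confidence = "ideal",
                               seed = 12)
  est <- fit_meta_d(tabulate_counts(tab))
  expect_equal(est$meta_dprime, est$dprime, tolerance = 0.1)
  expect_true(est$m_ratio_defined)
  expect_equal(est$m_ratio, 1, tolerance = 0.07)
})

test_that("the optimizer agrees with a 0.001-step grid search on all fixtures", {
  fixtures <- list(
    tabulate_counts(simulate_sdt_observer(3000, 1.2, "ideal", seed = 21)),
    tabulate_counts(simulate_sdt_observer(3000, 0.5, "random", seed = 22)),
    tabulate_counts(simulate_sdt_observer(500, 2.0, "ideal",
                                          conf_threshold = 1.5, seed = 23)),
    tabulate_counts(default_experiment()[default_experiment()$subject == "s05", ],
                    1, 1))
  for (counts in fixtures) {
    est <- fit_meta_d(counts)
    grid <- meta_d_grid(counts, step = 0.001)
    expect_lt(abs(est$meta_dprime - grid), 0.01)
  }
})

test_that("meta-d' magnitude is invariant under stimulus relabelling", {
  tab <- simulate_sdt_observer(5000, 1.2, "ideal", seed = 31)
  flip <- function(v) ifelse(v == "left", "right", "left")
  # relabel the stimulus only (responses unchanged): d' negates
  relab <- make_table(stimulus = flip(tab$stimulus), response = tab$response,
                      confidence = tab$confidence)
  a <- fit_meta_d(tabulate_counts(tab))
  b <- fit_meta_d(tabulate_counts(relab))
  expect_equal(b$dprime, -a$dprime, tolerance = 1e-6)
  expect_equal(abs(b$meta_dprime), abs(a$meta_dprime), tolerance = 0.02)
  # relabelling stimulus and response together leaves both invariant
  both <- make_table(stimulus = flip(tab$stimulus),
                     response = flip(tab$response),
                     confidence = tab$confidence)
  c <- fit_meta_d(tabulate_counts(both))
  expect_equal(c$dprime, a$dprime, tolerance = 1e-6)
  expect_equal(c$meta_dprime, a$meta_dprime, tolerance = 0.02)
})

test_that("the condition grid recovers the generative sensitivities", {
  grid <- condition_sdt_grid(default_experiment())
  expect_equal(nrow(grid), 15 * 4)
  aware <- grid$dprime[grid$awareness == 1]
  unaware <- grid$dprime[grid$awareness == 0]
  # pooled over 15 subjects x 600 trials the cell means recover the
  # generative d' (1.2 aware, 0.3 unaware) closely
  expect_lt(abs(mean(aware, na.rm = TRUE) - 1.2), 0.15)
  expect_lt(abs(mean(unaware, na.rm = TRUE) - 0.3), 0.15)
  expect_gt(mean(aware, na.rm = TRUE), mean(unaware, na.rm = TRUE))
  # confidence noise is independent of the prospective state, so meta-d'
  # shows no prospective effect beyond its cell-level estimation noise
  # (SE of a ~150-trial cell estimate is roughly 0.4-0.5)
  diff <- mean(grid$meta_dprime[grid$prospective == 1], na.rm = TRUE) -
    mean(grid$meta_dprime[grid$prospective == 0], na.rm = TRUE)
  expect_lt(abs(diff), 0.3)
})

test_that("the long-format SDT export reports missing cells as missing", {
  tab <- default_experiment(seed = 9, n_subjects = 2)
  drop <- tab$awareness == 1 & tab$prospective == 1 & tab$subject == "s01"
  grid <- condition_sdt_grid(tab[!drop, ])
  row <- grid[grid$subject == "s01" & grid$awareness == 1 &
                grid$prospective == 1, ]
  expect_equal(row$n, 0L)
  expect_true(is.na(row$dprime))
  expect_false(any(is.na(grid$dprime[grid$n > 0])))
})
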