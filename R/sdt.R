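# Type-1 and type-2 signal-detection estimation.
#
# Convention: the left-oriented stimulus is S1 ("signal"), right is S2
# ("noise"); a hit is a 'left' response to a left stimulus and a correct
# rejection a 'right' response to a right stimulus.

#' Tabulate type-2 counts for one awareness x prospective cell
#'
#' Restricts the table to trials at the requested awareness and prospective
#' levels and cross-tabulates stimulus x response x confidence (8 cells).
#' Marginalising over confidence recovers the type-1 hit/miss/false-alarm/
#' correct-rejection counts.
#'
#' @param table a `trial_table`.
#' @param awareness_level 0/1, or `NULL` to pool over awareness.
#' @param prospective_level 0/1, or `NULL` to pool over the prospective
#'   decision.
#' @return a `type2_counts`: a 2 x 2 x 2 array with dimnames
#'   `stimulus` (S1, S2) x `response` (S1, S2) x `confidence` (low, high).
#'   An empty selection raises a condition of class `metalag_empty_cell`.
#' @export
tabulate_counts <- function(table, awareness_level = NULL,
                            prospective_level = NULL) {
  table <- as_trial_table(table)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(awareness_level)) keep <- keep & table$awareness == awareness_level
  if (!is.null(prospective_level)) keep <- keep & table$prospective == prospective_level
  sub <- table[keep, ]
  if (nrow(sub) == 0)
    stop(errorCondition(
      sprintf("no trials in cell awareness=%s, prospective=%s",
              toString(awareness_level %||% "any"),
              toString(prospective_level %||% "any")),
      class = c("metalag_empty_cell", "error")))
  counts <- array(0, dim = c(2, 2, 2),
                  dimnames = list(stimulus = c("S1", "S2"),
                                  response = c("S1", "S2"),
                                  confidence = c("low", "high")))
  si <- ifelse(sub$stimulus == "left", 1L, 2L)
  ri <- ifelse(sub$response == "left", 1L, 2L)
  ci <- sub$confidence + 1L
  for (i in seq_along(si))
    counts[si[i], ri[i], ci[i]] <- counts[si[i], ri[i], ci[i]] + 1
  structure(counts, class = c("type2_counts", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Type-1 margin of a type-2 count array
#'
#' @param counts a `type2_counts`.
#' @return named numeric vector `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`.
#' @export
type1_counts <- function(counts) {
  m <- apply(unclass(counts), c(1, 2), sum)
  c(hits = m["S1", "S1"], misses = m["S1", "S2"],
    false_alarms = m["S2", "S1"], correct_rejections = m["S2", "S2"])
}

#' Type-1 sensitivity and criterion
#'
#' Equal-variance Gaussian estimates from hit and false-alarm rates:
#' `d' = z(HR) - z(FAR)` and `c = -(z(HR) + z(FAR)) / 2`, with `z` the
#' standard-normal quantile function. Rates of exactly 0 or 1 are a
#' numerical-domain error; pad the counts first (see [fit_meta_d()]).
#'
#' @param counts named vector with `hits`, `misses`, `false_alarms`,
#'   `correct_rejections` (a `type2_counts` is also accepted and
#'   marginalised).
#' @return named numeric vector `dprime`, `criterion`.
#' @export
type1_sensitivity <- function(counts) {
  if (inherits(counts, "type2_counts")) counts <- type1_counts(counts)
  hr <- counts[["hits"]] / (counts[["hits"]] + counts[["misses"]])
  far <- counts[["false_alarms"]] /
    (counts[["false_alarms"]] + counts[["correct_rejections"]])
  if (hr <= 0 || hr >= 1 || far <= 0 || far >= 1)
    stop("hit or false-alarm rate of exactly 0 or 1; pad counts before ",
         "computing sensitivity", call. = FALSE)
  zh <- stats::qnorm(hr); zf <- stats::qnorm(far)
  c(dprime = zh - zf, criterion = -0.5 * (zh + zf))
}

# negative log-likelihood of the confidence data under the meta-d' model:
# type-1 criterion rescaled to c' = c * meta_d / d', one type-2 criterion on
# each side of c', equal-variance Gaussians at -meta_d/2 (S1) and +meta_d/2.
# The likelihood is over confidence *conditional* on each stimulus x
# response cell, so the observed type-1 performance is taken as given and
# only the type-2 (confidence) structure drives meta-d'.
meta_d_nll <- function(par, counts, dprime, criterion) {
  meta_d <- par[1]
  ratio <- if (abs(dprime) > 1e-8) meta_d / dprime else 1
  c_prime <- criterion * ratio
  c2_lo <- c_prime - exp(par[2])   # below: high-confidence S1 responses
  c2_hi <- c_prime + exp(par[3])   # above: high-confidence S2 responses
  eps <- 1e-12
  nll <- 0
  for (st in 1:2) {
    mu <- if (st == 1) -meta_d / 2 else meta_d / 2
    p_r1 <- stats::pnorm(c_prime - mu)
    # P(high | S1 response) and P(high | S2 response)
    p_hi_r1 <- stats::pnorm(c2_lo - mu) / max(p_r1, eps)
    p_hi_r2 <- (1 - stats::pnorm(c2_hi - mu)) / max(1 - p_r1, eps)
    for (pr in list(c(p_hi_r1, 1L), c(p_hi_r2, 2L))) {
      p <- min(max(pr[1], eps), 1 - eps)
      rs <- pr[2]
      nll <- nll - counts[st, rs, 2] * log(p) - counts[st, rs, 1] * log(1 - p)
    }
  }
  nll
}

#' Maximum-likelihood meta-d' estimation
#'
#' Fits the type-2 (confidence) data with a type-1 signal-detection model:
#' the observer's confidence is assumed to arise from the same
#' equal-variance Gaussian evidence axis, but with sensitivity `meta-d'`
#' instead of `d'`; the type-1 criterion is rescaled proportionally
#' (`c' = c * meta-d'/d'`) and one type-2 criterion per response side is
#' fitted jointly by maximising the multinomial likelihood of the 8
#' stimulus x response x confidence cells. `meta-d'` is constrained to
#' \[-5, 5\]. Before fitting, `pad` is added to every cell (default
#' `1/(2*4)` for the 4 response categories per stimulus) so no rate is
#' degenerate; `d'` and `c` are computed from the padded type-1 margins.
#'
#' @param counts a `type2_counts`.
#' @param pad value added to each of the 8 cells before estimation.
#' @param m_ratio_epsilon the M-ratio is flagged undefined when
#'   `|d'|` is below this value.
#' @return an `sdt_estimates` list: `dprime`, `criterion`, `meta_dprime`,
#'   `m_ratio`, `m_ratio_defined`, `type2_criteria` (low/high side),
#'   `logLik`, `convergence`, `n` (unpadded trial count).
#' @export
fit_meta_d <- function(counts, pad = 1 / 8, m_ratio_epsilon = 0.1) {
  stopifnot(inherits(counts, "type2_counts"))
  n_obs <- sum(counts)
  padded <- unclass(counts) + pad
  t1 <- type1_sensitivity(structure(padded, class = c("type2_counts", "array")))
  dprime <- t1[["dprime"]]; criterion <- t1[["criterion"]]

  fit_one <- function(start) {
    stats::optim(start, meta_d_nll, counts = padded, dprime = dprime,
                 criterion = criterion, method = "L-BFGS-B",
                 lower = c(-5, -10, -10), upper = c(5, 5, 5),
                 control = list(maxit = 500, factr = 1e4))
  }
  starts <- list(c(max(min(dprime, 4.9), -4.9), log(0.5), log(0.5)),
                 c(0, log(1), log(1)))
  fits <- lapply(starts, function(s) tryCatch(fit_one(s), error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("meta-d' optimisation failed from all starting points", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (best$convergence != 0)
    warning("meta-d' optimiser did not fully converge (code ",
            best$convergence, "); returning best value found", call. = FALSE)
  meta_d <- best$par[1]
  defined <- abs(dprime) >= m_ratio_epsilon
  structure(list(
    dprime = dprime, criterion = criterion, meta_dprime = meta_d,
    m_ratio = if (defined) meta_d / dprime else NA_real_,
    m_ratio_defined = defined,
    type2_criteria = c(low_side = criterion * (if (abs(dprime) > 1e-8) meta_d / dprime else 1) - exp(best$par[2]),
                       high_side = criterion * (if (abs(dprime) > 1e-8) meta_d / dprime else 1) + exp(best$par[3])),
    logLik = -best$value, convergence = best$convergence, n = n_obs),
    class = "sdt_estimates")
}

#' @export
print.sdt_estimates <- function(x, ...) {
  cat(sprintf("<sdt_estimates> d'=%.3f c=%.3f meta-d'=%.3f M-ratio=%s (n=%d)\n",
              x$dprime, x$criterion, x$meta_dprime,
              if (x$m_ratio_defined) sprintf("%.3f", x$m_ratio) else "undefined",
              x$n))
  invisible(x)
}

#' Grid-search meta-d' estimate
#'
#' Profile-likelihood grid search over meta-d': for each candidate value
#' the two type-2 criteria are optimised and the candidate maximising the
#' likelihood is returned. A coarse pass over \[-5, 5\] is refined at
#' `step` resolution around the coarse optimum. Slower than
#' [fit_meta_d()] but independent of the joint optimiser; used as an
#' estimation oracle.
#'
#' @param counts a `type2_counts`.
#' @param pad cell padding as in [fit_meta_d()].
#' @param step resolution of the fine grid.
#' @return the grid meta-d' estimate (numeric scalar).
#' @export
meta_d_grid <- function(counts, pad = 1 / 8, step = 0.001) {
  stopifnot(inherits(counts, "type2_counts"))
  padded <- unclass(counts) + pad
  t1 <- type1_sensitivity(structure(padded, class = c("type2_counts", "array")))
  profile_nll <- function(meta_d) {
    f <- function(p2) meta_d_nll(c(meta_d, p2), padded, t1[["dprime"]],
                                 t1[["criterion"]])
    stats::optim(c(log(0.5), log(0.5)), f, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))$value
  }
  coarse <- seq(-5, 5, by = 0.05)
  v <- vapply(coarse, profile_nll, numeric(1))
  center <- coarse[which.min(v)]
  fine <- seq(max(-5, center - 0.1), min(5, center + 0.1), by = step)
  vf <- vapply(fine, profile_nll, numeric(1))
  fine[which.min(vf)]
}

#' Signal-detection estimates on the awareness x prospective grid
#'
#' Computes [fit_meta_d()] per subject within each cell of the
#' awareness x prospective-decision 2 x 2. Cells with no trials are
#' reported as missing rows (`NA` estimates), never imputed.
#'
#' @param table a `trial_table`.
#' @inheritParams fit_meta_d
#' @return a tidy tibble: `subject`, `awareness`, `prospective`, `n`,
#'   `dprime`, `criterion`, `meta_dprime`, `m_ratio`, `defined`.
#' @export
condition_sdt_grid <- function(table, pad = 1 / 8, m_ratio_epsilon = 0.1) {
  table <- as_trial_table(table)
  grid <- expand.grid(subject = unique(table$subject), awareness = 0:1,
                      prospective = 0:1, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- table[table$subject == g$subject, ]
    est <- tryCatch({
      counts <- tabulate_counts(sub, g$awareness, g$prospective)
      fit_meta_d(counts, pad = pad, m_ratio_epsilon = m_ratio_epsilon)
    }, metalag_empty_cell = function(e) NULL)
    tibble::tibble(
      subject = g$subject, awareness = g$awareness, prospective = g$prospective,
      n = if (is.null(est)) 0L else est$n,
      dprime = if (is.null(est)) NA_real_ else est$dprime,
      criterion = if (is.null(est)) NA_real_ else est$criterion,
      meta_dprime = if (is.null(est)) NA_real_ else est$meta_dprime,
      m_ratio = if (is.null(est)) NA_real_ else est$m_ratio,
      defined = if (is.null(est)) NA else est$m_ratio_defined)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$awareness,
                 .data$prospective)
}
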