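# Shared fixtures and independent oracles, built in code at test time.

fixture_cache <- new.env(parent = emptyenv())

# default-calibration experiment, cached across tests in one file run
default_experiment <- function(seed = 7, n_subjects = 15) {
  key <- sprintf("exp_%d_%d", seed, n_subjects)
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- simulate_experiment(
      generator_config(n_subjects = n_subjects, seed = seed))
  fixture_cache[[key]]
}

small_config <- function(...) {
  generator_config(n_subjects = 3, n_blocks = 2, trials_per_block = 25,
                   seed = 5, ...)
}

# minimal valid trial table from per-trial vectors
make_table <- function(stimulus, response, awareness = 0L, confidence = 0L,
                       prospective = 0L, subject = "s1",
                       experiment = "belief") {
  n <- length(stimulus)
  as_trial_table(tibble::tibble(
    subject = subject, experiment = experiment, block = 1L,
    trial = seq_len(n), prospective = rep_len(prospective, n),
    stimulus = stimulus, response = response,
    correct = as.integer(stimulus == response),
    awareness = rep_len(awareness, n), confidence = rep_len(confidence, n)))
}

# exhaustive concordant-pair ROC AUC oracle (ties count 1/2)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# simulate an equal-variance SDT observer; confidence either random
# (coin flip) or ideal (|evidence| thresholded), one subject
simulate_sdt_observer <- function(n, dprime, confidence = c("ideal", "random"),
                                  conf_threshold = 1, seed = 1) {
  confidence <- match.arg(confidence)
  set.seed(seed)
  s <- sample(c(1L, -1L), n, replace = TRUE)
  e <- rnorm(n, s * dprime / 2, 1)
  resp <- ifelse(e > 0, 1L, -1L)
  conf <- if (confidence == "ideal") as.integer(abs(e) > conf_threshold)
          else rbinom(n, 1L, 0.5)
  make_table(stimulus = ifelse(s == 1L, "left", "right"),
             response = ifelse(resp == 1L, "left", "right"),
             confidence = conf)
}
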