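# Default synthetic study cohort (60 paired subjects, fixed seed), built at
# most once per test run and shared by the acceptance checks.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- simulate_cohort(n_subjects = 60, seed = 1)
  }
  .cohort_cache$cohort
}

default_cohort_features <- function() {
  if (is.null(.cohort_cache$features)) {
    .cohort_cache$features <- cohort_features(default_cohort(), seed = 1)
  }
  .cohort_cache$features
}

# small separable two-class table for classifier unit tests
separable_table <- function(n_per_class = 30, p_noise = 3, gap = 6, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * (p_noise + 1)), n)
  x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + gap
  colnames(x) <- c("signal", paste0("noise", seq_len(p_noise)))
  df <- data.frame(condition = rep(c("slow_paced", "spontaneous"),
                                   each = n_per_class), x,
                   stringsAsFactors = FALSE)
  df
}
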