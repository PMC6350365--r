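# Fixtures are built in code: small hand-checkable trials and trajectories.

# A tiny well-formed 1AN trial: 1 tumor, Vehicle + 2 treatments, 2 animals
# each, days 0/7/14, exponential growth with hand-picked rates.
small_trial <- function() {
  grid <- expand.grid(arm = c("Vehicle", "T1", "T2"),
                      animal = 1:2, day = c(0, 7, 14),
                      stringsAsFactors = FALSE)
  rate <- c(Vehicle = 0.10, T1 = 0.05, T2 = 0.00)
  grid$volume <- (100 + 10 * grid$animal) * exp(rate[grid$arm] * grid$day)
  trial_dataset(
    data.frame(tumor_id = "T", arm = grid$arm,
               animal_id = paste0(grid$arm, "_m", grid$animal),
               day = grid$day, volume = grid$volume,
               body_weight = 20 + grid$animal),
    control_arm = "Vehicle")
}

# 3-vs-3 trial with complete separation at every day: treatment volumes sit
# strictly below every control volume, so the observed labeling (and its
# mirror) uniquely maximise |mean t| over all C(6,3) = 20 assignments.
separated_pair_trial <- function() {
  days <- c(0, 3, 6, 9)
  rows <- list()
  for (a in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      tumor_id = "T", arm = "Vehicle", animal_id = paste0("c", a),
      day = days, volume = (200 + 10 * a) * exp(0.10 * days))
    rows[[length(rows) + 1L]] <- data.frame(
      tumor_id = "T", arm = "Drug", animal_id = paste0("t", a),
      day = days, volume = (100 + 5 * a) * exp(0.01 * days))
  }
  trial_dataset(do.call(rbind, rows), control_arm = "Vehicle")
}

# Worked trajectory used across the labeling tests.
worked_trajectory <- function() {
  list(days = c(0, 7, 14, 21), volumes = c(100, 120, 80, 60))
}

# Independent oracle: naive two-way ANOVA on ranks (cell/marginal means),
# balanced designs only. Returns H = SS_term / (SS_total / (N - 1)).
srh_oracle <- function(values, fa, fb) {
  r <- rank(values)
  fa <- factor(fa); fb <- factor(fb)
  n <- length(r)
  gm <- mean(r)
  cell <- tapply(r, list(fa, fb), mean)
  na <- tapply(r, list(fa, fb), length)
  ma <- tapply(r, fa, mean); mb <- tapply(r, fb, mean)
  ss_a <- sum(tapply(r, fa, length) * (ma - gm)^2)
  ss_b <- sum(tapply(r, fb, length) * (mb - gm)^2)
  ss_cells <- sum(na * (cell - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_total <- sum((r - gm)^2)
  ms_total <- ss_total / (n - 1)
  c(a = ss_a / ms_total, b = ss_b / ms_total, ab = ss_ab / ms_total)
}

# Random positive trajectory on a fixed day grid (lognormal random walk).
random_trajectory <- function(days = c(0, 3, 7, 10, 14, 17, 21)) {
  v <- numeric(length(days))
  v[1] <- exp(rnorm(1, log(200), 0.3))
  for (i in 2:length(v)) v[i] <- v[i - 1] * exp(rnorm(1, 0.1, 0.5))
  list(days = days, volumes = v)
}
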