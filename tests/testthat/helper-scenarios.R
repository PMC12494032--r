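# Programmatic fixtures: small scenarios built in code at test time.

# A kernel concentrated on the first post-dose day: with a first dose on day
# 7w - 2, labelling covers exactly the cells born in weeks <= w, so the
# estimated increments are unbiased for the birth-week composition.
delta_kernel <- function() c(1, rep(0, 7))

# Continuous-renewal tissue: constant influx, uniform loss, no residency.
renewal_schedule <- function(name = "sim", horizon = 60, loss = 0.02,
                             division = 0, sampled_cells = 2000,
                             kappa = 50) {
  tissue_schedule(name, horizon, influx = rep(1, horizon),
                  division_prob = division, loss_resident = loss,
                  loss_flux = loss, residency_cutoff_day = 0,
                  sampled_cells = sampled_cells,
                  overdispersion_kappa = kappa)
}

# Constant-pool replacement at per-day rate rho: pool mass stays 1, label
# fraction decays by (1 - rho) per day after a full pulse.
replacement_schedule <- function(name = "sim", horizon = 220, rho = 0.01,
                                 division = 0, sampled_cells = 2000,
                                 kappa = 50) {
  tissue_schedule(name, horizon,
                  influx = c(1, rep(rho, horizon - 1)),
                  division_prob = division,
                  loss_resident = rho, loss_flux = rho,
                  residency_cutoff_day = 0,
                  sampled_cells = sampled_cells,
                  overdispersion_kappa = kappa)
}

# Wrap a single schedule as a scenario usable by simulate_cohort().
as_scenario <- function(schedule, efficiency = 1, kernel = delta_kernel(),
                        analysis_day = 56, pulse_weeks = 1:6,
                        mice_per_group = 8, seed = 42, markers = NULL,
                        subsets = NULL) {
  entry <- list(schedule = schedule, efficiency = efficiency,
                markers = markers, subsets = subsets)
  tissues <- list(entry)
  names(tissues) <- schedule$name
  list(name = "test_scenario", seed = seed, kernel = kernel,
       analysis_day = analysis_day, pulse_weeks = pulse_weeks,
       mice_per_group = mice_per_group, turnover = NULL,
       tissues = tissues)
}

# First-dose days that make the delta kernel label exactly weeks <= w.
aligned_pulse_days <- function(weeks) 7 * weeks - 2

# Brute-force weighted isotonic oracle: enumerate all partitions of 1..n
# into consecutive blocks, keep those with nondecreasing weighted block
# means, return the minimum weighted SSE fit.
isotonic_bruteforce <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {  # bit j set: cut between j and j+1
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (k in seq_len(length(bounds) - 1)) {
      idx <- (bounds[k] + 1):bounds[k + 1]
      means[k] <- sum(values[idx] * weights[idx]) / sum(weights[idx])
      fit[idx] <- means[k]
    }
    if (is.unsorted(means)) next
    sse <- sum(weights * (values - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Exact two-sided signed-rank p by full 2^n sign enumeration.
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  lower <- mean(v_all <= v_obs + 1e-9)
  upper <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}
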