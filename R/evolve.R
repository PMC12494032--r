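#' Deterministic cohort expectation engine
#'
#' Propagates expected cohort masses day by day: each birth-day cohort c has
#' mass N_c(t+1) = N_c(t) * (1 + pi(t) - delta_c(t)), where pi is the
#' division probability and delta_c the loss probability of the cohort's
#' residency class; influx founds a new cohort each day. Labelling is
#' heritable, so the labelled share of a cohort is constant after the
#' activity window closes; labelled mass is the cohort mass times the kernel
#' mass accrued by the analysis day (see \code{\link{tag_probability}}).
#'
#' @param schedule A \code{\link{tissue_schedule}}.
#' @param pulse A \code{\link{pulse_design}}, or NULL for an unpulsed cohort
#'   (all labelled masses zero).
#' @param analysis_day Day of analysis, within the schedule horizon.
#' @return A data.frame of class \code{cohort_state} with columns
#'   \code{birth_day}, \code{N} (expected mass) and \code{L} (expected
#'   labelled mass), one row per birth-day cohort, plus attribute
#'   \code{analysis_day}.
#' @export
evolve_expectation <- function(schedule, pulse = NULL, analysis_day) {
  H <- schedule$horizon_days
  if (analysis_day < 0 || analysis_day > H - 1)
    stop("analysis_day must lie in [0, horizon_days - 1]")
  A <- as.integer(analysis_day)
  birth <- 0:A
  D <- schedule$residency_cutoff_day
  m <- numeric(A + 1)
  m[1] <- schedule$influx[1]
  if (A >= 1) {
    pi_t <- schedule$division_prob
    lres <- schedule$loss_resident
    lflux <- schedule$loss_flux
    res_class <- birth < D
    for (t in 0:(A - 1)) {
      idx <- seq_len(t + 1)
      g <- 1 + pi_t[t + 1] -
        ifelse(res_class[idx], lres[t + 1], lflux[t + 1])
      if (any(g < 0))
        stop("negative growth factor on day ", t,
             ": division/loss parameters inconsistent")
      m[idx] <- m[idx] * g
      m[t + 2] <- schedule$influx[t + 2]
    }
  }
  if (is.null(pulse)) {
    L <- numeric(A + 1)
  } else {
    E <- efficiency_for(pulse, schedule$name)
    L <- m * E * kernel_tag_fraction(birth, pulse, analysis_day = A)
  }
  out <- data.frame(birth_day = birth, N = m, L = L)
  attr(out, "analysis_day") <- A
  class(out) <- c("cohort_state", "data.frame")
  out
}

#' Expected tagged fraction of the pool
#'
#' @inheritParams evolve_expectation
#' @return Expected proportion of labelled Tregs at the analysis day.
#' @export
tagged_fraction <- function(schedule, pulse, analysis_day) {
  st <- evolve_expectation(schedule, pulse, analysis_day)
  tot <- sum(st$N)
  if (tot <= 0) stop("empty pool at analysis day")
  sum(st$L) / tot
}

#' True pool composition by generation week
#'
#' Decomposes the expected pool mass at the analysis day by birth-week
#' cohort: the ground truth that the retrospective reconstruction estimates.
#'
#' @inheritParams evolve_expectation
#' @param week_length Days per week (7).
#' @param n_weeks Number of leading generation weeks to report; mass born
#'   later is pooled into the tail.
#' @return List with \code{fractions} (named w1..wn), \code{tail} (mass
#'   generated after week \code{n_weeks}), and \code{analysis_day}.
#' @export
true_composition <- function(schedule, analysis_day, week_length = 7,
                             n_weeks = 6) {
  st <- evolve_expectation(schedule, NULL, analysis_day)
  wk <- st$birth_day %/% week_length + 1L
  tot <- sum(st$N)
  q <- vapply(seq_len(n_weeks),
              function(w) sum(st$N[wk == w]) / tot, numeric(1))
  names(q) <- paste0("w", seq_len(n_weeks))
  list(fractions = q, tail = 1 - sum(q), analysis_day = analysis_day)
}

#' Expected recently-divided (Ki67-like) fraction
#'
#' Expected proportion of pool cells that divided at least once within the
#' trailing marker window, 1 - prod(1 - pi(s)) over the window, truncated at
#' each cohort's birth and weighted by cohort mass.
#'
#' @inheritParams evolve_expectation
#' @param day Analysis day.
#' @param window_days Length of the trailing window in days during which a
#'   division leaves the cell marker-positive (default 4).
#' @return Expected marker-positive fraction.
#' @export
divided_recent_fraction <- function(schedule, day, window_days = 4) {
  stopifnot(window_days >= 1)
  st <- evolve_expectation(schedule, NULL, day)
  pi_t <- schedule$division_prob
  ## division during transition s -> s+1 uses division_prob[s + 1]
  frac <- vapply(st$birth_day, function(b) {
    s0 <- max(b, day - window_days)
    if (s0 >= day) return(0)
    1 - prod(1 - pi_t[(s0 + 1):day])
  }, numeric(1))
  sum(frac * st$N) / sum(st$N)
}
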