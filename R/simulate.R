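## Stochastic cohort simulation: per-mouse Beta overdispersion around the
## expectation-model fraction, then finite-cell binomial flow sampling.

rbeta_mean <- function(n, mean, kappa) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

#' Simulate one mouse record
#'
#' Draws the mouse's true tagged fraction from a Beta distribution with mean
#' equal to the expectation-engine fraction and concentration kappa, then the
#' observed tagged count from a binomial over the flow-sampled cells. Uses
#' the current RNG state; seed upstream for reproducibility.
#'
#' @inheritParams evolve_expectation
#' @param mouse_id Identifier stored in the record.
#' @param pulse_week Pulse-group label stored in the record (week of life,
#'   or the week containing an adult-age first dose).
#' @return One-row data.frame with columns mouse_id, tissue, pulse_week,
#'   pulse_day, analysis_day, n_cells, n_tagged.
#' @export
simulate_mouse <- function(schedule, pulse, analysis_day,
                           mouse_id = "m1",
                           pulse_week = (pulse$first_dose_day - 1) %/% 7 + 1) {
  n <- schedule$sampled_cells
  if (n <= 0) stop("sampled_cells must be positive")
  f <- tagged_fraction(schedule, pulse, analysis_day)
  p <- rbeta_mean(1, f, schedule$overdispersion_kappa)
  data.frame(mouse_id = mouse_id, tissue = schedule$name,
             pulse_week = pulse_week, pulse_day = pulse$first_dose_day,
             analysis_day = analysis_day,
             n_cells = n, n_tagged = stats::rbinom(1, n, p),
             stringsAsFactors = FALSE)
}

## expected tagged fraction with caching across mice of one group
group_expectation <- function(schedule, pulse, analysis_day) {
  tagged_fraction(schedule, pulse, analysis_day)
}

simulate_group_rows <- function(entry, tissue, pulse, pulse_week, ad,
                                n_mice, mouse_ids, markers, ki67_window) {
  n <- entry$schedule$sampled_cells
  kappa <- entry$schedule$overdispersion_kappa
  rows <- vector("list", n_mice)
  has_subsets <- !is.null(entry$subsets) && length(entry$subsets) > 0
  if (has_subsets) {
    sub_names <- names(entry$subsets)
    sub_w <- vapply(entry$subsets, function(s) s$weight, numeric(1))
    sub_w <- sub_w / sum(sub_w)
    sub_f <- vapply(entry$subsets, function(s)
      tagged_fraction(s$schedule, pulse, ad), numeric(1))
  } else {
    f <- tagged_fraction(entry$schedule, pulse, ad)
  }
  dr <- if (!is.null(ki67_window))
    divided_recent_fraction(entry$schedule, ad, ki67_window) else NULL
  for (i in seq_len(n_mice)) {
    if (has_subsets) {
      n_sub <- as.vector(stats::rmultinom(1, n, sub_w))
      k_sub <- integer(length(n_sub))
      for (s in seq_along(n_sub)) {
        p_s <- rbeta_mean(1, sub_f[s], kappa)
        k_sub[s] <- stats::rbinom(1, n_sub[s], p_s)
      }
      n_tag <- sum(k_sub)
      row <- data.frame(mouse_id = mouse_ids[i], tissue = tissue,
                        pulse_week = pulse_week,
                        pulse_day = pulse$first_dose_day, analysis_day = ad,
                        n_cells = n, n_tagged = n_tag,
                        stringsAsFactors = FALSE)
      for (s in seq_along(sub_names)) {
        row[[paste0(sub_names[s], "_tag_pos")]] <- k_sub[s]
        row[[paste0(sub_names[s], "_tag_tot")]] <- n_tag
        row[[paste0(sub_names[s], "_untag_pos")]] <- n_sub[s] - k_sub[s]
        row[[paste0(sub_names[s], "_untag_tot")]] <- n - n_tag
      }
    } else {
      p <- rbeta_mean(1, f, kappa)
      row <- data.frame(mouse_id = mouse_ids[i], tissue = tissue,
                        pulse_week = pulse_week,
                        pulse_day = pulse$first_dose_day, analysis_day = ad,
                        n_cells = n, n_tagged = stats::rbinom(1, n, p),
                        stringsAsFactors = FALSE)
    }
    if (markers && !is.null(entry$markers)) {
      for (mk in names(entry$markers)) {
        pr <- entry$markers[[mk]]
        p_tag <- rbeta_mean(1, pr[["tag"]], kappa)
        p_un <- rbeta_mean(1, pr[["untag"]], kappa)
        n_tag_i <- row$n_tagged
        row[[paste0(mk, "_tag_pos")]] <- stats::rbinom(1, n_tag_i, p_tag)
        row[[paste0(mk, "_tag_tot")]] <- n_tag_i
        row[[paste0(mk, "_untag_pos")]] <- stats::rbinom(1, n - n_tag_i, p_un)
        row[[paste0(mk, "_untag_tot")]] <- n - n_tag_i
      }
    }
    if (!is.null(dr))
      row$divided_recent <- stats::rbinom(1, n, dr)
    rows[[i]] <- row
  }
  rows
}

#' Simulate a fate-mapping cohort
#'
#' Generates one mouse record per mouse x tissue for every requested pulse
#' group and analysis age, using the scenario's tissue schedules. Mice
#' sharing a pulse group and analysis age share mouse ids across tissues.
#' Deterministic given \code{seed}.
#'
#' @param scenario A scenario, from \code{\link{read_scenario}} or
#'   \code{\link{paper_scenario}}.
#' @param seed Integer seed; defaults to the scenario's seed.
#' @param tissues Tissues to simulate (default: all in the scenario).
#' @param pulse_weeks Weekly pulse groups (first dose on day 7(w-1)+1);
#'   ignored when \code{pulse_days} is given.
#' @param pulse_days Optional vector of first-dose days for adult pulses.
#' @param analysis_day Analysis age(s) in days; a full group set is
#'   simulated per analysis age.
#' @param mice_per_group Mice per pulse group.
#' @param markers Simulate configured phenotype marker counts?
#' @param ki67_window If non-NULL, also simulate a \code{divided_recent}
#'   count using this trailing window (days).
#' @return A cohort data.frame (one row per mouse x tissue) with attributes
#'   \code{scenario} (name) and \code{seed}.
#' @export
simulate_cohort <- function(scenario, seed = scenario$seed,
                            tissues = names(scenario$tissues),
                            pulse_weeks = scenario$pulse_weeks,
                            pulse_days = NULL,
                            analysis_day = scenario$analysis_day,
                            mice_per_group = scenario$mice_per_group,
                            markers = TRUE, ki67_window = NULL) {
  missing_t <- setdiff(tissues, names(scenario$tissues))
  if (length(missing_t))
    stop("no schedule for requested tissue(s): ",
         paste(missing_t, collapse = ", "))
  set.seed(seed)
  if (is.null(pulse_days)) {
    fds <- 7 * (pulse_weeks - 1) + 1
  } else {
    fds <- pulse_days
  }
  eff <- vapply(scenario$tissues, function(e) e$efficiency, numeric(1))
  out <- list()
  for (tis in tissues) {
    entry <- scenario$tissues[[tis]]
    ## subset schedules share the parent tissue's efficiency
    eff_map <- eff
    if (!is.null(entry$subsets))
      for (s in names(entry$subsets))
        eff_map[[entry$subsets[[s]]$schedule$name]] <- eff[[tis]]
    for (ad in analysis_day) {
      for (fi in seq_along(fds)) {
        fd <- fds[fi]
        pw <- (fd - 1) %/% 7 + 1
        pulse <- pulse_design(fd, eff_map, kernel = scenario$kernel)
        ids <- sprintf("w%d_d%d_m%d", pw, ad, seq_len(mice_per_group))
        out <- c(out, simulate_group_rows(
          entry, tis, pulse, pw, ad, mice_per_group, ids,
          markers, ki67_window))
      }
    }
  }
  cohort <- do.call(rbind_fill, list(out))
  attr(cohort, "scenario") <- scenario$name
  attr(cohort, "seed") <- seed
  cohort
}

## rbind a list of one-row data.frames that may differ in optional columns
rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    for (m in miss) r[[m]] <- NA
    r[cols]
  })
  do.call(rbind, filled)
}
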