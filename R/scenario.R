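## Scenario configuration: structured-text (YAML) description of per-tissue
## generation/turnover schedules, pulse design, group sizes and seed.
##
## A tissue block states the observable the schedule must generate -- the
## corrected cumulative tagged-fraction curve over pulse weeks 1..6 at the
## 8-week analysis -- together with mechanistic parameters (division-rate
## profile, loss rates, residency cutoff, adult-phase replacement). The
## per-day influx vector is then solved from the target curve, so the
## schedule's expected observables reproduce the configured values by
## construction, while masses, proliferation and turnover follow the stated
## mechanism.

## Survival factor to `analysis_day` for a unit of influx on each birth day,
## by residency class of the birth day.
survival_factors <- function(division, loss_res, loss_flux, cutoff,
                             analysis_day) {
  A <- analysis_day
  t <- seq_len(A)                       # transition index tau = t -> uses [tau]
  g_res <- 1 + division[t] - loss_res[t]
  g_flux <- 1 + division[t] - loss_flux[t]
  if (any(g_res <= 0) || any(g_flux <= 0))
    stop("nonpositive growth factor in schedule parameters")
  cum_res <- c(0, cumsum(log(g_res)))   # cum_res[b+1] = log prod_{t<b}
  cum_flux <- c(0, cumsum(log(g_flux)))
  b <- 0:(A - 1)
  ifelse(b < cutoff,
         exp(cum_res[A + 1] - cum_res[b + 1]),
         exp(cum_flux[A + 1] - cum_flux[b + 1]))
}

#' Solve per-day influx from a target cumulative labelling curve
#'
#' Finds nonnegative weekly influx levels such that the expected corrected
#' tagged fraction for pulses at weeks 1..length(target) equals the target
#' curve at the analysis day, given the division/loss schedule and the
#' activity kernel (which smears labelling across the week boundary). The
#' influx is constant within each week and normalized so the expected pool
#' mass at the analysis day is 1. Weeks beyond the last target share the
#' last solved level.
#'
#' @param target Nondecreasing cumulative fractions for pulse weeks
#'   1..W (W < analysis weeks).
#' @param division,loss_res,loss_flux Per-day vectors (length >=
#'   \code{analysis_day}).
#' @param cutoff Residency cutoff birth day.
#' @param kernel Activity kernel (8 weights).
#' @param analysis_day Analysis day (a multiple of 7).
#' @return Per-day influx vector of length \code{analysis_day}.
#' @export
solve_influx <- function(target, division, loss_res, loss_flux, cutoff,
                         kernel = trapezoid_kernel(), analysis_day = 56) {
  W <- length(target)
  V <- analysis_day %/% 7
  stopifnot(analysis_day %% 7 == 0, W < V, !is.unsorted(target),
            all(target >= 0), all(target <= 1))
  phi <- survival_factors(division, loss_res, loss_flux, cutoff, analysis_day)
  b <- 0:(analysis_day - 1)
  wk <- b %/% 7 + 1
  M <- vapply(seq_len(V), function(v) sum(phi[wk == v]), numeric(1))
  ## Amat[w, v]: labelled mass credit of week-v influx under a week-w pulse
  Amat <- matrix(0, W, V)
  for (w in seq_len(W)) {
    pd <- pulse_design(7 * (w - 1) + 1, c(x = 1), kernel = kernel)
    tpn <- kernel_tag_fraction(b, pd)
    for (v in seq_len(V)) Amat[w, v] <- sum((phi * tpn)[wk == v])
  }
  rows <- rbind(
    Amat - target %o% M,                       # F_w constraints
    do.call(rbind, lapply(seq_len(V - W - 1), function(j) {
      r <- numeric(V); r[W + j] <- 1; r[W + j + 1] <- -1; r
    })),                                       # equal late-week levels
    M)                                         # normalization
  rhs <- c(numeric(V - 1), 1)
  free <- rep(TRUE, V)
  x <- numeric(V)
  repeat {
    sol <- qr.solve(rows[, free, drop = FALSE], rhs)
    if (min(sol) >= -1e-9) { x[free] <- pmax(sol, 0); break }
    drop_i <- which(free)[which.min(sol)]
    free[drop_i] <- FALSE
    if (!any(free)) stop("influx solve failed: all levels eliminated")
  }
  achieved <- as.vector(Amat %*% x) / sum(M * x)
  if (max(abs(achieved - target)) > 0.01)
    message("influx solve: target curve met within ",
            signif(max(abs(achieved - target)), 2), " (nonnegativity active)")
  x <- x / sum(M * x)
  rep(x, each = 7)
}

## Build one tissue_schedule from a config block. The adult phase (after the
## composition analysis day) switches to a constant-pool replacement regime:
## per-day loss = division + (1 - exp(-r/7)) per class, influx topping the
## pool back to its analysis-day mass.
build_schedule <- function(name, cfg, global) {
  H <- global$horizon_days
  A <- global$analysis_day
  div <- stats::approx(cfg$division$days, cfg$division$probs,
                       xout = 0:(H - 1), rule = 2)$y
  rho_res <- 1 - exp(-(cfg$adult_loss_resident_per_week %||% 0) / 7)
  rho_flux <- 1 - exp(-(cfg$adult_replacement_per_week %||% 0) / 7)
  loss_res <- ifelse(seq_len(H) <= A, cfg$loss_resident, div + rho_res)
  loss_flux <- ifelse(seq_len(H) <= A, cfg$loss_flux, div + rho_flux)
  cutoff <- cfg$residency_cutoff_day
  influx_growth <- solve_influx(
    unlist(cfg$target_cumulative), div, loss_res, loss_flux, cutoff,
    kernel = global$kernel, analysis_day = A)
  ## adult influx: run the recursion forward, topping mass up to 1 each day
  influx <- c(influx_growth, numeric(H - A))
  m <- numeric(H)
  m[1] <- influx[1]
  birth <- 0:(H - 1)
  for (t in 0:(H - 2)) {
    idx <- seq_len(t + 1)
    g <- 1 + div[t + 1] -
      ifelse(birth[idx] < cutoff, loss_res[t + 1], loss_flux[t + 1])
    m[idx] <- m[idx] * g
    if (t + 1 > A) influx[t + 2] <- max(0, 1 - sum(m[idx]))
    m[t + 2] <- influx[t + 2]
  }
  tissue_schedule(
    name = name, horizon_days = H, influx = influx,
    division_prob = div, loss_resident = loss_res, loss_flux = loss_flux,
    residency_cutoff_day = cutoff,
    sampled_cells = cfg$sampled_cells %||% global$sampled_cells %||% 2000,
    overdispersion_kappa = cfg$kappa %||% global$kappa %||% 50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario configuration
#'
#' Parses a YAML scenario file (per-tissue schedule blocks, pulse design,
#' group sizes, seed) and builds the tissue schedules, solving each tissue's
#' influx from its target cumulative curve (see \code{\link{solve_influx}}).
#'
#' @param path Path to a scenario YAML file.
#' @return A scenario list with elements \code{name}, \code{seed},
#'   \code{kernel}, \code{analysis_day}, \code{pulse_weeks},
#'   \code{mice_per_group}, \code{turnover} and \code{tissues} (each tissue:
#'   \code{schedule}, \code{efficiency}, optional \code{markers} and
#'   \code{subsets}).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  global <- list(
    horizon_days = y$horizon_days %||% 211,
    analysis_day = 7 * (y$analysis_week %||% 8),
    kernel = if (!is.null(y$kernel)) as.numeric(y$kernel) else
      trapezoid_kernel(),
    sampled_cells = y$sampled_cells, kappa = y$kappa)
  tissues <- lapply(names(y$tissues), function(tn) {
    cfg <- y$tissues[[tn]]
    entry <- list(
      schedule = build_schedule(tn, cfg, global),
      efficiency = cfg$efficiency)
    if (!is.null(cfg$markers))
      entry$markers <- lapply(cfg$markers, function(m)
        c(tag = m$tag, untag = m$untag))
    if (!is.null(cfg$subsets))
      entry$subsets <- lapply(stats::setNames(nm = names(cfg$subsets)),
        function(sn) {
          scfg <- cfg$subsets[[sn]]
          for (f in c("division", "loss_resident", "loss_flux",
                      "residency_cutoff_day", "sampled_cells", "kappa"))
            if (is.null(scfg[[f]])) scfg[[f]] <- cfg[[f]]
          list(weight = scfg$weight,
               schedule = build_schedule(paste0(tn, ".", sn), scfg, global))
        })
    entry
  })
  names(tissues) <- names(y$tissues)
  list(name = y$name %||% "scenario", seed = y$seed %||% 1L,
       kernel = global$kernel, analysis_day = global$analysis_day,
       pulse_weeks = as.integer(y$pulse_weeks %||% 1:6),
       mice_per_group = y$mice_per_group %||% 8L,
       turnover = y$turnover, horizon_days = global$horizon_days,
       tissues = tissues)
}

#' The bundled multi-tissue reference scenario
#'
#' Loads the packaged scenario describing Treg pool assembly in seven mouse
#' tissues over the first 8 weeks of life plus an adult replacement phase:
#' skin and VAT with strong neonatal bias and residency, lymphoid tissues
#' with continuous renewal, lungs/liver/colon intermediate, and colonic
#' GATA3+/RORgt+/double-negative subsets with divergent ontogeny.
#'
#' @return A scenario list (see \code{\link{read_scenario}}).
#' @export
paper_scenario <- function() {
  read_scenario(system.file("extdata", "paper_scenario.yaml",
                            package = "tregfate", mustWork = TRUE))
}
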