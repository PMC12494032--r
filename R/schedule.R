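#' Tissue generation/turnover schedule
#'
#' The ground-truth generative model for one tissue: per-day influx of newly
#' generated Tregs into the pool (abstracting thymic output, peripheral
#' conversion and colonization), a per-cell per-day division probability, and
#' two per-day loss probabilities -- one for cells born before the residency
#' cutoff (resident cohorts) and one for cells born on or after it
#' (continuously replaced cohorts).
#'
#' Loss rates may be given as scalars (recycled over the horizon) or as
#' per-day vectors; the latter permits schedules whose turnover regime
#' changes between the growth phase and adulthood.
#'
#' @param name Tissue label.
#' @param horizon_days Number of simulated days; day 0 is birth and the last
#'   represented day is \code{horizon_days - 1}.
#' @param influx Numeric vector of length \code{horizon_days}; \code{influx[d+1]}
#'   is the expected mass of new Tregs entering the pool on day d.
#' @param division_prob Per-cell per-day division probability; scalar or
#'   vector of length \code{horizon_days}, values in \[0, 1).
#' @param loss_resident,loss_flux Per-day loss probabilities in \[0, 1) for
#'   cohorts born before / on-or-after \code{residency_cutoff_day}; scalar or
#'   vector.
#' @param residency_cutoff_day Birth-day cutoff separating the two loss
#'   classes (0 means every cohort is in the flux class).
#' @param sampled_cells Typical number of Tregs acquired by flow cytometry
#'   for this tissue (per mouse).
#' @param overdispersion_kappa Beta concentration parameter for per-mouse
#'   variation of the true tagged fraction; larger is less dispersed.
#' @return An object of class \code{tissue_schedule}.
#' @export
tissue_schedule <- function(name, horizon_days, influx,
                            division_prob = 0,
                            loss_resident = 0, loss_flux = 0,
                            residency_cutoff_day = 0,
                            sampled_cells = 2000,
                            overdispersion_kappa = 50) {
  H <- as.integer(horizon_days)
  stopifnot(H >= 1, length(influx) == H, all(influx >= -1e-12))
  influx <- pmax(influx, 0)
  expand <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, H)
    if (length(x) != H)
      stop(nm, " must be a scalar or a vector of length horizon_days")
    if (any(x < 0) || any(x >= 1)) stop(nm, " must lie in [0, 1)")
    x
  }
  division_prob <- expand(division_prob, "division_prob")
  loss_resident <- expand(loss_resident, "loss_resident")
  loss_flux <- expand(loss_flux, "loss_flux")
  if (any(loss_resident > loss_flux + 1e-12))
    message("schedule '", name, "': loss_resident exceeds loss_flux on some ",
            "days (anti-residency)")
  if (sampled_cells <= 0) stop("sampled_cells must be positive")
  if (overdispersion_kappa <= 0) stop("overdispersion_kappa must be positive")
  structure(
    list(name = name, horizon_days = H, influx = as.numeric(influx),
         division_prob = division_prob, loss_resident = loss_resident,
         loss_flux = loss_flux,
         residency_cutoff_day = as.integer(residency_cutoff_day),
         sampled_cells = as.integer(sampled_cells),
         overdispersion_kappa = overdispersion_kappa),
    class = "tissue_schedule")
}

#' @export
print.tissue_schedule <- function(x, ...) {
  cat("Tissue schedule '", x$name, "': ", x$horizon_days, " days\n", sep = "")
  cat("  total influx mass:", signif(sum(x$influx), 4),
      "| residency cutoff day:", x$residency_cutoff_day, "\n")
  cat("  division prob range:", signif(range(x$division_prob), 3),
      "| loss (res/flux) range:", signif(range(x$loss_resident), 3),
      "/", signif(range(x$loss_flux), 3), "\n")
  invisible(x)
}
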