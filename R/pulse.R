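#' Tamoxifen pulse design
#'
#' Describes one labelling pulse: the mouse age (in days) at the first dose,
#' the recombinase activity kernel over the 8 days following the first dose,
#' and the per-tissue tagging efficiency. The default kernel is a trapezoid
#' with full weight on days 1-5 and a linear decay to zero over days 6-8,
#' matching the observed activity envelope of a two-dose regimen (peak
#' activity 1-5 days after the first injection, none after 8 days).
#'
#' @param first_dose_day Integer mouse age in days at the first dose
#'   (day 0 = birth).
#' @param efficiency Named numeric vector, tissue -> tagging efficiency in
#'   \[0, 1\]: the probability that a Treg exposed to the full activity window
#'   becomes heritably labelled.
#' @param kernel Numeric vector of 8 nonnegative activity weights for days
#'   1..8 after the first dose. Activity is zero beyond day 8.
#' @return An object of class \code{pulse_design}.
#' @examples
#' pd <- pulse_design(1, c(spleen = 0.95))
#' tag_probability(0, pd, "spleen")
#' @export
pulse_design <- function(first_dose_day, efficiency,
                         kernel = trapezoid_kernel()) {
  stopifnot(length(first_dose_day) == 1L, first_dose_day >= 0)
  if (length(kernel) != 8L || any(kernel < 0) || sum(kernel) <= 0)
    stop("kernel must be 8 nonnegative weights with positive total mass")
  if (is.null(names(efficiency)) || any(efficiency < 0) || any(efficiency > 1))
    stop("efficiency must be a named vector of values in [0, 1]")
  structure(
    list(first_dose_day = as.integer(first_dose_day),
         kernel = as.numeric(kernel),
         efficiency = efficiency),
    class = "pulse_design")
}

#' Default trapezoidal activity kernel
#'
#' Full recombinase activity on days 1-5 after the first dose, linear decay
#' to zero over days 6-8.
#' @return Numeric vector of length 8.
#' @export
trapezoid_kernel <- function() c(1, 1, 1, 1, 1, 2 / 3, 1 / 3, 0)

#' @export
print.pulse_design <- function(x, ...) {
  cat("Pulse design: first dose at day", x$first_dose_day, "\n")
  cat("  kernel (days 1-8):", signif(x$kernel, 3), "\n")
  cat("  efficiency:",
      paste0(names(x$efficiency), "=", x$efficiency, collapse = ", "), "\n")
  invisible(x)
}

efficiency_for <- function(pulse, tissue) {
  if (!tissue %in% names(pulse$efficiency))
    stop("no tagging efficiency configured for tissue '", tissue, "'")
  unname(pulse$efficiency[[tissue]])
}

#' Labelling probability by birth day
#'
#' Probability that a cell born on a given day becomes heritably labelled by
#' the pulse. Cells already present when activity starts receive the full
#' efficiency E; cells born on day \code{first_dose_day + j} (1 <= j <= 8)
#' receive E times the kernel mass remaining from day j onward, divided by
#' the total kernel mass; cells born after \code{first_dose_day + 8} are
#' never labelled.
#'
#' @param birth_day Integer vector of birth days (day 0 = birth of the
#'   mouse), nonnegative.
#' @param pulse A \code{\link{pulse_design}}.
#' @param tissue Tissue name; must be present in the pulse's efficiency map.
#' @return Numeric vector of labelling probabilities.
#' @export
tag_probability <- function(birth_day, pulse, tissue) {
  stopifnot(all(birth_day >= 0))
  E <- efficiency_for(pulse, tissue)
  kernel_tag_fraction(birth_day, pulse) * E
}

## Kernel mass fraction accrued by `analysis_day` for cells born on
## `birth_day`, relative to total kernel mass. analysis_day = Inf gives the
## end-of-window probability used by tag_probability().
kernel_tag_fraction <- function(birth_day, pulse, analysis_day = Inf) {
  k <- pulse$kernel
  total <- sum(k)
  fd <- pulse$first_dose_day
  rem <- rev(cumsum(rev(k)))            # rem[j] = sum k[j..8]
  last <- min(8, analysis_day - fd)     # last active day index reached
  if (last < 1) return(rep(0, length(birth_day)))
  accrued_to <- cumsum(k)[last]         # mass accrued days 1..last
  j <- birth_day - fd                   # day-after-first-dose index at birth
  out <- numeric(length(birth_day))
  out[j <= 0] <- accrued_to / total
  mid <- which(j >= 1 & j <= last)
  if (length(mid))
    out[mid] <- (rem[j[mid]] - if (last < 8) rem[last + 1] else 0) / total
  out
}
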