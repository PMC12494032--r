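## Renewal/residency kinetics from labelled-fraction time courses.
## Time is in weeks throughout this module.

#' Two-point replacement rate
#'
#' Exact algebraic inverse of plateau-free exponential label decay: from
#' tagged fractions at two ages, r = log(F1/F2) / (t2 - t1) per week.
#'
#' @param f1,f2 Tagged fractions at the earlier/later timepoint
#'   (0 < f2 <= f1 <= 1).
#' @param t1,t2 Ages in weeks, t2 > t1.
#' @return List with \code{rate_per_week} and \code{half_life_weeks}
#'   (Inf when the fraction did not change).
#' @export
two_point_rate <- function(f1, t1, f2, t2) {
  stopifnot(t2 > t1, f1 > 0, f1 <= 1, f2 > 0)
  if (f2 > f1) stop("label gain is unphysical; check inputs")
  r <- log(f1 / f2) / (t2 - t1)
  list(rate_per_week = r,
       half_life_weeks = if (r == 0) Inf else log(2) / r)
}

decay_model <- function(t, t1, F0, plateau, r)
  plateau + (F0 - plateau) * exp(-r * (t - t1))

#' Fit an exponential-with-plateau label-decay model
#'
#' Least-squares fit of F(t) = plateau + (F0 - plateau) exp(-r (t - t1)) to
#' a labelled-fraction time course, with box constraints
#' 0 <= plateau <= F0 <= 1 and r >= 0. The plateau is the non-replaced
#' resident fraction; \code{free_plateau = FALSE} fixes it at 0 (pure
#' replacement). Optimization uses L-BFGS-B from 5 deterministic starting
#' points; the best SSE fit is kept.
#'
#' @param timepoints Ages in weeks (>= 3 points with a free plateau, >= 2
#'   otherwise).
#' @param fractions Tagged fractions (typically group medians) in \[0, 1\].
#' @param free_plateau Estimate the plateau (TRUE) or fix it at 0.
#' @param weights Optional nonnegative fit weights per point.
#' @return An object of class \code{decay_fit} with coefficients F0,
#'   plateau, rate_per_week, half_life_weeks.
#' @export
fit_decay <- function(timepoints, fractions, free_plateau = TRUE,
                      weights = rep(1, length(timepoints))) {
  n <- length(timepoints)
  stopifnot(length(fractions) == n, length(weights) == n,
            all(fractions >= 0), all(fractions <= 1), all(weights >= 0))
  if (n < (if (free_plateau) 3 else 2))
    stop("need at least ", if (free_plateau) 3 else 2, " timepoints")
  ord <- order(timepoints)
  tp <- timepoints[ord]; fr <- fractions[ord]; wt <- weights[ord]
  t1 <- tp[1]
  finish <- function(F0, plateau, r, conv) {
    fitted <- decay_model(tp, t1, F0, plateau, r)
    structure(list(
      coefficients = c(F0 = F0, plateau = plateau, rate_per_week = r,
                       half_life_weeks = if (r <= 0) Inf else log(2) / r),
      t1 = t1, timepoints = tp, fractions = fr, weights = wt,
      fitted = fitted, residuals = fr - fitted,
      sse = sum(wt * (fr - fitted)^2), free_plateau = free_plateau,
      convergence = conv), class = "decay_fit")
  }
  if (stats::var(fr) == 0)            # constant series: no decay
    return(finish(fr[1], if (free_plateau) fr[1] else 0, 0, 0L))
  if (!free_plateau && n == 2) {      # exact algebraic solution
    if (fr[2] > fr[1]) stop("label gain is unphysical; check inputs")
    if (fr[2] <= 0) stop("zero fraction: rate unidentifiable without plateau")
    r <- log(fr[1] / fr[2]) / (tp[2] - t1)
    return(finish(fr[1], 0, r, 0L))
  }
  r0 <- {
    i <- which(fr > 0)
    if (length(i) >= 2 && fr[i[1]] > fr[i[length(i)]])
      log(fr[i[1]] / fr[i[length(i)]]) / (tp[i[length(i)]] - tp[i[1]])
    else 0.05
  }
  ## the model is linear in (plateau, amplitude) for fixed r, so profile:
  ## constrained weighted least squares inside a 1-D search over r
  profile_fit <- function(r) {
    if (r < 1e-12) {
      c_hat <- min(1, max(0, sum(wt * fr) / sum(wt)))
      return(list(plateau = if (free_plateau) c_hat else 0,
                  amp = if (free_plateau) 0 else c_hat,
                  sse = sum(wt * (fr - c_hat)^2)))
    }
    w <- exp(-r * (tp - t1))
    cand <- list()
    if (free_plateau) {
      ## unconstrained (a, b): y ~ a + b w, weighted
      sw <- sum(wt); swx <- sum(wt * w); swxx <- sum(wt * w^2)
      swy <- sum(wt * fr); swxy <- sum(wt * w * fr)
      det <- sw * swxx - swx^2
      if (abs(det) > 1e-14) {
        a <- (swxx * swy - swx * swxy) / det
        b <- (sw * swxy - swx * swy) / det
        cand <- c(cand, list(c(a, b)))
      }
    }
    ## boundary cases: no plateau (a = 0), no decay amplitude (b = 0)
    cand <- c(cand,
              list(c(0, sum(wt * w * fr) / sum(wt * w^2)),
                   c(sum(wt * fr) / sum(wt), 0)))
    best_p <- NULL
    for (p in cand) {
      a <- min(max(p[1], 0), 1)
      b <- min(max(p[2], 0), 1 - a)   # 0 <= plateau <= F0 <= 1
      sse <- sum(wt * (fr - (a + b * w))^2)
      if (is.null(best_p) || sse < best_p$sse)
        best_p <- list(plateau = a, amp = b, sse = sse)
    }
    best_p
  }
  starts <- unique(pmin(pmax(r0 * c(0.25, 0.5, 1, 2, 4), 1e-4), 50))
  best <- NULL; best_r <- NA
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, function(r) profile_fit(r)$sse,
                   method = "L-BFGS-B", lower = 0, upper = 50,
                   control = list(maxit = 1000, factr = 1)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt; best_r <- opt$par
    }
  }
  if (is.null(best))
    stop("decay fit did not converge from any start; ",
         "data range: ", paste(signif(range(fr), 3), collapse = "-"))
  pf <- profile_fit(best_r)
  finish(pf$plateau + pf$amp, pf$plateau, best_r, best$convergence)
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Label-decay fit", if (!x$free_plateau) "(plateau fixed at 0)", "\n")
  print(signif(x$coefficients, digits))
  cat("SSE:", signif(x$sse, digits), "on", length(x$timepoints),
      "timepoints\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$timepoints else
    if (is.list(newdata)) newdata$timepoints else newdata
  co <- object$coefficients
  decay_model(t, object$t1, co[["F0"]], co[["plateau"]],
              co[["rate_per_week"]])
}

#' @export
plot.decay_fit <- function(x, ...) {
  tt <- seq(min(x$timepoints), max(x$timepoints), length.out = 100)
  graphics::plot(x$timepoints, 100 * x$fractions, ylim = c(0, 100),
                 xlab = "age (weeks)", ylab = "tagged (%)", ...)
  graphics::lines(tt, 100 * predict(x, tt))
  graphics::abline(h = 100 * x$coefficients[["plateau"]], lty = 3)
  invisible(x)
}

#' Persistence ratio between two ages
#'
#' Ratio of tagged fractions at a later versus earlier age, interpreted as
#' the fraction of the earlier labelled population persisting, under a
#' constant-pool assumption (pool size unchanged between the two ages).
#'
#' @param f_later,f_earlier Tagged fractions; \code{f_earlier} must be
#'   positive.
#' @return The ratio; values above 1 are allowed but flagged.
#' @export
persistence_ratio <- function(f_later, f_earlier) {
  if (f_earlier <= 0) stop("f_earlier must be positive")
  message("persistence ratio assumes a constant pool size between ",
          "the two ages")
  ratio <- f_later / f_earlier
  if (ratio > 1)
    message("persistence ratio exceeds 1: label fraction increased")
  ratio
}
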