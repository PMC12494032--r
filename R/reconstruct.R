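## Retrospective decomposition of the adult Treg pool by generation week:
## per-mouse tagged fractions -> group summaries -> efficiency correction ->
## isotonic cumulative fit -> week-by-week increments, with bootstrap CIs
## and a 10x10 waffle allocation.

mouse_fractions <- function(cohort, tissue, subset = NULL) {
  rows <- cohort[cohort$tissue == tissue, , drop = FALSE]
  if (!nrow(rows)) stop("no records for tissue '", tissue, "'")
  if (is.null(subset)) {
    rows$fraction <- rows$n_tagged / rows$n_cells
  } else {
    pc <- paste0(subset, "_tag_pos")
    uc <- paste0(subset, "_untag_pos")
    if (!all(c(pc, uc) %in% names(rows)) || all(is.na(rows[[pc]]))) {
      message("subset '", subset, "' absent in tissue '", tissue,
              "'; skipping")
      return(NULL)
    }
    tot <- rows[[pc]] + rows[[uc]]
    rows$fraction <- ifelse(tot > 0, rows[[pc]] / tot, NA)
  }
  rows[!is.na(rows$fraction), c("mouse_id", "pulse_week", "fraction")]
}

#' Summarize tagged fractions per pulse group
#'
#' Computes per-mouse tagged fractions (n_tagged / n_cells) and a group
#' summary per pulse week. The group statistic is the median by default, as
#' is conventional for flow-cytometry frequency plots; the mean is
#' available.
#'
#' @param cohort A cohort data.frame (see \code{\link{read_cohort}}).
#' @param tissue Tissue to summarize.
#' @param pulse_weeks Pulse weeks that must be present; defaults to those
#'   observed. An empty requested group is an error.
#' @param statistic "median" or "mean".
#' @param subset Optional subset name; per-mouse fractions are then taken
#'   from the subset's marker columns
#'   (\code{<subset>_tag_pos / (<subset>_tag_pos + <subset>_untag_pos)}).
#' @return data.frame with columns pulse_week, tissue, summary, n_mice and
#'   attribute \code{fractions} (list of per-mouse fractions per group).
#' @export
summarize_groups <- function(cohort, tissue, pulse_weeks = NULL,
                             statistic = c("median", "mean"),
                             subset = NULL) {
  statistic <- match.arg(statistic)
  fr <- mouse_fractions(cohort, tissue, subset)
  if (is.null(fr)) return(NULL)
  if (is.null(pulse_weeks)) pulse_weeks <- sort(unique(fr$pulse_week))
  missing_w <- setdiff(pulse_weeks, fr$pulse_week)
  if (length(missing_w))
    stop("empty pulse group(s) for tissue '", tissue, "': week ",
         paste(missing_w, collapse = ", "))
  stat_fun <- if (statistic == "median") stats::median else mean
  by_week <- lapply(pulse_weeks, function(w) fr$fraction[fr$pulse_week == w])
  out <- data.frame(
    pulse_week = pulse_weeks, tissue = tissue,
    summary = vapply(by_week, stat_fun, numeric(1)),
    n_mice = lengths(by_week))
  attr(out, "fractions") <- by_week
  out
}

#' Correct a tagged fraction for tagging efficiency
#'
#' Divides by the tissue's tagging efficiency and clamps at 1.
#'
#' @param f Tagged fraction(s) in \[0, 1\].
#' @param efficiency Tagging efficiency E, 0 < E <= 1.
#' @return \code{pmin(f / efficiency, 1)}.
#' @export
correct_efficiency <- function(f, efficiency) {
  if (length(efficiency) != 1 || efficiency <= 0 || efficiency > 1)
    stop("efficiency must be a single value in (0, 1]")
  pmin(f / efficiency, 1)
}

#' Weighted nondecreasing isotonic regression
#'
#' Pool-adjacent-violators fit of a nondecreasing sequence in weighted least
#' squares. Applied to the corrected cumulative tagged fractions so that
#' sampling noise cannot produce negative "generated at week w" increments.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @return Monotone (nondecreasing) fitted values.
#' @export
isotonic_nondecreasing <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  stopifnot(length(weights) == n, all(weights > 0))
  if (n <= 1) return(values)
  ## blocks as (mean, weight, size) stacks
  mu <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    mu[top] <- values[i]; wt[top] <- weights[i]; sz[top] <- 1L
    while (top > 1L && mu[top - 1L] > mu[top]) {
      w <- wt[top - 1L] + wt[top]
      mu[top - 1L] <- (wt[top - 1L] * mu[top - 1L] + wt[top] * mu[top]) / w
      wt[top - 1L] <- w
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(mu[seq_len(top)], sz[seq_len(top)])
}

#' Cumulative-to-incremental decomposition
#'
#' Differences a nondecreasing corrected cumulative labelling curve into
#' per-week increments: p_1 = F_1, p_w = F_w - F_(w-1), and a
#' "generated later" tail 1 - F_W.
#'
#' @param cumulative Nondecreasing corrected cumulative fractions in
#'   \[0, 1\], one per pulse week.
#' @return List with \code{increments} (named w1..wW) and \code{tail}.
#' @export
decompose <- function(cumulative) {
  if (any(cumulative < -1e-9) || any(cumulative > 1 + 1e-9))
    stop("cumulative fractions must lie in [0, 1]")
  if (is.unsorted(cumulative, strictly = FALSE) &&
      any(diff(cumulative) < -1e-9))
    stop("cumulative curve is not nondecreasing; run ",
         "isotonic_nondecreasing() first")
  p <- diff(c(0, cumulative))
  p <- pmax(p, 0)
  names(p) <- paste0("w", seq_along(p))
  list(increments = p, tail = max(0, 1 - cumulative[length(cumulative)]))
}

#' Largest-remainder (Hamilton) waffle allocation
#'
#' Apportions a fixed number of grid cells to composition fractions:
#' each part receives the floor of its quota, and remaining cells go to the
#' largest remainders, earlier parts first on ties.
#'
#' @param fractions Nonnegative fractions summing to 1 (within 1e-6).
#' @param cells Total cells to allocate (default 100, a 10x10 grid).
#' @return Integer allocation summing to \code{cells}.
#' @export
waffle_allocate <- function(fractions, cells = 100) {
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  quota <- fractions * cells
  base <- floor(quota + 1e-9)
  left <- cells - sum(base)
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, seq_along(rem))   # ties: earlier part first
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(fractions)
  out
}

## point estimate given per-group fraction lists
composition_point <- function(by_week, efficiency, statistic, n_mice) {
  stat_fun <- if (statistic == "median") stats::median else mean
  f <- vapply(by_week, stat_fun, numeric(1))
  corrected <- correct_efficiency(f, efficiency)
  iso <- isotonic_nondecreasing(corrected, weights = n_mice)
  c(decompose(iso)$increments, tail = decompose(iso)$tail)
}

#' Reconstruct the pool composition by generation week
#'
#' The full retrospective pipeline for one tissue (optionally one subset):
#' per-mouse tagged fractions, group summaries across pulse weeks,
#' efficiency correction, isotonic (nondecreasing) cumulative fit,
#' cumulative-to-incremental decomposition, percentile bootstrap confidence
#' intervals (mice resampled with replacement within pulse groups), and a
#' 10x10 waffle allocation.
#'
#' @inheritParams summarize_groups
#' @param efficiency Tagging efficiency for the tissue (0 < E <= 1).
#' @param B Bootstrap replicates (0 disables the bootstrap).
#' @param seed Seed for the bootstrap resampling.
#' @param cells Waffle grid size.
#' @return An object of class \code{treg_composition}: increments \code{p}
#'   (per week plus tail), corrected cumulative curve, per-increment CIs,
#'   waffle allocation, and the group table.
#' @export
reconstruct_composition <- function(cohort, tissue, efficiency,
                                    pulse_weeks = NULL,
                                    statistic = c("median", "mean"),
                                    subset = NULL, B = 1000, seed = 1,
                                    cells = 100) {
  statistic <- match.arg(statistic)
  groups <- summarize_groups(cohort, tissue, pulse_weeks, statistic, subset)
  if (is.null(groups)) return(NULL)
  by_week <- attr(groups, "fractions")
  weeks <- groups$pulse_week
  point <- composition_point(by_week, efficiency, statistic, groups$n_mice)
  corrected <- isotonic_nondecreasing(
    correct_efficiency(groups$summary, efficiency), weights = groups$n_mice)
  ci <- NULL
  if (B > 0) {
    if (B < 100) warning("B < 100 gives unstable percentile intervals")
    if (any(groups$n_mice == 1))
      warning("pulse group of size 1: degenerate bootstrap interval")
    set.seed(seed)
    boot <- matrix(NA_real_, B, length(point))
    for (b in seq_len(B)) {
      res <- lapply(by_week, function(v) v[sample.int(length(v),
                                                      replace = TRUE)])
      boot[b, ] <- composition_point(res, efficiency, statistic,
                                     groups$n_mice)
    }
    ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
    dimnames(ci) <- list(names(point), c("lo", "hi"))
  }
  structure(
    list(tissue = tissue, subset = subset, weeks = weeks,
         statistic = statistic, efficiency = efficiency,
         groups = groups, cumulative_raw = groups$summary,
         cumulative_corrected = corrected,
         increments = point[seq_along(weeks)],
         tail = unname(point[length(point)]),
         ci = ci, waffle = waffle_allocate(point, cells),
         B = B, seed = seed),
    class = "treg_composition")
}

#' Subset-stratified reconstruction
#'
#' Runs the reconstruction pipeline on a transcription-factor-defined Treg
#' subset (e.g. GATA3+, RORgt+ or double-negative in the colon), using the
#' subset's paired marker columns. Returns NULL with a message when the
#' subset is absent from the tissue.
#'
#' @inheritParams reconstruct_composition
#' @param subset Subset name (marker column prefix).
#' @export
stratified_reconstruct <- function(cohort, tissue, subset, efficiency,
                                   pulse_weeks = NULL,
                                   statistic = c("median", "mean"),
                                   B = 1000, seed = 1) {
  reconstruct_composition(cohort, tissue, efficiency,
                          pulse_weeks = pulse_weeks, statistic = statistic,
                          subset = subset, B = B, seed = seed)
}

#' @export
print.treg_composition <- function(x, digits = 3, ...) {
  cat("Treg pool composition by generation week --", x$tissue,
      if (!is.null(x$subset)) paste0("[", x$subset, "]"), "\n")
  df <- as.data.frame(x)
  print(format(df, digits = digits), row.names = FALSE)
  cat("Waffle (", sum(x$waffle), " cells): ",
      paste0(names(x$waffle), "=", x$waffle, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.treg_composition <- function(object, ...) {
  cat("Reconstruction of the", object$tissue, "Treg pool",
      if (!is.null(object$subset)) paste0("(subset ", object$subset, ")"),
      "\n")
  cat("  pulse weeks:", paste(object$weeks, collapse = ", "),
      "| statistic:", object$statistic,
      "| efficiency:", object$efficiency, "\n")
  cat("  generated in weeks 1-2:",
      sprintf("%.1f%%", 100 * sum(object$increments[1:min(2,
        length(object$increments))])), "\n")
  cat("  generated later than week", max(object$weeks), ":",
      sprintf("%.1f%%", 100 * object$tail), "\n")
  if (!is.null(object$ci)) cat("  bootstrap B =", object$B, "\n")
  invisible(object)
}

#' @export
as.data.frame.treg_composition <- function(x, ...) {
  wk <- c(as.character(x$weeks), paste0(">", max(x$weeks)))
  p <- c(unname(x$increments), x$tail)
  df <- data.frame(
    tissue = if (is.null(x$subset)) x$tissue else
      paste0(x$tissue, ".", x$subset),
    week = wk, increment = p,
    ci_lo = if (!is.null(x$ci)) x$ci[, "lo"] else NA_real_,
    ci_hi = if (!is.null(x$ci)) x$ci[, "hi"] else NA_real_,
    cumulative_corrected = c(x$cumulative_corrected, NA),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' @export
plot.treg_composition <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$weeks, 100 * x$cumulative_corrected, type = "b",
                 ylim = c(0, 100), xlab = "pulse week",
                 ylab = "cumulative tagged (%)",
                 main = paste(x$tissue,
                              if (!is.null(x$subset)) x$subset else ""), ...)
  graphics::barplot(100 * c(x$increments, later = x$tail),
                    ylab = "share of pool (%)", xlab = "generation week")
  invisible(x)
}
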