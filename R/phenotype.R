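## Paired Tag-vs-unTag marker statistics: exact Wilcoxon signed-rank within
## mice, Benjamini-Hochberg control across a marker panel.

## Exact null distribution of the signed-rank statistic by a
## generating-function convolution over doubled midranks (exact under ties):
## returns P(W2 = k) for W2 = 2 * (sum of positive ranks), k = 0..sum(2r).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' Paired Wilcoxon signed-rank test for marker proportions
#'
#' Compares marker-positive proportions between tagged and untagged Tregs of
#' the same mice. Zero differences are discarded by default (classic
#' convention); \code{zeros = "pratt"} keeps them for ranking. The null
#' distribution is exact (full enumeration via convolution over midranks,
#' valid under ties) up to \code{exact_max} informative pairs, and a normal
#' approximation with continuity and tie correction beyond.
#'
#' @param tag_fractions,untag_fractions Paired per-mouse proportions.
#' @param zeros "wilcoxon" (discard zero differences) or "pratt".
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with \code{statistic} (V, sum of positive ranks),
#'   \code{p.value} (two-sided), \code{n_used}, \code{method}.
#' @export
paired_marker_test <- function(tag_fractions, untag_fractions,
                               zeros = c("wilcoxon", "pratt"),
                               exact_max = 25) {
  zeros <- match.arg(zeros)
  stopifnot(length(tag_fractions) == length(untag_fractions))
  d <- tag_fractions - untag_fractions
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least 2 paired observations")
  if (all(d == 0)) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p.value = 1, n_used = 0,
                method = "degenerate"))
  }
  if (zeros == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  V <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  if (n <= exact_max) {
    null <- signed_rank_null(r2)
    obs <- as.integer(round(2 * V))
    lower <- sum(null[seq_len(obs + 1)])
    upper <- sum(null[(obs + 1):length(null)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    ew <- sum(r) / 2
    vw <- sum(r^2) / 4
    z <- (V - ew - 0.5 * sign(V - ew)) / sqrt(vw)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, n_used = n, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a marker panel (wraps
#' \code{stats::p.adjust}).
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted values, never below the raw p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-marker Tag-vs-unTag report for one tissue
#'
#' For every marker with paired columns
#' \code{<marker>_{tag,untag}_{pos,tot}} in the cohort, computes per-mouse
#' positive proportions in each arm, group medians, the paired Wilcoxon
#' test, and BH-adjusted q-values. Rows are ordered by decreasing absolute
#' median difference. Markers restricted to particular tissues (RORgt
#' expression is essentially confined to colon and skin) are skipped
#' elsewhere with a message, as are markers with a missing arm.
#'
#' @param cohort Cohort data.frame with marker columns.
#' @param tissue Tissue to report.
#' @param markers Marker names; default: all found in the columns.
#' @param restricted Named list: marker -> tissues where it is assessable.
#' @param zeros Zero-difference convention, see
#'   \code{\link{paired_marker_test}}.
#' @return data.frame (marker, n, median_tag, median_untag, delta, p, q).
#' @export
marker_report <- function(cohort, tissue, markers = NULL,
                          restricted = list(RORgt = c("colon", "skin")),
                          zeros = "wilcoxon") {
  rows <- cohort[cohort$tissue == tissue, , drop = FALSE]
  if (nrow(rows) < 2) stop("need at least 2 mice in tissue '", tissue, "'")
  if (is.null(markers)) {
    markers <- unique(sub("_tag_pos$", "",
                          grep("_tag_pos$", names(rows), value = TRUE)))
  }
  out <- list()
  for (mk in markers) {
    if (mk %in% names(restricted) && !tissue %in% restricted[[mk]]) {
      message("marker '", mk, "' not assessable in tissue '", tissue,
              "'; skipped")
      next
    }
    cols <- paste0(mk, c("_tag_pos", "_tag_tot", "_untag_pos", "_untag_tot"))
    if (!all(cols %in% names(rows)) || all(is.na(rows[[cols[1]]]))) {
      message("marker '", mk, "' missing an arm in tissue '", tissue,
              "'; skipped")
      next
    }
    ok <- stats::complete.cases(rows[, cols]) &
      rows[[cols[2]]] > 0 & rows[[cols[4]]] > 0
    if (sum(ok) < 2) {
      message("marker '", mk, "': fewer than 2 complete pairs; skipped")
      next
    }
    f_tag <- rows[[cols[1]]][ok] / rows[[cols[2]]][ok]
    f_untag <- rows[[cols[3]]][ok] / rows[[cols[4]]][ok]
    tst <- paired_marker_test(f_tag, f_untag, zeros = zeros)
    out[[mk]] <- data.frame(
      marker = mk, n = sum(ok),
      median_tag = stats::median(f_tag),
      median_untag = stats::median(f_untag),
      delta = stats::median(f_tag) - stats::median(f_untag),
      p = tst$p.value, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker = character(), n = integer(),
                      median_tag = numeric(), median_untag = numeric(),
                      delta = numeric(), p = numeric(), q = numeric()))
  rep_df <- do.call(rbind, out)
  rep_df$q <- bh_adjust(rep_df$p)
  rep_df <- rep_df[order(-abs(rep_df$delta)), ]
  rownames(rep_df) <- NULL
  rep_df
}
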