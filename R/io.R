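## Cohort CSV reader/writer with schema validation, and the end-to-end
## simulate -> reconstruct -> turnover -> phenotype driver. Only integer
## counts are serialized, never proportions, so downstream statistics are
## exactly reproducible from the files.

cohort_required_cols <- c("mouse_id", "tissue", "pulse_week", "pulse_day",
                          "analysis_day", "n_cells", "n_tagged")

#' Validate a cohort table
#'
#' @param cohort data.frame to validate against the cohort schema.
#' @return The validated cohort, invisibly classed as \code{cohort_table}.
#' @export
validate_cohort <- function(cohort) {
  missing_c <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing_c))
    stop("missing column(s): ", paste(missing_c, collapse = ", "))
  if (!nrow(cohort)) stop("no records")
  count_cols <- c("n_cells", "n_tagged",
                  grep("_(pos|tot)$|^divided_recent$", names(cohort),
                       value = TRUE))
  for (cc in count_cols) {
    v <- cohort[[cc]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad))
      stop("column ", cc, ", row ", bad[1],
           ": counts must be nonnegative integers")
  }
  bad <- which(cohort$n_tagged > cohort$n_cells)
  if (length(bad))
    stop("row ", bad[1], ": n_tagged exceeds n_cells")
  pos_cols <- grep("_pos$", names(cohort), value = TRUE)
  for (pc in pos_cols) {
    tc <- sub("_pos$", "_tot", pc)
    if (tc %in% names(cohort)) {
      bad <- which(!is.na(cohort[[pc]]) & cohort[[pc]] > cohort[[tc]])
      if (length(bad))
        stop("column ", pc, ", row ", bad[1], ": positives exceed total")
    }
  }
  key <- paste(cohort$mouse_id, cohort$tissue, cohort$pulse_week,
               cohort$analysis_day)
  if (anyDuplicated(key))
    stop("duplicate (mouse_id, tissue) record at row ",
         which(duplicated(key))[1])
  class(cohort) <- unique(c("cohort_table", class(cohort)))
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, mandatory header. Required columns:
#' mouse_id, tissue, pulse_week, pulse_day, analysis_day, n_cells, n_tagged;
#' optional marker columns \code{<marker>_{tag,untag}_{pos,tot}} and
#' \code{divided_recent}. Violations raise errors naming row and column.
#'
#' @param path File path.
#' @return Validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("no records"))
  if (!nrow(cohort)) stop("no records")
  validate_cohort(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(as.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full fate-mapping pipeline
#'
#' Simulates the scenario's cohorts and writes the analysis artifacts to a
#' directory: \code{cohort.csv} (ontogeny cohort), \code{composition.csv}
#' (per-tissue and per-subset generation-week decompositions),
#' \code{decay.csv} (adult-pulse label-decay fits), \code{report.csv}
#' (per-tissue marker statistics) and \code{run.log}. Byte-identical outputs
#' given the same scenario and seed.
#'
#' @param scenario Scenario list (\code{\link{read_scenario}}) or a path to
#'   a scenario YAML file.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed; defaults to the scenario's.
#' @param B Bootstrap replicates for composition CIs.
#' @return Invisibly, a list with the in-memory artifacts.
#' @export
run_pipeline <- function(scenario, out_dir, seed = NULL, B = 200) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  if (is.null(seed)) seed <- scenario$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  logline <- function(...) writeLines(paste0(...), logcon)
  logline("scenario: ", scenario$name, " | seed: ", seed,
          " | version: ", as.character(utils::packageVersion("tregfate")))
  logline("tissues: ", paste(names(scenario$tissues), collapse = ", "))
  logline("pulse weeks: ", paste(scenario$pulse_weeks, collapse = ", "),
          " | mice/group: ", scenario$mice_per_group,
          " | analysis day: ", scenario$analysis_day)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  cohort <- stage("simulate",
                  simulate_cohort(scenario, seed = seed))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  comp_list <- stage("reconstruct", {
    out <- list()
    for (tis in names(scenario$tissues)) {
      entry <- scenario$tissues[[tis]]
      out[[tis]] <- reconstruct_composition(
        cohort, tis, entry$efficiency, B = B, seed = seed + 1)
      logline("reconstructed ", tis)
      for (sn in names(entry$subsets)) {
        cs <- stratified_reconstruct(cohort, tis, sn, entry$efficiency,
                                     B = B, seed = seed + 1)
        if (!is.null(cs)) {
          out[[paste0(tis, ".", sn)]] <- cs
          logline("reconstructed ", tis, " subset ", sn)
        }
      }
    }
    out
  })
  comp_df <- do.call(rbind, lapply(comp_list, as.data.frame))
  utils::write.csv(comp_df, file.path(out_dir, "composition.csv"),
                   row.names = FALSE, quote = FALSE)

  decay_df <- NULL
  if (!is.null(scenario$turnover)) {
    decay_df <- stage("turnover", {
      tw <- scenario$turnover
      ads <- 7 * tw$analysis_weeks
      adult <- simulate_cohort(scenario, seed = seed + 2,
                               pulse_days = tw$pulse_day,
                               analysis_day = ads, markers = FALSE)
      rows <- lapply(names(scenario$tissues), function(tis) {
        med <- vapply(ads, function(ad) {
          fr <- adult[adult$tissue == tis & adult$analysis_day == ad, ]
          stats::median(fr$n_tagged / fr$n_cells)
        }, numeric(1))
        fit <- fit_decay(tw$analysis_weeks, med,
                         free_plateau = length(ads) >= 3)
        co <- coef(fit)
        logline("decay fit ", tis, ": r=", signif(co[["rate_per_week"]], 4),
                "/week, plateau=", signif(co[["plateau"]], 4))
        data.frame(tissue = tis, F0 = co[["F0"]], plateau = co[["plateau"]],
                   rate_per_week = co[["rate_per_week"]],
                   half_life_weeks = co[["half_life_weeks"]],
                   n_points = length(ads))
      })
      do.call(rbind, rows)
    })
    utils::write.csv(decay_df, file.path(out_dir, "decay.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  report_df <- stage("phenotype", {
    rows <- lapply(names(scenario$tissues), function(tis) {
      week1 <- cohort[cohort$pulse_week == 1, ]
      rep_t <- withCallingHandlers(
        marker_report(week1, tis),
        message = function(m) {
          logline(trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        })
      if (nrow(rep_t)) cbind(tissue = tis, rep_t) else NULL
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  })
  utils::write.csv(report_df, file.path(out_dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  logline("done")
  invisible(list(cohort = cohort, composition = comp_list,
                 decay = decay_df, report = report_df))
}
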