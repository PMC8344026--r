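# End-to-end screening workflow: categorize -> univariate screen per cause
# -> collinearity pruning -> multivariate model per cause -> cumulative
# incidence table, with TSV/markdown report output and a run log.

#' Run the full prognostic-factor screening pipeline
#'
#' Orchestrates the analysis sequence on a cohort: clinical categorization
#' (optional), a univariate competing-risks screen of every candidate
#' variable for each cause, collinearity pruning of the retained sets,
#' a multivariate model per cause, and the cumulative incidence table.
#' Stage errors are caught and reported per stage; earlier stage outputs
#' are kept.
#'
#' @param data Cohort data frame (`time`, `event`, covariates), e.g. from
#'   [simulate_cohort()] or [read_cohort()].
#' @param variables Candidate variables for screening; default is every
#'   column except `time` and `event`.
#' @param rules Optional [default_category_rules()]-style table; when given,
#'   [categorize()] is applied first and the categorized columns replace
#'   their quantitative sources in the candidate list.
#' @param univariate_alpha,multivariate_alpha Retention / significance
#'   gates (defaults 0.25 and 0.10).
#' @param ci_levels Interval levels for the univariate and multivariate
#'   tables (defaults 0.75 and 0.90).
#' @param collinearity_bound Association bound for pruning (default 0.8).
#' @param years Years for the cumulative incidence table.
#' @param out_dir Optional directory: writes `univariate_<cause>.tsv`,
#'   `multivariate_<cause>.tsv`, `cumulative_incidence.tsv`, `report.md`
#'   and `run.log`.
#' @param cause_labels Labels for causes 1 and 2.
#' @param control Optimizer settings shared by all fits.
#' @return An object of class `screen_report`: a list with elements
#'   `univariate` (per cause), `collinearity`, `retained`, `multivariate`
#'   (per cause), `incidence`, `notes`, and `log`.
#' @export
run_screening <- function(data, variables = NULL, rules = NULL,
                          univariate_alpha = 0.25, multivariate_alpha = 0.10,
                          ci_levels = c(0.75, 0.90),
                          collinearity_bound = 0.8, years = 1:4,
                          out_dir = NULL,
                          cause_labels = c("death", "transplant"),
                          control = crisk_control(multistart = 2)) {
  .check_records(data)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  notes <- character(0)

  if (!is.null(rules)) {
    data <- categorize(data, rules)
    binned <- unique(rules$variable)
    if (is.null(variables)) variables <- setdiff(names(data), c("time", "event"))
    variables <- union(setdiff(variables, binned), paste0(binned, "_cat"))
    note("categorized %d variable(s): %s", length(binned),
         paste(binned, collapse = ", "))
  }
  if (is.null(variables)) variables <- setdiff(names(data), c("time", "event"))
  note("screening %d candidate variable(s), n = %d (%d deaths, %d transplants)",
       length(variables), nrow(data), sum(data$event == 1),
       sum(data$event == 2))

  res <- list(univariate = list(), multivariate = list(),
              retained = list(), collinearity = NULL, incidence = NULL,
              notes = notes, log = log, cause_labels = cause_labels,
              thresholds = c(univariate = univariate_alpha,
                             multivariate = multivariate_alpha))

  present <- sort(unique(data$event[data$event > 0]))
  for (k in 1:2) {
    lab <- cause_labels[k]
    if (!k %in% present) {
      res$notes <- c(res$notes, sprintf(
        "no %s events in the cohort; %s regression tables omitted.", lab, lab))
      note("cause `%s`: no events; skipped", lab)
      next
    }
    uni <- tryCatch(
      univariate_screen(data, variables, outcome = k,
                        threshold = univariate_alpha,
                        ci_level = ci_levels[1],
                        cause_labels = cause_labels, control = control),
      error = function(e) e)
    if (inherits(uni, "error")) {
      res$notes <- c(res$notes, sprintf("univariate screen (%s) failed: %s",
                                        lab, conditionMessage(uni)))
      next
    }
    res$univariate[[lab]] <- uni
    kept <- unique(uni$variable[uni$retained])
    note("cause `%s`: retained %d of %d variable(s) at p < %.2f", lab,
         length(kept), length(variables), univariate_alpha)

    coll <- collinearity_check(data, kept, bound = collinearity_bound)
    if (nrow(coll)) {
      for (i in seq_len(nrow(coll))) {
        note("cause `%s`: dropping `%s` (assoc %.2f with `%s` > %.2f)",
             lab, coll$drop[i], coll$assoc[i], coll$var1[i],
             collinearity_bound)
      }
      kept <- setdiff(kept, coll$drop)
    }
    res$collinearity <- dplyr::bind_rows(res$collinearity, coll)
    res$retained[[lab]] <- kept

    if (length(kept) == 0) {
      res$notes <- c(res$notes, sprintf(
        "no variables retained for %s; multivariate model skipped.", lab))
      next
    }
    mv <- tryCatch(
      multivariate_fit(data,
                       retained1 = if (k == 1) kept else character(0),
                       retained2 = if (k == 2) kept else character(0),
                       threshold = multivariate_alpha,
                       ci_level = ci_levels[2],
                       cause_labels = cause_labels, control = control),
      error = function(e) e)
    if (inherits(mv, "error")) {
      res$notes <- c(res$notes, sprintf("multivariate fit (%s) failed: %s",
                                        lab, conditionMessage(mv)))
      next
    }
    res$multivariate[[lab]] <-
      mv$table[mv$table$cause == lab, , drop = FALSE]
    res$multivariate_fits[[lab]] <- mv$fit
    note("cause `%s`: multivariate model with %s", lab,
         paste(kept, collapse = " + "))
  }

  inc <- tryCatch(
    cumulative_incidence_table(data, years = years,
                               cause_labels = cause_labels,
                               control = control),
    error = function(e) e)
  if (inherits(inc, "error")) {
    res$notes <- c(res$notes, paste("incidence table failed:",
                                    conditionMessage(inc)))
  } else {
    res$incidence <- inc
  }
  res$log <- log
  out <- structure(res, class = "screen_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Competing-risks screening report\n")
  for (lab in names(x$univariate)) {
    u <- x$univariate[[lab]]
    cat(sprintf("\n== Univariate screen (%s), retain at p < %.2f ==\n",
                lab, x$thresholds["univariate"]))
    print(dplyr::select(u, "variable", "level", "shr", "conf.low",
                        "conf.high", "p.value", "retained"), n = Inf)
  }
  for (lab in names(x$multivariate)) {
    cat(sprintf("\n== Multivariate model (%s), flag at p < %.2f ==\n",
                lab, x$thresholds["multivariate"]))
    print(dplyr::select(x$multivariate[[lab]], -"cause"), n = Inf)
  }
  if (!is.null(x$incidence)) {
    cat("\n== Cumulative incidence (%) ==\n")
    print(x$incidence)
  }
  if (length(x$notes)) {
    cat("\nNotes:\n")
    for (nt in x$notes) cat(" -", nt, "\n")
  }
  invisible(x)
}

#' Write a screening report to disk
#'
#' Emits TSV tables, a markdown summary and the run log.
#'
#' @param report A `screen_report` from [run_screening()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
  }
  md <- c("# Competing-risks screening report", "")
  for (lab in names(report$univariate)) {
    wr(report$univariate[[lab]], paste0("univariate_", lab))
    u <- report$univariate[[lab]]
    md <- c(md, sprintf("## Univariate screen (%s)", lab), "",
            sprintf("Retained at p < %.2f: %s",
                    report$thresholds["univariate"],
                    paste(unique(u$variable[u$retained]), collapse = ", ")),
            "")
  }
  for (lab in names(report$multivariate)) {
    wr(report$multivariate[[lab]], paste0("multivariate_", lab))
    m <- report$multivariate[[lab]]
    sig <- m[!m$reference & m$significant, , drop = FALSE]
    md <- c(md, sprintf("## Multivariate model (%s)", lab), "",
            sprintf("Significant at p < %.2f:",
                    report$thresholds["multivariate"]), "")
    pct_col <- grep("^shr_ci_", names(m), value = TRUE)[1]
    for (i in seq_len(nrow(sig))) {
      md <- c(md, sprintf("- %s%s: adjusted S-HR %s, p = %.3g",
                          sig$variable[i],
                          ifelse(is.na(sig$level[i]), "",
                                 paste0(" [", sig$level[i], "]")),
                          sig[[pct_col]][i], sig$p.value[i]))
    }
    md <- c(md, "")
  }
  if (!is.null(report$incidence)) {
    wr(report$incidence, "cumulative_incidence")
    md <- c(md, "## Cumulative incidence (%)", "",
            paste(capture_table(report$incidence), collapse = "\n"), "")
  }
  if (length(report$notes)) {
    md <- c(md, "## Notes", "", paste("-", report$notes), "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

# minimal markdown table rendering
capture_table <- function(df) {
  hd <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r)
    paste("|", paste(format(r, digits = 4), collapse = " | "), "|"))
  c(hd, sep, rows)
}
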