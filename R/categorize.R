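# Clinical categorization of quantitative labs, following the graded
# cutpoints used in dialysis practice.  Bins are closed intervals exactly
# as printed in clinical tables; since lab values are reported to one
# decimal, consecutive printed bins are exhaustive at that resolution.
# Values falling outside every bin are labeled "out-of-range" and flagged,
# never silently clamped.

#' Clinical category rules for dialysis laboratory variables
#'
#' One row per bin: variable, closed interval `[lower, upper]` (with
#' open-ended bins encoded by infinite bounds and strict inequality), the
#' printed label, and whether the bin is the reference category for
#' sub-hazard-ratio tables.
#'
#' @return A tibble with columns `variable`, `lower`, `upper`,
#'   `incl_lower`, `incl_upper`, `label`, `reference`.
#' @export
default_category_rules <- function() {
  r <- function(variable, lower, upper, incl_lower, incl_upper, label,
                reference = FALSE) {
    tibble::tibble(variable = variable, lower = lower, upper = upper,
                   incl_lower = incl_lower, incl_upper = incl_upper,
                   label = label, reference = reference)
  }
  dplyr::bind_rows(
    r("hemoglobin", -Inf, 10,  FALSE, FALSE, "<10"),
    r("hemoglobin", 10, 12.5,  TRUE,  TRUE,  "10-12.5", TRUE),
    r("hemoglobin", 12.5, Inf, FALSE, FALSE, ">12.5"),
    r("potassium", 3.5, 5,     TRUE,  TRUE,  "3.5-5", TRUE),
    r("potassium", 5, Inf,     FALSE, FALSE, ">5"),
    r("alp", -Inf, 300,        FALSE, FALSE, "<300", TRUE),
    r("alp", 300, Inf,         FALSE, FALSE, ">300"),
    r("hba1c", -Inf, 7,        FALSE, FALSE, "<7", TRUE),
    r("hba1c", 7, Inf,         FALSE, FALSE, ">7"),
    r("calcium", -Inf, 8.5,    FALSE, FALSE, "<8.5"),
    r("calcium", 8.5, 9.5,     TRUE,  TRUE,  "8.5-9.5", TRUE),
    r("calcium", 9.5, Inf,     FALSE, FALSE, ">9.5"),
    r("phosphorus", 2.7, 4.6,  TRUE,  TRUE,  "2.7-4.6", TRUE),
    r("phosphorus", 4.7, 5.7,  TRUE,  TRUE,  "4.7-5.7"),
    r("phosphorus", 5.8, 6.8,  TRUE,  TRUE,  "5.8-6.8"),
    r("phosphorus", 6.9, 9.9,  TRUE,  TRUE,  "6.9-9.9"),
    r("pth", -Inf, 150,        FALSE, FALSE, "<150"),
    r("pth", 150, 600,         TRUE,  TRUE,  "150-600", TRUE),
    r("pth", 600, Inf,         FALSE, FALSE, ">600"),
    r("albumin", -Inf, 4,      FALSE, FALSE, "<4", TRUE),
    r("albumin", 4, 6.3,       TRUE,  TRUE,  "4-6.3")
  )
}

.bin_one <- function(x, rules_v) {
  lab <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(rules_v))) {
    lo_ok <- if (rules_v$incl_lower[i]) x >= rules_v$lower[i] else x > rules_v$lower[i]
    hi_ok <- if (rules_v$incl_upper[i]) x <= rules_v$upper[i] else x < rules_v$upper[i]
    hit <- lo_ok & hi_ok & is.na(lab)
    lab[hit] <- rules_v$label[i]
  }
  lab
}

#' Categorize quantitative variables by clinical cutpoints
#'
#' Adds, for each variable named in `rules`, a factor column
#' `<variable>_cat` whose levels put the reference category first.  Values
#' outside every bin become the explicit level `"out-of-range"` with a
#' warning.
#'
#' @param data Data frame holding the quantitative variables.
#' @param rules Rule table as from [default_category_rules()]; may cover a
#'   subset of variables.
#' @return `data` with the categorical columns appended.
#' @examples
#' categorize(data.frame(phosphorus = c(5.0, 4.7, 9.0)),
#'            default_category_rules())
#' @export
categorize <- function(data, rules = default_category_rules()) {
  stopifnot(is.data.frame(data), is.data.frame(rules))
  vars <- unique(rules$variable)
  missing_v <- setdiff(vars, names(data))
  if (length(missing_v)) {
    stop("variable(s) not found in data: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  for (v in vars) {
    rv <- rules[rules$variable == v, , drop = FALSE]
    if (sum(rv$reference) != 1) {
      stop("rules for `", v, "` must name exactly one reference category.",
           call. = FALSE)
    }
    lab <- .bin_one(data[[v]], rv)
    oor <- !is.na(data[[v]]) & is.na(lab)
    if (any(oor)) {
      warning(sum(oor), " value(s) of `", v,
              "` fall outside every bin; labeled \"out-of-range\".",
              call. = FALSE)
      lab[oor] <- "out-of-range"
    }
    lv <- c(rv$label[rv$reference], rv$label[!rv$reference])
    if (any(oor)) lv <- c(lv, "out-of-range")
    data[[paste0(v, "_cat")]] <- factor(lab, levels = lv)
  }
  data
}
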