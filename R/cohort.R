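#' Load a specimen cohort table
#'
#' Reads a CSV of congenital-heart-disease specimen metadata: one row per
#' specimen with its category, years spent in formalin, age at death, sex,
#' ventricular-septal-defect (VSD) flag, pulmonary valve status, surgical
#' note and T1/T2 summaries (metadata only). Missing age/sex are preserved
#' as `NA`. A transcription of the study cohort ships with the package:
#' `system.file("extdata", "cohort_table1.csv", package = "helixdti")`.
#'
#' @param path CSV path with header columns `id`, `category`,
#'   `years_formalin`, `age`, `t1_mean`, `t1_sd`, `t2_mean`, `t2_sd`, `sex`,
#'   `vsd`, `pulmonary_valve`, `surgery`.
#' @return Data frame of class `chd_cohort`.
#' @export
load_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA", "–", "-"))
  if (nrow(tab) == 0) stop("empty cohort file")
  required <- c("id", "category", "years_formalin", "age", "vsd")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  vocab <- c("D-TGA", "L-TGA", "TOF", "uni. sys RV", "bi. sys RV", "SIT")
  bad <- setdiff(unique(tab$category), vocab)
  if (length(bad))
    stop("unknown CHD category: ", paste(bad, collapse = ", "))
  yrs <- suppressWarnings(as.numeric(tab$years_formalin))
  if (any(!is.finite(yrs)) || any(yrs <= 0))
    stop("years_formalin must be positive numbers")
  tab$years_formalin <- yrs
  tab$age <- suppressWarnings(as.numeric(tab$age))
  tab$vsd <- toupper(trimws(as.character(tab$vsd))) %in% "Y"
  class(tab) <- c("chd_cohort", "data.frame")
  tab
}

#' Summarize a specimen cohort
#'
#' Counts per CHD category and VSD status, and five-number summaries
#' (min, lower quartile, median, upper quartile, max) of years in formalin
#' and age at death. The median is midpoint-interpolated and quartiles use
#' the inclusive (Tukey hinge) method; missing ages are excluded.
#'
#' @param tab A `chd_cohort`.
#' @return List with `n`, `by_category`, `n_vsd`, `formalin_years`, `age`
#'   (each a named vector min/q1/median/q3/max), and `n_age_missing`.
#' @export
cohort_summary <- function(tab) {
  stopifnot(inherits(tab, "chd_cohort"), nrow(tab) >= 1)
  list(n = nrow(tab),
       by_category = table(tab$category),
       n_vsd = sum(tab$vsd),
       formalin_years = five_number(tab$years_formalin),
       age = five_number(tab$age[is.finite(tab$age)]),
       n_age_missing = sum(!is.finite(tab$age)))
}

## Tukey hinges: halves include the median when n is odd.
five_number <- function(x) {
  x <- sort(x)
  n <- length(x)
  lower <- x[seq_len(ceiling(n / 2))]
  upper <- x[seq.int(floor(n / 2) + 1, n)]
  c(min = x[1], q1 = stats::median(lower), median = stats::median(x),
    q3 = stats::median(upper), max = x[n])
}
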