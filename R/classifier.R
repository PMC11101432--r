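#' Classify a tumor into the LAR subtype or a TIL group
#'
#' The decision rule: AR Allred total >= 6 -> LAR; otherwise the stromal TIL
#' percentage splits the non-LAR cases into LP (TILs >= 60), LI
#' (20 <= TILs < 60) and LD (TILs < 20). Cut-offs are parameters so the rule
#' can be re-derived and compared, but the shipped defaults (6; 20 and 60)
#' are the operative classification.
#'
#' @param allred_total integer vector of Allred totals in 0--8.
#' @param til_percent numeric vector of stromal TIL percentages in \[0, 100\].
#' @param allred_cutoff LAR threshold on the Allred total (default 6).
#' @param til_cutoffs length-2 ascending TIL thresholds (default c(20, 60)).
#' @return character vector with levels `LAR`, `LP`, `LI`, `LD`.
#' @examples
#' classify_subtype(6, 0)    # LAR
#' classify_subtype(5, 60)   # LP
#' classify_subtype(0, 10)   # LD
#' @export
classify_subtype <- function(allred_total, til_percent,
                             allred_cutoff = 6, til_cutoffs = c(20, 60)) {
  stopifnot(length(til_cutoffs) == 2L, til_cutoffs[1] < til_cutoffs[2])
  stop_if_not_in_range(allred_total, 0, 8, "allred_total")
  stop_if_not_in_range(til_percent, 0, 100, "til_percent")
  n <- max(length(allred_total), length(til_percent))
  allred_total <- rep_len(allred_total, n)
  til_percent <- rep_len(til_percent, n)
  out <- rep(NA_character_, n)
  lar <- allred_total >= allred_cutoff
  out[lar] <- "LAR"
  out[!lar & til_percent >= til_cutoffs[2]] <- "LP"
  out[!lar & til_percent >= til_cutoffs[1] & til_percent < til_cutoffs[2]] <- "LI"
  out[!lar & til_percent < til_cutoffs[1]] <- "LD"
  out
}

#' Classify a case table
#'
#' Scores each case (if not already scored) and applies the subtype rule.
#' Rows with missing AR or TIL values are excluded from the output and
#' reported in the `exclusions` attribute, mirroring how cases failing TIL
#' or IHC evaluation are dropped from the analysis set.
#'
#' @param cases data.frame of case records (see [generate_cohort()] for the
#'   column dictionary).
#' @inheritParams classify_subtype
#' @return the scored table with a `classified` column; excluded rows are
#'   recorded in `attr(, "exclusions")` (case_id + reason).
#' @export
classify_table <- function(cases, allred_cutoff = 6, til_cutoffs = c(20, 60)) {
  stopifnot(is.data.frame(cases))
  if (nrow(cases) == 0L) {
    cases$classified <- character(0)
    attr(cases, "exclusions") <- data.frame(case_id = character(0),
                                            reason = character(0))
    return(cases)
  }
  if (!"allred_total" %in% names(cases)) cases <- score_cases(cases)
  miss <- is.na(cases$allred_total) | is.na(cases$til_percent)
  exclusions <- data.frame(
    case_id = if ("case_id" %in% names(cases)) {
      as.character(cases$case_id[miss])
    } else as.character(which(miss)),
    reason = ifelse(is.na(cases$allred_total[miss]),
                    "missing AR reading", "missing TIL score"),
    stringsAsFactors = FALSE
  )
  if (any(miss)) {
    message(sum(miss), " case(s) excluded for missing AR/TIL values")
  }
  kept <- cases[!miss, , drop = FALSE]
  kept$classified <- classify_subtype(kept$allred_total, kept$til_percent,
                                      allred_cutoff, til_cutoffs)
  attr(kept, "exclusions") <- exclusions
  kept
}
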