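#' Allred proportion score for AR immunohistochemistry
#'
#' Bins the percentage of AR-positive tumor nuclei into the 0--5 Allred
#' proportion score. The printed bin anchors (0%; <=1%; 1--10%; 11--33%;
#' 34--66%; >=67%) leave non-integer values between bins unassigned, so the
#' bins are taken half-open on the right: 0 -> 0, (0,1] -> 1, (1,10] -> 2,
#' (10,33] -> 3, (33,66] -> 4, (66,100] -> 5. This covers the whole
#' continuum and is consistent with the "<= 1%" and ">= 67%" anchors.
#'
#' @param ar_percent numeric vector of positive-nucleus percentages in
#'   \[0, 100\].
#' @return integer vector of proportion scores in 0--5.
#' @examples
#' allred_proportion_score(c(0, 1, 10, 33, 66, 67, 100))
#' @export
allred_proportion_score <- function(ar_percent) {
  stopifnot(is.numeric(ar_percent))
  stop_if_not_in_range(ar_percent, 0, 100, "ar_percent")
  breaks <- c(-Inf, 0, 1, 10, 33, 66, 100)
  # cut with right-closed intervals: (-Inf,0]=0, (0,1]=1, ..., (66,100]=5
  score <- cut(ar_percent, breaks = breaks, labels = FALSE, right = TRUE) - 1L
  as.integer(score)
}

#' Allred intensity score for AR immunohistochemistry
#'
#' Maps the nuclear staining intensity to 0--3 points: negative -> 0,
#' weak -> 1, intermediate -> 2, strong -> 3.
#'
#' @param level character vector of intensity levels
#'   (`"negative"`, `"weak"`, `"intermediate"`, `"strong"`).
#' @return integer vector of intensity scores in 0--3.
#' @export
allred_intensity_score <- function(level) {
  level <- as.character(level)
  idx <- match(level, INTENSITY_LEVELS)
  bad <- !is.na(level) & is.na(idx)
  if (any(bad)) {
    stop("unknown intensity level(s): ",
         paste(unique(level[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(idx - 1L)
}

#' Total Allred score
#'
#' Sum of the proportion score (0--5) and intensity score (0--3); the total
#' ranges from 0 to 8 points.
#'
#' @inheritParams allred_proportion_score
#' @inheritParams allred_intensity_score
#' @return a data.frame with columns `proportion_score`, `intensity_score`
#'   and `total`.
#' @examples
#' allred_score(100, "strong")  # total 8
#' allred_score(0, "negative")  # total 0
#' @export
allred_score <- function(ar_percent, level) {
  ps <- allred_proportion_score(ar_percent)
  is <- allred_intensity_score(level)
  data.frame(proportion_score = ps, intensity_score = is, total = ps + is)
}

#' Stromal TIL range assignment
#'
#' Bins the stromal tumor-infiltrating lymphocyte percentage into the three
#' ranges used by the non-LAR subtype split: `LP_range` for TILs >= 60%,
#' `LI_range` for 20% <= TILs < 60%, and `LD_range` for TILs < 20%. The
#' boundary values 20 and 60 belong to the upper group (LI and LP
#' respectively).
#'
#' @param til_percent numeric vector of stromal TIL percentages in \[0, 100\].
#' @return character vector in `{"LP_range", "LI_range", "LD_range"}`.
#' @export
til_group <- function(til_percent) {
  stopifnot(is.numeric(til_percent))
  stop_if_not_in_range(til_percent, 0, 100, "til_percent")
  out <- rep(NA_character_, length(til_percent))
  out[til_percent >= 60] <- "LP_range"
  out[til_percent >= 20 & til_percent < 60] <- "LI_range"
  out[til_percent < 20] <- "LD_range"
  out
}

#' Score a case table
#'
#' Vectorized application of the Allred and TIL scoring over a case table;
#' appends `allred_proportion`, `allred_intensity_score`, `allred_total` and
#' `til_range` columns.
#'
#' @param cases data.frame with columns `ar_percent`, `ar_intensity`,
#'   `til_percent`.
#' @return the input with the four scoring columns appended.
#' @export
score_cases <- function(cases) {
  stopifnot(is.data.frame(cases),
            all(c("ar_percent", "ar_intensity", "til_percent") %in%
                  names(cases)))
  sc <- allred_score(cases$ar_percent, cases$ar_intensity)
  cases$allred_proportion <- sc$proportion_score
  cases$allred_intensity_score <- sc$intensity_score
  cases$allred_total <- sc$total
  cases$til_range <- til_group(cases$til_percent)
  cases
}
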