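#' @keywords internal
"_PACKAGE"

## Label spaces used throughout the package.

#' Subtype and scoring label constants
#'
#' Fixed label spaces: the four histopathology-derived subtypes
#' (`SUBTYPE_LEVELS`), the five molecular subclassification labels including
#' the unclassified group (`MOLECULAR_LEVELS`), the AR staining intensity
#' levels (`INTENSITY_LEVELS`) and the classified-to-molecular correspondence
#' used by all agreement metrics (`SUBTYPE_CORRESPONDENCE`).
#'
#' The correspondence is LAR<->LAR, LP<->IM, LI<->BL1, LD<->M: the
#' lymphocyte-predominant group is matched to the immunomodulatory molecular
#' subtype, the intermediate group to basal-like 1, and the depleted group to
#' mesenchymal.
#'
#' @name label-constants
#' @keywords internal
NULL

SUBTYPE_LEVELS <- c("LAR", "LP", "LI", "LD")
MOLECULAR_LEVELS <- c("LAR", "IM", "BL1", "M", "UNC")
MOLECULAR_CORE <- c("LAR", "IM", "BL1", "M")
INTENSITY_LEVELS <- c("negative", "weak", "intermediate", "strong")
P16_LEVELS <- c("negative", "weak_mosaic", "diffuse_strong")

## classified label -> corresponding molecular truth label
SUBTYPE_CORRESPONDENCE <- c(LAR = "LAR", LP = "IM", LI = "BL1", LD = "M")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_in_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(sprintf("%s out of range [%g, %g]: %s", what, lo, hi,
                 paste(utils::head(x[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
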