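#' Valid EDSS score levels
#'
#' The Expanded Disability Status Scale (EDSS) is an ordinal scale from 0 to
#' 10 in half-point steps. The step from 0 goes directly to 1.0: the standard
#' scale has no 0.5 level, so the strict level set is
#' \{0, 1.0, 1.5, ..., 9.5, 10\}. Registries occasionally contain 0.5 entries;
#' the permissive level set accepts any multiple of 0.5 in \[0, 10\].
#'
#' @param strict Logical; if `TRUE` (default) exclude 0.5.
#' @return Numeric vector of valid EDSS levels, ascending.
#' @export
#' @examples
#' edss_levels()
#' setdiff(edss_levels(strict = FALSE), edss_levels())
edss_levels <- function(strict = TRUE) {
  lv <- seq(0, 10, by = 0.5)
  if (strict) lv <- lv[lv != 0.5]
  lv
}

#' Check EDSS validity
#'
#' @param x Numeric vector of candidate scores.
#' @param strict Logical; if `TRUE`, 0.5 is invalid.
#' @return Logical vector, `TRUE` where the score is on the valid grid.
#' @export
is_valid_edss <- function(x, strict = TRUE) {
  !is.na(x) & x >= 0 & x <= 10 & (x * 2) == round(x * 2) & (!strict | x != 0.5)
}

#' Minimal required EDSS increase for a worsening candidate
#'
#' The required magnitude of worsening depends on the reference score:
#' at least 1.5 points from a reference of 0, at least 1.0 point from a
#' reference below 5.5, and at least 0.5 points from a reference of 5.5 or
#' above. This reference-dependent rule reflects the non-linear granularity
#' of the EDSS at its upper end.
#'
#' @param reference Numeric vector of reference EDSS scores.
#' @return Numeric vector of minimal required increases (EDSS points).
#' @export
#' @examples
#' minimal_required_increase(c(0, 3, 6))
minimal_required_increase <- function(reference) {
  ok <- is_valid_edss(reference, strict = FALSE)
  if (any(!ok)) {
    stop("invalid reference EDSS value(s): ",
         paste(reference[!ok], collapse = ", "))
  }
  ifelse(reference == 0, 1.5, ifelse(reference < 5.5, 1.0, 0.5))
}

# Snap arbitrary numeric values to the valid EDSS grid (strict set).
# 0.5 is not on the strict grid; values landing there are taken down to 0
# (conservative: no disability conjured by rounding).
snap_edss <- function(x) {
  x <- pmin(10, pmax(0, x))
  x <- round(x * 2) / 2
  x[x == 0.5] <- 0
  x
}
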