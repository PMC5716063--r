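# Structural complexity: summarizing the substrate-height-bin encoding
# (recorded from 2012 onwards) and bridging it to the earlier ordinal scale
# via a linear conversion.

#' Default midpoints of the substrate-height bins
#'
#' The divers estimate the percentage of the cylinder in relief bins
#' <0.20, 0.20--0.50, 0.50--1, 1--1.5 and >1.5 m. The open top bin has no
#' printed representative height; its midpoint of 1.75 m assumes an
#' effective 1.5--2 m span and is configurable.
#'
#' @return Numeric vector of five bin midpoints in meters.
#' @export
height_bin_midpoints <- function() c(0.10, 0.35, 0.75, 1.25, 1.75)

#' Mean substrate height from a height-bin vector
#'
#' The percentage-weighted mean of the bin midpoints:
#' `sum(fraction * midpoint)`.
#'
#' @param heights Numeric vector of five percentages (bins in increasing
#'   height order), or a 5-column matrix/data frame of such vectors.
#' @param midpoints_m Bin midpoints in meters (default
#'   [height_bin_midpoints()]).
#' @param strict When `TRUE` (default) a vector not summing to 100 +/- 0.5 is
#'   an error; when `FALSE` it yields `NA` (used when summarizing records
#'   whose height fields may be absent).
#' @return Mean height(s) in meters.
#' @export
mean_substrate_height <- function(heights,
                                  midpoints_m = height_bin_midpoints(),
                                  strict = TRUE) {
  if (is.data.frame(heights)) heights <- as.matrix(heights)
  if (!is.matrix(heights)) heights <- matrix(heights, nrow = 1)
  if (ncol(heights) != 5) stop("expected five height-bin percentages")
  stopifnot(length(midpoints_m) == 5)
  tot <- rowSums(heights)
  bad_range <- apply(heights, 1, function(h)
    any(!is.na(h) & (h < 0 | h > 100)))
  bad <- !is.na(tot) & (abs(tot - 100) > 0.5 | bad_range)
  if (strict && any(bad)) {
    stop("height-bin percentages must lie in [0,100] and sum to 100 +/- 0.5")
  }
  out <- as.numeric(heights %*% midpoints_m) / 100
  out[is.na(tot) | bad] <- NA_real_
  out
}

#' Fit a conversion between the ordinal complexity score and mean height
#'
#' The complexity protocol changed from an ordinal visual score (surveys up
#' to 2011) to the height-bin encoding (2012 onwards); a linear regression on
#' co-scored observations gives a standard conversion between the two.
#' Calibration pairs must be supplied externally. Both regression directions
#' are available since the published convention does not fix one.
#'
#' @param score Ordinal complexity scores.
#' @param height_m Mean substrate heights (m) for the same observations.
#' @param direction `"height_on_score"` (default) regresses height on score;
#'   `"score_on_height"` the reverse.
#' @return List with `slope`, `intercept`, `r_squared`, `direction`, `n`,
#'   and the underlying `lm` fit.
#' @export
fit_complexity_conversion <- function(score, height_m,
    direction = c("height_on_score", "score_on_height")) {
  direction <- match.arg(direction)
  ok <- !is.na(score) & !is.na(height_m)
  score <- score[ok]; height_m <- height_m[ok]
  x <- if (direction == "height_on_score") score else height_m
  y <- if (direction == "height_on_score") height_m else score
  if (length(x) < 3) stop("need at least 3 calibration pairs")
  if (length(unique(x)) < 2) {
    stop("degenerate design: need at least 2 distinct predictor values")
  }
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       direction = direction, n = length(x), fit = fit)
}

#' Write conversion coefficients as JSON
#'
#' @param conv Result of [fit_complexity_conversion()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conversion_json <- function(conv, path) {
  writeLines(jsonlite::toJSON(
    conv[c("slope", "intercept", "r_squared", "direction", "n")],
    auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}
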