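# Count and length observations -> abundance and biomass densities per
# cylinder, via the allometric weight model W = a (cL)^b.

#' Survey cylinder geometry
#'
#' The SPC plot is a visually estimated cylinder of fixed diameter laid out
#' along a transect line; a pair of divers survey adjacent cylinders centred
#' at the quarter marks of the line. The protocol specifies only the 15 m
#' diameter; the survey area is its disc, `pi * (diameter/2)^2`.
#'
#' @param diameter_m Cylinder diameter in meters (default 15).
#' @param transect_length_m Transect line length in meters (default 30).
#' @return List of class `cylinder_geometry` with `diameter_m`, `radius_m`,
#'   `area_m2`, `transect_length_m`, `centre_marks_m`.
#' @export
cylinder_geometry <- function(diameter_m = 15, transect_length_m = 30) {
  stopifnot(diameter_m > 0, transect_length_m >= diameter_m)
  r <- diameter_m / 2
  structure(list(
    diameter_m = diameter_m,
    radius_m = r,
    area_m2 = pi * r^2,
    transect_length_m = transect_length_m,
    centre_marks_m = c(r, transect_length_m - r)
  ), class = "cylinder_geometry")
}

#' Individual fish weight from estimated length
#'
#' Allometric length-weight model `W = a (c L)^b`, with `W` in grams and `L`
#' the estimated total length in centimeters. The length-conversion factor
#' `c` rescales total length to the length form (fork or standard length) the
#' `a`, `b` constants were fitted in, and is applied to `L` before
#' exponentiation. Lengths exceeding the species' recorded maximum length are
#' converted anyway but flagged.
#'
#' @param length_cm Positive numeric vector of total lengths (cm).
#' @param lw_a,lw_b Allometric constants (`a > 0`, `b` typically near 3).
#' @param length_conversion_factor Positive scale factor `c` (default 1).
#' @param lmax Optional species maximum length (cm) used for the flag.
#' @param warn_lmax Emit a warning when any length exceeds `lmax`.
#' @return Numeric vector of weights in grams, with attribute
#'   `exceeds_lmax` (logical vector) when `lmax` is supplied.
#' @export
fish_weight_g <- function(length_cm, lw_a, lw_b,
                          length_conversion_factor = 1,
                          lmax = NULL, warn_lmax = TRUE) {
  if (any(is.na(length_cm)) || any(length_cm <= 0)) {
    stop("length_cm must be positive")
  }
  if (any(is.na(lw_a) | lw_a <= 0)) stop("lw_a must be positive")
  if (any(is.na(lw_b) | lw_b <= 0)) stop("lw_b must be positive")
  cf <- ifelse(is.na(length_conversion_factor), 1, length_conversion_factor)
  if (any(cf <= 0)) stop("length_conversion_factor must be positive")
  w <- lw_a * (cf * length_cm)^lw_b
  if (!is.null(lmax)) {
    flag <- !is.na(lmax) & length_cm > lmax
    if (warn_lmax && any(flag)) {
      warning("size exceeds LMAX for ", sum(flag), " observation(s)")
    }
    attr(w, "exceeds_lmax") <- flag
  }
  w
}

#' Filter observations by observation type
#'
#' Routine density reporting pools the instantaneous (`I`) and
#' non-instantaneous (`N`) types; the time-integrated types `F` and `T` can
#' be added for questions about rarer or more mobile species. `P` records are
#' presence-only and may never enter a density computation.
#'
#' @param records Observation data frame with an `obs_type` column.
#' @param include Subset of [obs_type_codes()] to retain (default `c("I","N")`).
#' @param target `"density"` (default; rejects `P` in `include`) or
#'   `"presence"`.
#' @return The retained rows.
#' @export
filter_observations <- function(records, include = c("I", "N"),
                                target = c("density", "presence")) {
  target <- match.arg(target)
  if (!length(include)) stop("observation-type filter must be non-empty")
  bad <- setdiff(include, obs_type_codes())
  if (length(bad)) stop("unknown observation type(s): ",
                        paste(bad, collapse = ", "))
  if (target == "density" && "P" %in% include) {
    stop("presence-only type in density filter")
  }
  records[!is.na(records$obs_type) & records$obs_type %in% include, ,
          drop = FALSE]
}

#' Per-species densities for one cylinder
#'
#' Converts the retained observations of a single cylinder (replicate) into
#' per-species abundance (fish m^-2) and biomass (g m^-2) densities:
#' `sum(count) / area` and `sum(count * W(size)) / area`.
#'
#' @param records Observations of one `replicateid`.
#' @param geometry A [cylinder_geometry()].
#' @param include Observation-type filter passed to [filter_observations()].
#' @return Data frame with `replicateid`, `species`, `abundance_m2`,
#'   `biomass_g_m2`.
#' @export
cylinder_densities <- function(records, geometry = cylinder_geometry(),
                               include = c("I", "N")) {
  if (!nrow(records)) {
    return(data.frame(replicateid = integer(), species = character(),
                      abundance_m2 = numeric(), biomass_g_m2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (length(unique(records$replicateid)) > 1L) {
    stop("records span more than one replicateid")
  }
  x <- filter_observations(records, include)
  if (!nrow(x)) {
    return(data.frame(replicateid = integer(), species = character(),
                      abundance_m2 = numeric(), biomass_g_m2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  no_trait <- unique(x$species[is.na(x$lw_a) | is.na(x$lw_b)])
  if (length(no_trait)) {
    stop("missing length-weight constants for species: ",
         paste(no_trait, collapse = ", "))
  }
  w <- fish_weight_g(x$size_tl_cm, x$lw_a, x$lw_b,
                     x$length_conversion_factor, warn_lmax = FALSE)
  a <- geometry$area_m2
  ab <- tapply(x$count, x$species, sum) / a
  bm <- tapply(x$count * w, x$species, sum) / a
  data.frame(replicateid = records$replicateid[1],
             species = names(ab),
             abundance_m2 = as.numeric(ab),
             biomass_g_m2 = as.numeric(bm),
             row.names = NULL, stringsAsFactors = FALSE)
}
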