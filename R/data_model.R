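# Observation-level schema for the SPC survey CSV dialect: column dictionary,
# reader/writer, record validation, and the small classifiers (depth bins,
# DACOR urchin abundance, pooled reporting units) used throughout.

# Column dictionary: published header name, storage type, whether the column
# is mandatory for any downstream processing.
.spc_column_dict <- function() {
  d <- rbind(
    c("REGION", "character", FALSE),
    c("ISLAND", "character", FALSE),
    c("SITE", "character", FALSE),
    c("LATITUDE", "numeric", FALSE),
    c("LONGITUDE", "numeric", FALSE),
    c("REEF_ZONE", "character", FALSE),
    c("DEPTH_BIN", "character", FALSE),
    c("SITEVISITID", "integer", TRUE),
    c("DATE", "character", FALSE),
    c("OBS_YEAR", "integer", FALSE),
    c("DIVER", "integer", TRUE),
    c("REPLICATEID", "integer", TRUE),
    c("REP", "character", FALSE),
    c("DEPTH_M", "numeric", FALSE),
    c("HARD_CORAL", "numeric", FALSE),
    c("MA", "numeric", FALSE),
    c("CCA", "numeric", FALSE),
    c("SAND", "numeric", FALSE),
    c("OTHER", "numeric", FALSE),
    c("HABITAT_CODE", "character", FALSE),
    c("CURRENT_STRENGTH", "character", FALSE),
    c("VISIBILITY_M", "numeric", FALSE),
    c("MIN_DEPTH_M", "numeric", FALSE),
    c("MAX_DEPTH_M", "numeric", FALSE),
    c("COMPLEXITY", "integer", FALSE),
    c("SUBSTRATE_HEIGHT_0", "numeric", FALSE),
    c("SUBSTRATE_HEIGHT_20", "numeric", FALSE),
    c("SUBSTRATE_HEIGHT_50", "numeric", FALSE),
    c("SUBSTRATE_HEIGHT_100", "numeric", FALSE),
    c("SUBSTRATE_HEIGHT_150", "numeric", FALSE),
    c("MAX_HEIGHT", "numeric", FALSE),
    c("URCHIN_DACOR", "character", FALSE),
    c("BORING_URCHIN_DACOR", "character", FALSE),
    c("SPECIES", "character", TRUE),
    c("TAXONNAME", "character", FALSE),
    c("COMMON_FAMILY", "character", FALSE),
    c("FAMILY", "character", FALSE),
    c("CONSUMER_GROUP", "character", FALSE),
    c("LW_A", "numeric", FALSE),
    c("LW_B", "numeric", FALSE),
    c("LMAX", "numeric", FALSE),
    c("LENGTH_CONVERSION_FACTOR", "numeric", FALSE),
    c("COUNT", "integer", TRUE),
    c("SIZE_TL_CM", "numeric", TRUE),
    c("OBS_TYPE", "character", TRUE)
  )
  data.frame(name = d[, 1], type = d[, 2],
             mandatory = as.logical(d[, 3]), stringsAsFactors = FALSE)
}

#' Valid observation-type codes
#'
#' `I` instantaneous, `N` non-instantaneous, `F` first seen 5--10 min into the
#' survey, `T` first seen 10--30 min in, `P` present in the vicinity of the
#' cylinder (presence only, never a density datum).
#'
#' @return Character vector of the five valid codes.
#' @export
obs_type_codes <- function() c("I", "N", "F", "T", "P")

#' Habitat codes accepted in the HABITAT_CODE field
#' @return Character vector of recognised habitat type codes.
#' @export
habitat_codes <- function() {
  c("AGR", "APR", "APS", "MIX", "PAV", "PPR", "PSC",
    "ROB", "RRB", "SAG", "SCR", "UNK", "WAL")
}

#' Read an SPC observation file
#'
#' Reads the published comma-separated observation dialect (one row = one
#' size/count observation of one taxon by one diver in one cylinder). Header
#' names are matched case-insensitively against the published column set;
#' columns outside that set are kept but reported with a warning. Empty cells
#' become `NA`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with lower-case canonical column names and columns
#'   coerced to their schema types.
#' @export
read_spc_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = c("", "NA"), stringsAsFactors = FALSE)
  dict <- .spc_column_dict()
  hdr <- toupper(names(raw))
  names(raw) <- hdr
  missing <- setdiff(dict$name[dict$mandatory], hdr)
  if (length(missing)) {
    stop("mandatory column(s) missing: ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(hdr, dict$name)
  if (length(unknown)) {
    warning("unknown column(s) retained: ", paste(unknown, collapse = ", "))
  }
  out <- raw
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (!nm %in% names(out)) next
    out[[nm]] <- switch(dict$type[i],
      numeric = suppressWarnings(as.numeric(out[[nm]])),
      integer = suppressWarnings(as.integer(out[[nm]])),
      out[[nm]])
  }
  names(out) <- tolower(names(out))
  out
}

#' Write observations in the published CSV dialect
#'
#' Inverse of [read_spc_csv()]: canonical lower-case columns are written under
#' the published upper-case header names, in dictionary order, with `NA` as
#' the empty string and dates as ISO-8601 text.
#'
#' @param x Data frame of observation records (lower-case canonical names).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spc_csv <- function(x, path) {
  dict <- .spc_column_dict()
  known <- dict$name[tolower(dict$name) %in% names(x)]
  extra <- setdiff(names(x), tolower(dict$name))
  out <- x[, c(tolower(known), extra), drop = FALSE]
  names(out) <- c(known, toupper(extra))
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Classify a survey depth into the shallow/mid/deep stratification
#'
#' Bins are lower-closed and upper-open — `[0, 6)` shallow, `[6, 18)` mid —
#' except the deepest, `[18, 30]`, which is closed at the 30 m safe-diving
#' limit of the survey domain.
#'
#' @param depth_m Numeric vector of depths in meters, each in `(0, 30]`.
#' @return Character vector of `"shallow"`, `"mid"`, `"deep"` (`NA` in, `NA`
#'   out).
#' @export
classify_depth_bin <- function(depth_m) {
  bad <- !is.na(depth_m) & (depth_m <= 0 | depth_m > 30)
  if (any(bad)) {
    stop("depth out of survey domain (0, 30]: ",
         paste(utils::head(depth_m[bad], 5), collapse = ", "))
  }
  out <- rep(NA_character_, length(depth_m))
  ok <- !is.na(depth_m)
  out[ok & depth_m < 6] <- "shallow"
  out[ok & depth_m >= 6 & depth_m < 18] <- "mid"
  out[ok & depth_m >= 18] <- "deep"
  out
}

#' Classify an urchin count on the DACOR scale
#'
#' Semi-quantitative abundance bands for free urchins (R <=5, O 6--20,
#' C 21--50, A 51--100, D >100) and boring urchins (R <=25, O 26--100,
#' C 101--250, A 251--500, D >500). The published bands leave one integer
#' unassigned in each scale (5 free, 25 boring); both are assigned to the
#' rarer class R so the scale covers every non-negative count.
#'
#' @param count Non-negative integer vector of urchin counts.
#' @param category `"free"` or `"boring"`.
#' @return Character vector of codes `D`, `A`, `C`, `O`, `R`.
#' @export
classify_dacor <- function(count, category = c("free", "boring")) {
  category <- match.arg(category)
  if (any(!is.na(count) & (count < 0 | count != floor(count)))) {
    stop("count must be a non-negative integer")
  }
  breaks <- if (category == "free") c(-Inf, 5, 20, 50, 100, Inf)
            else c(-Inf, 25, 100, 250, 500, Inf)
  as.character(cut(count, breaks = breaks,
                   labels = c("R", "O", "C", "A", "D")))
}

#' Expand pooled reporting units into their member islands
#'
#' Small neighbouring islands surveyed as one statistical unit (by default the
#' AGS group: Alamagan, Guguan, Sarigan) are replaced by their members; all
#' other names pass through unchanged, preserving order.
#'
#' @param units Character vector of reporting-unit names.
#' @param pooled Named list mapping a pooled unit name to its member islands.
#' @return Character vector of island names.
#' @export
expand_reporting_units <- function(units,
    pooled = list(AGS = c("Alamagan", "Guguan", "Sarigan"))) {
  out <- lapply(units, function(u) {
    if (!is.na(u) && u %in% names(pooled)) pooled[[u]] else u
  })
  unlist(out, use.names = FALSE)
}

#' Read a hard-bottom area table
#'
#' Long-format CSV with columns `reporting_unit`, `reef_zone`, optionally
#' `depth_bin`, and `area_ha` (hectares of hard-bottom substrate shallower
#' than 30 m). These areas define the stratum weights of the design.
#'
#' @param path CSV path.
#' @return Data frame of stratum areas.
#' @export
read_area_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  need <- c("reporting_unit", "reef_zone", "area_ha")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("area table missing column(s): ",
                         paste(miss, collapse = ", "))
  x$area_ha <- as.numeric(x$area_ha)
  if (any(is.na(x$area_ha)) || any(x$area_ha < 0)) {
    stop("area_ha must be non-negative numbers")
  }
  pos <- tapply(x$area_ha, x$reporting_unit, function(a) any(a > 0))
  if (any(!pos)) {
    stop("reporting unit(s) with no positive area: ",
         paste(names(pos)[!pos], collapse = ", "))
  }
  x
}

#' Hard-bottom areas for the Pacific monitoring domain
#'
#' The shipped island-by-reef-zone table of hard-bottom area (<30 m, ha) for
#' the 37 reporting units (39 islands once the pooled AGS unit is expanded).
#' Zone `"Other"` collects hard-bottom types that are not surveyed (e.g.
#' channels).
#'
#' @return Data frame with columns `region`, `reporting_unit`, `reef_zone`,
#'   `area_ha`.
#' @export
pacific_area_table <- function() {
  read_area_table(system.file("extdata", "hardbottom_area_pacific.csv",
                              package = "reefspc", mustWork = TRUE))
}

# -- validation ---------------------------------------------------------------

.issue <- function(rows, rule, severity, message) {
  if (!length(rows)) return(NULL)
  data.frame(row = rows, rule = rule, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

#' Validate SPC observation records
#'
#' Applies the protocol's record-level rules: observation-type codes, positive
#' counts and sizes, the survey depth domain and the 1.5 m centre-depth floor,
#' the 7.5 m horizontal-visibility floor (surveys are not conducted below it)
#' and the 30 m visibility cap, percent-cover and substrate-height closure to
#' 100 +/- 0.5, and the restriction of `F`/`T` observation types to surveys
#' from 2012 onwards. A recorded depth-bin label that disagrees with
#' [classify_depth_bin()] of the recorded depth is a warning; all other
#' failures are errors, and a record with any error is excluded from analysis
#' sets.
#'
#' @param records Data frame from [read_spc_csv()].
#' @return An object of class `spc_validation`: list with `issues` (data frame
#'   of row, rule, severity, message), `counts` (issues per rule), `n_records`,
#'   and `error_rows` (row indices carrying at least one error).
#' @export
validate_spc <- function(records) {
  n <- nrow(records)
  g <- function(nm) if (nm %in% names(records)) records[[nm]] else rep(NA, n)
  iss <- list()

  ot <- g("obs_type")
  iss$ot_missing <- .issue(which(is.na(ot)), "obs_type_missing", "error",
                           "missing observation type")
  iss$ot <- .issue(which(!is.na(ot) & !ot %in% obs_type_codes()),
                   "obs_type_code", "error",
                   "observation type not one of I,N,F,T,P")

  cnt <- g("count")
  iss$cnt <- .issue(which(is.na(cnt) | cnt < 1), "count_positive", "error",
                    "count must be a positive integer")

  sz <- g("size_tl_cm")
  iss$sz <- .issue(which(is.na(sz) | sz <= 0), "size_positive", "error",
                   "size must be a positive length in cm")

  dep <- g("depth_m")
  iss$dep_dom <- .issue(which(!is.na(dep) & dep > 30), "depth_range", "error",
                        "depth beyond the 30 m survey domain")
  iss$dep_floor <- .issue(which(!is.na(dep) & dep < 1.5), "depth_floor",
                          "error",
                          "cylinder centre depth below the 1.5 m survey floor")

  vis <- g("visibility_m")
  iss$vis_floor <- .issue(which(!is.na(vis) & vis < 7.5), "visibility_floor",
                          "error", "below visibility floor (7.5 m)")
  iss$vis_cap <- .issue(which(!is.na(vis) & (vis <= 0 | vis > 30)),
                        "visibility_range", "error",
                        "visibility outside (0, 30] m")

  cov <- cbind(g("hard_coral"), g("ma"), g("cca"), g("sand"), g("other"))
  full <- which(complete.cases(cov))
  bad <- full[abs(rowSums(cov[full, , drop = FALSE]) - 100) > 0.5]
  iss$cov <- .issue(bad, "benthic_cover_sum", "error",
                    "benthic cover percentages do not sum to 100 +/- 0.5")

  sh <- cbind(g("substrate_height_0"), g("substrate_height_20"),
              g("substrate_height_50"), g("substrate_height_100"),
              g("substrate_height_150"))
  full <- which(complete.cases(sh))
  bad <- full[abs(rowSums(sh[full, , drop = FALSE]) - 100) > 0.5]
  iss$sh <- .issue(bad, "substrate_height_sum", "error",
                   "substrate height percentages do not sum to 100 +/- 0.5")

  yr <- g("obs_year")
  iss$ft <- .issue(which(!is.na(ot) & ot %in% c("F", "T") &
                           !is.na(yr) & yr < 2012),
                   "obs_type_year", "error",
                   "F/T observation types only recorded from 2012 onwards")

  db <- g("depth_bin")
  ok_dep <- !is.na(dep) & dep > 0 & dep <= 30
  expect <- rep(NA_character_, n)
  expect[ok_dep] <- classify_depth_bin(dep[ok_dep])
  iss$db <- .issue(which(!is.na(db) & !is.na(expect) &
                           tolower(db) != expect),
                   "depth_bin_label", "warning",
                   "recorded depth bin disagrees with classified depth")

  issues <- do.call(rbind, iss[!vapply(iss, is.null, logical(1))])
  if (is.null(issues)) {
    issues <- data.frame(row = integer(), rule = character(),
                         severity = character(), message = character(),
                         stringsAsFactors = FALSE)
  }
  issues <- issues[order(issues$row, issues$rule), , drop = FALSE]
  rownames(issues) <- NULL
  structure(list(
    issues = issues,
    counts = table(issues$rule),
    n_records = n,
    error_rows = sort(unique(issues$row[issues$severity == "error"]))
  ), class = "spc_validation")
}

#' @export
print.spc_validation <- function(x, ...) {
  cat("SPC validation report:", x$n_records, "records,",
      nrow(x$issues), "issues,",
      length(x$error_rows), "records with errors\n")
  if (nrow(x$issues)) {
    tab <- aggregate(row ~ rule + severity, data = x$issues, FUN = length)
    names(tab)[3] <- "n"
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report An `spc_validation` object.
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
validation_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "spc_validation"))
  j <- jsonlite::toJSON(list(
    n_records = report$n_records,
    n_issues = nrow(report$issues),
    n_error_records = length(report$error_rows),
    counts = as.list(report$counts),
    issues = report$issues
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Drop records carrying validation errors
#'
#' @param records Data frame of observation records.
#' @param report Matching `spc_validation` report (recomputed when omitted).
#' @return The records with error-carrying rows removed.
#' @export
valid_records <- function(records, report = validate_spc(records)) {
  if (length(report$error_rows)) records[-report$error_rows, , drop = FALSE]
  else records
}
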