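# Collapse diver/cylinder replicates into the site-level sample unit.
# Adjacent cylinders surveyed simultaneously are not independent, so the
# survey (site visit) is always the combination of its cylinders: metrics are
# averaged within each SPC-pair and then between pairs.

.consumer_groups <- c("Primary Consumer", "Secondary Consumer",
                      "Planktivore", "Piscivore")

.metric_cols <- c("abundance_m2", "biomass_g_m2",
                  "biomass_primary_g_m2", "biomass_secondary_g_m2",
                  "biomass_planktivore_g_m2", "biomass_piscivore_g_m2",
                  "biomass_unknown_g_m2", "richness",
                  "hard_coral", "ma", "cca", "sand", "other",
                  "mean_height_m", "depth_m")

.group_col <- function(g) {
  switch(g,
         "Primary Consumer" = "biomass_primary_g_m2",
         "Secondary Consumer" = "biomass_secondary_g_m2",
         "Planktivore" = "biomass_planktivore_g_m2",
         "Piscivore" = "biomass_piscivore_g_m2",
         "biomass_unknown_g_m2")
}

#' Per-cylinder metric summaries
#'
#' One row per replicate (cylinder): total and per-consumer-group biomass
#' density, total abundance density, species richness under the observation
#' filter, the replicate's benthic cover and substrate-height fields, and its
#' depth. Replicates whose every observation is filtered out keep a row with
#' zero densities and richness. Observations whose consumer group is missing
#' or unrecognised are assigned to `"unknown"` with a warning.
#'
#' @param records Validated observation data frame (any number of replicates).
#' @param geometry A [cylinder_geometry()].
#' @param include Observation-type filter (see [filter_observations()]).
#' @return Data frame, one row per `replicateid`, with identification columns
#'   (`sitevisitid`, `site`, `region`, `island`, `reef_zone`, `depth_bin`,
#'   `rep`, `diver`) and the metric columns.
#' @export
replicate_summaries <- function(records, geometry = cylinder_geometry(),
                                include = c("I", "N")) {
  if (!nrow(records)) stop("no observation records")
  first <- !duplicated(records$replicateid)
  meta_cols <- intersect(
    c("sitevisitid", "site", "region", "island", "reef_zone", "depth_bin",
      "rep", "diver", "depth_m", "hard_coral", "ma", "cca", "sand", "other",
      "substrate_height_0", "substrate_height_20", "substrate_height_50",
      "substrate_height_100", "substrate_height_150"),
    names(records))
  meta <- records[first, c("replicateid", meta_cols), drop = FALSE]
  rownames(meta) <- NULL
  m <- nrow(meta)

  x <- filter_observations(records, include)
  no_trait <- unique(x$species[is.na(x$lw_a) | is.na(x$lw_b)])
  if (length(no_trait)) {
    stop("missing length-weight constants for species: ",
         paste(no_trait, collapse = ", "))
  }
  f <- factor(x$replicateid, levels = meta$replicateid)
  zero <- function(v) { v[is.na(v)] <- 0; v }
  sum_by <- function(values) {
    zero(as.numeric(tapply(values, f, sum)))
  }

  area <- geometry$area_m2
  out <- meta[, c("replicateid", setdiff(meta_cols, "depth_m")), drop = FALSE]
  out$depth_m <- if ("depth_m" %in% meta_cols) meta$depth_m else NA_real_

  if (nrow(x)) {
    w <- fish_weight_g(x$size_tl_cm, x$lw_a, x$lw_b,
                       x$length_conversion_factor, warn_lmax = FALSE)
    cg <- if ("consumer_group" %in% names(x)) x$consumer_group
          else rep(NA_character_, nrow(x))
    unknown <- is.na(cg) | !cg %in% .consumer_groups
    if (any(unknown)) {
      warning(sum(unknown),
              " observation(s) with missing/unknown consumer group",
              " assigned to 'unknown'")
      cg[unknown] <- "unknown"
    }
    out$abundance_m2 <- sum_by(x$count) / area
    out$biomass_g_m2 <- sum_by(x$count * w) / area
    for (g in c(.consumer_groups, "unknown")) {
      out[[.group_col(g)]] <- sum_by(x$count * w * (cg == g)) / area
    }
    out$richness <- zero(as.numeric(
      tapply(x$species, f, function(s) length(unique(s)))))
  } else {
    out$abundance_m2 <- out$biomass_g_m2 <- numeric(m)
    for (g in c(.consumer_groups, "unknown")) out[[.group_col(g)]] <- numeric(m)
    out$richness <- numeric(m)
  }

  sh_cols <- paste0("substrate_height_", c(0, 20, 50, 100, 150))
  out$mean_height_m <- if (all(sh_cols %in% names(meta))) {
    mean_substrate_height(as.matrix(meta[, sh_cols]), strict = FALSE)
  } else rep(NA_real_, m)
  out
}

#' Summarize one cylinder
#'
#' Convenience wrapper around [replicate_summaries()] for the records of a
#' single replicate.
#'
#' @inheritParams replicate_summaries
#' @return One-row data frame of replicate metrics.
#' @export
summarize_replicate <- function(records, geometry = cylinder_geometry(),
                                include = c("I", "N")) {
  if (length(unique(records$replicateid)) != 1L) {
    stop("records must belong to a single replicateid")
  }
  replicate_summaries(records, geometry, include)
}

#' Site-level summaries by pair-then-site averaging
#'
#' Collapses replicate summaries to the site sample unit: each metric is
#' averaged within each SPC-pair (`rep` label) and the pair means are then
#' averaged. With the usual single pair of two divers this is the plain mean
#' of the two cylinders. Missing values (e.g. benthic fields absent on one
#' replicate) are dropped at each averaging stage. The site depth bin is
#' recomputed from the midpoint between the minimum and maximum replicate
#' depths and compared with the recorded label.
#'
#' @param repsum Output of [replicate_summaries()].
#' @param records Optional: the observation records the summaries came from,
#'   used to add `richness_union` (distinct species per site under the
#'   filter).
#' @param include Observation-type filter used for `richness_union`.
#' @return Data frame, one row per `sitevisitid`, with the metric columns of
#'   `repsum` plus `n_replicates`, `n_pairs`, recomputed `depth_bin`,
#'   `depth_bin_recorded`, and `depth_bin_mismatch`.
#' @export
site_summaries_from_replicates <- function(repsum, records = NULL,
                                           include = c("I", "N")) {
  if (!nrow(repsum)) stop("no replicate summaries")
  rep_label <- if ("rep" %in% names(repsum)) repsum$rep else NA_character_
  rep_label[is.na(rep_label)] <- "A"
  mcols <- intersect(.metric_cols, names(repsum))

  denan <- function(df) {
    for (nm in mcols) df[[nm]][is.nan(df[[nm]])] <- NA_real_
    df
  }
  pair <- aggregate(repsum[mcols],
                    by = list(sitevisitid = repsum$sitevisitid,
                              rep = rep_label),
                    FUN = mean, na.rm = TRUE)
  pair <- denan(pair)
  sites <- aggregate(pair[mcols], by = list(sitevisitid = pair$sitevisitid),
                     FUN = mean, na.rm = TRUE)
  sites <- denan(sites)

  first <- !duplicated(repsum$sitevisitid)
  id_cols <- intersect(c("site", "region", "island", "reef_zone"),
                       names(repsum))
  meta <- repsum[first, c("sitevisitid", id_cols), drop = FALSE]
  out <- merge(meta, sites, by = "sitevisitid", sort = TRUE)

  out$n_replicates <- as.integer(table(repsum$sitevisitid)[
    as.character(out$sitevisitid)])
  np <- tapply(rep_label, repsum$sitevisitid,
               function(r) length(unique(r)))
  out$n_pairs <- as.integer(np[as.character(out$sitevisitid)])

  if ("depth_m" %in% names(repsum)) {
    mid <- tapply(repsum$depth_m, repsum$sitevisitid, function(d) {
      d <- d[!is.na(d)]
      if (!length(d)) NA_real_ else (min(d) + max(d)) / 2
    })
    mid <- as.numeric(mid[as.character(out$sitevisitid)])
    ok <- !is.na(mid) & mid > 0 & mid <= 30
    db <- rep(NA_character_, nrow(out))
    db[ok] <- classify_depth_bin(mid[ok])
    out$depth_bin_recorded <- if ("depth_bin" %in% names(repsum)) {
      as.character(tapply(repsum$depth_bin, repsum$sitevisitid,
                          function(z) z[1])[as.character(out$sitevisitid)])
    } else NA_character_
    out$depth_bin <- ifelse(is.na(db), tolower(out$depth_bin_recorded), db)
    out$depth_bin_mismatch <- !is.na(db) & !is.na(out$depth_bin_recorded) &
      tolower(out$depth_bin_recorded) != db
  }

  if (!is.null(records)) {
    x <- filter_observations(records, include)
    ru <- tapply(x$species, x$sitevisitid, function(s) length(unique(s)))
    out$richness_union <- as.numeric(ru[as.character(out$sitevisitid)])
    out$richness_union[is.na(out$richness_union)] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Summarize one site visit
#'
#' @param repsum Replicate summaries for a single `sitevisitid`.
#' @return One-row site summary (see [site_summaries_from_replicates()]).
#' @export
summarize_site <- function(repsum) {
  if (length(unique(repsum$sitevisitid)) != 1L) {
    stop("replicate summaries span more than one sitevisitid")
  }
  site_summaries_from_replicates(repsum)
}

#' Observation records to site summaries
#'
#' End-to-end convenience: [replicate_summaries()] followed by
#' [site_summaries_from_replicates()].
#'
#' @inheritParams replicate_summaries
#' @return Site-summary data frame, one row per site visit.
#' @export
site_summaries <- function(records, geometry = cylinder_geometry(),
                           include = c("I", "N")) {
  repsum <- replicate_summaries(records, geometry, include)
  site_summaries_from_replicates(repsum, records = records, include = include)
}
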