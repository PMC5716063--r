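# Design-based pooling of site summaries: per-stratum means and variances,
# hard-bottom area weights, the pooled-mean and pooled-variance equations
#   X = sum_i Xi * wi     VAR = sum_i VARi * wi^2
# and Neyman-style allocation of survey effort across strata.

.strat_keys <- c("reporting_unit", "reef_zone", "depth_bin")

.key_cols <- function(a, b) {
  k <- intersect(.strat_keys, intersect(names(a), names(b)))
  if (!"reporting_unit" %in% k) {
    stop("both tables must carry a reporting_unit column")
  }
  k
}

.key_id <- function(df, keys) {
  do.call(paste, c(df[keys], sep = " / "))
}

#' Per-stratum means and variances of a site metric
#'
#' Sites are the sample units; within each stratum (reporting unit x reef
#' zone x depth bin) the stratum mean `xi` is the plain mean of site values,
#' `s2i` the unbiased (n-1) sample variance among sites, and the variance of
#' the stratum mean `vari = s2i / ni` (simple random sampling within the
#' stratum, no finite-population correction). Strata with a single site have
#' `vari = NA`.
#'
#' @param sites Site-summary data frame (see [site_summaries()]).
#' @param metric Name of the metric column to summarize.
#' @param by Stratum key columns in `sites`; the first is treated as the
#'   reporting unit.
#' @return Data frame with `reporting_unit`, remaining key columns, `metric`,
#'   `ni`, `xi`, `s2i`, `vari`.
#' @export
stratum_estimates <- function(sites, metric = "biomass_g_m2",
                              by = c("island", "reef_zone", "depth_bin")) {
  miss <- setdiff(c(metric, by), names(sites))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  v <- sites[[metric]]
  keep <- !is.na(v)
  if (!any(keep)) stop("metric '", metric, "' has no non-missing values")
  v <- v[keep]
  keys <- lapply(sites[keep, by, drop = FALSE], as.character)
  id <- do.call(paste, c(keys, sep = "\r"))
  sp <- split(v, id)
  kdf <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  out <- data.frame(kdf, stringsAsFactors = FALSE)
  names(out) <- c("reporting_unit", by[-1])
  out$metric <- metric
  out$ni <- vapply(sp, length, integer(1))
  out$xi <- vapply(sp, mean, numeric(1))
  out$s2i <- vapply(sp, function(z) if (length(z) >= 2) var(z) else NA_real_,
                    numeric(1))
  out$vari <- out$s2i / out$ni
  rownames(out) <- NULL
  out[order(.key_id(out, names(out)[seq_along(by)])), , drop = FALSE]
}

#' Stratum weights from hard-bottom areas
#'
#' Each stratum is weighted by its share of its reporting unit's hard-bottom
#' area, renormalized over the strata actually sampled: `wi = Ai / sum(Aj)`
#' over the sampled strata of the unit, so weights sum to 1 per unit. When
#' some mapped strata were not sampled, the resulting estimate covers the
#' sampled domain only.
#'
#' @param area_table Data frame with stratum key columns and `area_ha` (see
#'   [read_area_table()]).
#' @param sampled Data frame whose rows name the sampled strata (key columns
#'   matching `area_table`; e.g. the output of [stratum_estimates()]).
#' @return Data frame of sampled strata with `area_ha` and `weight`.
#' @export
compute_weights <- function(area_table, sampled) {
  keys <- .key_cols(area_table, sampled)
  s <- unique(sampled[keys])
  rownames(s) <- NULL
  # collapse the area table onto the key granularity of the sampled strata
  a_id <- .key_id(area_table, keys)
  area <- tapply(area_table$area_ha, a_id, sum)
  s_id <- .key_id(s, keys)
  s$area_ha <- as.numeric(area[s_id])
  if (any(is.na(s$area_ha))) {
    stop("sampled stratum missing from area table: ",
         paste(s_id[is.na(s$area_ha)], collapse = "; "))
  }
  if (any(s$area_ha <= 0)) {
    stop("sampled stratum with non-positive area: ",
         paste(s_id[s$area_ha <= 0], collapse = "; "))
  }
  tot <- tapply(s$area_ha, s$reporting_unit, sum)
  s$weight <- s$area_ha / as.numeric(tot[s$reporting_unit])
  s
}

#' Pooled mean across strata
#'
#' The design-based pooled mean `X = sum_i Xi * wi`.
#'
#' @param xi Stratum means.
#' @param wi Stratum weights, summing to 1.
#' @return The pooled mean.
#' @export
pool_mean <- function(xi, wi) {
  if (length(xi) != length(wi)) stop("xi and wi lengths differ")
  if (any(is.na(wi)) || any(wi < 0)) stop("weights must be non-negative")
  if (abs(sum(wi) - 1) > 1e-9) stop("weights must sum to 1")
  sum(xi * wi)
}

#' Pooled variance of the mean across strata
#'
#' The design-based pooled variance `VAR = sum_i VARi * wi^2`.
#'
#' @param vari Variances of the stratum means.
#' @param wi Stratum weights, summing to 1.
#' @return The pooled variance.
#' @export
pool_variance <- function(vari, wi) {
  if (length(vari) != length(wi)) stop("vari and wi lengths differ")
  if (any(is.na(wi)) || any(wi < 0)) stop("weights must be non-negative")
  if (abs(sum(wi) - 1) > 1e-9) stop("weights must sum to 1")
  if (all(is.na(vari))) stop("variance unestimable: all strata have null VARi")
  sum(vari * wi^2)
}

#' Reporting-unit estimates from stratum estimates and weights
#'
#' Applies [pool_mean()] and [pool_variance()] per reporting unit. The
#' weights must cover exactly the strata present. Single-site strata
#' contribute their mean; their null variance is, by default, imputed as the
#' mean `vari` of the unit's other strata (the number of imputations is
#' reported), or kept null under `single_site = "strict"` (in which case the
#' pooled variance is `NA` whenever any stratum variance is missing).
#'
#' The effective degrees of freedom of the pooled variance are computed by
#' the Satterthwaite approximation over the strata with at least two sites,
#' `df = VAR^2 / sum((wi^2 vari)^2 / (ni - 1))`; the reported 95% confidence
#' bounds use the t quantile at that df.
#'
#' @param estimates Output of [stratum_estimates()].
#' @param weights Output of [compute_weights()] for the same strata.
#' @param single_site `"impute"` (default) or `"strict"`.
#' @return Data frame with one row per reporting unit: `metric`, `x`, `var`,
#'   `se`, `df`, `lcl95`, `ucl95`, `n_sites`, `n_strata`, `n_imputed_var`.
#' @export
pool_estimates <- function(estimates, weights,
                           single_site = c("impute", "strict")) {
  single_site <- match.arg(single_site)
  keys <- .key_cols(estimates, weights)
  e_id <- .key_id(estimates, keys)
  w_id <- .key_id(weights, keys)
  if (!setequal(e_id, w_id) || anyDuplicated(e_id) || anyDuplicated(w_id)) {
    stop("weights do not match the strata present in the estimates")
  }
  m <- merge(estimates, weights[c(keys, "weight")], by = keys)
  out <- lapply(split(m, m$reporting_unit), function(u) {
    vari <- u$vari
    n_imp <- 0L
    if (single_site == "impute" && any(is.na(vari)) && !all(is.na(vari))) {
      n_imp <- sum(is.na(vari))
      vari[is.na(vari)] <- mean(vari, na.rm = TRUE)
    }
    v <- if (all(is.na(vari))) {
      stop("variance unestimable for reporting unit ", u$reporting_unit[1],
           ": all strata have a single site")
    } else if (any(is.na(vari))) NA_real_ else pool_variance(vari, u$weight)
    multi <- u$ni >= 2
    df <- if (!is.na(v) && any(multi)) {
      comp <- (u$weight[multi]^2 * u$vari[multi])^2 / (u$ni[multi] - 1)
      if (sum(comp) > 0) v^2 / sum(comp) else NA_real_
    } else NA_real_
    x <- pool_mean(u$xi, u$weight)
    half <- if (!is.na(v) && !is.na(df)) qt(0.975, df) * sqrt(v) else NA_real_
    data.frame(reporting_unit = u$reporting_unit[1],
               metric = u$metric[1],
               x = x, var = v, se = sqrt(v), df = df,
               lcl95 = x - half, ucl95 = x + half,
               n_sites = sum(u$ni), n_strata = nrow(u),
               n_imputed_var = n_imp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Allocate survey effort across strata
#'
#' Neyman-style proportional allocation: the target number of sites for a
#' reef area (generally 30--50 per visit) is split across strata in
#' proportion to `area_ha * sd` (stratum size times the standard deviation of
#' the target metric), with integer counts fixed by largest-remainder
#' rounding. Ties are broken by larger area, then by lexicographic stratum
#' key.
#'
#' @param strata Data frame with stratum key columns, `area_ha`, and `sd`
#'   (the among-site standard deviation of the target metric).
#' @param target_total Total number of sites to allocate (positive integer).
#' @return `strata` with an integer `nh` column summing to `target_total`.
#' @export
allocate_sites <- function(strata, target_total) {
  stopifnot(target_total >= 1, target_total == floor(target_total))
  need <- c("area_ha", "sd")
  miss <- setdiff(need, names(strata))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  demand <- strata$area_ha * strata$sd
  if (any(is.na(demand)) || any(demand < 0)) {
    stop("area_ha and sd must be non-negative")
  }
  if (sum(demand) <= 0) stop("no stratum with positive allocation demand")
  raw <- target_total * demand / sum(demand)
  nh <- floor(raw)
  remainder <- raw - nh
  left <- target_total - sum(nh)
  if (left > 0) {
    keys <- intersect(.strat_keys, names(strata))
    key_str <- if (length(keys)) .key_id(strata, keys)
               else as.character(seq_len(nrow(strata)))
    ord <- order(-remainder, -strata$area_ha, key_str)
    nh[ord[seq_len(left)]] <- nh[ord[seq_len(left)]] + 1
  }
  strata$nh <- as.integer(nh)
  strata
}
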