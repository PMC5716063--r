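# Observer quality control: paired diver differences ("diver performance"),
# size-estimation calibration trials against fish models of known length,
# and species-identification test scoring.

#' Per-site paired differences between dive partners
#'
#' For every SPC-pair surveyed by exactly two divers, computes each diver's
#' difference from their partner (`delta = own - partner`) for the requested
#' metrics. Antisymmetric by construction: the two rows of a pair carry
#' opposite deltas.
#'
#' @param repsum Replicate summaries (see [replicate_summaries()]).
#' @param metrics Metric columns to difference (default: total biomass,
#'   richness, and the benthic covers — the quantities assessed in the
#'   field).
#' @param group Optional extra grouping column (e.g. a cruise identifier)
#'   carried through to the output.
#' @return Long-format data frame: `sitevisitid`, `rep`, `diver`, `partner`,
#'   `metric`, `delta` (plus `group` when requested) — boxplot-ready.
#' @export
paired_differences <- function(repsum,
    metrics = c("biomass_g_m2", "richness",
                "hard_coral", "ma", "cca", "sand", "other"),
    group = NULL) {
  metrics <- intersect(metrics, names(repsum))
  if (!length(metrics)) stop("no requested metric present")
  rep_label <- if ("rep" %in% names(repsum)) repsum$rep else "A"
  rep_label[is.na(rep_label)] <- "A"
  pid <- paste(repsum$sitevisitid, rep_label, sep = "/")
  keep <- pid %in% names(which(table(pid) == 2))
  x <- repsum[keep, , drop = FALSE]
  pid <- pid[keep]
  if (!nrow(x)) {
    return(data.frame(sitevisitid = integer(), rep = character(),
                      diver = integer(), partner = integer(),
                      metric = character(), delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(pid)
  x <- x[ord, , drop = FALSE]
  i1 <- seq(1, nrow(x), by = 2)
  i2 <- i1 + 1
  out <- lapply(metrics, function(mm) {
    d <- x[[mm]][i1] - x[[mm]][i2]
    data.frame(
      sitevisitid = rep(x$sitevisitid[i1], 2),
      rep = rep(if ("rep" %in% names(x)) x$rep[i1] else "A", 2),
      diver = c(x$diver[i1], x$diver[i2]),
      partner = c(x$diver[i2], x$diver[i1]),
      metric = mm,
      delta = c(d, -d),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(group) && group %in% names(x)) {
    g <- rep(x[[group]][i1], 2 * length(metrics))
    out[[group]] <- g
  }
  rownames(out) <- NULL
  out
}

#' Diver performance summary
#'
#' Summarizes each diver's paired differences for one metric: number of
#' paired sites, median and quartiles of the deltas, and a bias flag from an
#' exact two-sided sign test on the delta signs (zeros dropped). A diver with
#' no consistent bias has a median difference near zero — roughly half their
#' estimates above their partners', half below.
#'
#' @param repsum Replicate summaries.
#' @param metric Metric column to assess (default total biomass density).
#' @param alpha Significance level of the sign test (default 0.05).
#' @param group Optional grouping column passed to [paired_differences()].
#' @return Data frame per diver: `n`, `median_delta`, `q25`, `q75`,
#'   `p_sign`, `bias_flag`.
#' @export
diver_performance <- function(repsum, metric = "biomass_g_m2",
                              alpha = 0.05, group = NULL) {
  pd <- paired_differences(repsum, metrics = metric, group = group)
  unpaired <- setdiff(unique(repsum$diver), unique(pd$diver))
  if (length(unpaired)) {
    warning("diver(s) with no paired sites omitted: ",
            paste(unpaired, collapse = ", "))
  }
  if (!nrow(pd)) stop("no paired replicates for metric ", metric)
  out <- lapply(split(pd, pd$diver), function(d) {
    dl <- d$delta[!is.na(d$delta)]
    pos <- sum(dl > 0)
    neg <- sum(dl < 0)
    p <- if (pos + neg > 0) binom.test(pos, pos + neg)$p.value else NA_real_
    data.frame(diver = d$diver[1], metric = metric, n = length(dl),
               median_delta = median(dl),
               q25 = unname(quantile(dl, 0.25)),
               q75 = unname(quantile(dl, 0.75)),
               p_sign = p,
               bias_flag = !is.na(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Size-calibration trial summary
#'
#' During training dives, divers estimate the lengths of fish models of known
#' size (10 to >150 cm); accuracy is the mean difference between estimated
#' and actual length, reported with its standard error. The closer the mean
#' error is to zero, the more accurate the sizing.
#'
#' @param trials Data frame with columns `diver`, `model_length_cm`,
#'   `estimate_cm`.
#' @return Data frame per diver: `n`, `mean_error_cm`, `sd_error_cm`,
#'   `se_error_cm`.
#' @export
size_calibration <- function(trials) {
  need <- c("diver", "model_length_cm", "estimate_cm")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(trials)) stop("no calibration trials")
  err <- trials$estimate_cm - trials$model_length_cm
  out <- lapply(split(err, trials$diver), function(e) {
    e <- e[!is.na(e)]
    s <- if (length(e) >= 2) sd(e) else NA_real_
    data.frame(n = length(e), mean_error_cm = mean(e), sd_error_cm = s,
               se_error_cm = s / sqrt(length(e)))
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(diver = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Score a species-identification test
#'
#' Before each cruise, divers must accurately identify more than 90% of the
#' fishes shown in a region-specific identification test (the comparison is
#' strict: exactly 90% fails).
#'
#' @param correct Number of correct identifications.
#' @param total Number of fishes shown (positive).
#' @param threshold Pass threshold in percent (default 90, strict `>`).
#' @return List with `percent` and logical `pass`.
#' @export
id_test_score <- function(correct, total, threshold = 90) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(correct < 0 | correct > total)) {
    stop("correct must lie in [0, total]")
  }
  pct <- 100 * correct / total
  list(percent = pct, pass = pct > threshold)
}
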