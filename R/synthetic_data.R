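# Synthetic SPC surveys with known ground truth. Emulates the survey
# hierarchy (reporting unit -> stratum -> site -> SPC-pair -> diver replicate
# -> species observation) so the full processing chain can be exercised and
# checked against truth without any archived data. Both divers of a pair
# sample the same latent site state, perturbed by independent observer error;
# that shared latent state is what makes paired-difference QC meaningful.

#' Configuration for the synthetic survey generator
#'
#' Defaults describe a Saipan-like reef area: backreef and lagoon (shallow),
#' and a forereef split across the three depth bins, with the published
#' hard-bottom areas (backreef 598 ha, forereef 3539 ha split evenly across
#' depth bins, lagoon 583 ha) and about 30 sites per visit. Species
#' abundances follow a negative-binomial site model with per-stratum relative
#' abundance multipliers; sizes are lognormal truncated at each species'
#' maximum length. Observer error is multiplicative on counts (lognormal
#' factor, mean 1) and additive on sizes.
#'
#' @param reporting_unit Name of the simulated reef area.
#' @param strata Data frame with `reef_zone`, `depth_bin`, `area_ha`,
#'   `n_sites`, `rel_abund` (per-stratum abundance multiplier).
#' @param n_species Species-pool size.
#' @param species Optional pre-generated pool from [generate_species_pool()];
#'   when `NULL` one is generated deterministically from `species_seed`, so
#'   the same configuration always describes the same community regardless of
#'   the survey seed.
#' @param species_seed Seed for the species pool.
#' @param lw_a_range,lw_b_range,lcf_range,lmax_range Uniform trait ranges.
#' @param group_probs Named probabilities over the four consumer groups.
#' @param mu_range Range of baseline mean counts per cylinder per species.
#' @param dispersion Negative-binomial size parameter of site abundance.
#' @param size_sdlog Lognormal sd (log scale) of fish length.
#' @param obs_type_probs Probabilities of `I` vs `N` for core density rows.
#' @param extra_rate Named Poisson means of additional `F`, `T`, `P` rows per
#'   cylinder. These model sightings beyond the instantaneous community and
#'   carry no density truth.
#' @param count_error_sd Observer count error: observed ~
#'   Poisson(N * exp(e)), `e ~ N(-sd^2/2, sd^2)` so the observation is
#'   unbiased for the latent count; 0 reproduces the latent count exactly.
#' @param size_error_sd_cm Additive observer size error (cm); 0 is exact.
#' @param benthic_mean Named mean percent covers (hard_coral, ma, cca, sand,
#'   other), summing to 100.
#' @param benthic_theta Dirichlet concentration of replicate covers.
#' @param substrate_mean Mean percentages of the five height bins.
#' @param substrate_theta Dirichlet concentration of height bins.
#' @param n_pairs SPC-pairs per site (1 or 2).
#' @param obs_year Survey year written to the records.
#' @return List of class `spc_sim_config`.
#' @export
simulation_config <- function(
    reporting_unit = "Synthea",
    strata = data.frame(
      reef_zone = c("Backreef", "Forereef", "Forereef", "Forereef", "Lagoon"),
      depth_bin = c("shallow", "shallow", "mid", "deep", "shallow"),
      area_ha = c(598, 3539 / 3, 3539 / 3, 3539 / 3, 583),
      n_sites = c(6, 6, 6, 6, 6),
      rel_abund = c(0.8, 1.2, 1.0, 0.7, 0.9),
      stringsAsFactors = FALSE),
    n_species = 20,
    species = NULL,
    species_seed = 1000L,
    lw_a_range = c(0.005, 0.05),
    lw_b_range = c(2.8, 3.2),
    lcf_range = c(0.8, 1),
    lmax_range = c(15, 80),
    group_probs = c("Primary Consumer" = 0.35, "Secondary Consumer" = 0.30,
                    "Planktivore" = 0.20, "Piscivore" = 0.15),
    mu_range = c(0.2, 4),
    dispersion = 10,
    size_sdlog = 0.25,
    obs_type_probs = c(I = 0.9, N = 0.1),
    extra_rate = c(F = 0.15, T = 0.10, P = 0.10),
    count_error_sd = 0.2,
    size_error_sd_cm = 0.5,
    benthic_mean = c(hard_coral = 30, ma = 15, cca = 10, sand = 25,
                     other = 20),
    benthic_theta = 50,
    substrate_mean = c(40, 25, 15, 10, 10),
    substrate_theta = 30,
    n_pairs = 1,
    obs_year = 2015) {
  stopifnot(nrow(strata) >= 1, all(strata$area_ha > 0),
            all(strata$n_sites >= 1), all(strata$rel_abund > 0),
            n_species >= 1, dispersion > 0,
            count_error_sd >= 0, size_error_sd_cm >= 0,
            n_pairs %in% 1:2)
  if (abs(sum(obs_type_probs) - 1) > 1e-9 ||
      !setequal(names(obs_type_probs), c("I", "N"))) {
    stop("obs_type_probs must be named I, N and sum to 1")
  }
  if (abs(sum(group_probs) - 1) > 1e-9) stop("group_probs must sum to 1")
  if (abs(sum(benthic_mean) - 100) > 1e-9) {
    stop("benthic_mean must sum to 100")
  }
  structure(as.list(environment()), class = "spc_sim_config")
}

.int_to_code <- function(i) {
  # bijective base-26 over AAAA..ZZZZ
  l <- character(4)
  i <- i - 1
  for (k in 4:1) {
    l[k] <- LETTERS[i %% 26 + 1]
    i <- i %/% 26
  }
  paste(l, collapse = "")
}

#' Generate a synthetic species pool
#'
#' Draws per-taxon constants within the configured ranges: allometric `a`,
#' `b`, length-conversion factor, maximum length, consumer group, a baseline
#' mean count per cylinder, and lognormal size-model parameters (median
#' length set at 35% of the species' maximum length).
#'
#' @param config An [simulation_config()] (ranges and pool size are read from
#'   it).
#' @param seed Integer seed; defaults to the config's `species_seed`.
#' @return Data frame of species traits and abundance/size parameters.
#' @export
generate_species_pool <- function(config = simulation_config(),
                                  seed = config$species_seed) {
  set.seed(seed)
  n <- config$n_species
  codes <- vapply(sample.int(26^4, n), .int_to_code, character(1))
  ru <- function(r) runif(n, r[1], r[2])
  lmax <- ru(config$lmax_range)
  data.frame(
    species = codes,
    taxonname = paste("Synthetia", tolower(codes)),
    common_family = "synthetic fish",
    family = paste0("Synthidae", (seq_len(n) - 1) %% 5 + 1),
    consumer_group = sample(names(config$group_probs), n, replace = TRUE,
                            prob = config$group_probs),
    lw_a = ru(config$lw_a_range),
    lw_b = ru(config$lw_b_range),
    lmax = lmax,
    length_conversion_factor = ru(config$lcf_range),
    mu = ru(config$mu_range),
    size_meanlog = log(0.35 * lmax),
    size_sdlog = config$size_sdlog,
    stringsAsFactors = FALSE)
}

# expected weight of one fish: E[a (cL)^b] for L lognormal truncated above at
# lmax, via the lognormal partial-moment closed form
.expected_weight <- function(sp) {
  mu <- sp$size_meanlog; s <- sp$size_sdlog
  b <- sp$lw_b; K <- sp$lmax
  z <- (log(K) - mu) / s
  part <- exp(b * mu + b^2 * s^2 / 2) * pnorm(z - b * s) / pnorm(z)
  sp$lw_a * sp$length_conversion_factor^b * part
}

.rdirichlet_pct <- function(n, mean_pct, theta) {
  shape <- mean_pct / 100 * theta
  g <- matrix(rgamma(n * length(shape), shape = rep(shape, each = n)),
              nrow = n)
  100 * g / rowSums(g)
}

.draw_trunc_lnorm <- function(n, meanlog, sdlog, upper) {
  pmax <- plnorm(upper, meanlog, sdlog)
  qlnorm(runif(n, 0, pmax), meanlog, sdlog)
}

#' Simulate one SPC survey of a reef area
#'
#' Emits observation records in the published dialect — two divers per
#' SPC-pair at every site, with counts and sizes drawn from a shared latent
#' site state perturbed by independent observer error — together with the
#' ground truth. `truth$expected` holds the analytic means implied by the
#' generating parameters; `truth$realized` the area-weighted means of the
#' latent site states actually drawn (what a perfect observer pipeline should
#' reproduce). Both are computed by direct arithmetic on the latent values,
#' independently of the package's aggregation functions.
#'
#' @param config An [simulation_config()].
#' @param seed Integer seed; fixes the whole stream (identical seeds give
#'   byte-identical output).
#' @return List of class `spc_simulation`: `observations` (data frame in the
#'   published dialect), `truth`, `species`, `config`, `seed`.
#' @export
simulate_survey <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "spc_sim_config"))
  sp <- if (is.null(config$species)) generate_species_pool(config)
        else config$species
  set.seed(seed)
  st <- config$strata
  nsp <- nrow(sp)
  nsite <- sum(st$n_sites)
  site_stratum <- rep(seq_len(nrow(st)), st$n_sites)
  area_m2 <- cylinder_geometry()$area_m2

  # latent site state ---------------------------------------------------------
  MU <- outer(st$rel_abund[site_stratum], sp$mu)      # nsite x nsp
  N <- matrix(rnbinom(nsite * nsp, size = config$dispersion, mu = MU),
              nrow = nsite)
  L <- matrix(0, nsite, nsp)
  for (j in seq_len(nsp)) {
    L[, j] <- .draw_trunc_lnorm(nsite, sp$size_meanlog[j], sp$size_sdlog[j],
                                sp$lmax[j])
  }
  W1 <- sweep((sweep(L, 2, sp$length_conversion_factor, `*`))^
                matrix(sp$lw_b, nsite, nsp, byrow = TRUE),
              2, sp$lw_a, `*`)                        # weight of one fish

  # site metadata -------------------------------------------------------------
  bin_lims <- list(shallow = c(1.55, 5.75), mid = c(6.25, 17.75),
                   deep = c(18.25, 29.75))
  site_depth <- vapply(site_stratum, function(s) {
    lim <- bin_lims[[st$depth_bin[s]]]
    runif(1, lim[1], lim[2])
  }, numeric(1))
  site_code <- sprintf("SYN-%05d", seq_len(nsite))
  sitevisitid <- 10000L + seq_len(nsite)
  lat <- round(15.1 + runif(nsite, 0, 0.2), 5)
  lon <- round(145.6 + runif(nsite, 0, 0.2), 5)
  vis <- round(runif(nsite, 8, 30), 1)
  habitat <- sample(c("AGR", "PAV", "SAG", "ROB", "RRB"), nsite,
                    replace = TRUE)
  current <- sample(c("None", "Slight", "Moderate"), nsite, replace = TRUE)
  date <- format(as.Date(paste0(config$obs_year, "-05-01")) +
                   (seq_len(nsite) - 1) %/% 4, "%Y-%m-%d")

  # replicates -----------------------------------------------------------------
  n_rep_per_site <- 2L * config$n_pairs
  nrep <- nsite * n_rep_per_site
  rep_site <- rep(seq_len(nsite), each = n_rep_per_site)
  rep_pair <- rep(rep(LETTERS[seq_len(config$n_pairs)], each = 2L), nsite)
  replicateid <- 50000L + seq_len(nrep)
  divers <- unlist(lapply(seq_len(nsite * config$n_pairs),
                          function(i) sample(8L, 2L)))
  rep_depth <- round(pmin(pmax(site_depth[rep_site] +
                                 runif(nrep, -0.2, 0.2), 1.55), 29.95), 1)
  benthic <- .rdirichlet_pct(nrep, config$benthic_mean, config$benthic_theta)
  substrate <- .rdirichlet_pct(nrep, config$substrate_mean,
                               config$substrate_theta)
  max_h <- round(runif(nrep, 30, 250))
  urch <- classify_dacor(rnbinom(nrep, size = 2, mu = 8), "free")
  burch <- classify_dacor(rnbinom(nrep, size = 2, mu = 40), "boring")

  # observed counts and sizes per replicate ------------------------------------
  Nrep <- N[rep_site, , drop = FALSE]
  if (config$count_error_sd > 0) {
    s <- config$count_error_sd
    eps <- matrix(exp(rnorm(nrep * nsp, -s^2 / 2, s)), nrep, nsp)
    Nobs <- matrix(rpois(nrep * nsp, Nrep * eps), nrep, nsp)
  } else {
    Nobs <- Nrep
  }
  Lrep <- L[rep_site, , drop = FALSE]
  if (config$size_error_sd_cm > 0) {
    Lobs <- pmax(Lrep + matrix(rnorm(nrep * nsp, 0,
                                     config$size_error_sd_cm), nrep, nsp), 1)
  } else {
    Lobs <- Lrep
  }

  idx <- which(Nobs > 0, arr.ind = TRUE)
  r <- idx[, 1]; j <- idx[, 2]
  core_type <- sample(c("I", "N"), nrow(idx), replace = TRUE,
                      prob = config$obs_type_probs[c("I", "N")])

  # extra time-integrated / presence sightings ---------------------------------
  extra <- lapply(names(config$extra_rate), function(tp) {
    k <- rpois(nrep, config$extra_rate[[tp]])
    if (!sum(k)) return(NULL)
    rr <- rep(seq_len(nrep), k)
    jj <- sample.int(nsp, sum(k), replace = TRUE)
    data.frame(r = rr, j = jj, count = 1L + rpois(sum(k), 1),
               size = .draw_trunc_lnorm(sum(k), sp$size_meanlog[jj],
                                        sp$size_sdlog[jj], sp$lmax[jj]),
               obs_type = tp, stringsAsFactors = FALSE)
  })
  extra <- do.call(rbind, extra[!vapply(extra, is.null, logical(1))])

  rows <- data.frame(r = r, j = j, count = Nobs[idx],
                     size = Lobs[idx], obs_type = core_type,
                     stringsAsFactors = FALSE)
  if (!is.null(extra)) rows <- rbind(rows, extra)
  rows <- rows[order(rows$r, rows$j, rows$obs_type), , drop = FALSE]

  rs <- rep_site[rows$r]
  obs <- data.frame(
    region = "SYNTH",
    island = config$reporting_unit,
    site = site_code[rs],
    latitude = lat[rs],
    longitude = lon[rs],
    reef_zone = st$reef_zone[site_stratum[rs]],
    depth_bin = st$depth_bin[site_stratum[rs]],
    sitevisitid = sitevisitid[rs],
    date = date[rs],
    obs_year = config$obs_year,
    diver = divers[rows$r],
    replicateid = replicateid[rows$r],
    rep = rep_pair[rows$r],
    depth_m = rep_depth[rows$r],
    hard_coral = benthic[rows$r, 1],
    ma = benthic[rows$r, 2],
    cca = benthic[rows$r, 3],
    sand = benthic[rows$r, 4],
    other = benthic[rows$r, 5],
    habitat_code = habitat[rs],
    current_strength = current[rs],
    visibility_m = vis[rs],
    min_depth_m = pmax(round(rep_depth[rows$r] - 1, 1), 0.5),
    max_depth_m = pmin(round(rep_depth[rows$r] + 1, 1), 30),
    complexity = NA_integer_,
    substrate_height_0 = substrate[rows$r, 1],
    substrate_height_20 = substrate[rows$r, 2],
    substrate_height_50 = substrate[rows$r, 3],
    substrate_height_100 = substrate[rows$r, 4],
    substrate_height_150 = substrate[rows$r, 5],
    max_height = max_h[rows$r],
    urchin_dacor = urch[rows$r],
    boring_urchin_dacor = burch[rows$r],
    species = sp$species[rows$j],
    taxonname = sp$taxonname[rows$j],
    common_family = sp$common_family[rows$j],
    family = sp$family[rows$j],
    consumer_group = sp$consumer_group[rows$j],
    lw_a = sp$lw_a[rows$j],
    lw_b = sp$lw_b[rows$j],
    lmax = sp$lmax[rows$j],
    length_conversion_factor = sp$length_conversion_factor[rows$j],
    count = as.integer(rows$count),
    size_tl_cm = rows$size,
    obs_type = rows$obs_type,
    stringsAsFactors = FALSE)
  rownames(obs) <- NULL

  # truth ----------------------------------------------------------------------
  w <- st$area_ha / sum(st$area_ha)
  Ew <- .expected_weight(sp)
  exp_ab <- vapply(seq_len(nrow(st)), function(s)
    sum(st$rel_abund[s] * sp$mu) / area_m2, numeric(1))
  exp_bm <- vapply(seq_len(nrow(st)), function(s)
    sum(st$rel_abund[s] * sp$mu * Ew) / area_m2, numeric(1))

  site_ab <- rowSums(N) / area_m2
  site_bm <- rowSums(N * W1) / area_m2
  real_ab <- as.numeric(tapply(site_ab, site_stratum, mean))
  real_bm <- as.numeric(tapply(site_bm, site_stratum, mean))
  # realized covers: pair-then-site means of the replicate draws
  cover_site <- sapply(1:5, function(k) {
    pm <- tapply(benthic[, k], list(rep_site, rep_pair), mean)
    rowMeans(pm, na.rm = TRUE)
  })
  real_cov <- do.call(rbind, lapply(
    split(seq_len(nsite), site_stratum),
    function(i) colMeans(cover_site[i, , drop = FALSE])))
  colnames(real_cov) <- names(config$benthic_mean)

  strat <- data.frame(reporting_unit = config$reporting_unit,
                      reef_zone = st$reef_zone, depth_bin = st$depth_bin,
                      area_ha = st$area_ha, weight = w,
                      n_sites = st$n_sites, stringsAsFactors = FALSE)
  truth <- list(
    expected = cbind(strat, abundance_m2 = exp_ab, biomass_g_m2 = exp_bm),
    realized = cbind(strat, abundance_m2 = real_ab, biomass_g_m2 = real_bm,
                     as.data.frame(real_cov)),
    pooled_expected = list(abundance_m2 = sum(w * exp_ab),
                           biomass_g_m2 = sum(w * exp_bm)),
    pooled_realized = c(list(abundance_m2 = sum(w * real_ab),
                             biomass_g_m2 = sum(w * real_bm)),
                        as.list(colSums(real_cov * w))))
  structure(list(observations = obs, truth = truth, species = sp,
                 config = config, seed = seed),
            class = "spc_simulation")
}

#' Monte Carlo validation configuration
#'
#' The fixed study conditions used to validate the design-based estimator by
#' repeated simulation: a two-stratum forereef unit (shallow and mid depth
#' bins, 10 sites each) with a species-rich, moderately dispersed community.
#' The community is deliberately smooth — 40 species of moderate abundance,
#' high negative-binomial dispersion parameter, narrow size spread — so that
#' site-level biomass is close to Gaussian and interval calibration measures
#' the estimator rather than small-sample skew.
#'
#' @return An [simulation_config()] object.
#' @export
mc_validation_config <- function() {
  simulation_config(
    strata = data.frame(
      reef_zone = "Forereef", depth_bin = c("shallow", "mid"),
      area_ha = c(1800, 1739), n_sites = c(10, 10),
      rel_abund = c(1.1, 0.9), stringsAsFactors = FALSE),
    n_species = 40, dispersion = 50, size_sdlog = 0.10,
    lmax_range = c(25, 60), mu_range = c(1, 4))
}

#' Area table of a simulation configuration
#'
#' @param config An [simulation_config()].
#' @return Data frame (`reporting_unit`, `reef_zone`, `depth_bin`,
#'   `area_ha`) usable with [compute_weights()].
#' @export
sim_area_table <- function(config) {
  data.frame(reporting_unit = config$reporting_unit,
             reef_zone = config$strata$reef_zone,
             depth_bin = config$strata$depth_bin,
             area_ha = config$strata$area_ha,
             stringsAsFactors = FALSE)
}

#' Write a simulated survey to disk
#'
#' @param sim Result of [simulate_survey()].
#' @param csv_path Output observation CSV (published dialect).
#' @param truth_path Optional JSON path for the ground truth.
#' @param area_path Optional CSV path for the stratum area table.
#' @return `csv_path`, invisibly.
#' @export
write_simulation <- function(sim, csv_path, truth_path = NULL,
                             area_path = NULL) {
  write_spc_csv(sim$observations, csv_path)
  if (!is.null(truth_path)) {
    writeLines(jsonlite::toJSON(sim$truth, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), truth_path)
  }
  if (!is.null(area_path)) {
    write.csv(sim_area_table(sim$config), area_path, row.names = FALSE)
  }
  invisible(csv_path)
}
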