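make_sites <- function(values, island = "TestIsle", reef_zone = "Forereef",
                       depth_bin = "mid") {
  data.frame(sitevisitid = seq_along(values), island = island,
             reef_zone = reef_zone, depth_bin = depth_bin,
             biomass_g_m2 = values, stringsAsFactors = FALSE)
}

test_that("stratum mean, sample variance and variance of the mean", {
  est <- stratum_estimates(make_sites(c(10, 20)))
  expect_equal(est$xi, 15)
  expect_equal(est$s2i, 50)
  expect_equal(est$vari, 25)
  expect_equal(est$ni, 2L)
  # single-site stratum keeps its mean but a null variance
  est1 <- stratum_estimates(make_sites(42))
  expect_equal(est1$xi, 42)
  expect_true(is.na(est1$vari))
})

test_that("stratum mean recovers a known simulation mean", {
  set.seed(31)
  mu <- 12
  est <- stratum_estimates(make_sites(rnorm(100, mu, 4)))
  expect_lt(abs(est$xi - mu), 4 * sqrt(est$vari))
})

test_that("area weights are proportional shares summing to one", {
  at <- data.frame(reporting_unit = "U", reef_zone = c("A", "B"),
                   area_ha = c(100, 100))
  w <- compute_weights(at, at)
  expect_equal(w$weight, c(0.5, 0.5))
  w1 <- compute_weights(at, at[1, ])
  expect_equal(w1$weight, 1)
  # Saipan-like zone areas against the direct-division oracle
  areas <- c(598, 3539, 583, 127)
  at2 <- data.frame(reporting_unit = "Saipan",
                    reef_zone = c("Backreef", "Forereef", "Lagoon", "Other"),
                    area_ha = areas)
  w2 <- compute_weights(at2, at2)
  expect_equal(w2$weight, areas / sum(areas))
  expect_equal(sum(w2$weight), 1, tolerance = 1e-12)
  # scaling all areas leaves weights unchanged
  at3 <- at2; at3$area_ha <- at3$area_ha * 3.7
  expect_equal(compute_weights(at3, at3)$weight, w2$weight)
  # sampled stratum absent from the table is a named error
  expect_error(compute_weights(at2, data.frame(reporting_unit = "Saipan",
                                               reef_zone = "Protected Slope")),
               "Protected Slope")
})

test_that("pooled mean and variance follow the published equations", {
  expect_equal(pool_mean(c(10, 20), c(0.5, 0.5)), 15)
  expect_equal(pool_mean(42, 1), 42)
  expect_equal(pool_variance(c(4, 16), c(0.5, 0.5)), 5)
  expect_equal(pool_variance(9, 1), 9)
  expect_error(pool_mean(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(pool_mean(c(1, 2), 1), "lengths differ")
  expect_error(pool_variance(c(NA_real_, NA_real_), c(0.5, 0.5)),
               "unestimable")
})

test_that("census pooling equals the area-weighted population mean", {
  set.seed(32)
  for (i in 1:5) {
    areas <- runif(4, 10, 1000)
    pop <- lapply(1:4, function(s) runif(50, 0, 100))
    sites <- data.frame(
      sitevisitid = 1:200, island = "U",
      reef_zone = rep(c("Backreef", "Forereef", "Lagoon", "Protected Slope"),
                      each = 50),
      depth_bin = "mid", biomass_g_m2 = unlist(pop))
    est <- stratum_estimates(sites)
    at <- data.frame(reporting_unit = "U",
                     reef_zone = sort(c("Backreef", "Forereef", "Lagoon",
                                        "Protected Slope")),
                     depth_bin = "mid", area_ha = areas)
    w <- compute_weights(at, est)
    x <- pool_estimates(est, w)$x
    oracle <- sum(areas * vapply(pop, mean, numeric(1))[
      order(c("Backreef", "Forereef", "Lagoon", "Protected Slope"))]) /
      sum(areas)
    expect_equal(x, oracle, tolerance = 1e-9)
  }
})

test_that("single-site strata contribute their mean with imputed variance", {
  sites <- make_sites(c(10, 20, 30), depth_bin = c("mid", "mid", "deep"))
  est <- stratum_estimates(sites)
  at <- data.frame(reporting_unit = "TestIsle", reef_zone = "Forereef",
                   depth_bin = c("mid", "deep"), area_ha = c(60, 40))
  w <- compute_weights(at, est)
  d <- pool_estimates(est, w)
  expect_equal(d$x, 0.6 * 15 + 0.4 * 30)
  expect_equal(d$n_imputed_var, 1L)
  # imputed vari equals the mid stratum's 25, so VAR = 25*(.36+.16)
  expect_equal(d$var, 25 * (0.6^2 + 0.4^2))
  strict <- pool_estimates(est, w, single_site = "strict")
  expect_true(is.na(strict$var))
})

test_that("pooled variance does not increase when a stratum gains sites", {
  s2i <- c(40, 90); wi <- c(0.5, 0.5)
  v <- sapply(2:20, function(n1) pool_variance(s2i / c(n1, 5), wi))
  expect_true(all(diff(v) < 0))
})

test_that("repeated surveys recover the population mean with calibrated variance", {
  # parameter recovery over 2,000 simulated two-stratum surveys: the pooled
  # mean is unbiased, its design variance matches the empirical spread, and
  # the plain X +/- 1.96 SE interval covers truth near its nominal rate
  cfg <- mc_validation_config()
  at <- sim_area_table(cfg)
  truth <- simulate_survey(cfg, seed = 1)$truth$pooled_expected$biomass_g_m2
  res <- vapply(seq_len(2000), function(s) {
    sm <- simulate_survey(cfg, seed = s)
    st <- stratum_estimates(site_summaries(sm$observations), "biomass_g_m2")
    d <- pool_estimates(st, compute_weights(at, st))
    c(d$x, d$se)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) / truth - 1), 0.02)
  ratio <- var(res[1, ]) / mean(res[2, ]^2)
  expect_gt(ratio, 0.85); expect_lt(ratio, 1.15)
  z_cov <- mean(abs(res[1, ] - truth) <= 1.96 * res[2, ])
  expect_gte(z_cov, 0.93); expect_lte(z_cov, 0.97)
})

test_that("effort allocation is Neyman-proportional with largest remainders", {
  eq <- data.frame(reporting_unit = "U", reef_zone = letters[1:4],
                   area_ha = 100, sd = 2)
  expect_equal(allocate_sites(eq, 40)$nh, rep(10L, 4))
  zv <- eq; zv$sd <- c(2, 2, 2, 0)
  expect_equal(allocate_sites(zv, 30)$nh[4], 0L)
  expect_error(allocate_sites(transform(eq, sd = 0), 30), "demand")

  # randomized fixtures against a brute-force largest-remainder oracle
  set.seed(33)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    st <- data.frame(reporting_unit = "U",
                     reef_zone = paste0("z", seq_len(k)),
                     area_ha = runif(k, 1, 500), sd = runif(k, 0, 10))
    total <- sample(20:60, 1)
    got <- allocate_sites(st, total)$nh
    raw <- total * st$area_ha * st$sd / sum(st$area_ha * st$sd)
    base <- floor(raw)
    left <- total - sum(base)
    ord <- order(-(raw - base), -st$area_ha, st$reef_zone)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    expect_equal(got, as.integer(base))
    expect_equal(sum(got), total)
  }
})
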