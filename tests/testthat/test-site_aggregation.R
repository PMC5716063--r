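test_that("site metrics average within pairs, then between pairs", {
  one_pair <- make_repsum(1L, c("A", "A"), 1:2, c(10, 8))
  expect_equal(summarize_site(one_pair)$biomass_g_m2, 9)

  two_pairs <- make_repsum(1L, c("A", "A", "B", "B"), 1:4,
                           c(10, 8, 20, 22))
  expect_equal(summarize_site(two_pairs)$biomass_g_m2, (9 + 21) / 2)

  single <- make_repsum(1L, "A", 1L, 7.5)
  expect_equal(summarize_site(single)$biomass_g_m2, 7.5)
  expect_error(summarize_site(make_repsum(1:2, "A", 1L, 1)),
               "more than one sitevisitid")
})

test_that("replicate order never changes site metrics", {
  set.seed(21)
  rs <- make_repsum(rep(1:3, each = 4),
                    rep(c("A", "A", "B", "B"), 3), 1:12, runif(12, 0, 50))
  base <- site_summaries_from_replicates(rs)
  for (i in 1:5) {
    shuf <- rs[sample(nrow(rs)), ]
    expect_equal(site_summaries_from_replicates(shuf), base)
  }
})

test_that("with balanced pairs the two-stage mean is the grand mean", {
  set.seed(22)
  for (i in 1:10) {
    v <- runif(4, 0, 100)
    rs <- make_repsum(1L, c("A", "A", "B", "B"), 1:4, v)
    expect_equal(summarize_site(rs)$biomass_g_m2, mean(v))
  }
  # unbalanced pairs: stages weight pairs, not replicates
  rs <- make_repsum(1L, c("A", "A", "A", "B"), 1:4, c(3, 6, 9, 10))
  expect_equal(summarize_site(rs)$biomass_g_m2, (6 + 10) / 2)
})

test_that("richness counts distinct species under the filter, P excluded", {
  rec <- make_records(6,
    species = c("AAAA", "BBBB", "CCCC", "DDDD", "EEEE", "FFFF"),
    obs_type = c("I", "I", "N", "I", "I", "P"))
  rs <- replicate_summaries(rec)
  expect_equal(rs$richness, 5)
  site <- site_summaries(rec)
  expect_equal(site$richness, 5)
  expect_equal(site$richness_union, 5)
})

test_that("consumer-group biomass partitions the total", {
  rec <- make_records(3,
    species = c("AAAA", "BBBB", "CCCC"),
    consumer_group = c("Piscivore", "Planktivore", "Planktivore"),
    count = c(2L, 1L, 4L), size_tl_cm = c(20, 10, 15))
  rs <- replicate_summaries(rec)
  expect_equal(rs$biomass_piscivore_g_m2 + rs$biomass_planktivore_g_m2,
               rs$biomass_g_m2, tolerance = 1e-12)
  expect_equal(rs$biomass_primary_g_m2, 0)
  # single planktivore row: group biomass equals the total
  rec1 <- make_records(1, consumer_group = "Planktivore")
  rs1 <- replicate_summaries(rec1)
  expect_equal(rs1$biomass_planktivore_g_m2, rs1$biomass_g_m2)
  # unrecognised group lands in 'unknown' with a warning
  expect_warning(rs2 <- replicate_summaries(
    make_records(1, consumer_group = "Grazer")), "unknown")
  expect_equal(rs2$biomass_unknown_g_m2, rs2$biomass_g_m2)
})

test_that("group partition holds on simulated communities", {
  sim <- simulate_survey(simulation_config(), seed = 5)
  rs <- replicate_summaries(sim$observations)
  groups <- rs$biomass_primary_g_m2 + rs$biomass_secondary_g_m2 +
    rs$biomass_planktivore_g_m2 + rs$biomass_piscivore_g_m2 +
    rs$biomass_unknown_g_m2
  expect_equal(groups, rs$biomass_g_m2, tolerance = 1e-9)
  # replicates whose rows are all filtered away keep zero-density rows
  rec <- make_records(2, replicateid = c(1L, 2L), diver = c(1L, 2L),
                      obs_type = c("I", "P"),
                      species = c("AAAA", "BBBB"))
  rs2 <- replicate_summaries(rec)
  expect_equal(nrow(rs2), 2)
  expect_equal(rs2$biomass_g_m2[2], 0)
  expect_equal(rs2$richness[2], 0)
})

test_that("site depth bin is recomputed from the replicate depth midpoint", {
  rec <- make_records(2, replicateid = c(1L, 2L), diver = 1:2,
                      depth_m = c(16, 21), depth_bin = "mid")
  s <- site_summaries(rec)
  # midpoint (16+21)/2 = 18.5 -> deep, disagreeing with the recorded label
  expect_equal(s$depth_bin, "deep")
  expect_true(s$depth_bin_mismatch)
})
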