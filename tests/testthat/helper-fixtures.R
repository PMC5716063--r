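# Fixture builders: observation records with sensible defaults, overridable
# per column (values recycled to n).

make_records <- function(n = 1, ...) {
  base <- list(
    region = "SYNTH", island = "TestIsle", site = "TST-00001",
    latitude = 15.2, longitude = 145.7,
    reef_zone = "Forereef", depth_bin = "mid",
    sitevisitid = 1L, date = "2015-05-01", obs_year = 2015L,
    diver = 1L, replicateid = 1L, rep = "A", depth_m = 12,
    hard_coral = 30, ma = 15, cca = 10, sand = 25, other = 20,
    habitat_code = "AGR", current_strength = "Slight",
    visibility_m = 15, min_depth_m = 11, max_depth_m = 13,
    complexity = NA_integer_,
    substrate_height_0 = 40, substrate_height_20 = 25,
    substrate_height_50 = 15, substrate_height_100 = 10,
    substrate_height_150 = 10, max_height = 120,
    urchin_dacor = "R", boring_urchin_dacor = "O",
    species = "AAAA", taxonname = "Testus fishus",
    common_family = "testfish", family = "Testidae",
    consumer_group = "Piscivore",
    lw_a = 0.01, lw_b = 3, lmax = 50, length_conversion_factor = 1,
    count = 1L, size_tl_cm = 10, obs_type = "I")
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(lapply(base, function(v) rep(v, length.out = n)),
                stringsAsFactors = FALSE)
}

# replicate-summary rows for aggregation/QC tests without going through
# observation records
make_repsum <- function(sitevisitid, rep, diver, biomass_g_m2,
                        richness = NA_real_) {
  data.frame(sitevisitid = sitevisitid, site = "TST-00001",
             island = "TestIsle", reef_zone = "Forereef", depth_bin = "mid",
             rep = rep, diver = diver, replicateid = seq_along(sitevisitid),
             biomass_g_m2 = biomass_g_m2, richness = richness,
             depth_m = 12, stringsAsFactors = FALSE)
}

cyl_area <- pi * 7.5^2
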