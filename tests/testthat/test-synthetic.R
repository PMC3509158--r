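test_that("trait tables are populated, seeded and near-uncorrelated", {
  t1 <- generate_trait_table(1, seed = 7)
  expect_equal(nrow(t1), 1)
  expect_true(all(!is.na(t1[, c("n_pct", "lignin_pct", "polyphenol_pct",
                                "green_fraction", "woody_fraction",
                                "conv_factor")])))
  expect_identical(t1, generate_trait_table(1, seed = 7))
  expect_error(generate_trait_table(0, seed = 1),
               class = "fallowfun_invalid_argument")
  # trait ranges and mutual independence across a larger pool
  t50 <- generate_trait_table(50, seed = 1)
  expect_true(all(t50$n_pct >= 0.5 & t50$n_pct <= 5))
  expect_true(all(t50$lignin_pct >= 2 & t50$lignin_pct <= 25))
  expect_true(all(t50$polyphenol_pct >= 0.5 & t50$polyphenol_pct <= 10))
  expect_true(all(t50$green_fraction + t50$woody_fraction <= 1 + 1e-12))
  expect_true(all(t50$conv_factor > 0))
  lt <- log(t50[, c("n_pct", "lignin_pct", "polyphenol_pct")])
  cors <- cor(lt)[lower.tri(diag(3))]
  expect_true(all(abs(cors) < 0.3))
})

test_that("infiltration curves follow the Horton closed form", {
  # degenerate: f0 = fc gives a constant rate
  flat <- generate_infiltration_curve(300, 300, 0.5, noise_sd = 0)
  expect_true(all(flat$rate_mm_hr == 300))
  # closed form at t = 60: 200 + 600 exp(-3)
  c1 <- generate_infiltration_curve(800, 200, 0.05, times = c(0, 30, 60, 90),
                                    noise_sd = 0)
  expect_equal(c1$rate_mm_hr[3], 200 + 600 * exp(-3), tolerance = 1e-12)
  expect_equal(c1$rate_mm_hr[3], 229.9, tolerance = 1e-3)
  # without noise the seed is irrelevant
  expect_identical(generate_infiltration_curve(800, 200, 0.05, seed = 1),
                   generate_infiltration_curve(800, 200, 0.05, seed = 99))
  expect_error(generate_infiltration_curve(200, 800, 0.05),
               class = "fallowfun_invalid_argument")
  expect_error(generate_infiltration_curve(800, 200, -1),
               class = "fallowfun_invalid_argument")
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(n_grazed = 0, n_improved = 0),
               class = "fallowfun_invalid_argument")
  expect_error(generator_config(noise_sd = -1),
               class = "fallowfun_invalid_argument")
  expect_error(generator_config(horton_params = list(
    f0_range = c(100, 200), fc_range = c(150, 400), k_range = c(0.03, 0.08),
    noise_sd = 10)), class = "fallowfun_invalid_argument")
})

test_that("default survey has the study's structure and is deterministic", {
  cfg <- generator_config(seed = 42)
  ds <- generate_fallow_survey(cfg)
  expect_equal(nrow(ds$plots), 39)
  expect_equal(sum(ds$plots$fallow_type == "grazed"), 18)
  expect_equal(sum(ds$plots$fallow_type == "improved"), 21)
  expect_true(all(ds$survey$species_id %in% ds$traits$species_id))
  expect_false(anyDuplicated(ds$plots$plot_id) > 0)
  # byte-identical regeneration under the same seed
  ds2 <- generate_fallow_survey(cfg)
  for (tab in c("plots", "survey", "traits", "soils", "infiltration")) {
    expect_identical(ds[[tab]], ds2[[tab]])
  }
  # grazed plots carry 5-15 species and graded grazing classes
  per_plot <- table(ds$survey$plot_id[ds$survey$plot_id %in%
                                        ds$plots$plot_id[ds$plots$fallow_type == "grazed"]])
  expect_true(all(per_plot >= 5 & per_plot <= 16))
  grp <- ds$plots$grazing_group[ds$plots$fallow_type == "grazed"]
  expect_true(all(grp %in% c("light", "moderate", "heavy")))
  expect_true(all(is.na(ds$plots$grazing_group[ds$plots$fallow_type == "improved"])))
})

test_that("improved fallows are dominated by 1-3 planted woody legumes", {
  ds <- generate_fallow_survey(generator_config(seed = 42))
  sb <- species_biomass(ds$survey, ds$traits)
  for (pid in ds$plots$plot_id[ds$plots$fallow_type == "improved"]) {
    rows <- sb[sb$plot_id == pid, ]
    tree_rows <- rows$growth_form == "tree"
    n_dom <- sum(tree_rows)
    expect_gte(n_dom, 1)
    expect_lte(n_dom, 3)
    dom_share <- sum(rows$green_t_ha[tree_rows]) / sum(rows$green_t_ha)
    expect_gte(dom_share, 0.8)
  }
})

test_that("generated diversity is higher in grazed than improved fallows", {
  ds <- generate_fallow_survey(generator_config(seed = 42))
  m <- merge(diversity_metrics(ds$survey, ds$traits), ds$plots, by = "plot_id")
  rich <- oneway_anova(m$richness, m$fallow_type)
  fd <- oneway_anova(m$fd, m$fallow_type)
  expect_gt(mean(m$richness[m$fallow_type == "grazed"]),
            mean(m$richness[m$fallow_type == "improved"]))
  expect_gt(mean(m$fd[m$fallow_type == "grazed"]),
            mean(m$fd[m$fallow_type == "improved"]))
  expect_lt(rich$p, 0.05)
  expect_lt(fd$p, 0.05)
})

test_that("pipeline function means stay near the calibration targets", {
  # 10x the study size tightens the stochastic check on the gamma margins
  cfg <- generator_config(n_grazed = 180, n_improved = 210, seed = 1)
  ds <- generate_fallow_survey(cfg)
  wood <- wood_biomass(ds$survey, ds$traits)
  forage <- forage_biomass(ds$survey, ds$traits)
  soil <- soil_functions(ds$soils, ds$infiltration)
  prof <- function_profiles(ds$plots, wood, forage, soil)
  cal <- cfg$calibration_targets
  for (i in seq_len(nrow(cal))) {
    got <- mean(prof[[cal$fn[i]]][prof$fallow_type == cal$fallow_type[i]])
    expect_lt(abs(got - cal$mean[i]) / cal$mean[i], 0.25,
              label = sprintf("%s/%s mean %.2f vs target %.2f",
                              cal$fallow_type[i], cal$fn[i], got, cal$mean[i]))
  }
})
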