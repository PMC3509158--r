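test_that("allometric equation reproduces the humid-region closed form", {
  # ln(1) = 0 isolates the intercept
  expect_equal(allometric_tree_biomass_kg(1, check = FALSE), exp(-2.134))
  expect_equal(allometric_tree_biomass_kg(10), 40.11, tolerance = 1e-3)
  expect_equal(allometric_tree_biomass_kg(2.5), 1.202, tolerance = 1e-3)
  dbh <- seq(2.5, 50, length.out = 200)
  expect_true(all(diff(allometric_tree_biomass_kg(dbh)) > 0))
  expect_error(allometric_tree_biomass_kg(1), class = "fallowfun_invalid_argument")
  expect_error(allometric_tree_biomass_kg(-2, check = FALSE),
               class = "fallowfun_invalid_argument")
})

test_that("cover class midpoints match the 5-point field scale", {
  expect_equal(cover_class_midpoint(1:5), c(0.025, 0.095, 0.275, 0.525, 0.825))
  expect_error(cover_class_midpoint(0), class = "fallowfun_invalid_argument")
  expect_error(cover_class_midpoint(6), class = "fallowfun_invalid_argument")
  expect_error(cover_class_midpoint(2.5), class = "fallowfun_invalid_argument")
})

test_that("biovolume conversion does the unit arithmetic for a 100 m2 plot", {
  z <- biovolume_to_biomass(0, 2, 0.3, 0.5)
  expect_equal(unlist(z), c(aboveground_t_ha = 0, green_t_ha = 0, woody_t_ha = 0))
  b <- biovolume_to_biomass(10, 2, 0.3, 0.5)
  expect_equal(b$aboveground_t_ha, 2.0)   # 20 kg per plot
  expect_equal(b$green_t_ha, 0.6)
  expect_equal(b$woody_t_ha, 1.0)
  expect_error(biovolume_to_biomass(-1, 2, 0.3, 0.5),
               class = "fallowfun_invalid_argument")
})

test_that("missing trait rows are reported by species", {
  sv <- make_survey("spX")
  tr <- make_traits("spA")
  expect_error(species_biomass(sv, tr), "spX",
               class = "fallowfun_missing_trait")
})

test_that("wood biomass applies the stem and height filters", {
  tr <- rbind(make_traits("grass"),
              make_traits("tree1", growth_form = "tree", green_fraction = 0.2,
                          woody_fraction = 0.8, conv_factor = 20),
              make_traits("bush", growth_form = "shrub", green_fraction = 0.4,
                          woody_fraction = 0.5, conv_factor = 10))
  # herbs only -> zero wood
  herb_only <- make_survey("grass")
  expect_equal(wood_biomass(herb_only, tr)$wood_t_ha, 0)
  # one tree stem of 10 cm, nothing else: 40.11 * 0.8 * 0.1 t/ha
  one_tree <- make_survey("tree1", growth_form = "tree", avg_height_m = 5,
                          dbh_cm = "10", biovolume_m3 = 0)
  expect_equal(wood_biomass(one_tree, tr)$wood_t_ha,
               exp(-2.134 + 2.53 * log(10)) * 0.8 * 0.1)
  # short shrub (0.5 m, no stems) contributes nothing
  short_shrub <- make_survey("bush", growth_form = "shrub",
                             avg_height_m = 0.5, biovolume_m3 = 3)
  expect_equal(wood_biomass(short_shrub, tr)$wood_t_ha, 0)
  # tall shrub takes the biovolume path: 3 m3 * 10 kg/m3 * 0.5 woody * 0.1
  tall_shrub <- make_survey("bush", growth_form = "shrub",
                            avg_height_m = 1.2, biovolume_m3 = 3)
  expect_equal(wood_biomass(tall_shrub, tr)$wood_t_ha, 1.5)
})

test_that("forage quality rule is CP:lignin >= 0.8, boundary inclusive", {
  expect_true(is_quality_forage(2, 10))        # CP = 12.5, ratio 1.25
  expect_false(is_quality_forage(0.8, 10))     # ratio 0.5
  expect_true(is_quality_forage(0.8 * 10 / 6.25, 10))  # ratio exactly 0.8
  expect_error(is_quality_forage(2, 0), class = "fallowfun_invalid_argument")
})

test_that("forage biomass keeps quality herbs and short woody plants only", {
  tr <- rbind(make_traits("grass", n_pct = 2, lignin_pct = 10,
                          green_fraction = 0.8, conv_factor = 2.5),
              make_traits("poorgrass", n_pct = 0.8, lignin_pct = 10,
                          green_fraction = 0.8, conv_factor = 2.5),
              make_traits("tree1", growth_form = "tree", n_pct = 3,
                          lignin_pct = 5, green_fraction = 0.3,
                          woody_fraction = 0.6, conv_factor = 20))
  # single qualifying grass: green biomass 2.0 t/ha
  sv <- make_survey("grass", biovolume_m3 = 10)  # 25 kg * 0.8 = 2.0 t/ha
  expect_equal(forage_biomass(sv, tr)$forage_t_ha, 2.0)
  # the same plot with a low CP:lignin grass yields zero
  sv2 <- make_survey("poorgrass", biovolume_m3 = 10)
  expect_equal(forage_biomass(sv2, tr)$forage_t_ha, 0)
  # a tall tree never counts as forage, however high its CP:lignin
  sv3 <- rbind(make_survey("grass", biovolume_m3 = 5),
               make_survey("tree1", growth_form = "tree", avg_height_m = 6,
                           biovolume_m3 = 4, dbh_cm = "12"))
  expect_equal(forage_biomass(sv3, tr)$forage_t_ha, 1.0)
})

test_that("wood and forage never score the same record", {
  ds <- generate_fallow_survey(generator_config(n_grazed = 6, n_improved = 6,
                                                seed = 5))
  sb <- species_biomass(ds$survey, ds$traits)
  tr <- ds$traits[match(sb$species_id, ds$traits$species_id), ]
  tall_woody <- sb$growth_form %in% c("tree", "shrub") & sb$avg_height_m >= 0.7
  quality <- is_quality_forage(tr$n_pct, tr$lignin_pct)
  wood_contrib <- sb$stem_woody_t_ha + ifelse(tall_woody, sb$bv_woody_t_ha, 0)
  forage_contrib <- ifelse(!tall_woody & quality, sb$bv_green_t_ha, 0)
  expect_true(all(pmin(wood_contrib, forage_contrib) == 0))
  # and tall woody records alone can never produce forage
  only_tall <- ds$survey[ds$survey$growth_form != "herb" &
                           ds$survey$avg_height_m >= 0.7, ]
  expect_true(all(forage_biomass(only_tall, ds$traits)$forage_t_ha == 0))
})

test_that("plot totals are order-invariant and linear in biovolume", {
  ds <- generate_fallow_survey(generator_config(n_grazed = 4, n_improved = 4,
                                                seed = 9))
  sv <- ds$survey
  perm <- sv[sample(nrow(sv)), ]
  w1 <- wood_biomass(sv, ds$traits)
  w2 <- wood_biomass(perm, ds$traits)
  expect_equal(w1[order(w1$plot_id), ], w2[order(w2$plot_id), ],
               ignore_attr = TRUE)
  # scaling all biovolumes by c scales the biovolume-path biomass by c
  no_stem <- sv
  no_stem$dbh_cm <- ""
  sc <- no_stem
  sc$biovolume_m3 <- sc$biovolume_m3 * 3
  expect_equal(wood_biomass(sc, ds$traits)$wood_t_ha,
               3 * wood_biomass(no_stem, ds$traits)$wood_t_ha)
  expect_equal(forage_biomass(sc, ds$traits)$forage_t_ha,
               3 * forage_biomass(no_stem, ds$traits)$forage_t_ha)
})
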