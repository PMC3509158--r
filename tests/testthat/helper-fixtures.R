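# In-code fixture builders for small hand-constructed plots.

make_traits <- function(species_id, growth_form = "herb", n_pct = 2,
                        lignin_pct = 10, polyphenol_pct = 2,
                        green_fraction = 0.8, woody_fraction = 0,
                        conv_factor = 2) {
  data.frame(species_id = species_id, growth_form = growth_form,
             n_pct = n_pct, lignin_pct = lignin_pct,
             polyphenol_pct = polyphenol_pct,
             green_fraction = green_fraction,
             woody_fraction = woody_fraction, conv_factor = conv_factor,
             forage_known = NA, stringsAsFactors = FALSE)
}

make_survey <- function(species_id, plot_id = "p1", growth_form = "herb",
                        avg_height_m = 0.5, cover_class = 3L, dbh_cm = "",
                        biovolume_m3 = 1) {
  data.frame(plot_id = plot_id, species_id = species_id,
             growth_form = growth_form, avg_height_m = avg_height_m,
             cover_class = cover_class, dbh_cm = dbh_cm,
             biovolume_m3 = biovolume_m3, stringsAsFactors = FALSE)
}

# Minimal profile table on the transformed scale only (raw columns unused by
# the reference/indicator operations).
make_profiles <- function(wood_t, forage_t, cations_t, infiltration_t,
                          fallow_type = "grazed",
                          plot_id = sprintf("p%02d", seq_along(wood_t))) {
  data.frame(plot_id = plot_id, fallow_type = fallow_type,
             wood_t = wood_t, forage_t = forage_t, cations_t = cations_t,
             infiltration_t = infiltration_t, stringsAsFactors = FALSE)
}

make_reference <- function(max3, mean, fallow_type = "grazed") {
  fns <- c("wood", "forage", "cations", "infiltration")
  data.frame(fallow_type = fallow_type, fn = fns,
             max3 = rep_len(max3, 4), mean = rep_len(mean, 4),
             stringsAsFactors = FALSE)
}
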