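# Vegetation biomass: survey records -> standing aboveground/green/woody biomass
# and the wood and forage ecosystem-function indicators.
#
# Plot convention: all field records refer to a 100 m^2 plot, so 1 kg per plot
# equals 0.1 t/ha.

KG_PER_PLOT_TO_T_HA <- 0.1
DBH_MIN_CM <- 2.5
WOODY_HEIGHT_MIN_M <- 0.7
CP_PER_N <- 6.25
CP_LIGNIN_MIN <- 0.8

#' Whole-tree aboveground biomass from stem diameter
#'
#' General allometric equation for humid regions relating diameter at breast
#' height to whole-tree aboveground biomass:
#' \deqn{Y = e^{-2.134 + 2.53\,\ln \mathrm{DBH}}}
#' with DBH in cm and Y in kg per stem.
#'
#' @param dbh Stem diameter at breast height in cm. Stems below 2.5 cm are not
#'   measured in the field protocol and are rejected; route them through the
#'   biovolume path instead.
#' @param check If \code{FALSE}, skip the 2.5 cm lower bound (used when
#'   evaluating the bare formula).
#' @return Biomass in kg per stem, strictly increasing in \code{dbh}.
#' @examples
#' allometric_tree_biomass_kg(10)
#' @export
allometric_tree_biomass_kg <- function(dbh, check = TRUE) {
  check_numeric(dbh, "dbh", min = if (check) DBH_MIN_CM else 1e-12)
  exp(-2.134 + 2.53 * log(dbh))
}

#' Mid-point of a vegetation cover class
#'
#' Cover is scored on a 5-point scale with classes 1--4, 4--15, 15--40,
#' 40--65 and >65 \%; the midpoint of the open top class is taken against 100
#' \%. Returned as a proportion.
#'
#' @param cover_class Integer vector with values in 1..5.
#' @return Proportions: 0.025, 0.095, 0.275, 0.525, 0.825.
#' @export
cover_class_midpoint <- function(cover_class) {
  if (!is.numeric(cover_class) || anyNA(cover_class) ||
      any(cover_class != as.integer(cover_class)) ||
      any(cover_class < 1L | cover_class > 5L)) {
    stop_invalid("cover_class must be an integer in 1..5")
  }
  c(0.025, 0.095, 0.275, 0.525, 0.825)[as.integer(cover_class)]
}

parse_dbh_list <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  vals <- suppressWarnings(as.numeric(strsplit(trimws(x), ";", fixed = TRUE)[[1]]))
  if (anyNA(vals)) stop_invalid("malformed DBH list: '", x, "'")
  if (any(vals < DBH_MIN_CM)) {
    stop_invalid("DBH list contains stems below ", DBH_MIN_CM,
                 " cm; small stems belong to the biovolume path")
  }
  vals
}

lookup_traits <- function(species, traits) {
  idx <- match(species, traits$species_id)
  if (anyNA(idx)) stop_missing_trait(unique(species[is.na(idx)]))
  traits[idx, , drop = FALSE]
}

#' Aboveground biomass of one surveyed species via the biovolume path
#'
#' Visually estimated biovolume (m^3 per 100 m^2 plot) is multiplied by a
#' growth-form/species conversion factor (kg biomass per m^3) to estimate
#' aboveground biomass; green and woody pools follow from the species'
#' literature fractions.
#'
#' @param biovolume_m3 Biovolume in m^3 for the 100 m^2 plot.
#' @param conv_factor kg aboveground biomass per m^3 biovolume.
#' @param green_fraction,woody_fraction Proportions of aboveground biomass.
#' @return A list with \code{aboveground_t_ha}, \code{green_t_ha},
#'   \code{woody_t_ha}.
#' @export
biovolume_to_biomass <- function(biovolume_m3, conv_factor,
                                 green_fraction, woody_fraction) {
  check_numeric(biovolume_m3, "biovolume_m3", min = 0)
  check_numeric(conv_factor, "conv_factor", min = 1e-12)
  check_numeric(green_fraction, "green_fraction", min = 0, max = 1)
  check_numeric(woody_fraction, "woody_fraction", min = 0, max = 1)
  ag_kg <- biovolume_m3 * conv_factor
  list(aboveground_t_ha = ag_kg * KG_PER_PLOT_TO_T_HA,
       green_t_ha = ag_kg * green_fraction * KG_PER_PLOT_TO_T_HA,
       woody_t_ha = ag_kg * woody_fraction * KG_PER_PLOT_TO_T_HA)
}

#' Per-record biomass table for a survey
#'
#' Expands each plot x species survey record into aboveground, green and
#' woody standing biomass (t/ha). Stems >= 2.5 cm DBH go through the
#' allometric equation; everything else through the biovolume conversion.
#' Both pools are split into green and woody tissue by the species'
#' fractions. The stem and biovolume contributions are kept as separate
#' columns because the wood and forage indicators partition on them.
#'
#' @param survey Data frame with columns \code{plot_id}, \code{species_id},
#'   \code{growth_form} (\code{tree}/\code{shrub}/\code{herb}),
#'   \code{avg_height_m}, \code{cover_class}, \code{dbh_cm} (semicolon list,
#'   possibly empty) and \code{biovolume_m3}.
#' @param traits Trait table keyed by \code{species_id} with
#'   \code{green_fraction}, \code{woody_fraction}, \code{conv_factor},
#'   \code{n_pct}, \code{lignin_pct}.
#' @return Data frame, one row per survey record, with t/ha columns
#'   \code{aboveground_t_ha}, \code{green_t_ha}, \code{woody_t_ha} and the
#'   stem/biovolume split (\code{stem_woody_t_ha}, \code{bv_green_t_ha}, ...).
#' @export
species_biomass <- function(survey, traits) {
  require_columns(survey, c("plot_id", "species_id", "growth_form",
                            "avg_height_m", "cover_class", "biovolume_m3"),
                  "survey")
  if (nrow(survey) == 0) {
    return(data.frame(plot_id = character(0), species_id = character(0),
                      growth_form = character(0), avg_height_m = numeric(0),
                      aboveground_t_ha = numeric(0), green_t_ha = numeric(0),
                      woody_t_ha = numeric(0), stem_green_t_ha = numeric(0),
                      stem_woody_t_ha = numeric(0), bv_green_t_ha = numeric(0),
                      bv_woody_t_ha = numeric(0), stringsAsFactors = FALSE))
  }
  if (!all(survey$growth_form %in% c("tree", "shrub", "herb"))) {
    stop_invalid("growth_form must be one of tree/shrub/herb")
  }
  check_numeric(survey$avg_height_m, "avg_height_m", min = 0)
  cover_class_midpoint(survey$cover_class)  # validates the scale
  tr <- lookup_traits(survey$species_id, traits)
  dbh_col <- if ("dbh_cm" %in% names(survey)) as.character(survey$dbh_cm) else
    rep("", nrow(survey))
  stem_kg <- vapply(dbh_col, function(s) sum(allometric_tree_biomass_kg(parse_dbh_list(s))),
                    numeric(1), USE.NAMES = FALSE)
  check_numeric(survey$biovolume_m3, "biovolume_m3", min = 0)
  bv_kg <- survey$biovolume_m3 * tr$conv_factor
  k <- KG_PER_PLOT_TO_T_HA
  data.frame(
    plot_id = as.character(survey$plot_id),
    species_id = as.character(survey$species_id),
    growth_form = as.character(survey$growth_form),
    avg_height_m = survey$avg_height_m,
    aboveground_t_ha = (stem_kg + bv_kg) * k,
    green_t_ha = (stem_kg + bv_kg) * tr$green_fraction * k,
    woody_t_ha = (stem_kg + bv_kg) * tr$woody_fraction * k,
    stem_green_t_ha = stem_kg * tr$green_fraction * k,
    stem_woody_t_ha = stem_kg * tr$woody_fraction * k,
    bv_green_t_ha = bv_kg * tr$green_fraction * k,
    bv_woody_t_ha = bv_kg * tr$woody_fraction * k,
    stringsAsFactors = FALSE
  )
}

#' Is a species a higher-quality forage species?
#'
#' Crude protein is the standard tissue N x 6.25; species with green tissue
#' CP:lignin >= 0.8 count as higher-quality forage (the boundary is
#' inclusive).
#'
#' @param n_pct Green tissue N, \% dry mass.
#' @param lignin_pct Green tissue lignin, \% dry mass.
#' @return Logical vector.
#' @export
is_quality_forage <- function(n_pct, lignin_pct) {
  check_numeric(n_pct, "n_pct", min = 0)
  check_numeric(lignin_pct, "lignin_pct", min = 0)
  if (any(lignin_pct == 0)) {
    stop_invalid("CP:lignin ratio undefined for lignin_pct = 0")
  }
  (CP_PER_N * n_pct / lignin_pct) >= CP_LIGNIN_MIN
}

#' Wood biomass indicator (t/ha) per plot
#'
#' The ecosystem-service providers for wood are trees and large shrubs:
#' every measured stem >= 2.5 cm DBH contributes via the allometric
#' equation, and the biovolume-path biomass of woody species with average
#' height >= 0.7 m contributes as well. Herbaceous species and short woody
#' plants provide no useful wood and are excluded. Woody-tissue fractions
#' are applied throughout.
#'
#' @inheritParams species_biomass
#' @return Data frame (\code{plot_id}, \code{wood_t_ha}), one row per plot
#'   present in \code{survey}.
#' @export
wood_biomass <- function(survey, traits) {
  sb <- species_biomass(survey, traits)
  tall_woody <- sb$growth_form %in% c("tree", "shrub") &
    sb$avg_height_m >= WOODY_HEIGHT_MIN_M
  contrib <- sb$stem_woody_t_ha + ifelse(tall_woody, sb$bv_woody_t_ha, 0)
  agg <- rowsum(contrib, group = sb$plot_id)
  data.frame(plot_id = rownames(agg), wood_t_ha = agg[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Forage biomass indicator (t/ha) per plot
#'
#' Forage species are all herbaceous species plus woody species below 0.7 m
#' average height; of these, only higher-quality forage species (green
#' tissue CP:lignin >= 0.8) count toward the indicator. The indicator sums
#' their standing green biomass from the biovolume path (stems >= 2.5 cm are
#' wood, never forage).
#'
#' @inheritParams species_biomass
#' @return Data frame (\code{plot_id}, \code{forage_t_ha}), one row per plot.
#' @export
forage_biomass <- function(survey, traits) {
  sb <- species_biomass(survey, traits)
  tr <- if (nrow(sb) > 0) lookup_traits(sb$species_id, traits) else traits[0, ]
  forage_sp <- sb$growth_form == "herb" |
    (sb$growth_form %in% c("tree", "shrub") & sb$avg_height_m < WOODY_HEIGHT_MIN_M)
  quality <- if (nrow(sb) > 0) is_quality_forage(tr$n_pct, tr$lignin_pct) else logical(0)
  contrib <- ifelse(forage_sp & quality, sb$bv_green_t_ha, 0)
  agg <- rowsum(contrib, group = sb$plot_id)
  data.frame(plot_id = rownames(agg), forage_t_ha = agg[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}
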