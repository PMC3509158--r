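# Plant diversity metrics: the 1% green-biomass abundance filter, species
# richness, community-weighted trait means, and dendrogram-based functional
# diversity (summed UPGMA branch length in standardized ln-trait space).

ABUNDANCE_MIN_SHARE <- 0.01
FD_TRAITS <- c("n_pct", "lignin_pct", "polyphenol_pct")

#' Abundance filter on a community vector
#'
#' Species comprising at least 1\% of a fallow's standing green biomass are
#' retained (inclusive boundary); rarer species disproportionately influence
#' evenness without contributing materially to function.
#'
#' @param green_biomass Named numeric vector of per-species standing green
#'   biomass (t/ha) for one plot.
#' @return Character vector of retained species ids.
#' @export
abundance_filter <- function(green_biomass) {
  check_numeric(green_biomass, "green_biomass", min = 0)
  if (is.null(names(green_biomass))) {
    stop_invalid("green_biomass must be named by species_id")
  }
  total <- sum(green_biomass)
  if (total <= 0) {
    warning("zero total green biomass; abundance filter returns no species")
    return(character(0))
  }
  names(green_biomass)[green_biomass / total >= ABUNDANCE_MIN_SHARE]
}

#' Species richness after the abundance filter
#'
#' @inheritParams abundance_filter
#' @return Count of species with >= 1\% of standing green biomass.
#' @export
species_richness <- function(green_biomass) {
  if (length(green_biomass) == 0) return(0L)
  length(abundance_filter(green_biomass))
}

#' Community-weighted mean of a ln-transformed trait
#'
#' \deqn{\mathrm{CWM} = \sum_i w_i \ln x_i / \sum_i w_i} with weights
#' \eqn{w_i} the species' standing green biomass (within the chosen scope).
#'
#' @param weights Non-negative weights (green biomass, t/ha).
#' @param trait_values Positive trait values, same length.
#' @return Weighted mean of \code{ln(trait)}.
#' @export
community_weighted_mean <- function(weights, trait_values) {
  check_numeric(weights, "weights", min = 0)
  if (length(weights) != length(trait_values)) {
    stop_invalid("weights and trait_values must have equal length")
  }
  if (length(weights) == 0 || sum(weights) <= 0) {
    stop_missing_data("no species with positive weight in scope")
  }
  if (!is.numeric(trait_values) || anyNA(trait_values) || any(trait_values <= 0)) {
    stop_invalid("trait values must be positive for the ln transform")
  }
  sum(weights * log(trait_values)) / sum(weights)
}

#' Standardized ln-trait space for functional diversity
#'
#' Natural-log transforms the three functional traits (green tissue N,
#' lignins, polyphenols) and standardizes each to zero mean and unit SD
#' across the pooled species set of the whole dataset, so that FD is
#' comparable across plots. (Euclidean distances are translation-invariant,
#' so only the unit-SD scaling matters.)
#'
#' @param traits Trait table with \code{species_id} and the three trait
#'   columns.
#' @return Numeric matrix, rows named by species_id, 3 standardized columns.
#' @export
trait_space <- function(traits) {
  require_columns(traits, c("species_id", FD_TRAITS), "trait table")
  m <- as.matrix(traits[, FD_TRAITS])
  if (anyNA(m) || any(m <= 0)) stop_invalid("FD traits must be positive")
  m <- log(m)
  m <- scale(m)
  # A pool with a constant trait (e.g. a single species) has SD 0; that
  # trait then contributes no distance.
  m[, attr(m, "scaled:scale") == 0] <- 0
  rownames(m) <- as.character(traits$species_id)
  m[, , drop = FALSE]
}

# Summed branch length of an average-linkage (UPGMA) dendrogram, with node
# height = merge distance and leaves at height 0.
dendrogram_branch_sum <- function(hc) {
  heights_of <- function(idx) {
    h <- numeric(length(idx))        # leaves (negative entries) sit at 0
    h[idx > 0] <- hc$height[idx[idx > 0]]
    h
  }
  sum(hc$height - heights_of(hc$merge[, 1])) +
    sum(hc$height - heights_of(hc$merge[, 2]))
}

#' Dendrogram functional diversity (FD)
#'
#' FD is the summed branch length of the UPGMA (average linkage) dendrogram
#' built from Euclidean distances among the community's species in
#' standardized ln-trait space. Node heights are the UPGMA merge distances
#' and leaves sit at height 0, so two species at distance d give FD = 2d.
#' FD is 0 for communities of at most one species, and adding a species
#' whose traits duplicate an included species leaves FD unchanged (its merge
#' has zero height).
#'
#' Species occupying the same point in trait space are collapsed to one
#' leaf before clustering: a trait-identical twin would merge at height 0
#' and add no branch length, but under leaf-count-weighted UPGMA it would
#' still reweight later merges; collapsing makes the zero-length-merge
#' invariance exact.
#'
#' @param species Character vector of species ids in the community (already
#'   abundance-filtered; duplicates are collapsed).
#' @param space Standardized trait matrix from \code{\link{trait_space}}.
#' @return FD, a non-negative scalar.
#' @export
functional_diversity <- function(species, space) {
  species <- unique(as.character(species))
  missing <- setdiff(species, rownames(space))
  if (length(missing) > 0) stop_missing_trait(missing)
  pts <- unique(space[species, , drop = FALSE])
  if (nrow(pts) <= 1) return(0)
  hc <- stats::hclust(stats::dist(pts, method = "euclidean"),
                      method = "average")
  dendrogram_branch_sum(hc)
}

#' Per-plot green biomass community vectors
#'
#' @param biomass Output of \code{\link{species_biomass}}.
#' @return Named list (by plot) of named vectors of per-species standing
#'   green biomass (t/ha).
#' @export
community_vectors <- function(biomass) {
  lapply(split(biomass, biomass$plot_id), function(df) {
    v <- rowsum(df$green_t_ha, group = df$species_id)
    stats::setNames(v[, 1], rownames(v))
  })
}

cwm_scope_rows <- function(biomass, traits, scope) {
  tr <- lookup_traits(biomass$species_id, traits)
  switch(scope,
    all = rep(TRUE, nrow(biomass)),
    trees_shrubs = biomass$growth_form %in% c("tree", "shrub") &
      biomass$avg_height_m >= WOODY_HEIGHT_MIN_M,
    forage = (biomass$growth_form == "herb" |
                (biomass$growth_form %in% c("tree", "shrub") &
                   biomass$avg_height_m < WOODY_HEIGHT_MIN_M)) &
      is_quality_forage(tr$n_pct, tr$lignin_pct),
    stop_invalid("unknown CWM scope '", scope, "'")
  )
}

#' Per-plot diversity and trait metrics
#'
#' Computes, for every plot in the survey: abundance-filtered species
#' richness, dendrogram FD, community-weighted means (ln scale) of the three
#' traits over all species, and group-weighted means for trees/large shrubs
#' and for higher-quality forage species (NA when the group is absent).
#'
#' @inheritParams species_biomass
#' @param cwm_filtered If \code{TRUE}, restrict CWM weights to the >= 1\%
#'   species set; default uses all species (the filter is explicit only for
#'   richness and FD).
#' @return Data frame, one row per plot.
#' @export
diversity_metrics <- function(survey, traits, cwm_filtered = FALSE) {
  sb <- species_biomass(survey, traits)
  space <- trait_space(traits)
  comms <- community_vectors(sb)
  per_plot <- lapply(names(comms), function(pid) {
    gb <- comms[[pid]]
    kept <- if (sum(gb) > 0) abundance_filter(gb) else character(0)
    rows <- sb[sb$plot_id == pid, , drop = FALSE]
    cwm_rows <- if (cwm_filtered) rows[rows$species_id %in% kept, , drop = FALSE] else rows
    tr <- lookup_traits(cwm_rows$species_id, traits)
    cwm_one <- function(trait, keep) {
      w <- cwm_rows$green_t_ha[keep]
      if (length(w) == 0 || sum(w) <= 0) return(NA_real_)
      community_weighted_mean(w, tr[[trait]][keep])
    }
    scope_all <- cwm_scope_rows(cwm_rows, traits, "all")
    scope_ts <- cwm_scope_rows(cwm_rows, traits, "trees_shrubs")
    scope_fo <- cwm_scope_rows(cwm_rows, traits, "forage")
    data.frame(
      plot_id = pid,
      richness = length(kept),
      fd = if (length(kept) > 1) functional_diversity(kept, space) else 0,
      cwm_n = cwm_one("n_pct", scope_all),
      cwm_lignin = cwm_one("lignin_pct", scope_all),
      cwm_polyphenol = cwm_one("polyphenol_pct", scope_all),
      ts_cwm_n = cwm_one("n_pct", scope_ts),
      ts_cwm_lignin = cwm_one("lignin_pct", scope_ts),
      ts_cwm_polyphenol = cwm_one("polyphenol_pct", scope_ts),
      forage_cwm_n = cwm_one("n_pct", scope_fo),
      forage_cwm_lignin = cwm_one("lignin_pct", scope_fo),
      forage_cwm_polyphenol = cwm_one("polyphenol_pct", scope_fo),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, per_plot)
}
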