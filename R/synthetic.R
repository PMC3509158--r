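# Seeded synthetic fallow datasets with the statistical structure the
# analysis assumes: 18 grazed fallows (species-rich, graded grazing) and 21
# improved fallows (dominated by 1-3 planted woody legumes), calibrated so
# that the four ecosystem functions computed by the full downstream pipeline
# match stated per-type means and SDs.
#
# Construction is "inverse": per-plot raw function targets are drawn from
# gamma margins moment-matched to the calibration table, with a Gaussian
# copula planting the diversity (grazed) and soil-carbon (improved)
# dependence; survey, soil and infiltration records are then built to
# realize those targets through the package's own estimators.

default_calibration <- function() {
  data.frame(
    fallow_type = rep(c("grazed", "improved"), each = 4),
    fn = rep(c("wood", "forage", "cations", "infiltration"), 2),
    mean = c(3.0, 2.4, 4.8, 261.8, 24.2, 1.7, 3.7, 371.0),
    sd = c(3.3, 1.2, 2.2, 198.1, 5.9, 1.1, 1.2, 148.1),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic fallow generator
#'
#' Defaults state the study world: 18 grazed and 21 improved fallows, a
#' pool of 45 species, calibration targets equal to the published per-type
#' means and SDs of the four ecosystem functions, a planted
#' diversity-multifunctionality dependence in grazed fallows and a
#' soil-carbon dependence in improved fallows.
#'
#' @param n_grazed,n_improved Plot counts (>= 0, total >= 1).
#' @param species_pool_size Size of the species pool behind the trait table.
#' @param effect_fd_grazed Latent-scale slope tying grazed function values
#'   to standardized realized functional diversity (0 = no diversity
#'   effect).
#' @param effect_soc_improved Same, tying improved function values to
#'   standardized soil organic carbon.
#' @param noise_sd Latent residual SD; the latent correlate is
#'   \code{(effect*z + noise_sd*eps)} standardized, so the implied
#'   function-covariate correlation is \code{effect/sqrt(effect^2 +
#'   noise_sd^2)}.
#' @param horton_params List with \code{f0_range}, \code{fc_range} (mm/hr),
#'   \code{k_range} (1/min) and curve \code{noise_sd} (mm/hr).
#' @param calibration_targets Data frame (\code{fallow_type}, \code{fn},
#'   \code{mean}, \code{sd}) on the raw function scales.
#' @param seed Integer seed; same seed, same config gives an identical
#'   dataset.
#' @return A validated list of class \code{generator_config}.
#' @export
generator_config <- function(n_grazed = 18, n_improved = 21,
                             species_pool_size = 45,
                             effect_fd_grazed = 0.5,
                             effect_soc_improved = 0.5,
                             noise_sd = sqrt(1 - 0.5^2),
                             horton_params = list(
                               f0_range = c(250, 900),
                               fc_range = c(1, 700),
                               k_range = c(0.03, 0.08),
                               noise_sd = 10),
                             calibration_targets = default_calibration(),
                             seed = 1L) {
  cfg <- list(n_grazed = n_grazed, n_improved = n_improved,
              species_pool_size = species_pool_size,
              effect_fd_grazed = effect_fd_grazed,
              effect_soc_improved = effect_soc_improved,
              noise_sd = noise_sd, horton_params = horton_params,
              calibration_targets = calibration_targets,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_grazed < 0 || cfg$n_improved < 0 ||
      cfg$n_grazed + cfg$n_improved < 1) {
    stop_invalid("plot counts must be >= 0 with at least one plot in total")
  }
  if (cfg$species_pool_size < 8) {
    stop_invalid("species pool must hold >= 8 species (trees, shrubs, herbs)")
  }
  if (cfg$noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  hp <- cfg$horton_params
  if (any(hp$fc_range > hp$f0_range)) {
    stop_invalid("unsatisfiable calibration: fc range exceeds f0 range")
  }
  if (any(hp$k_range <= 0) || hp$noise_sd < 0) {
    stop_invalid("Horton parameter ranges must be positive")
  }
  ct <- cfg$calibration_targets
  require_columns(ct, c("fallow_type", "fn", "mean", "sd"),
                  "calibration_targets")
  if (any(ct$mean <= 0) || any(ct$sd <= 0)) {
    stop_invalid("calibration means and SDs must be positive")
  }
  invisible(cfg)
}

#' Generate a species trait table
#'
#' Draws a pool of tree, shrub and herb species with log-normal green-tissue
#' chemistry (N, lignins, polyphenols; mutually independent across species,
#' mirroring the near-zero trait correlations in the field data),
#' growth-form-typical green/woody biomass fractions and biovolume
#' conversion factors. The first few tree species stand in for the planted
#' woody legumes of improved fallows.
#'
#' @param n_species Pool size, >= 1.
#' @param seed Integer seed, or \code{NULL} to consume the current RNG
#'   stream.
#' @return Trait data frame keyed by \code{species_id}.
#' @export
generate_trait_table <- function(n_species, seed = NULL) {
  if (!is.numeric(n_species) || n_species < 1) {
    stop_invalid("n_species must be >= 1")
  }
  n_species <- as.integer(n_species)
  with_seed(seed, {
    n_tree <- min(ceiling(0.30 * n_species), n_species)
    n_shrub <- min(ceiling(0.20 * n_species), n_species - n_tree)
    n_herb <- n_species - n_tree - n_shrub
    form <- c(rep("tree", n_tree), rep("shrub", n_shrub), rep("herb", n_herb))

    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    n_pct <- clip(stats::rlnorm(n_species, log(2.0), 0.40), 0.5, 5)
    lignin_pct <- clip(stats::rlnorm(n_species, log(9.0), 0.50), 2, 25)
    polyphenol_pct <- clip(stats::rlnorm(n_species, log(2.5), 0.50), 0.5, 10)

    woody_fraction <- ifelse(form == "tree", stats::runif(n_species, 0.45, 0.65),
                      ifelse(form == "shrub", stats::runif(n_species, 0.35, 0.55),
                             0))
    green_draw <- ifelse(form == "herb", stats::runif(n_species, 0.75, 0.95),
                  ifelse(form == "tree", stats::runif(n_species, 0.25, 0.45),
                         stats::runif(n_species, 0.35, 0.55)))
    green_fraction <- pmin(green_draw, 1 - woody_fraction)
    conv_factor <- ifelse(form == "tree", stats::runif(n_species, 15, 40),
                   ifelse(form == "shrub", stats::runif(n_species, 8, 25),
                          stats::runif(n_species, 1.5, 6)))
    data.frame(
      species_id = sprintf("sp%03d", seq_len(n_species)),
      growth_form = form,
      n_pct = n_pct, lignin_pct = lignin_pct,
      polyphenol_pct = polyphenol_pct,
      green_fraction = green_fraction, woody_fraction = woody_fraction,
      conv_factor = conv_factor,
      forage_known = NA,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate one noisy Horton infiltration curve
#'
#' Rates are \eqn{f_c + (f_0 - f_c)e^{-kt}} plus Gaussian measurement noise,
#' floored at zero.
#'
#' @param f0,fc Initial and steady rates, mm/hr, \code{f0 >= fc > 0}.
#' @param k Decay rate, 1/min, > 0.
#' @param times Measurement times in minutes, increasing, within about 150
#'   minutes (a ~2.5 hr run).
#' @param noise_sd Measurement noise SD, mm/hr.
#' @param seed Seed or \code{NULL}.
#' @return Data frame (\code{time_min}, \code{rate_mm_hr}).
#' @export
generate_infiltration_curve <- function(f0, fc, k,
                                        times = default_infiltration_times(),
                                        noise_sd = 0, seed = NULL) {
  if (fc <= 0 || f0 < fc) stop_invalid("need f0 >= fc > 0")
  if (k <= 0) stop_invalid("k must be > 0")
  if (is.unsorted(times) || any(times < 0) || max(times) > 160) {
    stop_invalid("times must be increasing and within a ~2.5 hr run")
  }
  check_numeric(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    mu <- horton_rates(f0, fc, k, times)
    noise <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
    data.frame(time_min = times, rate_mm_hr = pmax(mu + noise, 0))
  })
}

horton_rates <- function(f0, fc, k, times) {
  fc + (f0 - fc) * exp(-k * times)
}

#' @rdname generate_infiltration_curve
#' @export
default_infiltration_times <- function() {
  c(1, 2.5, 5, 7.5, 10, 15, 20, 30, 45, 60, 75, 90, 105, 120, 135, 150)
}

# Dirichlet draw via gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(alpha))
  g / sum(g)
}

calib_lookup <- function(ct, type, fn) {
  row <- ct[ct$fallow_type == type & ct$fn == fn, ]
  if (nrow(row) != 1) {
    stop_invalid("calibration_targets must hold exactly one row for ",
                 type, "/", fn)
  }
  row
}

# Gamma margin moment-matched to (mean, sd), evaluated at copula quantile u.
gamma_target <- function(u, mean, sd) {
  shape <- (mean / sd)^2
  stats::qgamma(u, shape = shape, rate = mean / sd^2)
}

# Latent copula correlate: standardized effect*z + noise_sd*eps.
latent_quantile <- function(z, effect, noise_sd, n) {
  eps <- stats::rnorm(n)
  denom <- sqrt(effect^2 + noise_sd^2)
  lat <- if (denom > 0) (effect * z + noise_sd * eps) / denom else eps
  stats::pnorm(lat)
}

#' Generate a complete synthetic fallow dataset
#'
#' Builds plot communities (improved: 1-3 dominant planted woody legumes
#' holding at least ~80\% of green biomass plus a sparse understory; grazed:
#' 5-15 mostly native species with uneven Dirichlet abundances and graded
#' grazing classes with the moderate class over-represented), then draws the
#' four raw ecosystem-function targets per plot from gamma margins
#' moment-matched to the calibration table, tied by a Gaussian copula to
#' realized functional diversity (grazed) or soil organic carbon (improved),
#' and finally constructs survey records (allometric stems plus biovolume),
#' two soil subplots x two layers, and two noisy Horton infiltration curves
#' per plot that realize those targets through the package's own estimators.
#'
#' @param config A \code{\link{generator_config}}.
#' @return A \code{fallow_dataset}: list with \code{plots}, \code{survey},
#'   \code{traits}, \code{soils}, \code{infiltration}, \code{provenance}.
#' @export
generate_fallow_survey <- function(config = generator_config()) {
  validate_generator_config(config)
  with_seed(config$seed, build_fallow_dataset(config))
}

build_fallow_dataset <- function(config) {
  traits <- generate_trait_table(config$species_pool_size, seed = NULL)
  trees <- traits$species_id[traits$growth_form == "tree"]
  shrubs <- traits$species_id[traits$growth_form == "shrub"]
  herbs <- traits$species_id[traits$growth_form == "herb"]
  quality_herb <- herbs[is_quality_forage(
    traits$n_pct[match(herbs, traits$species_id)],
    traits$lignin_pct[match(herbs, traits$species_id)])]
  if (length(trees) < 1 || length(quality_herb) < 2) {
    stop_invalid("species pool too small to field both fallow types")
  }
  legumes <- trees[seq_len(min(4, length(trees)))]  # the planted species
  space <- trait_space(traits)

  n_total <- config$n_grazed + config$n_improved
  types <- c(rep("grazed", config$n_grazed), rep("improved", config$n_improved))
  plot_ids <- sprintf("%s%02d", ifelse(types == "grazed", "G", "I"),
                      unlist(lapply(split(seq_len(n_total), types)[unique(types)],
                                    seq_along)))

  # ---- Phase A: community structure --------------------------------------
  comm <- vector("list", n_total)
  grazing_class <- rep(NA_integer_, n_total)
  for (i in seq_len(n_total)) {
    if (types[i] == "grazed") {
      s <- sample(5:15, 1)
      n_woody <- max(1L, min(stats::rbinom(1, s, 0.35), length(trees) + length(shrubs)))
      n_herb <- max(2L, s - n_woody)
      woody_sp <- sample(c(trees, shrubs), n_woody)
      herb_sp <- unique(c(sample(quality_herb, min(2, length(quality_herb))),
                          sample(herbs, min(n_herb, length(herbs)))))[seq_len(min(n_herb, length(herbs)))]
      sp <- c(woody_sp, herb_sp)
      share <- rdirichlet1(rep(0.7, length(sp)))
      grazing_class[i] <- sample(2:5, 1, prob = c(0.12, 0.18, 0.45, 0.25))
      dominants <- character(0)
    } else {
      n_dom <- sample(1:3, 1)
      dominants <- sample(legumes, n_dom)
      n_minor <- sample(2:5, 1)
      minors <- unique(c(sample(quality_herb, 1),
                         sample(c(shrubs, herbs), n_minor)))
      sp <- c(dominants, minors)
      dom_mass <- stats::runif(1, 0.85, 0.97)
      share <- c(dom_mass * rdirichlet1(rep(2, n_dom)),
                 (1 - dom_mass) * rdirichlet1(rep(1, length(minors))))
    }
    comm[[i]] <- list(species = sp, share = share, dominants = dominants)
  }

  # ---- Phase B: realized diversity of the provisional communities --------
  fd <- vapply(seq_len(n_total), function(i) {
    gb <- stats::setNames(comm[[i]]$share, comm[[i]]$species)
    functional_diversity(abundance_filter(gb), space)
  }, numeric(1))

  # ---- Phase C: environmental covariates ---------------------------------
  soc_frac <- ifelse(types == "grazed",
                     pmax(stats::rnorm(n_total, 0.015, 0.004), 0.004),
                     pmax(stats::rnorm(n_total, 0.020, 0.005), 0.004))
  sand_pct <- pmin(pmax(ifelse(types == "grazed",
                               stats::rnorm(n_total, 58, 8),
                               stats::rnorm(n_total, 48, 8)), 15), 92)

  # ---- Phase D: function targets through the copula ----------------------
  standardize <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  targets <- matrix(NA_real_, n_total, 4,
                    dimnames = list(NULL, FUNCTION_KINDS))
  for (type in unique(types)) {
    rows <- which(types == type)
    z <- if (type == "grazed") standardize(fd[rows]) else standardize(soc_frac[rows])
    effect <- if (type == "grazed") config$effect_fd_grazed else config$effect_soc_improved
    for (fn in FUNCTION_KINDS) {
      cal <- calib_lookup(config$calibration_targets, type, fn)
      u <- latent_quantile(z, effect, config$noise_sd, length(rows))
      targets[rows, fn] <- gamma_target(u, cal$mean, cal$sd)
    }
  }
  # graded grazing suppresses wood in the heavily grazed class
  gmult <- c(`2` = 1.4, `3` = 1.4, `4` = 1.0, `5` = 0.6)
  gz <- types == "grazed"
  targets[gz, "wood"] <- targets[gz, "wood"] * gmult[as.character(grazing_class[gz])]
  targets[, "cations"] <- pmin(targets[, "cations"], 85)  # asin headroom at subplots

  # ---- Phase E: realize records ------------------------------------------
  # Records accumulate in plain vectors (one data.frame at the end); per-row
  # data.frame construction dominated runtime at simulation scale.
  hp <- config$horton_params
  survey_acc <- list(plot_id = list(), species_id = list(), growth_form = list(),
                     avg_height_m = list(), cover_class = list(),
                     dbh_cm = list(), biovolume_m3 = list())
  soil_acc <- list(plot_id = list(), subplot = list(), layer = list(),
                   soc_pct = list(), mg = list(), ca = list(), k = list(),
                   sand_pct = list())
  infil_acc <- list(plot_id = list(), subplot = list(), time_min = list(),
                    rate_mm_hr = list())
  times <- default_infiltration_times()
  tr_at <- function(sp) traits[match(sp, traits$species_id), ]

  for (i in seq_len(n_total)) {
    pid <- plot_ids[i]
    sp <- comm[[i]]$species
    share <- comm[[i]]$share
    tr <- tr_at(sp)
    woody <- tr$growth_form %in% c("tree", "shrub")
    # heights: dominant legumes tall; shrubs occasionally short (sub-0.7 m)
    height <- numeric(length(sp))
    height[tr$growth_form == "tree"] <- stats::runif(sum(tr$growth_form == "tree"),
                                                     if (types[i] == "improved") 3 else 1.5, 8)
    is_shrub <- tr$growth_form == "shrub"
    height[is_shrub] <- ifelse(stats::runif(sum(is_shrub)) < 0.25,
                               stats::runif(sum(is_shrub), 0.2, 0.65),
                               stats::runif(sum(is_shrub), 0.8, 2.5))
    height[tr$growth_form == "herb"] <- stats::runif(sum(tr$growth_form == "herb"),
                                                     0.1, 1.2)

    wood_esp <- woody & height >= WOODY_HEIGHT_MIN_M
    forage_sp <- tr$growth_form == "herb" | (woody & height < WOODY_HEIGHT_MIN_M)
    quality <- is_quality_forage(tr$n_pct, tr$lignin_pct)

    W <- targets[i, "wood"]
    F_t <- targets[i, "forage"]

    woody_t_ha <- numeric(length(sp))   # woody biomass target per species
    green_t_ha <- numeric(length(sp))   # green biomass target per species
    if (any(wood_esp)) {
      wshare <- share[wood_esp] / sum(share[wood_esp])
      woody_t_ha[wood_esp] <- W * wshare
      green_t_ha[wood_esp] <- woody_t_ha[wood_esp] *
        tr$green_fraction[wood_esp] / pmax(tr$woody_fraction[wood_esp], 0.05)
    }
    fq <- forage_sp & quality
    if (any(fq)) {
      qshare <- share[fq] / sum(share[fq])
      green_t_ha[fq] <- F_t * qshare
    }
    fnq <- forage_sp & !quality
    if (any(fnq)) {
      green_t_ha[fnq] <- stats::runif(sum(fnq), 0.05, 0.25) * max(F_t, 0.2)
    }

    if (types[i] == "improved" && length(comm[[i]]$dominants) > 0) {
      # keep the planted legumes at >= ~80% of standing green biomass;
      # woody targets shrink with green to preserve tissue-fraction ratios
      dom <- sp %in% comm[[i]]$dominants
      dom_green <- sum(green_t_ha[dom])
      rest <- sum(green_t_ha[!dom])
      if (dom_green > 0 && rest > 0.22 * dom_green) {
        f <- 0.22 * dom_green / rest
        green_t_ha[!dom] <- green_t_ha[!dom] * f
        woody_t_ha[!dom] <- woody_t_ha[!dom] * f
      }
    }

    # split woody targets into allometric stems + biovolume remainder
    dbh_str <- character(length(sp))
    bv_m3 <- numeric(length(sp))
    for (j in seq_along(sp)) {
      stem_woody <- 0
      if (wood_esp[j] && tr$growth_form[j] == "tree" && woody_t_ha[j] > 0.3) {
        p_stem <- stats::runif(1, 0.3, 0.7)
        dbhs <- numeric(0)
        while (stem_woody < p_stem * woody_t_ha[j] && length(dbhs) < 25) {
          d <- stats::runif(1, if (types[i] == "improved") 5 else 3, 16)
          add <- allometric_tree_biomass_kg(d) * tr$woody_fraction[j] *
            KG_PER_PLOT_TO_T_HA
          if (stem_woody + add > woody_t_ha[j]) break  # never overshoot target
          dbhs <- c(dbhs, d)
          stem_woody <- stem_woody + add
        }
        dbh_str[j] <- paste(sprintf("%.2f", dbhs), collapse = ";")
      }
      # biovolume path carries the rest of the biomass
      if (wood_esp[j]) {
        rem_woody <- max(woody_t_ha[j] - stem_woody, 0)
        ag_kg <- rem_woody * 10 / pmax(tr$woody_fraction[j], 0.05)
      } else {
        ag_kg <- green_t_ha[j] * 10 / pmax(tr$green_fraction[j], 0.05)
      }
      bv_m3[j] <- ag_kg / tr$conv_factor[j]
    }

    gshare <- green_t_ha / max(sum(green_t_ha), 1e-9)
    cc <- findInterval(gshare, c(0.04, 0.15, 0.40, 0.65)) + 1L
    survey_acc$plot_id[[i]] <- rep(pid, length(sp))
    survey_acc$species_id[[i]] <- sp
    survey_acc$growth_form[[i]] <- tr$growth_form
    survey_acc$avg_height_m[[i]] <- round(height, 2)
    survey_acc$cover_class[[i]] <- cc
    survey_acc$dbh_cm[[i]] <- dbh_str
    survey_acc$biovolume_m3[[i]] <- bv_m3

    # soils: 2 subplots x 2 layers; subplot pairs symmetric about the target
    C <- targets[i, "cations"]
    dC <- stats::runif(1, 0, 0.08); dS <- stats::runif(1, 0, 0.08)
    split3 <- rdirichlet1(c(35, 52, 13))  # mg/ca/k proportions
    soc_pct <- soc_frac[i] * 100
    bc_sub <- C * (1 + c(1, 1, -1, -1) * dC) * c(1, 0.8, 1, 0.8)
    soc_sub <- soc_pct * (1 + c(1, 1, -1, -1) * dS) * c(1, 0.55, 1, 0.55)
    soil_acc$plot_id[[i]] <- rep(pid, 4)
    soil_acc$subplot[[i]] <- c("center", "center", "edge", "edge")
    soil_acc$layer[[i]] <- c("topsoil", "subsoil", "topsoil", "subsoil")
    soil_acc$soc_pct[[i]] <- soc_sub
    soil_acc$mg[[i]] <- bc_sub * split3[1]
    soil_acc$ca[[i]] <- bc_sub * split3[2]
    soil_acc$k[[i]] <- bc_sub * split3[3]
    soil_acc$sand_pct[[i]] <- pmin(rep(c(sand_pct[i], sand_pct[i] + 4), 2), 95)

    # infiltration: 2 subplot curves whose fitted asymptotes average to target
    fc_plot <- min(max(targets[i, "infiltration"], hp$fc_range[1]), hp$fc_range[2])
    dI <- stats::runif(1, 0, 0.05)
    fc_sub <- fc_plot * (1 + c(1, -1) * dI)
    f0 <- pmax(stats::runif(2, hp$f0_range[1], hp$f0_range[2]),
               fc_sub * 1.15 + 40)
    k <- stats::runif(2, hp$k_range[1], hp$k_range[2])
    rates <- c(horton_rates(f0[1], fc_sub[1], k[1], times),
               horton_rates(f0[2], fc_sub[2], k[2], times))
    if (hp$noise_sd > 0) {
      rates <- pmax(rates + stats::rnorm(length(rates), 0, hp$noise_sd), 0)
    }
    infil_acc$plot_id[[i]] <- rep(pid, 2 * length(times))
    infil_acc$subplot[[i]] <- rep(c("center", "edge"), each = length(times))
    infil_acc$time_min[[i]] <- rep(times, 2)
    infil_acc$rate_mm_hr[[i]] <- rates
  }
  flatten <- function(acc) {
    data.frame(lapply(acc, function(col) unlist(col, use.names = FALSE)),
               stringsAsFactors = FALSE)
  }

  plots <- data.frame(
    plot_id = plot_ids, fallow_type = types,
    grazing_class = grazing_class,
    grazing_group = ifelse(is.na(grazing_class), NA_character_,
                    ifelse(grazing_class <= 3, "light",
                    ifelse(grazing_class == 4, "moderate", "heavy"))),
    year = rep_len(c(2008L, 2009L), n_total),
    stringsAsFactors = FALSE)

  structure(list(
    plots = plots,
    survey = flatten(survey_acc),
    traits = traits,
    soils = flatten(soil_acc),
    infiltration = flatten(infil_acc),
    provenance = list(config = unclass(config), seed = config$seed,
                      generator = paste0("fallowfun ",
                                         as.character(utils::packageVersion("fallowfun"))))
  ), class = "fallow_dataset")
}

#' @export
print.fallow_dataset <- function(x, ...) {
  cat("Synthetic fallow dataset\n")
  tab <- table(x$plots$fallow_type)
  cat("  plots:", paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), "\n")
  cat("  species pool:", nrow(x$traits), "| survey records:", nrow(x$survey), "\n")
  cat("  soil rows:", nrow(x$soils), "| infiltration points:",
      nrow(x$infiltration), "\n")
  cat("  seed:", x$provenance$seed, "\n")
  invisible(x)
}
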