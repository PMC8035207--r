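#' @title Synthetic two-census plot networks with known ground truth
#' @description Generates census, plot, trait, climate, phylogeny and
#'   forest-cover tables from a parameterized stochastic forest model, so
#'   that every downstream estimator has a parameter-recovery test surface.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Ground-truth parameters of the synthetic plot network. Defaults describe
#' a realistic montane-forest monitoring network: one-hectare plots spread
#' over a 500-3500 m elevation gradient, ~450 stems (>= 10 cm DBH) per plot,
#' decade-long census intervals, interval mortality of roughly 8% governed
#' by `logit(P) = mortality_intercept + mortality_slope * DBH`, median
#' diameter growth of 0.3 cm per year, and recruitment of 1.5 stems per ha
#' per year (a slowly self-thinning, growth-dominated carbon sink).
#'
#' @param n_plots number of plots.
#' @param plot_area_ha plot area, ha (> 0).
#' @param elevation_range plot elevation span, m asl (within 500-3600).
#' @param latitude_range plot latitude span, decimal degrees (south
#'   negative).
#' @param n_species_pool size of the regional species pool.
#' @param stems_per_plot first-census stems >= 10 cm DBH per plot (>= 86 so
#'   that rarefaction at 86 stems is defined).
#' @param census_interval_years interval between the two censuses, years.
#' @param mortality_intercept,mortality_slope `a` and `beta` of the
#'   per-interval death logit (logit units; slope per cm DBH).
#' @param growth_mean,growth_sd annual diameter increment distribution of
#'   survivors, cm per year (truncated to plausible rates).
#' @param recruit_rate recruitment, stems per ha per year.
#' @param thermo_drift expected thermophilization rate injected into the
#'   community, degrees C per year (see [generate_census_pair()]).
#' @param height_measured_frac fraction of stems with measured heights.
#' @param niche_breadth thermal niche width (Gaussian SD, degrees C) used
#'   when sampling species along the elevation gradient.
#' @param lapse_rate temperature lapse, degrees C per km of elevation.
#' @param mat_sea_level mean annual temperature extrapolated to sea level,
#'   degrees C.
#' @param prop_ecm probability that a genus is ectomycorrhizal (0 gives an
#'   all-AM pool).
#' @param dbh_scale mean excess of the truncated-exponential first-census
#'   DBH distribution above 10 cm, cm.
#' @param max_dbh truncation point of the DBH distribution, cm.
#' @param seed integer seed; identical configurations reproduce outputs
#'   byte for byte.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_plots = 12, plot_area_ha = 1,
                       elevation_range = c(500, 3500),
                       latitude_range = c(-27.8, 7.1),
                       n_species_pool = 150, stems_per_plot = 450,
                       census_interval_years = 10,
                       mortality_intercept = -2.5, mortality_slope = 0,
                       growth_mean = 0.3, growth_sd = 0.2,
                       recruit_rate = 1.5, thermo_drift = 0,
                       height_measured_frac = 0.6, niche_breadth = 2.5,
                       lapse_rate = -5.5, mat_sea_level = 28,
                       prop_ecm = 0.15, dbh_scale = 12, max_dbh = 150,
                       seed = 1) {
  cfg <- as.list(environment())
  if (length(cfg$elevation_range) != 2 || cfg$elevation_range[1] < 500 ||
      cfg$elevation_range[2] > 3600 || diff(cfg$elevation_range) <= 0) {
    stop("elevation_range must be increasing and within [500, 3600] m")
  }
  if (cfg$stems_per_plot < 86) {
    stop("stems_per_plot must be >= 86 (rarefaction depth)")
  }
  if (cfg$plot_area_ha <= 0) stop("plot_area_ha must be positive")
  if (cfg$census_interval_years <= 0) {
    stop("census_interval_years must be positive")
  }
  if (cfg$prop_ecm < 0 || cfg$prop_ecm > 1) stop("prop_ecm must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_plots, " plots x ", x$stems_per_plot, " stems, ",
      x$elevation_range[1], "-", x$elevation_range[2], " m, t = ",
      x$census_interval_years, " y, seed = ", x$seed, "\n",
      "  mortality logit = ", x$mortality_intercept, " + ",
      x$mortality_slope, " * DBH;  drift = ", x$thermo_drift, " C/y\n",
      sep = "")
  invisible(x)
}

.mat_at <- function(config, elevation) {
  config$mat_sea_level + config$lapse_rate * elevation / 1000
}

# true canopy allometry used by the generator (Michaelis-Menten, canopy
# stature decreasing with elevation)
.true_height <- function(dbh, elevation) {
  c0 <- 33 - 0.0045 * elevation
  c0 * dbh / (15 + dbh)
}

#' Generate the regional species pool
#'
#' Builds the species-trait table (wood density, thermal optimum,
#' genus-level mycorrhizal type) and an ultrametric pure-birth phylogeny
#' whose tips are the species ids. Thermal optima span the temperature range
#' of the elevation gradient; wood densities are drawn from a truncated
#' normal within (0.1, 1.2) g cm^-3.
#'
#' @param config a [sim_config()].
#' @return list: `traits` (data frame with `species`, `genus`, `family`,
#'   `wd_g_cm3`, `thermal_optimum_c`, `mycorrhiza`), `phylogeny`
#'   ([ape::phylo]), `newick` (string).
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_species_pool
  if (n < 2) stop("n_species_pool must be at least 2")
  set.seed(config$seed)
  species <- sprintf("sp%03d", seq_len(n))
  genus <- sprintf("gen%03d", (seq_len(n) - 1) %/% 3 + 1)
  family <- sprintf("fam%02d", (match(genus, unique(genus)) - 1) %/% 4 + 1)
  wd <- pmin(pmax(stats::rnorm(n, 0.58, 0.15), 0.15), 1.1)
  mat_warm <- .mat_at(config, config$elevation_range[1])
  mat_cold <- .mat_at(config, config$elevation_range[2])
  optimum <- stats::runif(n, mat_cold - 1, mat_warm + 1)
  genera <- unique(genus)
  gtype <- ifelse(stats::runif(length(genera)) < config$prop_ecm, "EcM", "AM")
  traits <- data.frame(species = species, genus = genus, family = family,
                       wd_g_cm3 = wd, thermal_optimum_c = optimum,
                       mycorrhiza = gtype[match(genus, genera)],
                       stringsAsFactors = FALSE)
  tree <- ape::rphylo(n, birth = 0.15, death = 0)
  tree$tip.label <- species[as.integer(sub("^t", "", tree$tip.label))]
  list(traits = traits, phylogeny = tree, newick = ape::write.tree(tree))
}

#' Genus-level mycorrhizal table from a trait table
#'
#' @param traits trait table with `genus` and `mycorrhiza` columns.
#' @return data frame with `taxon`, `rank`, `type` suitable for [sra()].
#' @export
myco_table_from_traits <- function(traits) {
  g <- unique(traits[c("genus", "mycorrhiza")])
  if (anyDuplicated(g$genus)) stop("inconsistent mycorrhizal type within genus")
  data.frame(taxon = g$genus, rank = "genus", type = g$mycorrhiza,
             stringsAsFactors = FALSE)
}

# Solve for the warm-biased survival strength s such that the expected
# basal-area-weighted CTI moves by drift * t over the interval. Death logit:
# a + beta * DBH - s * (optimum - CTI1); pivoting on the community's own
# CTI (not the site temperature) guarantees that strong selection always
# moves the weighted mean upward. Recruits enter at the shifted kernel mean
# with the basal area of an 11-cm stem.
.solve_drift_strength <- function(dbh, opt, mat, config, pool_optima) {
  drift <- config$thermo_drift
  if (drift == 0) return(list(s = 0, pivot = 0))
  t <- config$census_interval_years
  ba <- (dbh / 2)^2  # pi cancels throughout
  cti1 <- sum(ba * opt) / sum(ba)
  target <- cti1 + drift * t
  n_rec <- config$recruit_rate * config$plot_area_ha * t
  ba_rec <- (11 / 2)^2
  w <- stats::dnorm(pool_optima, mat + drift * t, config$niche_breadth) + 1e-12
  rec_opt_mean <- sum(w * pool_optima) / sum(w)
  f <- function(s) {
    p <- stats::plogis(config$mortality_intercept +
                         config$mortality_slope * dbh - s * (opt - cti1))
    num <- sum((1 - p) * ba * opt) + n_rec * ba_rec * rec_opt_mean
    den <- sum((1 - p) * ba) + n_rec * ba_rec
    num / den - target
  }
  s <- tryCatch(stats::uniroot(f, c(-25, 25), tol = 1e-8)$root,
                error = function(e) NA_real_)
  if (is.na(s)) {
    warning("requested thermophilization drift not attainable; ",
            "using boundary selectivity")
    s <- if (f(25) < 0) 25 else -25
  }
  list(s = s, pivot = cti1)
}

# simulate one plot's two censuses; returns a census data frame
.simulate_plot <- function(config, pool, plot_id, elevation, date1) {
  tr <- pool$traits
  nsp <- nrow(tr)
  t <- config$census_interval_years
  n0 <- config$stems_per_plot
  mat <- .mat_at(config, elevation)
  kern <- stats::dnorm(tr$thermal_optimum_c, mat, config$niche_breadth) + 1e-12

  sp1 <- sample.int(nsp, n0, replace = TRUE, prob = kern)
  u <- stats::runif(n0)
  rate <- 1 / config$dbh_scale
  dbh1 <- 10 + stats::qexp(u * stats::pexp(config$max_dbh - 10, rate), rate)
  opt1 <- tr$thermal_optimum_c[sp1]

  sel <- .solve_drift_strength(dbh1, opt1, mat, config,
                               tr$thermal_optimum_c)
  p_die <- stats::plogis(config$mortality_intercept +
                           config$mortality_slope * dbh1 -
                           sel$s * (opt1 - sel$pivot))
  died <- stats::runif(n0) < p_die

  inc <- pmin(pmax(stats::rnorm(n0, config$growth_mean, config$growth_sd),
                   -0.09), 7.4)
  dbh2 <- dbh1 + inc * t

  n_rec <- stats::rpois(1, config$recruit_rate * config$plot_area_ha * t)
  kern2 <- stats::dnorm(tr$thermal_optimum_c,
                        mat + config$thermo_drift * t,
                        config$niche_breadth) + 1e-12
  sp_rec <- if (n_rec > 0) sample.int(nsp, n_rec, replace = TRUE, prob = kern2)
            else integer(0)
  dbh_rec <- stats::runif(n_rec, 10, 12)

  # sapling pool (5-10 cm), first census only, anchors the H:D fit low end
  n_sap <- round(0.15 * n0)
  sp_sap <- sample.int(nsp, n_sap, replace = TRUE, prob = kern)
  dbh_sap <- stats::runif(n_sap, 5, 10)

  h_noise <- function(n) exp(stats::rnorm(n, 0, 0.08))
  measured1 <- stats::runif(n0) < config$height_measured_frac
  h1 <- ifelse(measured1,
               .true_height(dbh1, elevation) * h_noise(n0), NA_real_)
  measured2 <- stats::runif(n0) < config$height_measured_frac
  h2 <- ifelse(!died & measured2,
               .true_height(dbh2, elevation) * h_noise(n0), NA_real_)
  h_sap <- .true_height(dbh_sap, elevation) * h_noise(n_sap)

  date2 <- date1 + round(t * 365.25)
  tag <- sprintf("%s-%04d", plot_id, seq_len(n0 + n_rec + n_sap))
  tag_main <- tag[seq_len(n0)]
  tag_rec <- tag[n0 + seq_len(n_rec)]
  tag_sap <- tag[n0 + n_rec + seq_len(n_sap)]

  row_block <- function(tags, census, date, dbh, h, sp, status) {
    data.frame(plot_id = plot_id, tag = tags, census = census,
               date = as.character(date), dbh_cm = dbh, height_m = h,
               species = tr$species[sp], genus = tr$genus[sp],
               family = tr$family[sp], status = status,
               stringsAsFactors = FALSE)
  }
  rbind(
    row_block(tag_main, 1L, date1, dbh1, h1, sp1, "alive"),
    row_block(tag_sap, 1L, date1, dbh_sap, h_sap, sp_sap, "alive"),
    row_block(tag_main[!died], 2L, date2, dbh2[!died], h2[!died],
              sp1[!died], "alive"),
    row_block(tag_main[died], 2L, date2, dbh1[died], NA_real_,
              sp1[died], "dead"),
    row_block(tag_rec, 2L, date2, dbh_rec, NA_real_, sp_rec, "recruit")
  )
}

#' Generate a two-census plot network
#'
#' Simulates the first census (stems >= 10 cm from a truncated-exponential
#' DBH distribution, species sampled along a thermal niche kernel), deaths
#' drawn per stem from `logit(P) = a + beta * DBH`, survivor growth,
#' recruitment into the 10-12 cm class, plus a plot table and a CHELSA-style
#' bioclim climate table driven by elevation (lapse rate) and latitude
#' (seasonality) with observation noise.
#'
#' A non-zero `thermo_drift` is injected as warm-biased survival plus a
#' recruit sampling kernel shifted by `drift * t`: the survival bias
#' strength is solved per plot so that the expected basal-area-weighted CTI
#' changes by exactly `drift * t` (i.e. `thermo_drift` is the expected
#' thermophilization rate, the quantity the estimator recovers).
#'
#' @param config a [sim_config()].
#' @param pool output of [generate_species_pool()] (compatible config).
#' @return list: `census` (two-census table, schema of [load_census()]),
#'   `plots` (plot attributes) and `climate` (19 bioclim variables per
#'   plot).
#' @export
generate_census_pair <- function(config, pool) {
  stopifnot(inherits(config, "sim_config"))
  if (config$census_interval_years <= 0) stop("census interval must be > 0")
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  n <- config$n_plots
  plot_id <- sprintf("plot%03d", seq_len(n))
  elevation <- seq(config$elevation_range[1], config$elevation_range[2],
                   length.out = n)
  latitude <- stats::runif(n, config$latitude_range[1],
                           config$latitude_range[2])
  longitude <- stats::runif(n, -79.5, -63.8)
  date1 <- as.Date("2003-07-01") + round(stats::runif(n, -270, 270))
  country <- ifelse(latitude < -20, "Argentina",
                    ifelse(latitude < -10, "Bolivia",
                           ifelse(latitude < -2, "Peru",
                                  ifelse(latitude < 2, "Ecuador",
                                         "Colombia"))))
  plot_seeds <- sample.int(.Machine$integer.max - 1L, n)
  climate_seed <- sample.int(.Machine$integer.max - 1L, 1)

  census <- do.call(rbind, lapply(seq_len(n), function(i) {
    set.seed(plot_seeds[i])
    .simulate_plot(config, pool, plot_id[i], elevation[i], date1[i])
  }))
  plots <- data.frame(plot_id = plot_id, area_ha = config$plot_area_ha,
                      elevation_m = elevation, latitude = latitude,
                      longitude = longitude, country = country,
                      stringsAsFactors = FALSE)
  set.seed(climate_seed)
  climate <- .simulate_climate(config, plots)
  list(census = census, plots = plots, climate = climate)
}

# bioclim-style climate table: temperature level set by elevation through
# the lapse rate, seasonality set by |latitude|, plus extraction noise
.simulate_climate <- function(config, plots) {
  n <- nrow(plots)
  absl <- abs(plots$latitude)
  MAT <- .mat_at(config, plots$elevation_m) + stats::rnorm(n, 0, 0.2)
  TAR <- 12 + 0.55 * absl + stats::rnorm(n, 0, 0.5)
  TS <- 150 + 28 * absl + stats::rnorm(n, 0, 5)
  MDR <- 9 + 0.12 * absl + stats::rnorm(n, 0, 0.3)
  Isoth <- 100 * MDR / TAR + stats::rnorm(n, 0, 1)
  MAP <- pmax(2600 - 0.25 * plots$elevation_m - 25 * absl +
                stats::rnorm(n, 0, 120), 650)
  PS <- 35 + 2.2 * absl + stats::rnorm(n, 0, 3)
  data.frame(
    plot_id = plots$plot_id,
    MAT = MAT, MDR = MDR, Isoth = Isoth, TS = TS,
    MaxTWarmM = MAT + 0.45 * TAR + stats::rnorm(n, 0, 0.15),
    MinTCM = MAT - 0.55 * TAR + stats::rnorm(n, 0, 0.15),
    TAR = TAR,
    MeanTWarmQ = MAT + 0.25 * TAR + stats::rnorm(n, 0, 0.15),
    MeanTDQ = MAT - 0.10 * TAR + stats::rnorm(n, 0, 0.15),
    MeanTWetQ = MAT + 0.10 * TAR + stats::rnorm(n, 0, 0.15),
    MeanTCQ = MAT - 0.30 * TAR + stats::rnorm(n, 0, 0.15),
    MAP = MAP,
    PWetM = MAP * (0.13 + 0.002 * PS) + stats::rnorm(n, 0, 20),
    PDM = pmax(MAP * (0.045 - 0.0007 * PS) + stats::rnorm(n, 0, 5), 0),
    PS = PS,
    PWetQ = MAP * (0.34 + 0.003 * PS) + stats::rnorm(n, 0, 40),
    PDQ = pmax(MAP * (0.16 - 0.002 * PS) + stats::rnorm(n, 0, 15), 0),
    PWarmQ = MAP * 0.30 + stats::rnorm(n, 0, 30),
    PCQ = MAP * 0.20 + stats::rnorm(n, 0, 25),
    stringsAsFactors = FALSE
  )
}

#' Generate a band-by-year forest-cover table
#'
#' @param breaks elevation band edges (non-overlapping, increasing).
#' @param cover_initial cover per band in the initial year, km^2.
#' @param loss_rates fractional cover loss per band over the period
#'   (`cover_final = cover_initial * (1 - loss_rate)`); must be < 1.
#' @return data frame: `band`, `cover_initial`, `cover_final`.
#' @export
generate_cover_table <- function(breaks, cover_initial, loss_rates) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
  nb <- length(breaks) - 1
  if (length(cover_initial) != nb || length(loss_rates) != nb) {
    stop("cover_initial and loss_rates must have one value per band")
  }
  if (any(loss_rates >= 1)) stop("loss rates must be below 1")
  if (any(cover_initial <= 0)) stop("cover must be positive")
  data.frame(band = paste0(breaks[-length(breaks)], "-", breaks[-1]),
             cover_initial = cover_initial,
             cover_final = cover_initial * (1 - loss_rates),
             stringsAsFactors = FALSE)
}

#' Simulate a complete forest network
#'
#' One-call wrapper: species pool, censuses, plots and climate.
#'
#' @param config a [sim_config()].
#' @return list with `census`, `plots`, `climate`, `traits`, `phylogeny`,
#'   `newick` and the `config`.
#' @export
simulate_forest_network <- function(config) {
  pool <- generate_species_pool(config)
  cp <- generate_census_pair(config, pool)
  c(cp, pool["traits"], pool["phylogeny"], pool["newick"],
    list(config = config))
}
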