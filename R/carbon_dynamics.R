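#' @title Annualized aboveground-carbon dynamics
#' @name carbon_dynamics
NULL

# wood density for one stem block of a pair (species/genus/family columns),
# assigned against the union of the pair's stems so the plot-mean fallback
# sees the whole plot
.pair_wd <- function(pair, wd_table) {
  taxa <- c("species", "genus", "family")
  all_stems <- rbind(pair$survivors[taxa], pair$deaths[taxa], pair$recruits[taxa])
  n <- c(nrow(pair$survivors), nrow(pair$deaths), nrow(pair$recruits))
  if (sum(n) == 0L) {
    return(list(survivors = numeric(0), deaths = numeric(0), recruits = numeric(0)))
  }
  wd <- assign_wd(all_stems, wd_table)$wd
  split(wd, rep(c("survivors", "deaths", "recruits"), n))[
    c("survivors", "deaths", "recruits")]
}

#' Annualized AGC mortality
#'
#' Sum of the AGC of all stems that died between the censuses, valued at
#' their first-census DBH, divided by plot area and census interval.
#'
#' @param pair a `census_pair` (growth caps applied or not; deaths are
#'   valued at census-1 size either way).
#' @param model plot `hd_model`.
#' @param wd_table wood-density table.
#' @return Mg C ha^-1 y^-1.
#' @export
agc_mortality <- function(pair, model, wd_table) {
  if (nrow(pair$deaths) == 0L) return(0)
  wd <- .pair_wd(pair, wd_table)$deaths
  sum(stem_agc(pair$deaths$dbh1, wd, model)) / 1000 / pair$area_ha / pair$t
}

#' Annualized AGC recruitment
#'
#' Each recruit contributes its AGC at observed DBH minus the AGC of a tree
#' of the same wood density at 9.99 cm (just below the 10-cm census
#' threshold), so that biomass grown below the detection limit is not
#' credited to recruitment. Per-recruit contributions are floored at zero.
#'
#' @inheritParams agc_mortality
#' @param ref_dbh reference DBH just below the census threshold (9.99 cm).
#' @return Mg C ha^-1 y^-1.
#' @export
agc_recruitment <- function(pair, model, wd_table, ref_dbh = 9.99) {
  if (nrow(pair$recruits) == 0L) return(0)
  wd <- .pair_wd(pair, wd_table)$recruits
  contrib <- stem_agc(pair$recruits$dbh2, wd, model) -
    stem_agc(rep(ref_dbh, nrow(pair$recruits)), wd, model)
  sum(pmax(contrib, 0)) / 1000 / pair$area_ha / pair$t
}

#' Annualized AGC growth of survivors
#'
#' Sum of the AGC increase of all surviving stems (census-2 minus census-1
#' AGC, after growth capping), annualized. Individual stems may contribute
#' small negative increments (shrinkage down to the -0.1 cm/y cap).
#'
#' @inheritParams agc_mortality
#' @return Mg C ha^-1 y^-1.
#' @export
agc_growth <- function(pair, model, wd_table) {
  if (nrow(pair$survivors) == 0L) return(0)
  wd <- .pair_wd(pair, wd_table)$survivors
  inc <- stem_agc(pair$survivors$dbh2, wd, model) -
    stem_agc(pair$survivors$dbh1, wd, model)
  sum(inc) / 1000 / pair$area_ha / pair$t
}

#' Full per-plot AGC dynamics
#'
#' Computes both census stocks, the annualized mortality, recruitment,
#' growth, productivity (recruitment + growth) and net change
#' `(AGC_final - AGC1) / t`. Net change is computed from the stock
#' difference; the component sum `productivity - mortality` is exposed as a
#' bookkeeping audit whose residual stems from the 9.99-cm recruitment
#' correction (and any growth-cap rewrites).
#'
#' @inheritParams agc_mortality
#' @param cap apply [cap_growth()] first (default `TRUE`; skipped if the
#'   pair is already capped).
#' @return one-row data frame: `plot_id`, `t`, `area_ha`, `agc1`,
#'   `agc_final`, `mortality`, `recruitment`, `growth`, `productivity`,
#'   `net_change`, `pct_change`, `component_residual`.
#' @export
plot_dynamics <- function(pair, model, wd_table, cap = TRUE) {
  stopifnot(inherits(pair, "census_pair"))
  if (cap && !isTRUE(pair$capped)) pair <- cap_growth(pair)
  agc1 <- plot_agc_stock(pair, 1, model, wd_table)
  agc2 <- plot_agc_stock(pair, 2, model, wd_table)
  mort <- agc_mortality(pair, model, wd_table)
  rec <- agc_recruitment(pair, model, wd_table)
  gro <- agc_growth(pair, model, wd_table)
  net <- (agc2 - agc1) / pair$t
  pct <- if (agc1 > 0) 100 * net / agc1 else NA_real_
  if (agc1 == 0) warning("AGC1 = 0 for plot ", pair$plot_id,
                         ": percent change undefined")
  data.frame(
    plot_id = pair$plot_id, t = pair$t, area_ha = pair$area_ha,
    agc1 = agc1, agc_final = agc2,
    mortality = mort, recruitment = rec, growth = gro,
    productivity = rec + gro, net_change = net, pct_change = pct,
    component_residual = net - (rec + gro - mort),
    stringsAsFactors = FALSE
  )
}

#' AGC dynamics for a whole plot network
#'
#' Fits height-diameter models per plot (with country/regional fallback),
#' then computes [plot_dynamics()] for every pair.
#'
#' @param pairs list of `census_pair` objects (see [pair_censuses()]).
#' @param wd_table wood-density table.
#' @param min_obs minimum height observations for a plot-level allometry.
#' @return data frame with one row per plot plus the selected allometry form
#'   and scope.
#' @export
network_dynamics <- function(pairs, wd_table, min_obs = 10) {
  models <- fit_hd_network(pairs, min_obs = min_obs)
  rows <- lapply(pairs, function(p) {
    m <- models[[p$plot_id]]
    out <- plot_dynamics(p, m, wd_table)
    out$hd_form <- m$form
    out$hd_scope <- m$scope
    out$elevation <- p$elevation
    out$latitude <- p$latitude
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
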