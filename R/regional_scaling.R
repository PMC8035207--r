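#' @title Elevation-band aggregation and regional carbon balance
#' @name regional_scaling
NULL

# Mg C ha^-1 x km^2 -> Pg: 1 km^2 = 100 ha, 1 Pg = 1e9 Mg
.PG_PER_MG_HA_KM2 <- 100 / 1e9
.CO2_PER_C <- 44 / 12

#' Assign plots to elevation bands
#'
#' Bands are half-open intervals `[low, high)`. Plots outside all bands are
#' flagged `NA` with a warning.
#'
#' @param elevation numeric vector of plot elevations, m asl.
#' @param breaks band edges, default `c(500, 1200, 2000, 2800, 3600)`.
#' @return factor of band labels (`"500-1200"`, ...), `NA` outside.
#' @export
assign_bands <- function(elevation, breaks = c(500, 1200, 2000, 2800, 3600)) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
  labels <- paste0(breaks[-length(breaks)], "-", breaks[-1])
  out <- cut(elevation, breaks = breaks, labels = labels, right = FALSE)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " plot(s) outside the band range excluded")
  }
  out
}

#' Bootstrap mean and percentile confidence interval of band stocks
#'
#' Plot-level resampling with replacement; 2.5/97.5 percentile CI.
#'
#' @param stocks numeric vector of per-plot stocks in one band.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional seed.
#' @param conf confidence level (default 0.95).
#' @return list: `mean`, `lower`, `upper`, `n`. For a single-plot band the
#'   CI is `NA` and flagged with a warning.
#' @export
band_bootstrap <- function(stocks, n_boot = 1000, seed = NULL, conf = 0.95) {
  stocks <- stocks[is.finite(stocks)]
  n <- length(stocks)
  if (n == 0L) stop("no stocks in band")
  if (!is.null(seed)) set.seed(seed)
  if (n == 1L) {
    warning("single-plot band: CI undefined")
    return(list(mean = stocks, lower = NA_real_, upper = NA_real_, n = 1L))
  }
  boots <- vapply(seq_len(n_boot),
                  function(i) mean(sample(stocks, n, replace = TRUE)),
                  numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(mean = mean(stocks), lower = qs[1], upper = qs[2], n = n)
}

#' Band mean stocks from plot-level data
#'
#' Aggregates plot AGC stocks into elevation bands for the initial and final
#' epochs, with bootstrap CIs. Following the census-to-epoch convention of
#' asynchronous networks, a plot contributes its initial stock only if its
#' first census falls in or before the cut year, and its final stock only if
#' its last census falls after it.
#'
#' @param plot_stocks data frame with columns `plot_id`, `elevation`,
#'   `agc1`, `agc_final` and (optionally) `date_first`, `date_last`
#'   (`Date`).
#' @param breaks band edges (see [assign_bands()]).
#' @param cut_year epoch cut (default 2009): first censuses <= cut_year are
#'   "initial", last censuses > cut_year are "final". Ignored when dates are
#'   absent.
#' @param n_boot,seed bootstrap controls.
#' @return data frame, one row per band: `band`, `n_initial`, `n_final`,
#'   `stock_initial`, `stock_initial_lo/hi`, `stock_final`,
#'   `stock_final_lo/hi`.
#' @export
band_stocks <- function(plot_stocks, breaks = c(500, 1200, 2000, 2800, 3600),
                        cut_year = 2009, n_boot = 1000, seed = NULL) {
  band <- assign_bands(plot_stocks$elevation, breaks)
  use_init <- rep(TRUE, nrow(plot_stocks))
  use_final <- rep(TRUE, nrow(plot_stocks))
  if (all(c("date_first", "date_last") %in% names(plot_stocks))) {
    use_init <- as.integer(format(plot_stocks$date_first, "%Y")) <= cut_year
    use_final <- as.integer(format(plot_stocks$date_last, "%Y")) > cut_year
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(levels(band), function(b) {
    i1 <- which(band == b & use_init)
    i2 <- which(band == b & use_final)
    b1 <- if (length(i1)) band_bootstrap(plot_stocks$agc1[i1], n_boot) else
      list(mean = NA_real_, lower = NA_real_, upper = NA_real_, n = 0L)
    b2 <- if (length(i2)) band_bootstrap(plot_stocks$agc_final[i2], n_boot) else
      list(mean = NA_real_, lower = NA_real_, upper = NA_real_, n = 0L)
    data.frame(band = b, n_initial = b1$n, n_final = b2$n,
               stock_initial = b1$mean, stock_initial_lo = b1$lower,
               stock_initial_hi = b1$upper,
               stock_final = b2$mean, stock_final_lo = b2$lower,
               stock_final_hi = b2$upper, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Band totals, weighted means and regional carbon balance
#'
#' Multiplies per-band mean stocks (Mg C ha^-1) by forest cover (km^2) into
#' total stocks (Pg C) per band and epoch, then derives the cover-weighted
#' mean stocks, region totals, the net annual carbon balance
#' `(total_final - total_initial) / elapsed_years` and the per-hectare rate
#' `(weighted_mean_final - weighted_mean_initial) / elapsed_years`.
#'
#' @param stocks data frame with columns `band`, `stock_initial`,
#'   `stock_final` (optionally `_lo`/`_hi` CI columns, which propagate to
#'   total CIs).
#' @param cover data frame with columns `band`, `cover_initial`,
#'   `cover_final` (km^2).
#' @param elapsed_years years between the two epochs (default 11).
#' @return object of class `regional_balance`: `bands` (per-band table with
#'   totals), `weighted_mean_initial/final` (Mg C ha^-1),
#'   `total_initial/final_pg`, `rate_per_ha` (Mg C ha^-1 y^-1),
#'   `net_balance_pg` (Pg C y^-1), `cover_loss_km2`, `elapsed_years`.
#' @export
band_totals <- function(stocks, cover, elapsed_years = 11) {
  if (!setequal(stocks$band, cover$band)) {
    stop("band mismatch between stock and cover tables")
  }
  cover <- cover[match(stocks$band, cover$band), ]
  bands <- data.frame(band = stocks$band,
                      stock_initial = stocks$stock_initial,
                      stock_final = stocks$stock_final,
                      cover_initial = cover$cover_initial,
                      cover_final = cover$cover_final,
                      stringsAsFactors = FALSE)
  bands$total_initial_pg <- bands$stock_initial * bands$cover_initial *
    .PG_PER_MG_HA_KM2
  bands$total_final_pg <- bands$stock_final * bands$cover_final *
    .PG_PER_MG_HA_KM2
  for (side in c("initial", "final")) for (q in c("lo", "hi")) {
    sc <- paste0("stock_", side, "_", q)
    if (sc %in% names(stocks)) {
      bands[[paste0("total_", side, "_", q)]] <-
        stocks[[sc]] * bands[[paste0("cover_", side)]] * .PG_PER_MG_HA_KM2
    }
  }
  wm_init <- sum(bands$stock_initial * bands$cover_initial) /
    sum(bands$cover_initial)
  wm_final <- sum(bands$stock_final * bands$cover_final) /
    sum(bands$cover_final)
  total_init <- sum(bands$total_initial_pg)
  total_final <- sum(bands$total_final_pg)
  structure(list(
    bands = bands,
    weighted_mean_initial = wm_init,
    weighted_mean_final = wm_final,
    total_initial_pg = total_init,
    total_final_pg = total_final,
    rate_per_ha = (wm_final - wm_init) / elapsed_years,
    net_balance_pg = (total_final - total_init) / elapsed_years,
    cover_loss_km2 = sum(bands$cover_initial) - sum(bands$cover_final),
    elapsed_years = elapsed_years
  ), class = "regional_balance")
}

#' @export
print.regional_balance <- function(x, ...) {
  cat("<regional_balance> over", x$elapsed_years, "years\n")
  print(x$bands, digits = 4)
  cat(sprintf("  weighted mean stock: %.2f -> %.2f Mg C/ha (%.2f Mg C/ha/y)\n",
              x$weighted_mean_initial, x$weighted_mean_final, x$rate_per_ha))
  cat(sprintf("  region total: %.2f -> %.2f Pg C (net %.3f Pg C/y)\n",
              x$total_initial_pg, x$total_final_pg, x$net_balance_pg))
  cat(sprintf("  forest cover loss: %.0f km2\n", x$cover_loss_km2))
  invisible(x)
}

#' Committed CO2-equivalent emissions from forest-cover loss
#'
#' Band-wise: lost cover (km^2) x 100 x initial mean stock (Mg C ha^-1)
#' x 44/12, in Pg CO2e. Bands that gained cover are flagged and contribute
#' zero.
#'
#' @param stocks data frame with `band` and `stock_initial` columns.
#' @param cover data frame with `band`, `cover_initial`, `cover_final`.
#' @return emissions, Pg CO2 equivalent.
#' @export
deforestation_emissions <- function(stocks, cover) {
  if (!setequal(stocks$band, cover$band)) {
    stop("band mismatch between stock and cover tables")
  }
  cover <- cover[match(stocks$band, cover$band), ]
  loss <- cover$cover_initial - cover$cover_final
  if (any(loss < 0)) {
    warning("band(s) with cover gain contribute no emissions: ",
            paste(stocks$band[loss < 0], collapse = ", "))
    loss <- pmax(loss, 0)
  }
  sum(loss * 100 * stocks$stock_initial) * .CO2_PER_C / 1e9
}

#' Bundled Andean band-level survey summary
#'
#' Per-elevation-band mean aboveground carbon stocks (with 95% CIs) and
#' forest cover for the tropical and subtropical Andes in 2003 and 2014, as
#' reported by a regional plot-network survey. Useful as a worked input to
#' [band_totals()] and [deforestation_emissions()].
#'
#' @return data frame: `band`, `stock_initial(_lo/_hi)`,
#'   `stock_final(_lo/_hi)` (Mg C ha^-1), `cover_initial`, `cover_final`
#'   (km^2).
#' @export
andes_band_summary <- function() {
  path <- system.file("extdata", "andes_band_summary.csv",
                      package = "andescarbon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
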