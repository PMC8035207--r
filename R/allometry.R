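#' @title Height-diameter allometry and per-tree carbon
#' @name allometry
NULL

hd_forms <- c("loglog1", "loglog2", "weibull3", "mm2")

#' Fit the four candidate height-diameter models
#'
#' Fits the candidate set used for montane plot networks: first- and
#' second-order log-log polynomials, the three-parameter Weibull model
#' `H = c0 * (1 - exp(-(D/c1)^c2))` and the two-parameter Michaelis-Menten
#' model `H = c0 * D / (c1 + D)`. Residual standard error (RSE) and mean
#' signed bias are computed on the metre scale for all forms; log-log
#' predictions are back-transformed with the Baskerville correction
#' `exp(sigma_log^2 / 2)` so that they are unbiased on the arithmetic scale.
#'
#' @param heights data frame with columns `dbh` (cm, >= 5) and `h` (m).
#' @param min_obs minimum number of height observations required (default 10).
#' @param scope provenance label stored on each fit: `"plot"`, `"country"`
#'   or `"regional"`.
#' @return named list of `hd_model` objects (one per form that converged);
#'   forms that fail to converge are dropped with a warning.
#' @export
fit_hd_candidates <- function(heights, min_obs = 10, scope = "plot") {
  stopifnot(is.data.frame(heights), all(c("dbh", "h") %in% names(heights)))
  heights <- heights[is.finite(heights$dbh) & is.finite(heights$h) &
                       heights$dbh >= 5 & heights$h > 0, , drop = FALSE]
  if (nrow(heights) < min_obs) {
    stop("need at least ", min_obs, " height observations, got ", nrow(heights))
  }
  d <- heights$dbh
  h <- heights$h
  fits <- list()

  mk <- function(form, coef, corr = 1) {
    m <- structure(list(form = form, coef = coef, corr = corr,
                        rse = NA_real_, bias = NA_real_,
                        n = length(d), scope = scope), class = "hd_model")
    pred <- predict_height(m, d)
    resid <- h - pred
    m$rse <- sqrt(sum(resid^2) / max(1, length(d) - length(coef)))
    m$bias <- mean(resid)
    m
  }

  # log-log polynomials: fit on the log scale, keep sigma for Baskerville
  f1 <- stats::lm(log(h) ~ log(d))
  fits$loglog1 <- mk("loglog1", stats::coef(f1),
                     corr = exp(stats::sigma(f1)^2 / 2))
  f2 <- stats::lm(log(h) ~ log(d) + I(log(d)^2))
  fits$loglog2 <- mk("loglog2", stats::coef(f2),
                     corr = exp(stats::sigma(f2)^2 / 2))

  # nonlinear candidates: Levenberg-Marquardt with data-driven starts
  hmax <- max(h)
  w3 <- tryCatch({
    fit <- minpack.lm::nlsLM(h ~ c0 * (1 - exp(-(d / c1)^c2)),
                             start = list(c0 = hmax * 1.1,
                                          c1 = stats::median(d), c2 = 0.9),
                             lower = c(1, 0.5, 0.05),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    mk("weibull3", stats::coef(fit))
  }, error = function(e) NULL)
  if (is.null(w3)) warning("weibull3 candidate failed to converge") else
    fits$weibull3 <- w3

  mm <- tryCatch({
    fit <- minpack.lm::nlsLM(h ~ c0 * d / (c1 + d),
                             start = list(c0 = hmax * 1.5,
                                          c1 = stats::median(d)),
                             lower = c(1, 0.1),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    mk("mm2", stats::coef(fit))
  }, error = function(e) NULL)
  if (is.null(mm)) warning("mm2 candidate failed to converge") else
    fits$mm2 <- mm

  fits
}

#' Predict tree height from DBH
#'
#' @param model an `hd_model`.
#' @param dbh numeric DBH vector, cm.
#' @return predicted heights, m.
#' @export
predict_height <- function(model, dbh) {
  stopifnot(inherits(model, "hd_model"))
  cf <- unname(model$coef)
  switch(model$form,
    loglog1 = model$corr * exp(cf[1] + cf[2] * log(dbh)),
    loglog2 = model$corr * exp(cf[1] + cf[2] * log(dbh) + cf[3] * log(dbh)^2),
    weibull3 = cf[1] * (1 - exp(-(dbh / cf[2])^cf[3])),
    mm2 = cf[1] * dbh / (cf[2] + dbh),
    stop("unknown form: ", model$form)
  )
}

#' @export
print.hd_model <- function(x, ...) {
  cat("<hd_model> ", x$form, " [", x$scope, "]  RSE = ", signif(x$rse, 4),
      " m, bias = ", signif(x$bias, 4), " m, n = ", x$n, "\n  coef: ",
      paste(signif(x$coef, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select the best height-diameter model
#'
#' The candidate with the lowest RSE wins. Candidates whose RSE lies within
#' a relative tolerance of the minimum (plus a small absolute floor, so that
#' noise-free fits tie cleanly) are tie-broken by smaller absolute bias, then
#' by fewer parameters.
#'
#' @param fits list of `hd_model` fits from [fit_hd_candidates()].
#' @param rse_tol relative RSE tie window (default 0.01).
#' @return the selected `hd_model`.
#' @export
select_hd_model <- function(fits, rse_tol = 0.01) {
  fits <- Filter(function(f) inherits(f, "hd_model") && is.finite(f$rse), fits)
  if (length(fits) == 0L) stop("no available height-diameter fits")
  rse <- vapply(fits, function(f) f$rse, numeric(1))
  rmin <- min(rse)
  tied <- which(rse <= rmin * (1 + rse_tol) + 1e-8)
  if (length(tied) > 1L) {
    bias <- vapply(fits[tied], function(f) abs(f$bias), numeric(1))
    bmin <- min(bias)
    tied2 <- tied[bias <= bmin + 1e-8]
    if (length(tied2) > 1L) {
      npar <- vapply(fits[tied2], function(f) length(f$coef), numeric(1))
      tied2 <- tied2[which.min(npar)]
    }
    fits[[tied2[1L]]]
  } else {
    fits[[tied]]
  }
}

#' Fit plot-level height-diameter models with fallback
#'
#' Fits and selects a model per plot; plots without enough height data fall
#' back to a pooled country-level fit, and failing that to a pooled fit over
#' all plots (regional scope).
#'
#' @param pairs list of `census_pair` objects.
#' @param min_obs minimum height observations for a plot-level fit.
#' @return named list of selected `hd_model` objects, one per plot, each
#'   tagged with its `scope`.
#' @export
fit_hd_network <- function(pairs, min_obs = 10) {
  pool_by_country <- list()
  all_heights <- list()
  for (p in pairs) {
    key <- if (is.na(p$country)) ".na" else p$country
    pool_by_country[[key]] <- rbind(pool_by_country[[key]], p$heights)
    all_heights[[p$plot_id]] <- p$heights
  }
  regional <- do.call(rbind, all_heights)
  country_models <- list()
  out <- list()
  for (p in pairs) {
    model <- NULL
    if (nrow(p$heights) >= min_obs) {
      model <- tryCatch(
        select_hd_model(fit_hd_candidates(p$heights, min_obs = min_obs)),
        error = function(e) NULL)
    }
    if (is.null(model)) {
      key <- if (is.na(p$country)) ".na" else p$country
      if (is.null(country_models[[key]]) &&
          nrow(pool_by_country[[key]]) >= min_obs) {
        country_models[[key]] <- tryCatch({
          m <- select_hd_model(fit_hd_candidates(pool_by_country[[key]],
                                                 min_obs = min_obs,
                                                 scope = "country"))
          m
        }, error = function(e) NULL)
      }
      model <- country_models[[key]]
    }
    if (is.null(model)) {
      model <- select_hd_model(fit_hd_candidates(regional, min_obs = min_obs,
                                                 scope = "regional"))
    }
    out[[p$plot_id]] <- model
  }
  out
}

#' Assign wood density down the taxonomic hierarchy
#'
#' Looks up stem wood density at species level, then genus mean, then family
#' mean; stems still unassigned receive the mean wood density of the
#' assigned stems in the same plot. The resolution level is recorded for
#' every stem.
#'
#' @param stems data frame with columns `species`, `genus`, `family`.
#' @param wd_table data frame with columns `species`, `genus`, `family`,
#'   `wd_g_cm3` (one row per species; genus and family means are derived).
#' @return data frame with columns `wd` (g cm^-3) and `level`
#'   (species/genus/family/plot-mean), one row per stem.
#' @export
assign_wd <- function(stems, wd_table) {
  stopifnot(all(c("species", "genus", "family") %in% names(stems)),
            all(c("species", "wd_g_cm3") %in% names(wd_table)))
  wd <- rep(NA_real_, nrow(stems))
  level <- rep(NA_character_, nrow(stems))

  i <- match(stems$species, wd_table$species)
  hit <- !is.na(i)
  wd[hit] <- wd_table$wd_g_cm3[i[hit]]
  level[hit] <- "species"

  if ("genus" %in% names(wd_table)) {
    gm <- tapply(wd_table$wd_g_cm3, wd_table$genus, mean)
    todo <- is.na(wd)
    g <- gm[stems$genus[todo]]
    wd[todo] <- as.numeric(g)
    level[todo][!is.na(g)] <- "genus"
  }
  if ("family" %in% names(wd_table)) {
    fm <- tapply(wd_table$wd_g_cm3, wd_table$family, mean)
    todo <- is.na(wd)
    f <- fm[stems$family[todo]]
    wd[todo] <- as.numeric(f)
    level[todo][!is.na(f)] <- "family"
  }
  todo <- is.na(wd)
  if (any(todo)) {
    if (all(todo)) stop("no stem in the plot could be assigned a wood density")
    wd[todo] <- mean(wd[!todo])
    level[todo] <- "plot-mean"
  }
  data.frame(wd = wd, level = level, stringsAsFactors = FALSE)
}

#' Aboveground biomass of a stem (pantropical moist-forest equation)
#'
#' `AGB = 0.0673 * (WD * DBH^2 * H)^0.976`, with AGB in kg, wood density in
#' g cm^-3, DBH in cm and height in m.
#'
#' @param wd wood density, g cm^-3.
#' @param dbh diameter at breast height, cm.
#' @param h total height, m.
#' @return AGB in kg (vectorized).
#' @export
agb_chave <- function(wd, dbh, h) {
  if (any(wd <= 0) || any(dbh <= 0) || any(h <= 0)) {
    stop("wd, dbh and h must all be positive")
  }
  0.0673 * (wd * dbh^2 * h)^0.976
}

#' Convert aboveground biomass to aboveground carbon
#'
#' Applies the carbon fraction 0.456 kg C per kg AGB.
#'
#' @param agb aboveground biomass, kg.
#' @return aboveground carbon, kg C.
#' @export
agc_from_agb <- function(agb) {
  if (any(agb < 0)) stop("AGB must be non-negative")
  0.456 * agb
}

# per-stem AGC in kg C given dbh vector, wood densities and a plot hd model
stem_agc <- function(dbh, wd, model) {
  agc_from_agb(agb_chave(wd, dbh, predict_height(model, dbh)))
}

#' Plot-level aboveground carbon stock
#'
#' Sums per-stem AGC over a census and scales to one hectare.
#'
#' @param pair a `census_pair`.
#' @param census 1 (first) or 2 (last census).
#' @param model the plot's selected `hd_model` (one model serves both
#'   censuses).
#' @param wd_table wood-density table (see [assign_wd()]).
#' @return stock in Mg C per ha.
#' @export
plot_agc_stock <- function(pair, census = 1, model, wd_table) {
  stopifnot(inherits(pair, "census_pair"))
  if (pair$area_ha <= 0) stop("plot area must be positive")
  if (census == 1) {
    stems <- rbind(pair$survivors[c("species", "genus", "family")],
                   pair$deaths[c("species", "genus", "family")])
    dbh <- c(pair$survivors$dbh1, pair$deaths$dbh1)
  } else {
    stems <- rbind(pair$survivors[c("species", "genus", "family")],
                   pair$recruits[c("species", "genus", "family")])
    dbh <- c(pair$survivors$dbh2, pair$recruits$dbh2)
  }
  if (length(dbh) == 0L) return(0)
  wd <- assign_wd(stems, wd_table)$wd
  sum(stem_agc(dbh, wd, model)) / 1000 / pair$area_ha
}
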