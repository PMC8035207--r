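#' @title Census data model
#' @description Reading, validation and first/last-census alignment of
#'   repeated tree-census tables.
#' @name census_model
NULL

.census_columns <- c("plot_id", "tag", "census", "date", "dbh_cm", "height_m",
                     "species", "genus", "family", "status")
.census_mandatory <- setdiff(.census_columns, "height_m")
.status_levels <- c("alive", "dead", "recruit")

#' Load and validate a tree-census table
#'
#' Reads a census CSV (or validates an in-memory data frame) against the
#' package's census schema. One row is one stem at one census. Stems down to
#' 5 cm DBH are accepted: stems below 10 cm are used only for height-diameter
#' fitting, never for carbon accounting.
#'
#' @param x path to a CSV file, or a data frame already in census layout.
#' @return A validated data frame with columns `plot_id`, `tag`, `census`
#'   (integer), `date` (`Date`), `dbh_cm`, `height_m` (may be `NA`),
#'   `species`, `genus`, `family`, `status` (one of `"alive"`, `"dead"`,
#'   `"recruit"`).
#' @details Validation is strict and row-addressed: unparseable DBH or dates,
#'   DBH below 5 cm, unknown status codes and duplicated
#'   (plot, census, tag) keys all raise errors that name the offending rows
#'   or tags. Nothing is silently dropped.
#' @export
load_census <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("census file not found: ", x)
    utils::read.csv(x, stringsAsFactors = FALSE, colClasses = "character")
  } else if (is.data.frame(x)) {
    x
  } else {
    stop("`x` must be a file path or a data frame")
  }
  missing_cols <- setdiff(.census_mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("census table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"height_m" %in% names(df)) df$height_m <- NA_real_

  out <- data.frame(
    plot_id = as.character(df$plot_id),
    tag     = as.character(df$tag),
    census  = suppressWarnings(as.integer(df$census)),
    date    = as.Date(as.character(df$date), format = "%Y-%m-%d"),
    dbh_cm  = suppressWarnings(as.numeric(df$dbh_cm)),
    height_m = suppressWarnings(as.numeric(df$height_m)),
    species = as.character(df$species),
    genus   = as.character(df$genus),
    family  = as.character(df$family),
    status  = as.character(df$status),
    stringsAsFactors = FALSE
  )

  bad_dbh <- which(is.na(out$dbh_cm) | out$dbh_cm < 5)
  if (length(bad_dbh) > 0L) {
    stop("invalid DBH (unparseable or < 5 cm) in row(s): ",
         paste(utils::head(bad_dbh, 20), collapse = ", "))
  }
  bad_date <- which(is.na(out$date))
  if (length(bad_date) > 0L) {
    stop("unparseable census date in row(s): ",
         paste(utils::head(bad_date, 20), collapse = ", "))
  }
  bad_status <- which(!out$status %in% .status_levels)
  if (length(bad_status) > 0L) {
    stop("unknown status (expected alive/dead/recruit) in row(s): ",
         paste(utils::head(bad_status, 20), collapse = ", "))
  }
  key <- paste(out$plot_id, out$census, out$tag, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicated (plot, census, tag) key(s): ",
         paste(utils::head(unique(paste0(out$plot_id[dup], "/", out$tag[dup])), 10),
               collapse = ", "))
  }
  out
}

#' Load a plot-attribute table
#'
#' @param x path to a CSV file or a data frame with columns `plot_id`,
#'   `area_ha`, `elevation_m`, `latitude`, `longitude` and optionally
#'   `country`.
#' @return validated data frame.
#' @export
load_plots <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("plot_id", "area_ha", "elevation_m", "latitude", "longitude")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("plot table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"country" %in% names(df)) df$country <- NA_character_
  if (any(df$area_ha <= 0)) stop("plot areas must be positive")
  if (anyDuplicated(df$plot_id)) stop("duplicated plot_id in plot table")
  df
}

#' Align the first and last census of each plot
#'
#' For every plot with at least two censuses, pairs the first and the last
#' census and partitions stems into survivors (alive in both), deaths (alive
#' first, dead or absent last) and recruits (absent first, alive last).
#' The census interval `t` is the date difference in decimal years
#' (days / 365.25). Only stems with DBH >= 10 cm enter the partition;
#' all measured heights (DBH >= 5 cm, either census) are pooled into a
#' height-fitting subset.
#'
#' @param census validated census data frame (see [load_census()]).
#' @param plots validated plot table (see [load_plots()]).
#' @return A named list of `census_pair` objects, one per plot. Each holds
#'   `plot_id`, `area_ha`, `elevation`, `latitude`, `longitude`, `country`,
#'   `t` (years), and data frames `survivors` (with `dbh1`, `dbh2`),
#'   `deaths` (`dbh1`), `recruits` (`dbh2`) and `heights` (`dbh`, `h`).
#'   Single-census plots are excluded with a warning.
#' @export
pair_censuses <- function(census, plots) {
  pids <- unique(census$plot_id)
  unknown <- setdiff(pids, plots$plot_id)
  if (length(unknown) > 0L) {
    stop("census plots missing from plot table: ", paste(unknown, collapse = ", "))
  }
  pairs <- list()
  skipped <- character(0)
  for (pid in pids) {
    cs <- census[census$plot_id == pid, , drop = FALSE]
    idx <- sort(unique(cs$census))
    if (length(idx) < 2L) {
      skipped <- c(skipped, pid)
      next
    }
    prow <- plots[plots$plot_id == pid, , drop = FALSE]
    c1 <- cs[cs$census == idx[1L], , drop = FALSE]
    c2 <- cs[cs$census == idx[length(idx)], , drop = FALSE]
    t_years <- as.numeric(stats::median(c2$date) - stats::median(c1$date)) / 365.25
    if (t_years <= 0) stop("non-positive census interval for plot ", pid)

    a1 <- c1[c1$status != "dead" & c1$dbh_cm >= 10, , drop = FALSE]
    alive2 <- c2[c2$status != "dead", , drop = FALSE]
    # survivorship is defined by census-1 size: a stem that shrinks below
    # 10 cm but is re-measured alive remains a survivor (the growth cap
    # bounds how far it can shrink)
    a2 <- alive2[alive2$dbh_cm >= 10 | alive2$tag %in% a1$tag, , drop = FALSE]
    d2 <- c2[c2$status == "dead", , drop = FALSE]

    surv_tags <- intersect(a1$tag, a2$tag)
    death_tags <- setdiff(a1$tag, surv_tags)  # absent or explicitly dead
    rec_tags <- setdiff(a2$tag, a1$tag)

    taxa <- c("species", "genus", "family")
    i1 <- match(surv_tags, a1$tag); i2 <- match(surv_tags, a2$tag)
    survivors <- data.frame(tag = surv_tags, a1[i1, taxa, drop = FALSE],
                            dbh1 = a1$dbh_cm[i1], dbh2 = a2$dbh_cm[i2],
                            stringsAsFactors = FALSE, row.names = NULL)
    id <- match(death_tags, a1$tag)
    deaths <- data.frame(tag = death_tags, a1[id, taxa, drop = FALSE],
                         dbh1 = a1$dbh_cm[id],
                         stringsAsFactors = FALSE, row.names = NULL)
    ir <- match(rec_tags, a2$tag)
    recruits <- data.frame(tag = rec_tags, a2[ir, taxa, drop = FALSE],
                           dbh2 = a2$dbh_cm[ir],
                           stringsAsFactors = FALSE, row.names = NULL)

    hm <- rbind(c1, c2)
    hm <- hm[!is.na(hm$height_m) & hm$dbh_cm >= 5, , drop = FALSE]
    heights <- data.frame(dbh = hm$dbh_cm, h = hm$height_m)

    pairs[[pid]] <- structure(list(
      plot_id = pid,
      area_ha = prow$area_ha,
      elevation = prow$elevation_m,
      latitude = prow$latitude,
      longitude = prow$longitude,
      country = prow$country,
      t = t_years,
      survivors = survivors,
      deaths = deaths,
      recruits = recruits,
      heights = heights,
      n_explicit_dead = nrow(d2),
      capped = FALSE
    ), class = "census_pair")
  }
  if (length(skipped) > 0L) {
    warning("excluded single-census plot(s): ", paste(skipped, collapse = ", "))
  }
  pairs
}

#' @export
print.census_pair <- function(x, ...) {
  cat("<census_pair> plot ", x$plot_id,
      " (", round(x$elevation), " m asl, ", x$area_ha, " ha, t = ",
      round(x$t, 2), " y)\n",
      "  survivors: ", nrow(x$survivors),
      "  deaths: ", nrow(x$deaths),
      "  recruits: ", nrow(x$recruits),
      "  height obs: ", nrow(x$heights), "\n", sep = "")
  invisible(x)
}

#' Clamp implausible survivor growth rates
#'
#' Survivor stems whose annualized DBH increment falls outside
#' \[-0.1, 7.5\] cm per year have their second-census DBH rewritten to
#' `dbh1 + bound * t`, the standard census-cleaning rule for measurement
#' error around buttresses and tag movement. First-census DBH is never
#' modified. The operation is idempotent.
#'
#' @param pair a `census_pair`.
#' @param lower,upper allowed annualized increment bounds, cm per year.
#' @return the pair with adjusted `survivors$dbh2` and an `adjustments`
#'   data frame (tag, dbh2_old, dbh2_new) recording every rewritten stem.
#' @export
cap_growth <- function(pair, lower = -0.1, upper = 7.5) {
  stopifnot(inherits(pair, "census_pair"))
  s <- pair$survivors
  rate <- (s$dbh2 - s$dbh1) / pair$t
  new2 <- s$dbh2
  low <- rate < lower
  high <- rate > upper
  new2[low] <- s$dbh1[low] + lower * pair$t
  new2[high] <- s$dbh1[high] + upper * pair$t
  pair$adjustments <- data.frame(tag = s$tag[low | high],
                                 dbh2_old = s$dbh2[low | high],
                                 dbh2_new = new2[low | high],
                                 stringsAsFactors = FALSE)
  pair$survivors$dbh2 <- new2
  pair$capped <- TRUE
  pair
}
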