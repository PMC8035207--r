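# fixture builders shared across test files

# hand-built census pair: survivors/deaths/recruits with chosen sizes
make_pair <- function(survivors = NULL, deaths = NULL, recruits = NULL,
                      t = 5, area_ha = 1, elevation = 1500) {
  empty_s <- data.frame(tag = character(0), species = character(0),
                        genus = character(0), family = character(0),
                        dbh1 = numeric(0), dbh2 = numeric(0),
                        stringsAsFactors = FALSE)
  empty_d <- empty_s[, names(empty_s) != "dbh2"]
  empty_r <- empty_s[, names(empty_s) != "dbh1"]
  structure(list(
    plot_id = "fx1", area_ha = area_ha, elevation = elevation,
    latitude = -10, longitude = -70, country = "Peru", t = t,
    survivors = if (is.null(survivors)) empty_s else survivors,
    deaths = if (is.null(deaths)) empty_d else deaths,
    recruits = if (is.null(recruits)) empty_r else recruits,
    heights = data.frame(dbh = numeric(0), h = numeric(0)),
    capped = TRUE
  ), class = "census_pair")
}

stem_row <- function(tag, species = "sp001", genus = "gen001",
                     family = "fam01", dbh1 = NA, dbh2 = NA) {
  df <- data.frame(tag = tag, species = species, genus = genus,
                   family = family, stringsAsFactors = FALSE)
  if (!all(is.na(dbh1))) df$dbh1 <- dbh1
  if (!all(is.na(dbh2))) df$dbh2 <- dbh2
  df
}

# Michaelis-Menten allometry with known coefficients, no correction
mm_model <- function(c0 = 40, c1 = 20) {
  structure(list(form = "mm2", coef = c(c0 = c0, c1 = c1), corr = 1,
                 rse = 0, bias = 0, n = 0, scope = "plot"),
            class = "hd_model")
}

toy_wd_table <- function() {
  data.frame(species = c("sp001", "sp002", "sp003"),
             genus = c("gen001", "gen001", "gen002"),
             family = c("fam01", "fam01", "fam01"),
             wd_g_cm3 = c(0.6, 0.5, 0.7),
             stringsAsFactors = FALSE)
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# tiny well-formed census table (one plot, two censuses)
toy_census <- function() {
  data.frame(
    plot_id = "p1",
    tag = c("t1", "t2", "t3", "t1", "t2", "t4"),
    census = c(1, 1, 1, 2, 2, 2),
    date = c(rep("2004-01-01", 3), rep("2009-01-01", 3)),
    dbh_cm = c(20, 15, 30, 21, 15.5, 10.4),
    height_m = c(18, 14, 24, NA, NA, NA),
    species = c("sp001", "sp002", "sp001", "sp001", "sp002", "sp003"),
    genus = c("gen001", "gen001", "gen001", "gen001", "gen001", "gen002"),
    family = "fam01",
    status = c("alive", "alive", "alive", "alive", "alive", "recruit"),
    stringsAsFactors = FALSE
  )
}

toy_plots <- function() {
  data.frame(plot_id = "p1", area_ha = 1, elevation_m = 1500,
             latitude = -10, longitude = -70, country = "Peru",
             stringsAsFactors = FALSE)
}
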