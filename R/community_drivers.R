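#' @title Community-level driver metrics
#' @description Thermophilization, mycorrhizal stem ratio, phylogenetic
#'   diversity, rarefied richness, size-dependent mortality and stand
#'   structure.
#' @name community_drivers
NULL

#' Species thermal optima from occurrence temperatures
#'
#' A species' thermal optimum is the mean annual temperature over its
#' occurrence records; species with fewer than `min_records` records
#' inherit the pooled mean over all congeneric records; species with
#' neither are left unassigned (and excluded from CTI downstream).
#'
#' @param occurrences data frame with columns `species`, `genus`, `mat`
#'   (mean annual temperature at each occurrence, degrees C).
#' @param min_records minimum own-records threshold (default 10).
#' @return data frame: `species`, `optimum_c`, `level`
#'   (`"species"`/`"genus"`/`NA`), `n_records`; the fraction of species
#'   assigned is reported in attribute `"coverage"`.
#' @export
thermal_optima <- function(occurrences, min_records = 10) {
  stopifnot(all(c("species", "genus", "mat") %in% names(occurrences)))
  sp <- unique(occurrences[c("species", "genus")])
  n_rec <- as.numeric(table(occurrences$species)[sp$species])
  n_rec[is.na(n_rec)] <- 0
  own <- tapply(occurrences$mat, occurrences$species, mean)[sp$species]
  gen <- tapply(occurrences$mat, occurrences$genus, mean)[sp$genus]
  use_own <- n_rec >= min_records
  optimum <- ifelse(use_own, own, as.numeric(gen))
  level <- ifelse(use_own, "species", ifelse(is.na(gen), NA, "genus"))
  out <- data.frame(species = sp$species, optimum_c = as.numeric(optimum),
                    level = level, n_records = n_rec,
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- mean(!is.na(out$optimum_c))
  out
}

# normalize an optima argument (data.frame from thermal_optima() or a named
# numeric vector) into a named vector
.optima_vector <- function(optima) {
  if (is.data.frame(optima)) {
    stats::setNames(optima$optimum_c, optima$species)
  } else if (is.numeric(optima) && !is.null(names(optima))) {
    optima
  } else {
    stop("`optima` must be a thermal_optima() data frame or a named numeric vector")
  }
}

#' Community temperature index (CTI)
#'
#' Basal-area-weighted mean of the thermal optima of the stems in one
#' census. Stems of species without an assigned optimum are excluded (their
#' basal area does not enter the weights).
#'
#' @param stems data frame with columns `species` and `dbh_cm`.
#' @param optima optima table from [thermal_optima()] or a named vector
#'   (degrees C per species).
#' @return CTI in degrees C.
#' @export
cti <- function(stems, optima) {
  opt <- .optima_vector(optima)[stems$species]
  keep <- !is.na(opt)
  if (!any(keep)) {
    warning("no stem has an assigned thermal optimum; CTI undefined")
    return(NA_real_)
  }
  ba <- pi * (stems$dbh_cm[keep] / 2)^2
  sum(ba * opt[keep]) / sum(ba)
}

#' Thermophilization rate of a plot
#'
#' Annualized change in the community temperature index between the first
#' and last census: `TR = (CTI_final - CTI_first) / t`. Each census uses its
#' own basal areas (deaths count in the first census, recruits in the last).
#'
#' @param pair a `census_pair`.
#' @param optima see [cti()].
#' @return list with `cti_first`, `cti_final`, `tr` (degrees C per year).
#' @export
thermophilization_rate <- function(pair, optima) {
  stopifnot(inherits(pair, "census_pair"))
  s1 <- data.frame(species = c(pair$survivors$species, pair$deaths$species),
                   dbh_cm = c(pair$survivors$dbh1, pair$deaths$dbh1))
  s2 <- data.frame(species = c(pair$survivors$species, pair$recruits$species),
                   dbh_cm = c(pair$survivors$dbh2, pair$recruits$dbh2))
  c1 <- cti(s1, optima)
  c2 <- cti(s2, optima)
  list(cti_first = c1, cti_final = c2, tr = (c2 - c1) / pair$t)
}

#' Mycorrhizal stem ratio (symbiotic root associations)
#'
#' Assigns each stem an arbuscular (AM) or ectomycorrhizal (EcM) status from
#' genus-level designations first, then family level, and returns
#' `SRA = ln(n_AM / n_EcM)` weighted by stem number. Unassigned stems are
#' excluded from both counts; coverage is reported.
#'
#' @param stems data frame with columns `genus` and `family`.
#' @param myco_table data frame with columns `taxon`, `rank`
#'   (`"genus"`/`"family"`) and `type` (`"AM"`/`"EcM"`).
#' @return list: `n_am`, `n_ecm`, `sra` (`NA` and flagged if either count
#'   is zero), `coverage`.
#' @export
sra <- function(stems, myco_table) {
  stopifnot(all(c("taxon", "rank", "type") %in% names(myco_table)))
  g <- myco_table[myco_table$rank == "genus", ]
  f <- myco_table[myco_table$rank == "family", ]
  type <- g$type[match(stems$genus, g$taxon)]
  todo <- is.na(type)
  type[todo] <- f$type[match(stems$family[todo], f$taxon)]
  n_am <- sum(type == "AM", na.rm = TRUE)
  n_ecm <- sum(type == "EcM", na.rm = TRUE)
  sra_val <- if (n_am > 0 && n_ecm > 0) log(n_am / n_ecm) else {
    warning("SRA undefined: plot lacks stems of one mycorrhizal type")
    NA_real_
  }
  list(n_am = n_am, n_ecm = n_ecm, sra = sra_val,
       coverage = mean(!is.na(type)))
}

# edge-length / tips-below-edge decomposition of a tree, used to evaluate
# Faith's PD for many communities at once
.pd_edges <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  nnode <- ntip + tr$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (i in seq_len(nrow(tr$edge))) {
    below[tr$edge[i, 1], ] <- below[tr$edge[i, 1], ] | below[tr$edge[i, 2], ]
  }
  list(len = tr$edge.length,
       below = below[tr$edge[, 2], , drop = FALSE],  # edges x tips
       tips = tr$tip.label)
}

#' Faith's phylogenetic diversity (root-inclusive)
#'
#' Sum of the branch lengths on the minimum spanning path connecting a
#' community's species to the root of a dated tree. With a single species
#' this is its root-to-tip path length.
#'
#' @param species character vector of community species; species that are
#'   not tips of the tree are dropped with a warning.
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return PD (summed branch length, in the tree's units), or `NA` if no
#'   species matches a tip.
#' @export
pd_faith <- function(species, tree) {
  ed <- .pd_edges(tree)
  miss <- setdiff(unique(species), ed$tips)
  if (length(miss) > 0L) {
    warning("species not in tree dropped: ", paste(miss, collapse = ", "))
  }
  present <- ed$tips %in% species
  if (!any(present)) return(NA_real_)
  on_path <- ed$below %*% present > 0
  sum(ed$len[on_path])
}

# PD for every row of a binary community matrix (plots x species)
.pd_matrix <- function(comm, tree, edges = .pd_edges(tree)) {
  m <- match(edges$tips, colnames(comm))
  cm <- matrix(0, nrow(comm), length(edges$tips))
  ok <- !is.na(m)
  cm[, ok] <- as.matrix(comm)[, m[ok], drop = FALSE]
  ind <- tcrossprod(edges$below, cm) > 0  # edges x plots
  as.numeric(crossprod(ind, edges$len))
}

#' Standardized effect size of phylogenetic diversity (PDz)
#'
#' Compares each plot's observed PD with a null distribution generated by
#' the independent-swap algorithm, which shuffles the plot x species
#' presence matrix while preserving both species frequencies (column sums)
#' and plot richness (row sums). `PDz = (PD_obs - null_mean) / null_sd`.
#'
#' Null draws follow one swap chain: the matrix is first burnt in with
#' `burn_in` attempted checkerboard swaps, then each draw applies
#' `swap_iterations` further attempts.
#'
#' @param comm binary plot x species matrix with dimnames.
#' @param tree dated [ape::phylo] tree; tips must cover the matrix columns.
#' @param n_null number of null draws (default 999).
#' @param swap_iterations attempted swaps between consecutive draws
#'   (default 10000).
#' @param burn_in initial attempted swaps (default 1000).
#' @param seed optional integer seed for the null chain.
#' @return data frame, one row per plot: `plot`, `sr`, `pd_obs`,
#'   `null_mean`, `null_sd`, `pdz` (`NA` and flagged when the null is
#'   degenerate, e.g. every species in every plot).
#' @export
pdz <- function(comm, tree, n_null = 999, swap_iterations = 10000,
                burn_in = 1000, seed = NULL) {
  comm <- as.matrix(comm)
  if (is.null(rownames(comm)) || is.null(colnames(comm))) {
    stop("`comm` needs plot rownames and species colnames")
  }
  if (nrow(comm) < 2L || ncol(comm) < 2L) {
    stop("need at least 2 plots and 2 species")
  }
  comm <- (comm > 0) + 0
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  edges <- .pd_edges(tree)
  obs <- .pd_matrix(comm, tree, edges)
  # a checkerboard swap needs two rows i, j and columns where (i=1, j=0)
  # and (i=0, j=1) both occur; without one the swap chain cannot move
  cross <- comm %*% (1 - t(comm))
  if (!any(cross > 0 & t(cross) > 0)) {
    warning("no swappable 2x2 submatrix; null distribution degenerate, ",
            "PDz undefined")
    return(data.frame(plot = rownames(comm), sr = rowSums(comm),
                      pd_obs = obs, null_mean = obs, null_sd = 0,
                      pdz = NA_real_, stringsAsFactors = FALSE,
                      row.names = NULL))
  }
  nulls <- matrix(NA_real_, n_null, nrow(comm))
  cur <- picante::randomizeMatrix(comm, null.model = "independentswap",
                                  iterations = burn_in)
  for (k in seq_len(n_null)) {
    cur <- picante::randomizeMatrix(cur, null.model = "independentswap",
                                    iterations = swap_iterations)
    nulls[k, ] <- .pd_matrix(cur, tree, edges)
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  z <- (obs - null_mean) / null_sd
  degenerate <- !is.finite(z)
  if (any(degenerate)) {
    warning("degenerate null distribution for ", sum(degenerate),
            " plot(s); PDz set to NA")
    z[degenerate] <- NA_real_
  }
  data.frame(plot = rownames(comm), sr = rowSums(comm), pd_obs = obs,
             null_mean = null_mean, null_sd = null_sd, pdz = z,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rarefied species richness
#'
#' Expected number of species in a random draw of `m` stems without
#' replacement (analytic hypergeometric expectation, via
#' [vegan::rarefy()]).
#'
#' @param counts named or unnamed vector of per-species stem counts.
#' @param m rarefaction depth in stems (default 86, a typical minimum plot
#'   stem count).
#' @return expected species count, or `NA` with a warning when the plot has
#'   fewer than `m` stems.
#' @export
rarefied_richness <- function(counts, m = 86) {
  counts <- counts[counts > 0]
  if (sum(counts) < m) {
    warning("fewer than ", m, " stems; rarefied richness undefined")
    return(NA_real_)
  }
  as.numeric(vegan::rarefy(counts, sample = m))
}

#' Size-dependent mortality (logistic regression of death on DBH)
#'
#' Fits `logit(P(death)) = a + beta * DBH` by maximum likelihood over a
#' plot's first-census stems (survivors = 0, deaths = 1). A negative `beta`
#' indicates small-stem competitive thinning; a positive `beta` indicates
#' loss of large trees under active disturbance.
#'
#' @param pair a `census_pair`.
#' @return list: `a`, `beta`, `beta_se`, `n`, `n_deaths`, `separated`
#'   (logical; when the fit is separated or degenerate the estimates are
#'   `NA`).
#' @export
beta_mortality <- function(pair) {
  stopifnot(inherits(pair, "census_pair"))
  dbh <- c(pair$survivors$dbh1, pair$deaths$dbh1)
  died <- rep(c(0L, 1L), c(nrow(pair$survivors), nrow(pair$deaths)))
  if (sum(died) == 0L || sum(died) == length(died)) {
    warning("plot ", pair$plot_id,
            " has no deaths or no survivors; mortality fit undefined")
    return(list(a = NA_real_, beta = NA_real_, beta_se = NA_real_,
                n = length(died), n_deaths = sum(died), separated = TRUE))
  }
  fit <- suppressWarnings(stats::glm(died ~ dbh, family = stats::binomial()))
  cf <- stats::summary.glm(fit)$coefficients
  separated <- !fit$converged || any(abs(cf[, "Estimate"]) > 50) ||
    any(cf[, "Std. Error"] > 100)
  if (separated) {
    warning("separated/degenerate logistic fit for plot ", pair$plot_id)
    return(list(a = NA_real_, beta = NA_real_, beta_se = NA_real_,
                n = length(died), n_deaths = sum(died), separated = TRUE))
  }
  list(a = unname(cf["(Intercept)", "Estimate"]),
       beta = unname(cf["dbh", "Estimate"]),
       beta_se = unname(cf["dbh", "Std. Error"]),
       n = length(died), n_deaths = sum(died), separated = FALSE)
}

#' Quadratic mean diameter and stem density
#'
#' `Dq = sqrt(sum(DBH_i^2) / n)`.
#'
#' @param dbh vector of stem diameters, cm.
#' @param area_ha plot area for stem density (optional).
#' @return list: `dq` (cm), `n`, `stem_density` (stems per ha, `NA` without
#'   an area).
#' @export
dq <- function(dbh, area_ha = NULL) {
  stopifnot(length(dbh) >= 1, all(dbh > 0))
  list(dq = sqrt(sum(dbh^2) / length(dbh)), n = length(dbh),
       stem_density = if (is.null(area_ha)) NA_real_ else length(dbh) / area_ha)
}

#' Per-plot driver metrics for a whole network
#'
#' Convenience wrapper computing TR, SRA, rarefied richness, the mortality
#' slope and stand structure for every pair, plus PDz across plots from the
#' first-census communities.
#'
#' @param pairs list of `census_pair` objects.
#' @param traits trait table with `species`, `genus`, `family`,
#'   `thermal_optimum_c`, `mycorrhiza` columns (as produced by
#'   [generate_species_pool()]).
#' @param tree dated phylogeny covering the species pool.
#' @param m rarefaction depth (stems).
#' @param n_null,seed passed to [pdz()].
#' @return data frame with one row per plot.
#' @export
network_drivers <- function(pairs, traits, tree, m = 86, n_null = 999,
                            seed = NULL) {
  optima <- stats::setNames(traits$thermal_optimum_c, traits$species)
  myco <- myco_table_from_traits(traits)
  rows <- lapply(pairs, function(p) {
    s1_species <- c(p$survivors$species, p$deaths$species)
    s1_dbh <- c(p$survivors$dbh1, p$deaths$dbh1)
    th <- thermophilization_rate(p, optima)
    sr_assoc <- sra(data.frame(genus = c(p$survivors$genus, p$deaths$genus),
                               family = c(p$survivors$family, p$deaths$family)),
                    myco)
    bm <- beta_mortality(p)
    st <- dq(s1_dbh, p$area_ha)
    data.frame(plot_id = p$plot_id, elevation = p$elevation,
               latitude = p$latitude, t = p$t,
               cti_first = th$cti_first, cti_final = th$cti_final, tr = th$tr,
               sra = sr_assoc$sra,
               sr_rarefied = rarefied_richness(table(s1_species), m = m),
               beta = bm$beta, beta_se = bm$beta_se, a = bm$a,
               dq = st$dq, n_stems = st$n, stem_density = st$stem_density,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  comm <- community_matrix(pairs, census = 1)
  pz <- pdz(comm, tree, n_null = n_null, seed = seed)
  out$pdz <- pz$pdz[match(out$plot_id, pz$plot)]
  out
}

#' Plot x species presence matrix from census pairs
#'
#' @param pairs list of `census_pair` objects.
#' @param census 1 (first) or 2 (last).
#' @return binary matrix, plots as rows, species as columns.
#' @export
community_matrix <- function(pairs, census = 1) {
  sp_sets <- lapply(pairs, function(p) {
    if (census == 1) unique(c(p$survivors$species, p$deaths$species))
    else unique(c(p$survivors$species, p$recruits$species))
  })
  species <- sort(unique(unlist(sp_sets)))
  m <- t(vapply(sp_sets, function(s) as.integer(species %in% s),
                integer(length(species))))
  dimnames(m) <- list(names(pairs), species)
  m
}
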