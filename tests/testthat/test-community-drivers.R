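test_that("thermal optima pool own records, fall back to genus, else drop", {
  occ <- rbind(
    data.frame(species = "spA", genus = "gA",
               mat = rep(c(18, 20, 22), 4)),          # 12 own records
    data.frame(species = "spB", genus = "gB", mat = c(14, 15, 16)),  # 3
    data.frame(species = "spB2", genus = "gB",
               mat = rep(15, 12)),                    # fills the gB pool
    data.frame(species = "spC", genus = "gC", mat = 19)  # 1 record, alone
  )
  out <- thermal_optima(occ, min_records = 10)
  expect_equal(out$optimum_c[out$species == "spA"], 20)
  expect_equal(out$level[out$species == "spA"], "species")
  # spB inherits the pooled congeneric mean (its own 3 + spB2's 12 records)
  expect_equal(out$optimum_c[out$species == "spB"],
               mean(c(14, 15, 16, rep(15, 12))))
  expect_equal(out$level[out$species == "spB"], "genus")
  # spC has < 10 records but its genus pool is itself spC's single record
  expect_equal(out$optimum_c[out$species == "spC"], 19)
  expect_lt(attr(out, "coverage"), 1.01)
})

test_that("CTI is the basal-area-weighted mean of optima", {
  opt <- c(sp1 = 20, sp2 = 10)
  # basal area ratio 3:1 via dbh sqrt(3):1
  stems <- data.frame(species = c("sp1", "sp2"), dbh_cm = c(sqrt(3), 1))
  expect_equal(cti(stems, opt), 17.5)
  # monodominant plot
  expect_equal(cti(data.frame(species = "sp1", dbh_cm = c(10, 30)), opt), 20)
  # equal basal areas give the unweighted mean
  expect_equal(cti(data.frame(species = c("sp1", "sp2"), dbh_cm = c(7, 7)),
                   opt), 15)
  # bounded by the included optima; unassigned species excluded
  stems2 <- data.frame(species = c("sp1", "sp2", "spX"), dbh_cm = c(5, 9, 50))
  v <- cti(stems2, opt)
  expect_true(v >= 10 && v <= 20)
  expect_warning(cti(data.frame(species = "spX", dbh_cm = 10), opt),
                 "undefined")
})

test_that("thermophilization rate annualizes the CTI change", {
  opt <- c(w = 25, c = 15)
  s <- data.frame(tag = c("a", "b"), species = c("w", "c"),
                  genus = "g", family = "f", dbh1 = c(10, 10),
                  dbh2 = c(10, 10), stringsAsFactors = FALSE)
  pair <- make_pair(survivors = s, t = 5)
  th <- thermophilization_rate(pair, opt)
  expect_equal(th$tr, 0)  # identical communities
  # killing the cold-optimum stem raises the final CTI -> positive TR
  pair2 <- make_pair(survivors = s[1, ],
                     deaths = data.frame(tag = "b", species = "c",
                                         genus = "g", family = "f",
                                         dbh1 = 10, stringsAsFactors = FALSE),
                     t = 5)
  th2 <- thermophilization_rate(pair2, opt)
  expect_equal(th2$cti_first, 20)
  expect_equal(th2$cti_final, 25)
  expect_equal(th2$tr, 1)
})

test_that("SRA is the log AM:EcM stem ratio with coverage reporting", {
  myco <- data.frame(taxon = c("gAM", "gEcM", "fAM"),
                     rank = c("genus", "genus", "family"),
                     type = c("AM", "EcM", "AM"))
  stems <- data.frame(genus = c(rep("gAM", 50), rep("gEcM", 50)),
                      family = "fX")
  expect_equal(sra(stems, myco)$sra, 0)

  stems2 <- data.frame(genus = c(rep("gAM", 88), rep("gEcM", 10), "gX", "gX"),
                       family = c(rep("fX", 98), "fAM", "fZ"))
  out <- sra(stems2, myco)
  # 88 genus-level AM + 1 family-level AM = 89... the family fallback adds one
  expect_equal(out$n_am, 89)
  expect_equal(out$n_ecm, 10)
  expect_equal(out$coverage, 99 / 100)

  out3 <- sra(data.frame(genus = c(rep("gAM", 90), rep("gEcM", 10)),
                         family = "fX"), myco)
  expect_equal(out3$sra, log(9))

  expect_warning(res <- sra(data.frame(genus = rep("gAM", 5), family = "fX"),
                            myco), "undefined")
  expect_true(is.na(res$sra))
})

test_that("Faith PD is the root-inclusive spanning branch length", {
  tr <- toy_tree()
  expect_equal(pd_faith(c("A", "B"), tr), 3)   # hand enumeration
  expect_equal(pd_faith("A", tr), 2)           # root-to-tip path
  expect_equal(pd_faith(c("A", "B", "C"), tr), sum(tr$edge.length))
  expect_warning(v <- pd_faith(c("A", "Z"), tr), "Z")
  expect_equal(v, 2)
  # monotone: adding a species never decreases PD
  expect_gte(pd_faith(c("A", "C"), tr), pd_faith("A", tr))
})

test_that("PD agrees with an independent implementation on random trees", {
  set.seed(42)
  tr <- ape::rphylo(20, 1, 0)
  comm <- matrix(rbinom(5 * 20, 1, 0.4), 5, 20,
                 dimnames = list(paste0("p", 1:5), tr$tip.label))
  comm[1, ] <- 1  # include a full community
  ours <- vapply(seq_len(5), function(i)
    pd_faith(colnames(comm)[comm[i, ] == 1], tr), numeric(1))
  ref <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("PDz is seed-reproducible and flags degenerate nulls", {
  set.seed(7)
  tr <- ape::rphylo(15, 1, 0)
  comm <- matrix(rbinom(8 * 15, 1, 0.5), 8, 15,
                 dimnames = list(paste0("p", 1:8), tr$tip.label))
  z1 <- pdz(comm, tr, n_null = 99, seed = 1)
  z2 <- pdz(comm, tr, n_null = 99, seed = 1)
  expect_equal(z1, z2)
  expect_true(all(is.finite(z1$pdz)))

  # saturated matrix: nothing can swap, null distribution is degenerate
  full <- matrix(1, 4, 15,
                 dimnames = list(paste0("p", 1:4), tr$tip.label))
  expect_warning(zf <- pdz(full, tr, n_null = 19), "degenerate")
  expect_true(all(is.na(zf$pdz)))
})

test_that("rarefied richness matches the resampling oracle", {
  expect_equal(suppressWarnings(rarefied_richness(c(200), m = 86)), 1)
  expect_equal(rarefied_richness(rep(1, 86), m = 86), 86)  # all singletons
  expect_warning(v <- rarefied_richness(c(40, 20), m = 86), "undefined")
  expect_true(is.na(v))

  counts <- c(50, 30, 6)
  analytic <- suppressWarnings(rarefied_richness(counts, m = 20))
  set.seed(11)
  ids <- rep(seq_along(counts), counts)
  sim <- mean(replicate(10000, length(unique(sample(ids, 20)))))
  expect_equal(analytic, sim, tolerance = 0.1 / analytic)
})

test_that("the mortality logit recovers its generating slope", {
  set.seed(21)
  n <- 5000
  dbh <- 10 + rexp(n, 1 / 12)
  p <- plogis(-4 + 0.05 * dbh)
  died <- runif(n) < p
  surv <- stem_row(paste0("s", which(!died)), dbh1 = dbh[!died],
                   dbh2 = dbh[!died])
  dead <- stem_row(paste0("d", which(died)), dbh1 = dbh[died])
  fit <- beta_mortality(make_pair(survivors = surv, deaths = dead))
  expect_false(fit$separated)
  expect_lt(abs(fit$beta - 0.05), 2.5 * fit$beta_se)

  # all-survivor plot is flagged, not fitted
  expect_warning(f0 <- beta_mortality(make_pair(survivors = surv)), "no deaths")
  expect_true(f0$separated)
  expect_true(is.na(f0$beta))
})

test_that("quadratic mean diameter follows its closed form", {
  expect_equal(dq(c(10, 10, 10))$dq, 10)
  expect_equal(dq(c(6, 8))$dq, sqrt(50))
  expect_equal(dq(17)$dq, 17)
  out <- dq(c(12, 20, 33), area_ha = 0.5)
  expect_equal(out$stem_density, 6)
  expect_true(out$dq >= 12 && out$dq <= 33)
})
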