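# Synthetic panel generator: planted tract process, genotype emission,
# load asymmetry, determinism.

test_that("identical configs and seeds give identical panels", {
  cfg <- sim_config(n_individuals = c(4, 4), n_scaffolds = 2,
                    scaffold_length = 1e7, n_sites = 200,
                    sib_pair_count = c(1, 0), seed = 11)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$panel$depth, b$panel$depth)
  expect_identical(a$truth$tracts, b$truth$tracts)
})

test_that("all-zero class weights plant no tracts", {
  expect_equal(nrow(plant_hbd_tracts(10, numeric(13))), 0)
  cfg <- sim_config(n_individuals = c(2, 2),
                    hbd_class_weights = list(numeric(13), numeric(13)),
                    n_scaffolds = 2, n_sites = 100, seed = 3)
  gen <- generate_panel(cfg)
  expect_equal(nrow(gen$truth$tracts), 0)
  expect_true(all(gen$truth$autozygous_fraction$fraction == 0))
})

test_that("tract lengths are exponential with mean 1/R and cover the configured fraction", {
  set.seed(42)
  rates <- hbdload:::.DEFAULT_RATES
  w <- numeric(13); w[rates == 64] <- 0.5
  lens <- numeric(0); fracs <- numeric(0)
  for (i in 1:20) {
    tr <- plant_hbd_tracts(20, w, rates)      # ~20 * 32 = 640 tracts per call
    full <- tr$end < 20                       # drop the boundary-truncated tract
    lens <- c(lens, (tr$end - tr$start)[full])
    fracs <- c(fracs, sum(tr$end - tr$start) / 20)
  }
  expect_gt(length(lens), 10000)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 1 / 64), 2 * se + 1e-4)
  expect_lt(abs(mean(fracs) - 0.5), 0.02)
})

test_that("per-class tract lengths pass a KS test against Exp(R) in >= 95% of seeds", {
  rates <- hbdload:::.DEFAULT_RATES
  w <- numeric(13); w[rates == 32] <- 0.4
  pass <- vapply(1:40, function(s) {
    set.seed(s)
    tr <- plant_hbd_tracts(30, w, rates)
    lens <- (tr$end - tr$start)[tr$end < 30]
    stats::ks.test(lens, "pexp", rate = 32)$p.value > 0.01
  }, TRUE)
  expect_gte(mean(pass), 0.95)
})

test_that("tracts are non-overlapping, sorted and within the genome", {
  set.seed(5)
  w <- numeric(13); w[4] <- 0.3; w[7] <- 0.2
  tr <- plant_hbd_tracts(15, w)
  expect_true(all(diff(tr$start) > 0))
  expect_true(all(tr$end[-nrow(tr)] <= tr$start[-1]))
  expect_true(all(tr$start >= 0 & tr$end <= 15))
  expect_error(plant_hbd_tracts(-1, w), "positive")
})

test_that("truth fraction equals summed tract length over genome length", {
  w <- numeric(13); w[5] <- 0.2
  cfg <- sim_config(n_populations = 1, population_labels = "P",
                    group_labels = "g", n_individuals = 3,
                    n_scaffolds = 3, scaffold_length = 2e7, n_sites = 300,
                    divergence = 0, hbd_class_weights = list(w), seed = 9)
  gen <- generate_panel(cfg)
  for (id in gen$truth$autozygous_fraction$id) {
    tt <- gen$truth$tracts[gen$truth$tracts$id == id, ]
    expect_equal(gen$truth$autozygous_fraction$fraction[
                   gen$truth$autozygous_fraction$id == id],
                 sum(tt$end_bp - tt$start_bp) / (3 * 2e7),
                 tolerance = 1e-12)
  }
})

test_that("an individual fully inside tracts with zero error has no heterozygotes", {
  w <- numeric(13); w[1] <- 1   # weights sum to 1: the whole genome is HBD
  cfg <- sim_config(n_populations = 1, population_labels = "P",
                    group_labels = "g", n_individuals = 2,
                    n_scaffolds = 2, scaffold_length = 1e7, n_sites = 400,
                    divergence = 0, hbd_class_weights = list(w),
                    genotype_error = 0, seed = 21)
  gen <- generate_panel(cfg)
  expect_false(any(gen$panel$dosage == 1, na.rm = TRUE))
  expect_true(all(gen$truth$autozygous_fraction$fraction > 0.99))
})

test_that("emitted site categories match the configured fractions", {
  cfg <- sim_config(n_individuals = c(2, 2), n_scaffolds = 4,
                    scaffold_length = 1e7, n_sites = 2500, seed = 13)
  gen <- generate_panel(cfg)
  obs <- table(gen$panel$sites$category)[names(cfg$category_fractions)]
  m <- nrow(gen$panel$sites)
  for (cc in names(cfg$category_fractions)) {
    p <- cfg$category_fractions[[cc]]
    expect_lt(abs(obs[[cc]] / m - p), 4 * sqrt(p * (1 - p) / m))
  }
})

test_that("full sibs exceed the relatedness threshold while random pairs sit near zero", {
  cfg <- sim_config(n_individuals = c(10, 0), n_scaffolds = 4,
                    scaffold_length = 2e7, n_sites = 5000,
                    divergence = c(0, 0),
                    hbd_class_weights = list(numeric(13), numeric(13)),
                    sib_pair_count = c(1, 0), seed = 31)
  gen <- generate_panel(cfg)
  sub <- gen$panel[gen$panel$individuals$population == "MAINLAND", ]
  M <- allele_sharing_matrix(sub)$matching
  beta <- hbdload:::.beta_matrix(M)
  sibs <- sub$individuals$id[!is.na(sub$individuals$family)]
  expect_length(sibs, 2)
  expect_gt(beta[sibs[1], sibs[2]], 0.05)
  unrel <- sub$individuals$id[is.na(sub$individuals$family)]
  off <- beta[unrel, unrel][upper.tri(beta[unrel, unrel])]
  expect_lt(abs(mean(off)), 0.02)
  kept <- unrelated_set(allele_sharing_matrix(sub))
  expect_length(intersect(kept, sibs), 1)
})

test_that("load asymmetry shifts minor-allele frequencies with clamping, identity and guards", {
  f <- c(0.10, 0.40, 0.80, 0.95)
  cats <- c("high", "high", "high", "intergenic")
  expect_equal(apply_load_asymmetry(f, cats, c(high = 1)), f)
  out <- apply_load_asymmetry(f, cats, c(high = 0.5))
  expect_equal(out, c(0.05, 0.20, 0.90, 0.95))   # minor is alt, alt, ref; intergenic untouched
  out2 <- apply_load_asymmetry(f, cats, c(high = 3))
  expect_equal(out2[2], 1)                       # 0.4 * 3 clamps to 1
  expect_error(apply_load_asymmetry(f, cats, c(high = 0)), "positive")
  expect_error(apply_load_asymmetry(f, cats, c(intergenic = 0.5)), "never")
  expect_error(apply_load_asymmetry(c(-0.1), "high", c(high = 0.5)), "\\[0, 1\\]")
})
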