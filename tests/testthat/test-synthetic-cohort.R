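test_that("default configuration matches the documented generative model", {
  cfg <- defaultCohortConfig()
  expect_length(cfg$phenotypes, 8)
  expect_identical(cfg$n_markers, 6L)
  expect_length(cfg$neighborhoods, 4)
  for (nb in cfg$neighborhoods)
    expect_equal(sum(nb$phenotype_abundance), 1, tolerance = 1e-12)
  prev <- vapply(cfg$neighborhoods, `[[`, 0, "tissue_prevalence")
  expect_lte(sum(prev), 1 + 1e-9)
  for (ph in cfg$phenotypes) {
    expect_true(all(ph$marker_expression >= 0 & ph$marker_expression <= 1))
    expect_gt(ph$cell_radius_px, 0)
    expect_true(ph$eccentricity >= 0 && ph$eccentricity < 1)
  }
})

test_that("paradigms modify exactly the documented parameters", {
  base <- defaultCohortConfig()
  pf1 <- applyParadigm(base, "PF1", "II")
  expect_equal(pf1$neighborhoods[[3]]$phenotype_abundance[6], 0.30)
  expect_equal(sum(pf1$neighborhoods[[3]]$phenotype_abundance), 1)
  pf1_3 <- applyParadigm(base, "PF1", "III")
  expect_equal(pf1_3$neighborhoods[[3]]$phenotype_abundance[6], 0.60)
  pf2 <- applyParadigm(base, "PF2", "III")
  expect_equal(pf2$neighborhoods[[3]]$phenotype_abundance[6], 0.0025)

  cci <- applyParadigm(base, "CCI1", "III")
  expect_equal(cci$neighborhoods[[2]]$phenotype_abundance[4], 0.05)
  expect_equal(cci$neighborhoods[[2]]$phenotype_abundance[5], 0.05)
  expect_equal(cci$phenotype_interactions[4, 5], 1)
  expect_equal(applyParadigm(base, "CCI1", "I")$phenotype_interactions[4, 5], -1)
  expect_equal(applyParadigm(base, "CCI2", "II")$neighborhoods[[2]]$phenotype_abundance[4],
               0.01)

  pmi <- applyParadigm(base, "PMI1", "I")
  expect_equal(pmi$phenotypes[[6]]$marker_expression[6],
               base$phenotypes[[6]]$marker_expression[6] * 0.25)
  expect_equal(pmi$neighborhoods[[3]]$phenotype_abundance[6], 0.15)
  expect_equal(applyParadigm(base, "PMI2", "II")$neighborhoods[[3]]$phenotype_abundance[6],
               0.0025)

  nni <- applyParadigm(base, "NNI1", "I")
  expect_equal(nni$neighborhood_interactions[2, 3], -1)
  expect_equal(nni$neighborhoods[[2]]$tissue_prevalence, 0.15)
  expect_equal(nni$neighborhoods[[3]]$tissue_prevalence, 0.15)

  expect_error(applyParadigm(base, "XXX", "I"), "unknown paradigm")
})

test_that("simulated tissue has the configured shape and is reproducible", {
  cfg <- defaultCohortConfig(c(160L, 160L), seed = 5L)
  tt <- simulateTissue(cfg)
  expect_s4_class(tt$image, "MultiplexImage")
  expect_identical(dim(imageArray(tt$image)), c(160L, 160L, 6L))
  expect_true(all(imageArray(tt$image) >= 0 & imageArray(tt$image) <= 1))
  # bit-exact reproducibility from (config, seed)
  tt2 <- simulateTissue(cfg)
  expect_identical(imageArray(tt$image), imageArray(tt2$image))
  expect_identical(phenotypeMask(tt$truth), phenotypeMask(tt2$truth))
  # every phenotype pixel lies inside a neighborhood region (validity)
  expect_true(validObject(tt$truth))
  # neighborhood area fractions near configured prevalence
  prev <- vapply(cfg$neighborhoods, `[[`, 0, "tissue_prevalence")
  areas <- tabulate(neighborhoodMask(tt$truth), 4) / (160 * 160)
  expect_true(all(abs(areas - prev) / prev < 0.2))
})

test_that("a single-phenotype neighborhood yields cells of only that type", {
  cfg <- defaultCohortConfig(c(120L, 120L), seed = 3L)
  for (i in 1:4)
    cfg$neighborhoods[[i]]$phenotype_abundance <-
      c(0, 0, 1, 0, 0, 0, 0, 0)
  tt <- simulateTissue(cfg)
  expect_true(all(cellTable(tt$truth)$phenotype == 3L))
})

test_that("phenotype frequencies follow configured abundances (chi-square)", {
  cfg <- defaultCohortConfig(c(500L, 500L), seed = 17L)
  tt <- simulateTissue(cfg)
  ct <- cellTable(tt$truth)
  for (nb in 1:4) {
    sub <- ct[ct$neighborhood == nb, ]
    if (nrow(sub) < 200) next
    ab <- cfg$neighborhoods[[nb]]$phenotype_abundance
    obs <- tabulate(sub$phenotype, 8)
    p <- suppressWarnings(stats::chisq.test(obs[ab > 0], p = ab[ab > 0])$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("attraction pulls phenotype pairs together, repulsion separates them", {
  base <- defaultCohortConfig(c(240L, 240L))
  d <- vapply(1:3, function(ti) {
    mean(vapply(1:3, function(s) {
      cfg <- applyParadigm(base, "CCI1", ti)
      cfg$seed <- deriveSeed(550L + s, ti)
      phenotypeNNDistance(simulateTissue(cfg)$truth, 4, 5)
    }, 0), na.rm = TRUE)
  }, 0)
  # type I = repel, II = none, III = attract
  expect_true(d[3] < d[2])
  expect_true(d[2] < d[1])
})

test_that("cohorts have the requested composition and are deterministic", {
  co <- simulateCohort("PF1", 1L, c(100L, 100L), seed = 9L)
  expect_length(co$tissues, 3)
  expect_identical(co$manifest$patient_type, c("I", "II", "III"))
  co2 <- simulateCohort("PF1", 1L, c(100L, 100L), seed = 9L)
  expect_identical(imageArray(co$tissues[[2]]$image),
                   imageArray(co2$tissues[[2]]$image))
})

test_that("images, masks and configs round-trip through disk formats", {
  tt <- smallTissues("CCI1", 200L)[[1]]
  d <- withr::local_tempdir()
  p <- file.path(d, "img.tiff")
  writeMultiplexImage(tt$image, p)
  back <- readMultiplexImage(p)
  expect_equal(imageArray(back), imageArray(tt$image), tolerance = 1e-6)
  cfg <- applyParadigm(defaultCohortConfig(), "CCI1", "III")
  yml <- file.path(d, "cfg.yaml")
  writeCohortConfig(cfg, yml)
  cfg2 <- readCohortConfig(yml)
  expect_equal(cfg2$phenotype_interactions, cfg$phenotype_interactions)
  expect_equal(cfg2$neighborhoods[[2]]$phenotype_abundance,
               cfg$neighborhoods[[2]]$phenotype_abundance)
  mp <- file.path(d, "mask.png")
  multiplexTME:::.writeMask16(phenotypeMask(tt$truth), mp)
  expect_identical(multiplexTME:::.readMask16(mp),
                   unname(phenotypeMask(tt$truth)))
})

test_that("derived seeds are stable, distinct and within integer range", {
  s <- vapply(1:500, function(i) deriveSeed(42L, i), 0L)
  expect_identical(s, vapply(1:500, function(i) deriveSeed(42L, i), 0L))
  expect_gt(length(unique(s)), 498)
  expect_true(all(s >= 1 & s < 2^31))
})
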