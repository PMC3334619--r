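test_that("pool prevalences follow dosage-times-proportion arithmetic", {
  geno <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    ref = "A", alt = "G",
    D1 = c(0L, 0L, 0L, 0L), D2 = c(2L, 0L, 0L, 0L),
    D3 = c(0L, 0L, 0L, 0L), D4 = c(0L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
  props <- c(D1 = 0.74, D2 = 0.05, D3 = 0.20, D4 = 0.01)
  truth <- makePool(geno, props)
  tv <- truthVariants(truth)
  # hom-alt in the 5% donor: prevalence exactly 0.05
  expect_equal(tv$expected_prevalence[tv$pos == 10L], 0.05)
  # het in the 1% donor: 0.005, flagged below the 1% design floor
  expect_equal(tv$expected_prevalence[tv$pos == 20L], 0.005)
  expect_true(tv$sub_detectable[tv$pos == 20L])
  # zero-dosage position is not truth but remains masked
  expect_false(40L %in% tv$pos)
  expect_true(40L %in% maskedPositions(truth)$pos)

  # het in the 74% donor: 0.74 / 2 = 0.37
  props2 <- c(D1 = 0.01, D2 = 0.05, D3 = 0.20, D4 = 0.74)
  tv2 <- truthVariants(makePool(geno, props2))
  expect_equal(tv2$expected_prevalence[tv2$pos == 20L], 0.37)

  expect_error(makePool(geno, c(D1 = 0.5, D2 = 0.5, D3 = 0.2, D4 = 0.1)),
               "sum to 1")
})

test_that("pool proportions rotate so each donor sees each level", {
  props <- poolProportions()
  expect_length(props, 4L)
  m <- do.call(rbind, props)
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  # each donor receives each proportion exactly once across pools
  for (d in colnames(m))
    expect_setequal(m[, d], c(0.01, 0.05, 0.20, 0.74))
})

test_that("error profile presets differ at late cycles as designed", {
  ga <- errorProfile("GAII", seed = 3)
  mi <- errorProfile("MiSeq", seed = 3)
  va <- ga@rates[!is.na(ga@rates)]
  vm <- mi@rates[!is.na(mi@rates)]
  expect_true(all(va > 0 & va < 0.05))
  expect_true(all(vm > 0 & vm < 0.05))
  # GAII inflates A/T-reference rates up to threefold after cycle 100
  expect_equal(ga@rates["F", 122, "A", "G"] / ga@rates["F", 100, "A", "G"],
               3, tolerance = 1e-9)
  expect_equal(mi@rates["F", 122, "A", "G"], mi@rates["F", 1, "A", "G"])
  late_ratio_ga <- mean(ga@rates["F", 110, c("A", "T"), ] /
                          ga@rates["F", 50, c("A", "T"), ], na.rm = TRUE)
  late_ratio_mi <- mean(mi@rates["F", 110, c("A", "T"), ] /
                          mi@rates["F", 50, c("A", "T"), ], na.rm = TRUE)
  expect_gt(late_ratio_ga, late_ratio_mi + 0.5)
  # deterministic per seed
  expect_identical(errorProfile("GAII", seed = 3)@rates, ga@rates)
})

test_that("a near-zero error profile and empty truth give pure reference", {
  design <- simulateDesign(n_amplicons = 5)
  refs <- simulateReference(design, seed = 11)
  pl <- simulatePileup(design, refs, emptyTruth(), nearZeroProfile(),
                       mean_depth = 1000, seed = 12)
  d <- pileupData(pl)
  refc <- as.matrix(d[, paste0("count_", .BASES)])[
    cbind(seq_len(nrow(d)), match(d$ref, .BASES))]
  expect_true(all(refc == d$depth))
})

test_that("flat-rate simulation stays inside exact binomial bounds", {
  design <- simulateDesign(n_amplicons = 20)
  refs <- simulateReference(design, seed = 13)
  # constant depth: amplicon effects disabled via dispersion 0
  pl <- simulatePileup(design, refs, emptyTruth(), flatProfile(2e-3),
                       mean_depth = 10000, seed = 14, dispersion = 0)
  d <- pileupData(pl)
  refc <- as.matrix(d[, paste0("count_", .BASES)])[
    cbind(seq_len(nrow(d)), match(d$ref, .BASES))]
  alt <- d$depth - refc
  # total substitution rate away from the reference is 3 x 0.002
  lo <- qbinom(5e-4, d$depth, 0.006)
  hi <- qbinom(1 - 5e-4, d$depth, 0.006)
  inside <- alt >= lo & alt <= hi
  expect_gte(mean(inside), 0.99)
})

test_that("simulation is deterministic and truth positions must be inside", {
  design <- simulateDesign(n_amplicons = 5)
  refs <- simulateReference(design, seed = 15)
  geno <- simulateCalibrationGenotypes(design, refs, n_snps = 10, seed = 16)
  truth <- makePool(geno, poolProportions()[[2]])
  a <- simulatePileup(design, refs, truth, flatProfile(), 2000, seed = 17)
  b <- simulatePileup(design, refs, truth, flatProfile(), 2000, seed = 17)
  expect_identical(pileupData(a), pileupData(b))
  bad <- truthFromVariants(data.frame(
    chrom = "sim1", pos = 1L, ref = "A", alt = "G",
    expected_prevalence = 0.5))
  expect_error(simulatePileup(design, refs, bad, flatProfile(), 100,
                              seed = 1), "outside")
})

test_that("realized coverage dispersion matches the requested uniformity", {
  design <- simulateDesign(n_amplicons = 500, target_length = 40L)
  refs <- simulateReference(design, seed = 19)
  pl <- simulatePileup(design, refs, emptyTruth(), nearZeroProfile(),
                       mean_depth = 300, seed = 20, dispersion = 0.52)
  pd <- data.table::as.data.table(pileupData(pl))
  ad <- pd[, list(cov = mean(depth)), by = c("amplicon_id", "direction")]
  ad <- ad[, list(cov = sum(cov)), by = "amplicon_id"]
  mu <- mean(ad$cov)
  frac <- mean(ad$cov >= 0.5 * mu & ad$cov <= 2 * mu)
  expect_lt(abs(frac - 0.82), 0.05)
})

test_that("host contamination shifts only masked positions, binomially", {
  design <- simulateDesign(n_amplicons = 5)
  refs <- simulateReference(design, seed = 23)
  pl <- simulatePileup(design, refs, emptyTruth(), nearZeroProfile(),
                       mean_depth = 10000, seed = 24, dispersion = 0)
  mask <- data.frame(chrom = "sim1",
                     pos = pileupData(pl)$pos[c(30, 200)])
  # fraction 0 is the identity
  expect_identical(pileupData(injectHostContamination(pl, mask, 0)),
                   pileupData(pl))
  cont <- injectHostContamination(pl, mask, 0.3, seed = 25)
  d0 <- pileupData(pl); d1 <- pileupData(cont)
  hit <- d1$pos %in% mask$pos
  expect_identical(d1[!hit, ], d0[!hit, ])
  refc <- as.matrix(d1[hit, paste0("count_", .BASES)])[
    cbind(seq_len(sum(hit)), match(d1$ref[hit], .BASES))]
  altn <- d1$depth[hit] - refc
  lo <- qbinom(5e-4, d1$depth[hit], 0.3)
  hi <- qbinom(1 - 5e-4, d1$depth[hit], 0.3)
  expect_true(all(altn >= lo & altn <= hi))
  expect_identical(d1$depth, d0$depth)   # depth conserved
})

test_that("amplification bias attenuates low prevalences preferentially", {
  geno <- data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
                     D1 = c(2L, 0L), D2 = c(0L, 0L), D3 = c(0L, 0L),
                     D4 = c(0L, 2L), stringsAsFactors = FALSE)
  truth <- makePool(geno, c(D1 = 0.01, D2 = 0.05, D3 = 0.20, D4 = 0.74))
  expect_identical(truthVariants(applyWgaBias(truth, 0)),
                   truthVariants(truth))
  biased <- truthVariants(applyWgaBias(truth, 5, seed = 26))
  orig <- truthVariants(truth)
  # 1% variant attenuated; 74% variant essentially untouched
  expect_lt(biased$expected_prevalence[biased$pos == 1L], 0.01)
  expect_gt(biased$expected_prevalence[biased$pos == 2L], 0.735)
})

test_that("every well-covered high-prevalence truth variant is recovered", {
  ex <- simulateCalibrationExperiment(n_pools = 2, n_amplicons = 40,
                                      n_snps = 60, mean_depth = 3000,
                                      seed = 5)
  art <- runCalibrate(ex$design, ex$pileups[[1]], ex$truths[[1]])
  calls <- runCall(ex$pileups[[2]], art)
  tv <- truthVariants(ex$truths[[2]])
  cd <- collapsedDepth(ex$pileups[[2]])
  dep <- cd$depth[match(paste(tv$chrom, tv$pos),
                        paste(cd$chrom, cd$pos))]
  strong <- tv[tv$expected_prevalence >= 0.20 &
                 dep >= max(1000, art$coverage_floor), ]
  called <- calls[!is.na(calls$called) & calls$called, ]
  key <- function(c, p, a) paste(c, p, a)
  expect_true(all(key(strong$chrom, strong$pos, strong$alt) %in%
                    key(called$chrom, called$pos, called$alt)))
})
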