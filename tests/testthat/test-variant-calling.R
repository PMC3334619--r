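test_that("binomial tail p-values match exhaustive summation", {
  expect_equal(binomialTailPvalue(0L, 1000L, 0.001), 1)
  expect_equal(binomialTailPvalue(0L, 5L, 0.5), 1)

  p <- binomialTailPvalue(5L, 1000L, 0.001)
  expect_equal(p, binomTailOracle(5, 1000, 0.001), tolerance = 1e-12)

  # tail monotonicity in X
  expect_lt(binomialTailPvalue(6L, 1000L, 0.001),
            binomialTailPvalue(5L, 1000L, 0.001))

  # grid: N <= 500, X across the range, four error rates
  for (N in c(1L, 7L, 50L, 123L, 250L, 500L)) {
    for (E in c(1e-4, 1e-3, 1e-2, 0.05)) {
      for (X in unique(pmin(N, c(0L, 1L, 2L, 5L, 10L, 25L, N)))) {
        expect_equal(binomialTailPvalue(X, N, E), binomTailOracle(X, N, E),
                     tolerance = 1e-10)
      }
    }
  }

  expect_error(binomialTailPvalue(10L, 5L, 0.01), "exceed")
  expect_error(binomialTailPvalue(1L, 5L, 0), "within")
  expect_error(binomialTailPvalue(1L, 5L, 1), "within")
})

test_that("Stouffer combination is weighted, symmetric and passes through", {
  # equal p = 0.5 at equal depths: Z = 0, combined p = 0.5
  expect_equal(combineStouffer(0.5, 1000, 0.5, 1000), 0.5)
  # one absent direction returns the other's p unchanged
  expect_equal(combineStouffer(0.01, 500, NA, 0), 0.01)
  expect_equal(combineStouffer(NA, 0, 0.03, 800), 0.03)
  # frozen oracle value (independent high-precision normal evaluation):
  # p_f = 0.01, p_r = 0.02, N_f = N_r = 1000
  expect_equal(combineStouffer(0.01, 1000, 0.02, 1000),
               0.0009768028322181895, tolerance = 1e-9)
  # symmetry in the two (p, N) arguments
  set.seed(5)
  for (i in 1:20) {
    pf <- runif(1); pr <- runif(1)
    nf <- sample(1:5000, 1); nr <- sample(1:5000, 1)
    expect_equal(combineStouffer(pf, nf, pr, nr),
                 combineStouffer(pr, nr, pf, nf))
  }
  expect_error(combineStouffer(NA, 0, NA, 0), "direction")
})

test_that("prevalence pools accepted directions only", {
  expect_equal(estimatePrevalence(50, 1000, NA, 0), 0.05)
  expect_equal(estimatePrevalence(30, 500, 70, 1500), 0.05)
  # direction rejected by the consistency filter contributes nothing
  expect_equal(estimatePrevalence(5, 100, 10, 1000,
                                  f_accepted = FALSE, r_accepted = TRUE),
               0.01)
  expect_error(estimatePrevalence(0, 0, 0, 0), "zero accepted depth")
})

test_that("prefilters implement the documented boundary semantics", {
  design <- tinyDesign()  # target 121..280, primers 101..120 / 281..300
  rows <- rbind(
    # Filter 1: a primer-span position
    pileupRow(pos = 110L, read_pos = 10L, ref = "A", A = 9000L, G = 1000L),
    # Filter 2 boundary: 19/10,000 = 0.19% removed; 20/10,000 retained
    pileupRow(pos = 130L, read_pos = 30L, ref = "A", A = 9981L, G = 19L),
    pileupRow(pos = 131L, read_pos = 31L, ref = "A", A = 9980L, G = 20L),
    # Filter 3 boundary: single direction at read_pos 101 out, 100 in
    pileupRow(pos = 221L, read_pos = 101L, ref = "C", C = 900L, T = 100L),
    pileupRow(pos = 220L, read_pos = 100L, ref = "C", C = 900L, T = 100L))
  cand <- applyPrefilters(PileupTable(rows), design)
  get <- function(p) cand[cand$pos == p, ]
  expect_equal(unique(get(110L)$flags), "PRIMER")
  expect_equal(unique(get(110L)$status), "FILTERED")
  expect_equal(unique(get(130L)$flags), "MIN_ALT_FRAC")
  expect_true(all(get(131L)$status == "TESTED"))
  expect_equal(unique(get(221L)$flags), "READ_END")
  expect_true(all(get(220L)$status == "TESTED"))
})

test_that("strand-consistency rejection follows coverage and read position", {
  design <- tinyDesign()
  # dual-covered position 240: F read_pos 140 would exceed 122, so place
  # the dual position at 220 (F read_pos 120, R read_pos 81)
  mk <- function(NF, XF, NR, XR, rpF = 120L, rpR = 81L) {
    PileupTable(rbind(
      pileupRow(direction = "F", pos = 220L, read_pos = rpF, ref = "A",
                A = NF - XF, G = XF),
      pileupRow(direction = "R", pos = 220L, read_pos = rpR, ref = "A",
                A = NR - XR, G = XR)))
  }
  # inconsistent calls and Cov(F) < 0.1 Cov(R): F evidence rejected
  cand <- applyPrefilters(mk(50L, 0L, 1000L, 50L), design)
  g <- cand[cand$pos == 220L & cand$alt == "G", ]
  expect_false(g$f_accepted)
  expect_true(g$r_accepted)
  expect_match(g$flags, "DIRECTION_REJECTED_F")
  # boundary: Cov(F) = 0.1 Cov(R) exactly is not rejected (strict <) and
  # the later-reading direction is rejected instead (Pos(F) > Pos(R))
  cand2 <- applyPrefilters(mk(100L, 0L, 1000L, 50L), design)
  g2 <- cand2[cand2$pos == 220L & cand2$alt == "G", ]
  expect_false(g2$f_accepted)   # rejected via read position, not coverage
  # consistent calls in both directions: nothing rejected
  cand3 <- applyPrefilters(mk(500L, 25L, 1000L, 50L), design)
  g3 <- cand3[cand3$pos == 220L & cand3$alt == "G", ]
  expect_true(g3$f_accepted && g3$r_accepted)
})

test_that("prefiltering is idempotent on surviving evidence", {
  design <- simulateDesign(n_amplicons = 10)
  refs <- simulateReference(design, seed = 31)
  pl <- simulatePileup(design, refs, emptyTruth(), flatProfile(3e-3),
                       mean_depth = 3000, seed = 32)
  c1 <- applyPrefilters(pl, design)
  surv <- c1[c1$status == "TESTED", ]
  # rebuild a pileup holding only surviving positions; filters keep them
  pd <- pileupData(pl)
  keep <- paste(pd$chrom, pd$pos) %in% paste(surv$chrom, surv$pos)
  c2 <- applyPrefilters(PileupTable(pd[keep, ], sampleId(pl)), design)
  expect_equal(sum(c2$status == "FILTERED" & is.na(c2$alt)), 0L)
  s1 <- surv[order(surv$chrom, surv$pos, surv$alt),
             c("chrom", "pos", "alt", "X_f", "N_f", "X_r", "N_r",
               "f_accepted", "r_accepted")]
  s2 <- c2[c2$status == "TESTED", ]
  s2 <- s2[order(s2$chrom, s2$pos, s2$alt),
           c("chrom", "pos", "alt", "X_f", "N_f", "X_r", "N_r",
             "f_accepted", "r_accepted")]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("callVariants reports each position once with its best allele", {
  design <- tinyDesign()
  model <- flatErrorModel(1e-3)
  pl <- PileupTable(rbind(
    pileupRow(pos = 150L, read_pos = 50L, ref = "A",
              A = 9850L, C = 30L, G = 100L, T = 20L)))
  res <- callVariants(pl, design, model)
  r <- res[res$pos == 150L & res$status == "TESTED", ]
  expect_equal(nrow(r), 1L)
  expect_equal(r$alt, "G")   # strongest allele wins
  expect_equal(r$prevalence, 100 / 10000)
  expect_lt(r$p, 1e-10)
})
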