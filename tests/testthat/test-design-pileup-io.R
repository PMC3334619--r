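test_that("design files round the 1-based coordinate convention and flag overlap", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "amplicon_id\tchrom\ttarget_start\ttarget_end\tfwd_primer_start\tfwd_primer_end\trev_primer_start\trev_primer_end",
    "a1\tchr1\t1000\t1200\t980\t999\t1201\t1220",
    "a2\tchr1\t1150\t1350\t1130\t1149\t1351\t1370",
    "a3\tchr1\t2000\t2160\t1980\t1999\t2161\t2180"), path)
  d <- readAmpliconDesign(path)
  expect_s4_class(d, "AmpliconDesign")
  dt <- designTable(d)
  # coordinates kept 1-based inclusive: target of a1 spans 1000..1200
  expect_equal(dt$target_start[1], 1000L)
  expect_equal(dt$target_end[1], 1200L)
  expect_equal(dt$fwd_read_start[1], 980L)
  expect_equal(dt$rev_read_start[1], 1220L)
  # a1 and a2 share 51 bp of target: both retained, flagged overlapping
  expect_equal(length(d), 3L)
  expect_equal(dt$overlapping, c(TRUE, TRUE, FALSE))
})

test_that("inconsistent primer geometry is a validation error", {
  bad <- data.frame(
    amplicon_id = "a1", chrom = "chr1",
    target_start = 1000L, target_end = 1010L,
    fwd_primer_start = 999L, fwd_primer_end = 1018L,  # overlaps the target
    rev_primer_start = 1011L, rev_primer_end = 1030L)
  expect_error(AmpliconDesign(bad), "geometry")
})

test_that("pileup TSV write/read is a bit-exact round trip", {
  d <- rbind(
    pileupRow(pos = 150L, read_pos = 50L, ref = "A", A = 990L, C = 3L,
              G = 2L, T = 5L),
    pileupRow(direction = "R", pos = 150L, read_pos = 131L - 60L,
              ref = "A", A = 800L, G = 1L),
    pileupRow(pos = 151L, read_pos = 51L, ref = "C", C = 1000L))
  x <- PileupTable(d, sample_id = "s1")
  path <- tempfile(fileext = ".tsv")
  writePileup(x, path)
  y <- readPileup(path, sample_id = "s1")
  expect_identical(pileupData(x), pileupData(y))
  # second round trip is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  writePileup(y, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("pileup rows are parsed directly and invariants enforced", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("amplicon_id", "direction", "chrom", "pos", "read_pos", "ref",
            "count_A", "count_C", "count_G", "count_T", "depth"),
          collapse = "\t"),
    "amp1\tF\tchr1\t1000\t5\tA\t990\t3\t2\t5\t1000"), path)
  x <- readPileup(path)
  expect_equal(pileupData(x)$depth, 1000L)
  expect_equal(pileupData(x)$ref, "A")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("amplicon_id", "direction", "chrom", "pos", "read_pos", "ref",
            "count_A", "count_C", "count_G", "count_T", "depth"),
          collapse = "\t"),
    "amp1\tF\tchr1\t1000\t5\tA\t990\t3\t2\t5\t999"), bad)
  expect_error(readPileup(bad), "row")
})

test_that("buildPileup follows the counting rules", {
  design <- tinyDesign()           # fwd_read_start 101, rev_read_start 300
  dt <- designTable(design)
  ref <- data.frame(chrom = "chr1", pos = 101:300, ref = "A",
                    stringsAsFactors = FALSE)
  seq122 <- paste(rep("A", 122), collapse = "")
  reads <- list(
    list(flag = 0L, pos = 101L, cigar = "122M", seq = seq122),  # clean F
    # gapped alignment (2 bp deletion): excluded entirely
    list(flag = 0L, pos = 101L, cigar = "60M2D62M", seq = seq122),
    # 5 bp downstream of the amplicon start, tolerance 0: unassigned
    list(flag = 0L, pos = 106L, cigar = "122M", seq = seq122),
    # clean R read: 5' end at 300
    list(flag = 16L, pos = 179L, cigar = "122M", seq = seq122),
    # base at read cycle 3 has PHRED exactly 20: not counted (strict >)
    list(flag = 0L, pos = 101L, cigar = "122M", seq = seq122,
         qual = qualString(c(30L, 30L, 20L, rep(30L, 119L)))))
  sam <- writeSam(reads)
  pl <- buildPileup(sam, design, ref)
  pd <- pileupData(pl)
  expect_equal(pl@provenance$gapped, 1L)
  expect_equal(pl@provenance$unassigned, 1L)
  # two clean F reads cover position 103, but one has quality 20 there
  expect_equal(pd$depth[pd$direction == "F" & pd$pos == 103L], 1L)
  # elsewhere both F reads count
  expect_equal(pd$depth[pd$direction == "F" & pd$pos == 104L], 2L)
  # R read: covers 179..300 with read_pos counted from 300
  expect_equal(pd$read_pos[pd$direction == "R" & pd$pos == 300L], 1L)
  expect_equal(pd$read_pos[pd$direction == "R" & pd$pos == 179L], 122L)
  # no base of the gapped read was ever counted: F depth <= 2 everywhere
  expect_true(all(pd$depth[pd$direction == "F"] <= 2L))
})

test_that("gapped reads never contribute bases (randomized property)", {
  design <- tinyDesign()
  ref <- data.frame(chrom = "chr1", pos = 101:300, ref = "G",
                    stringsAsFactors = FALSE)
  seqG <- paste(rep("G", 122), collapse = "")
  set.seed(42)
  reads <- lapply(1:40, function(i) {
    gapped <- runif(1) < 0.4
    cigar <- if (gapped) sample(c("40M1D82M", "40M2I80M", "100M5D22M"), 1)
             else "122M"
    list(flag = 0L, pos = 101L, cigar = cigar, seq = seqG)
  })
  n_clean <- sum(vapply(reads, function(r) r$cigar == "122M", logical(1)))
  pl <- buildPileup(writeSam(reads), design, ref)
  pd <- pileupData(pl)
  expect_true(all(pd$depth == n_clean))
  expect_equal(pl@provenance$gapped, 40L - n_clean)
})

test_that("reference name mismatch is an error", {
  design <- tinyDesign(chrom = "chrX")
  ref <- data.frame(chrom = "chrX", pos = 101:300, ref = "A")
  sam <- writeSam(list(list(flag = 0L, pos = 101L, cigar = "10M",
                            seq = "AAAAAAAAAA")), chrom = "chr1")
  expect_error(buildPileup(sam, design, ref), "mismatch")
})

test_that("downsampling is deterministic, capped and unbiased", {
  design <- simulateDesign(n_amplicons = 45)
  refs <- simulateReference(design, seed = 3)
  pl <- simulatePileup(design, refs, emptyTruth(), flatProfile(2e-3),
                       mean_depth = 2000, seed = 4)
  expect_gt(nrow(pileupData(pl)), 1e4)

  same1 <- downsamplePileup(pl, 500, seed = 9)
  same2 <- downsamplePileup(pl, 500, seed = 9)
  expect_identical(pileupData(same1), pileupData(same2))

  # target equal to (or above) the current mean leaves the table unchanged
  mu <- mean(pileupData(pl)$depth)
  expect_identical(pileupData(downsamplePileup(pl, mu, seed = 1)),
                   pileupData(pl))
  expect_warning(downsamplePileup(pl, mu * 2, seed = 1), "capped")

  # binomial thinning leaves the mean alt fraction unbiased (3 SE band)
  thin <- downsamplePileup(pl, 500, seed = 11)
  altfrac <- function(x) {
    d <- pileupData(x)
    refc <- as.matrix(d[, paste0("count_", .BASES)])[
      cbind(seq_len(nrow(d)), match(d$ref, .BASES))]
    ifelse(d$depth > 0, (d$depth - refc) / d$depth, NA)
  }
  a0 <- altfrac(pl); a1 <- altfrac(thin)
  ok <- !is.na(a0) & !is.na(a1)
  ddiff <- a1[ok] - a0[ok]
  expect_lt(abs(mean(ddiff)), 3 * stats::sd(ddiff) / sqrt(length(ddiff)))

  expect_error(downsamplePileup(PileupTable(pileupRow()[0, ]), 10, 1),
               "empty")
})

test_that("thinning 24,000x to 3,000x is the 8-plex retention", {
  d <- do.call(rbind, lapply(1:200, function(i)
    pileupRow(pos = 150L + i, read_pos = 50L, ref = "A", A = 24000L)))
  pl <- PileupTable(d)
  thin <- downsamplePileup(pl, 3000, seed = 5)
  # retention probability 1/8: realized mean within 3 binomial SEs
  m <- mean(pileupData(thin)$depth)
  se <- sqrt(24000 * (1 / 8) * (7 / 8) / 200)
  expect_lt(abs(m - 3000), 3 * se)
})
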