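# Shared fixtures, built in code at test time.

.BASES <- c("A", "C", "G", "T")

# a minimal one-amplicon design: 20 bp primers flanking a 160 bp target
tinyDesign <- function(chrom = "chr1", start = 101L, target_len = 160L,
                       primer_len = 20L, n = 1L, gap = 60L) {
  span <- target_len + 2L * primer_len
  starts <- start + (seq_len(n) - 1L) * (span + gap)
  AmpliconDesign(data.frame(
    amplicon_id = sprintf("amp%02d", seq_len(n)), chrom = chrom,
    target_start = starts + primer_len,
    target_end = starts + primer_len + target_len - 1L,
    fwd_primer_start = starts, fwd_primer_end = starts + primer_len - 1L,
    rev_primer_start = starts + primer_len + target_len,
    rev_primer_end = starts + span - 1L))
}

# one pileup column as a data.frame row
pileupRow <- function(amplicon_id = "amp01", direction = "F",
                      chrom = "chr1", pos = 150L, read_pos = 50L,
                      ref = "A", A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(amplicon_id = amplicon_id, direction = direction,
             chrom = chrom, pos = pos, read_pos = read_pos, ref = ref,
             count_A = A, count_C = C, count_G = G, count_T = T,
             depth = A + C + G + T, stringsAsFactors = FALSE)
}

# a uniform-rate error model: every substitution bin has rate `e`
flatErrorModel <- function(e = 1e-3, depth = 1e6) {
  grid <- expand.grid(direction = c("F", "R"), read_pos = 1:122,
                      ref = .BASES, alt = .BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  grid$mismatches <- as.integer(round(e * depth))
  grid$depth <- as.integer(depth)
  grid$raw_rate <- grid$mismatches / grid$depth
  suppressWarnings(smoothErrorRates(grid, sample_id = "flat"))
}

# near-zero error profile (rates are constrained to be positive)
nearZeroProfile <- function(rate = 1e-12) {
  r <- array(rate, dim = c(2L, 122L, 4L, 4L),
             dimnames = list(c("F", "R"), NULL, .BASES, .BASES))
  for (i in 1:4) r[, , i, i] <- NA_real_
  new("ErrorProfile", rates = r, preset = "near-zero")
}

flatProfile <- function(rate = 2e-3) {
  r <- array(rate, dim = c(2L, 122L, 4L, 4L),
             dimnames = list(c("F", "R"), NULL, .BASES, .BASES))
  for (i in 1:4) r[, , i, i] <- NA_real_
  new("ErrorProfile", rates = r, preset = "flat")
}

truthFromVariants <- function(variants, masked = NULL, sample_id = "truth") {
  if (is.null(masked)) masked <- unique(variants[, c("chrom", "pos")])
  new("TruthSet", variants = variants, masked = masked,
      sample_id = sample_id)
}

emptyTruth <- function() {
  truthFromVariants(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), expected_prevalence = numeric(),
               stringsAsFactors = FALSE),
    masked = data.frame(chrom = character(), pos = integer()))
}

# write a SAM file from read specs; returns the path
writeSam <- function(reads, path = tempfile(fileext = ".sam"),
                     chrom = "chr1", ln = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, ln))
  recs <- vapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    qual <- if (!is.null(r$qual)) r$qual
            else paste(rep(rawToChar(as.raw(33L + 30L)), nchar(r$seq)),
                       collapse = "")
    paste(sprintf("read%03d", i), r$flag, chrom, r$pos, 60L, r$cigar,
          "*", 0L, 0L, r$seq, qual, sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  path
}

qualString <- function(q) {
  paste(vapply(q, function(x) rawToChar(as.raw(33L + x)), character(1)),
        collapse = "")
}

# a minimal called tumor variant and germline pileup for somatic-rule tests
mkTumorCall <- function(pos = 150L, alt = "G", prevalence = 0.2) {
  data.frame(chrom = "chr1", pos = pos, amplicon_id = "amp01", ref = "A",
             alt = alt, read_pos_f = 50L, read_pos_r = NA,
             X_f = 200L, N_f = 1000L, X_r = NA, N_r = 0L,
             f_accepted = TRUE, r_accepted = FALSE, flags = NA_character_,
             status = "TESTED", p_f = 1e-20, p_r = NA, p = 1e-20,
             prevalence = prevalence, called = TRUE,
             stringsAsFactors = FALSE)
}

mkGermline <- function(pos = 150L, depth = 500L, alt_count = 0L,
                       alt = "G") {
  counts <- c(A = depth - alt_count, C = 0L, G = 0L, T = 0L)
  counts[alt] <- counts[alt] + alt_count
  PileupTable(pileupRow(pos = pos, read_pos = 50L, ref = "A",
                        A = counts["A"], C = counts["C"], G = counts["G"],
                        T = counts["T"]))
}

noCalls <- mkTumorCall()[0, ]

# exhaustive-summation oracle for the binomial upper tail, independent of
# pbinom: direct log-space term summation
binomTailOracle <- function(X, N, E) {
  if (X == 0) return(1)
  k <- X:N
  sum(exp(lchoose(N, k) + k * log(E) + (N - k) * log1p(-E)))
}

# brute-force threshold scan over all cut-points, independent of the
# implementation's cumulative-count path
thresholdOracle <- function(p, is_tp, n_truth, n_assayed) {
  thr <- sort(unique(p))
  best <- NULL
  for (t in thr) {
    tp <- sum(is_tp & p <= t); fp <- sum(!is_tp & p <= t)
    fn <- n_truth - tp; tn <- n_assayed - n_truth - fp
    mcc <- matthewsCorrelation(tp, fp, tn, fn)
    if (is.null(best) || mcc > best$mcc + 1e-15)
      best <- list(t = t, mcc = mcc)
  }
  best
}

# memoised full-scale calibration experiment shared by acceptance blocks
.acc_env <- new.env(parent = emptyenv())
acceptanceExperiment <- function() {
  if (is.null(.acc_env$ex))
    .acc_env$ex <- simulateCalibrationExperiment(
      n_pools = 3, n_amplicons = 150, n_snps = 200, mean_depth = 24000,
      preset = "GAII", seed = 1)
  .acc_env$ex
}
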