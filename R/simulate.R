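#' Synthetic per-cycle substitution-rate profiles
#'
#' Builds an [ErrorProfile-class] for the pileup simulator. The
#' \code{"GAII"} preset draws a base rate per (direction, reference,
#' alternative) uniformly in 0.05-0.3% and inflates rates linearly up to
#' threefold after cycle 100 for A/T reference bases, emulating
#' late-cycle error growth of older sequencing-by-synthesis chemistry.
#' The \code{"MiSeq"} preset is flat with base rates in 0.05-0.15%. The
#' two presets differ measurably beyond cycle 100. These are
#' plausibility presets for testing, not measured machine profiles.
#'
#' @param preset \code{"GAII"} or \code{"MiSeq"}.
#' @param seed integer seed (profiles are deterministic per seed).
#' @return an [ErrorProfile-class].
#' @export
errorProfile <- function(preset = c("GAII", "MiSeq"), seed = 1L) {
  preset <- match.arg(preset)
  rng <- if (preset == "GAII") c(5e-4, 3e-3) else c(5e-4, 1.5e-3)
  rates <- array(NA_real_, dim = c(2L, .READ_LEN, 4L, 4L),
                 dimnames = list(c("F", "R"), NULL, .BASES, .BASES))
  .withSeed(seed, {
    for (di in 1:2) for (ri in 1:4) for (ai in 1:4) {
      if (ri == ai) next
      base <- runif(1, rng[1], rng[2])
      k <- seq_len(.READ_LEN)
      ramp <- rep(1, .READ_LEN)
      if (preset == "GAII" && .BASES[ri] %in% c("A", "T"))
        ramp[k > 100] <- 1 + 2 * (k[k > 100] - 100) / (.READ_LEN - 100)
      rates[di, , ri, ai] <- base * ramp
    }
  })
  new("ErrorProfile", rates = rates, preset = preset)
}

#' Simulate an amplicon panel design
#'
#' Lays out \code{n_amplicons} amplicons along one synthetic chromosome:
#' each amplicon is \code{primer_length + target_length + primer_length}
#' bp (defaults 20 + 160 + 20 = 200 bp, the assay's geometry, under which
#' every target base is reachable within 100 cycles from at least one
#' read direction).
#'
#' @param n_amplicons number of amplicons (default 150).
#' @param target_length target bases per amplicon (default 160).
#' @param primer_length primer bases at each end (default 20).
#' @param chrom chromosome name.
#' @param gap bp between consecutive amplicons (default 60).
#' @return an [AmpliconDesign-class].
#' @export
simulateDesign <- function(n_amplicons = 150L, target_length = 160L,
                           primer_length = 20L, chrom = "sim1",
                           gap = 60L) {
  span <- target_length + 2L * primer_length
  starts <- 1000L + (seq_len(n_amplicons) - 1L) * (span + gap)
  AmpliconDesign(data.frame(
    amplicon_id = sprintf("amp%03d", seq_len(n_amplicons)),
    chrom = chrom,
    target_start = starts + primer_length,
    target_end = starts + primer_length + target_length - 1L,
    fwd_primer_start = starts,
    fwd_primer_end = starts + primer_length - 1L,
    rev_primer_start = starts + primer_length + target_length,
    rev_primer_end = starts + span - 1L,
    stringsAsFactors = FALSE))
}

#' Draw a random reference base for every design position
#'
#' @param design an [AmpliconDesign-class].
#' @param seed integer seed.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref}; the same
#'   seed reproduces the same reference, so several samples of one
#'   experiment share it.
#' @export
simulateReference <- function(design, seed = 1L) {
  dp <- .designPositions(design)
  dp <- unique(dp[, c("chrom", "pos")])
  dp <- dp[order(dp$chrom, dp$pos), ]
  .withSeed(seed, {
    dp$ref <- sample(.BASES, nrow(dp), replace = TRUE)
  })
  rownames(dp) <- NULL
  dp
}

#' Simulate calibration-donor genotypes
#'
#' Places \code{n_snps} SNPs at random target (non-primer) positions and
#' assigns each to be homozygous-alternative in exactly one of the four
#' donors and homozygous-reference in the others, mirroring the selection
#' of calibration SNPs; donors receive equal shares. Positions spread
#' over the amplicons end up at varied read positions.
#'
#' @param design an [AmpliconDesign-class].
#' @param reference data.frame from [simulateReference()].
#' @param n_snps number of calibration SNPs (default 200).
#' @param donors donor names (default \code{D1..D4}).
#' @param seed integer seed.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} and one allele-dosage column (0/1/2) per donor.
#' @export
simulateCalibrationGenotypes <- function(design, reference, n_snps = 200L,
                                         donors = paste0("D", 1:4),
                                         seed = 1L) {
  ap <- assayedPositions(design)
  if (n_snps > nrow(ap)) stop("more SNPs requested than assayed positions")
  .withSeed(seed, {
    pick <- sort(sample.int(nrow(ap), n_snps))
    g <- ap[pick, ]
    g$ref <- .lookupReference(reference, g$chrom, g$pos)
    g$alt <- vapply(g$ref, function(r) sample(setdiff(.BASES, r), 1L),
                    character(1))
    owner <- rep_len(seq_along(donors), n_snps)[sample.int(n_snps)]
    for (di in seq_along(donors))
      g[[donors[di]]] <- ifelse(owner == di, 2L, 0L)
  })
  rownames(g) <- NULL
  g
}

#' Donor mixing proportions for the calibration pools
#'
#' Pool k assigns the proportions 1%, 5%, 20% and 74% to the donors
#' rotated by k-1, so each donor sits at each proportion in one pool.
#'
#' @param donors donor names.
#' @param n_pools number of pools (default 4, named POOL-A..).
#' @return named list of named proportion vectors, each summing to 1.
#' @export
poolProportions <- function(donors = paste0("D", 1:4), n_pools = 4L) {
  base <- c(0.01, 0.05, 0.20, 0.74)
  stopifnot(length(donors) == 4L, n_pools >= 1L, n_pools <= 4L)
  out <- lapply(seq_len(n_pools), function(k) {
    stats::setNames(base[((seq_along(donors) + k - 2L) %% 4L) + 1L], donors)
  })
  names(out) <- paste0("POOL-", LETTERS[seq_len(n_pools)])
  out
}

#' Build the truth set of a calibration pool
#'
#' The expected prevalence of each variant is
#' \eqn{\sum_i proportion_i \cdot dosage_i / 2} over the pool's donors.
#' Positions with zero prevalence in this pool are not truth (but remain
#' masked for error training, as do all genotyped positions); variants
#' expected below the assay's 1% design floor are flagged
#' \code{sub_detectable} and excluded from sensitivity accounting.
#'
#' @param genotypes data.frame from [simulateCalibrationGenotypes()] (or
#'   the same layout with 0/1/2 dosages).
#' @param proportions named numeric vector of donor mixing proportions
#'   summing to 1 (within 1e-9).
#' @param sample_id pool identifier.
#' @return a [TruthSet-class].
#' @export
makePool <- function(genotypes, proportions, sample_id = "pool") {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("mixing proportions must sum to 1")
  miss <- setdiff(names(proportions), names(genotypes))
  if (length(miss))
    stop("genotypes lack dosage columns for donor(s): ",
         paste(miss, collapse = ", "))
  dos <- as.matrix(genotypes[, names(proportions)])
  prev <- as.numeric(dos %*% proportions) / 2
  v <- genotypes[, c("chrom", "pos", "ref", "alt")]
  v$expected_prevalence <- prev
  masked <- unique(genotypes[, c("chrom", "pos")])
  v <- v[prev > 0, ]
  v$sub_detectable <- v$expected_prevalence < 0.01
  rownames(v) <- NULL
  new("TruthSet", variants = v, masked = masked,
      sample_id = as.character(sample_id))
}

#' Per-amplicon amplification efficiencies
#'
#' Relative amplicon coverage factors, lognormal with unit mean;
#' \code{dispersion} is the log-scale standard deviation. The default
#' 0.52 makes about 82% of amplicons fall within 0.5-2x of the mean
#' coverage, the uniformity of a well-behaved multiplex panel. Drawn once
#' per experiment and shared across its samples, because amplification
#' efficiency is a property of the primer pair and coverage is
#' reproducible between samples of a run.
#'
#' @param design an [AmpliconDesign-class].
#' @param dispersion log-sd of amplicon efficiency (default 0.52).
#' @param seed integer seed.
#' @return named numeric vector of efficiencies (one per amplicon).
#' @export
ampliconEffects <- function(design, dispersion = 0.52, seed = 1L) {
  d <- designTable(design)
  .withSeed(seed, {
    eff <- rlnorm(nrow(d), meanlog = -dispersion^2 / 2, sdlog = dispersion)
  })
  stats::setNames(eff, d$amplicon_id)
}

# chained-binomial multinomial: distribute origin-base reads of each
# column into observed bases given per-column substitution rates
# (columns of `rateMat` in .BASES order; the origin base keeps the rest)
.corrupt <- function(n, origin_idx, rateMat) {
  out <- matrix(0L, nrow = length(n), ncol = 4L)
  remaining <- n
  probleft <- rep(1, length(n))
  for (bi in 1:4) {
    r <- rateMat[, bi]
    r[is.na(r)] <- 0         # origin base handled last
    draw <- rbinom(length(n), remaining, ifelse(probleft > 0,
                                                pmin(r / probleft, 1), 0))
    out[, bi] <- draw
    remaining <- remaining - draw
    probleft <- probleft - r
  }
  # whatever remains stays the origin base
  out[cbind(seq_along(n), origin_idx)] <- out[cbind(seq_along(n),
                                                    origin_idx)] + remaining
  out
}

#' Simulate a per-direction amplicon pileup with known truth
#'
#' Generates the pileup a calibration-pool (or tumor) sequencing run
#' would produce: per (amplicon, direction) a Poisson depth around
#' \code{mean_depth} scaled by the amplicon's efficiency, constant along
#' the read (every read covers all retained cycles); at truth positions
#' the variant allele is drawn binomially at its expected prevalence; and
#' every base call is corrupted according to the profile's
#' (direction, cycle, reference, alternative) substitution rate, variant
#' reads included.
#'
#' @param design an [AmpliconDesign-class].
#' @param reference data.frame from [simulateReference()].
#' @param truth a [TruthSet-class] (may be empty for a null sample).
#' @param profile an [ErrorProfile-class].
#' @param mean_depth mean per-direction column depth (> 0).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param dispersion amplicon-efficiency log-sd used when
#'   \code{amplicon_effect} is not supplied (default 0.52).
#' @param amplicon_effect optional named efficiency vector from
#'   [ampliconEffects()], shared across the samples of one experiment.
#' @param sample_jitter per-sample lognormal log-sd multiplying the
#'   shared efficiencies (default 0.1; ignored when
#'   \code{amplicon_effect} is NULL).
#' @param sample_id sample identifier.
#' @return a [PileupTable-class].
#' @export
simulatePileup <- function(design, reference, truth, profile, mean_depth,
                           seed, dispersion = 0.52, amplicon_effect = NULL,
                           sample_jitter = 0.1, sample_id = "sim") {
  stopifnot(is(design, "AmpliconDesign"), is(profile, "ErrorProfile"),
            mean_depth > 0)
  dd <- designTable(design)
  tv <- if (is(truth, "TruthSet")) truthVariants(truth) else truth
  if (!is.null(tv) && nrow(tv)) {
    dp <- .designPositions(design)
    if (!all(.posKey(tv$chrom, tv$pos) %in% .posKey(dp$chrom, dp$pos)))
      stop("truth position(s) outside the design")
  }

  cols <- lapply(seq_len(nrow(dd)), function(i) {
    fpos <- seq.int(dd$fwd_read_start[i],
                    min(dd$fwd_read_start[i] + .READ_LEN - 1L,
                        dd$rev_primer_end[i]))
    rpos <- seq.int(max(dd$rev_read_start[i] - .READ_LEN + 1L,
                        dd$fwd_primer_start[i]), dd$rev_read_start[i])
    rbind(
      data.frame(amplicon_id = dd$amplicon_id[i], direction = "F",
                 chrom = dd$chrom[i], pos = fpos,
                 read_pos = fpos - dd$fwd_read_start[i] + 1L,
                 stringsAsFactors = FALSE),
      data.frame(amplicon_id = dd$amplicon_id[i], direction = "R",
                 chrom = dd$chrom[i], pos = rpos,
                 read_pos = dd$rev_read_start[i] - rpos + 1L,
                 stringsAsFactors = FALSE))
  })
  cols <- do.call(rbind, cols)
  cols$ref <- .lookupReference(reference, cols$chrom, cols$pos)
  if (anyNA(cols$ref)) stop("reference does not cover all design positions")

  prev <- rep(0, nrow(cols))
  alt_idx <- rep(NA_integer_, nrow(cols))
  if (!is.null(tv) && nrow(tv)) {
    m <- match(.posKey(cols$chrom, cols$pos), .posKey(tv$chrom, tv$pos))
    hit <- !is.na(m)
    prev[hit] <- tv$expected_prevalence[m[hit]]
    alt_idx[hit] <- match(tv$alt[m[hit]], .BASES)
  }

  diri <- match(cols$direction, c("F", "R"))
  refi <- match(cols$ref, .BASES)

  .withSeed(seed, {
    if (is.null(amplicon_effect)) {
      eff <- ampliconEffects(design, dispersion = dispersion,
                             seed = sample.int(.Machine$integer.max, 1))
    } else {
      jit <- rlnorm(nrow(dd), -sample_jitter^2 / 2, sample_jitter)
      eff <- amplicon_effect[dd$amplicon_id] * jit
      names(eff) <- dd$amplicon_id
    }
    lam <- mean_depth * eff[cols$amplicon_id]
    # one depth per (amplicon, direction): reads span all cycles
    adkey <- paste(cols$amplicon_id, cols$direction)
    first <- !duplicated(adkey)
    Nad <- stats::setNames(rpois(sum(first), lam[first]), adkey[first])
    N <- as.integer(Nad[adkey])

    n_alt <- integer(nrow(cols))
    has_var <- prev > 0 & !is.na(alt_idx)
    n_alt[has_var] <- rbinom(sum(has_var), N[has_var], prev[has_var])
    n_ref <- N - n_alt

    getRates <- function(origin_idx) {
      sapply(1:4, function(bi)
        profile@rates[cbind(diri, cols$read_pos, origin_idx,
                            rep(bi, nrow(cols)))])
    }
    counts <- .corrupt(n_ref, refi, getRates(refi))
    if (any(has_var)) {
      ai <- alt_idx
      ai[!has_var] <- 1L   # dummy, zero reads
      vc <- .corrupt(ifelse(has_var, n_alt, 0L), ai, getRates(ai))
      counts <- counts + vc
    }
  })
  out <- cols
  out$count_A <- counts[, 1]; out$count_C <- counts[, 2]
  out$count_G <- counts[, 3]; out$count_T <- counts[, 4]
  out$depth <- as.integer(rowSums(counts))
  PileupTable(out, sample_id = sample_id,
              provenance = list(simulated = TRUE, preset = profile@preset,
                                mean_depth = mean_depth, seed = seed))
}

#' Inject host-genome contamination at mismatch positions
#'
#' Emulates co-amplification of host (e.g. mouse) DNA in a xenograft: at
#' every masked position, a binomial fraction of each column's depth is
#' switched from the reference to the host allele. Other positions are
#' untouched.
#'
#' @param x a [PileupTable-class].
#' @param mask data.frame of host/graft mismatch positions (\code{chrom},
#'   \code{pos}, optional \code{host_alt} base; when absent a non-reference
#'   base is chosen deterministically per position).
#' @param fraction contamination fraction in [0, 1).
#' @param seed integer seed.
#' @return the contaminated [PileupTable-class].
#' @export
injectHostContamination <- function(x, mask, fraction, seed = 1L) {
  stopifnot(is(x, "PileupTable"), fraction >= 0, fraction < 1)
  if (fraction == 0 || is.null(mask) || nrow(mask) == 0L) return(x)
  d <- pileupData(x)
  hit <- which(.posKey(d$chrom, d$pos) %in% .posKey(mask$chrom, mask$pos))
  if (!length(hit)) return(x)
  if ("host_alt" %in% names(mask)) {
    m <- match(.posKey(d$chrom, d$pos)[hit], .posKey(mask$chrom, mask$pos))
    alt <- mask$host_alt[m]
  } else {
    # deterministic non-reference host allele: next base in A<C<G<T order
    alt <- .BASES[(match(d$ref[hit], .BASES) %% 4L) + 1L]
  }
  .withSeed(seed, {
    extra <- rbinom(length(hit), d$depth[hit], fraction)
  })
  refcol <- paste0("count_", d$ref[hit])
  altcol <- paste0("count_", alt)
  for (i in seq_along(hit)) {
    take <- min(extra[i], d[[refcol[i]]][hit[i]])
    d[[refcol[i]]][hit[i]] <- d[[refcol[i]]][hit[i]] - take
    d[[altcol[i]]][hit[i]] <- d[[altcol[i]]][hit[i]] + take
  }
  PileupTable(d, sample_id = sampleId(x),
              provenance = c(x@provenance,
                             list(host_contamination = fraction)))
}

#' Attenuate low prevalences to emulate whole-genome-amplification bias
#'
#' Whole-genome amplification introduces allele-specific bias that
#' depresses the observed prevalence of low-prevalence variants. This
#' stress-test knob multiplies each truth variant's generative prevalence
#' by a random attenuation with mean below 1 that is strong below 5%
#' prevalence and negligible at high prevalence. No quantitative fidelity
#' is claimed.
#'
#' @param truth a [TruthSet-class].
#' @param bias_strength non-negative; 0 is the identity.
#' @param seed integer seed.
#' @return the [TruthSet-class] with attenuated expected prevalences
#'   (used for simulation; evaluation against the original truth shows
#'   the downward bias in observed prevalence).
#' @export
applyWgaBias <- function(truth, bias_strength, seed = 1L) {
  stopifnot(is(truth, "TruthSet"), bias_strength >= 0)
  if (bias_strength == 0) return(truth)
  v <- truthVariants(truth)
  if (!nrow(v)) return(truth)
  .withSeed(seed, {
    u <- runif(nrow(v))
  })
  g <- pmin(1, 0.05 / v$expected_prevalence)^2
  v$expected_prevalence <- v$expected_prevalence / (1 + bias_strength * u * g)
  new("TruthSet", variants = v, masked = maskedPositions(truth),
      sample_id = truth@sample_id)
}

#' Simulate a complete multi-pool calibration experiment
#'
#' Builds a design, reference, donor genotypes, the rotated-proportion
#' pool truth sets, shared amplicon efficiencies, and one simulated
#' pileup per pool, reproducing the calibration-pool experimental design
#' at a chosen scale.
#'
#' @param n_pools number of pools to simulate (2-4).
#' @param n_amplicons,n_snps,mean_depth,dispersion experiment scale.
#' @param preset error-profile preset.
#' @param seed master integer seed; all sub-seeds derive from it.
#' @return list with \code{design}, \code{reference}, \code{genotypes},
#'   \code{profile}, \code{effects}, \code{truths} (named list of
#'   [TruthSet-class]) and \code{pileups} (named list of
#'   [PileupTable-class]).
#' @export
simulateCalibrationExperiment <- function(n_pools = 2L, n_amplicons = 150L,
                                          n_snps = 200L, mean_depth = 24000,
                                          preset = "GAII",
                                          dispersion = 0.52, seed = 1L) {
  seed <- as.integer(seed) %% 100000L
  design <- simulateDesign(n_amplicons = n_amplicons)
  reference <- simulateReference(design, seed = seed * 7L + 1L)
  genotypes <- simulateCalibrationGenotypes(design, reference,
                                            n_snps = n_snps,
                                            seed = seed * 7L + 2L)
  profile <- errorProfile(preset, seed = seed * 7L + 3L)
  effects <- ampliconEffects(design, dispersion = dispersion,
                             seed = seed * 7L + 4L)
  props <- poolProportions(n_pools = n_pools)
  truths <- mapply(function(p, nm) makePool(genotypes, p, sample_id = nm),
                   props, names(props), SIMPLIFY = FALSE)
  pileups <- mapply(function(tr, k) {
    simulatePileup(design, reference, tr, profile, mean_depth,
                   seed = seed * 7L + 10L + k,
                   amplicon_effect = effects,
                   sample_id = tr@sample_id)
  }, truths, seq_along(truths), SIMPLIFY = FALSE)
  names(pileups) <- names(truths)
  list(design = design, reference = reference, genotypes = genotypes,
       profile = profile, effects = effects, truths = truths,
       pileups = pileups)
}
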