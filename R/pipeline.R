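#' Calibrate the caller on a calibration sample
#'
#' Runs the training stages on a calibration sample with known truth:
#' trains the smoothed error model on invariant bases (truth and masked
#' positions excluded), computes candidate p-values on the calibration
#' sample itself, selects the MCC-maximizing significance threshold
#' against the truth set, derives the coverage floor (5th depth
#' percentile), and, when control samples are supplied, the
#' systematic-noise mask. The returned artifact bundle drives
#' [runCall()].
#'
#' @param design an [AmpliconDesign-class].
#' @param pileup calibration [PileupTable-class].
#' @param truth the calibration [TruthSet-class].
#' @param controls optional list of >= 3 control [PileupTable-class]
#'   samples for the noise mask.
#' @param out_dir optional directory to serialize artifacts (error model
#'   TSV, threshold TSV, noise mask TSV).
#' @param minAltFrac,maxReadPosSingle prefilter constants.
#' @return list with \code{model} ([ErrorModel-class]), \code{threshold}
#'   ([ThresholdResult-class]), \code{coverage_floor}, \code{noise_mask},
#'   \code{n_assayed} and per-filter accounting \code{filter_counts}.
#' @export
runCalibrate <- function(design, pileup, truth, controls = NULL,
                         out_dir = NULL, minAltFrac = 0.002,
                         maxReadPosSingle = 100L) {
  stopifnot(is(truth, "TruthSet"))
  if (nrow(truthVariants(truth)) == 0L)
    stop("calibration truth set has no variants")
  model <- trainErrorModel(pileup, truth)
  cand <- callVariants(pileup, design, model, minAltFrac = minAltFrac,
                       maxReadPosSingle = maxReadPosSingle)
  n_assayed <- nrow(assayedPositions(design))
  thr <- selectThreshold(cand[cand$status == "TESTED", ], truth, n_assayed)
  floor_depth <- coverageFloor(pileup)
  noise <- NULL
  if (!is.null(controls))
    noise <- detectSystematicNoise(controls, design)
  counts <- table(cand$flags[cand$status == "FILTERED"], useNA = "no")
  filter_counts <- stats::setNames(as.integer(counts), names(counts))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeErrorModel(model, file.path(out_dir, "error_model.tsv"))
    .writeTsv(data.frame(p_threshold = thr@p_threshold, mcc = thr@mcc,
                         tp = thr@tp, fp = thr@fp, tn = thr@tn,
                         fn = thr@fn, coverage_floor = floor_depth),
              file.path(out_dir, "threshold.tsv"))
    if (!is.null(noise))
      .writeTsv(noise, file.path(out_dir, "noise_mask.tsv"))
  }
  list(model = model, threshold = thr, coverage_floor = floor_depth,
       noise_mask = noise, n_assayed = n_assayed,
       filter_counts = filter_counts, design = design)
}

#' Call variants in a tested sample using calibration artifacts
#'
#' Applies the full calling pass (prefilters, binomial/Stouffer
#' statistics with the calibration error model, coverage floor, MCC
#' threshold, optional noise mask) to a tested sample.
#'
#' @param pileup tested-sample [PileupTable-class].
#' @param calibration artifact bundle from [runCalibrate()].
#' @param design the [AmpliconDesign-class] (defaults to the one recorded
#'   in the calibration bundle; a mismatch is an error).
#' @param min_prevalence_report calls at or above this prevalence are
#'   PASS records in the VCF (default 0.05, the reporting floor of the
#'   clinical workflow); all calls are returned either way.
#' @param out_vcf optional VCF output path (a TSV mirror is written
#'   alongside).
#' @return data.frame of candidates and calls (see [callVariants()]).
#' @export
runCall <- function(pileup, calibration, design = calibration$design,
                    min_prevalence_report = 0.05, out_vcf = NULL) {
  if (!identical(designTable(design), designTable(calibration$design)))
    stop("design mismatch between the sample and the calibration artifacts")
  calls <- callVariants(pileup, design, calibration$model,
                        threshold = calibration$threshold,
                        coverage_floor = calibration$coverage_floor,
                        noise_mask = calibration$noise_mask)
  if (!is.null(out_vcf))
    .writeCandidateVcf(calls, out_vcf, min_prevalence_report)
  calls
}

# minimal VCF 4.2 emission for (non-somatic) candidate calls
.writeCandidateVcf <- function(calls, path, min_prevalence_report) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ampliCall %s",
            as.character(utils::packageVersion("ampliCall"))),
    "##FILTER=<ID=ABOVE_THRESHOLD,Description=\"Combined p above MCC threshold\">",
    "##FILTER=<ID=LOW_PREVALENCE,Description=\"Below the reporting prevalence floor\">",
    "##INFO=<ID=PREV,Number=1,Type=Float,Description=\"Estimated prevalence\">",
    "##INFO=<ID=PCOMB,Number=1,Type=Float,Description=\"Combined p-value\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- calls[calls$status == "TESTED" & !is.na(calls$p), ]
  rows <- rows[order(rows$chrom, rows$pos), ]
  filt <- ifelse(!rows$called, "ABOVE_THRESHOLD",
                 ifelse(rows$prevalence >= min_prevalence_report,
                        "PASS", "LOW_PREVALENCE"))
  keep <- filt == "PASS" | rows$called |
    (!is.na(rows$flags) & rows$flags == "ABOVE_THRESHOLD")
  rows <- rows[keep, ]; filt <- filt[keep]
  recs <- if (nrow(rows))
    paste(rows$chrom, rows$pos, ".", rows$ref, rows$alt,
          sprintf("%.1f", pmin(-10 * log10(pmax(rows$p, 1e-99)), 999)),
          filt,
          sprintf("PREV=%.6g;PCOMB=%.6g", rows$prevalence, rows$p),
          sep = "\t")
  else character(0)
  writeLines(c(hdr, recs), path)
  .writeTsv(calls, paste0(path, ".tsv"))
  invisible(path)
}

#' Somatic workflow: tumor versus germline with optional host mask
#'
#' Calls variants in the tumor sample with the run's calibration
#' artifacts, classifies them against the matched germline (analyzed
#' with the same artifacts), applies the cross-species mismatch mask
#' for xenografts, and optionally writes the somatic VCF.
#'
#' @param tumor_pileup,germline_pileup [PileupTable-class] samples.
#' @param calibration artifact bundle from [runCalibrate()].
#' @param cross_species_mask optional data.frame from
#'   [readCrossSpeciesMask()].
#' @param min_prevalence tumor calls below this prevalence are dropped
#'   before somatic classification (default 0.05; performance is
#'   substantially better at 5%+ prevalence).
#' @param out_vcf optional VCF path.
#' @return data.frame of classified somatic calls (see [callSomatic()]).
#' @export
runSomatic <- function(tumor_pileup, germline_pileup, calibration,
                       cross_species_mask = NULL, min_prevalence = 0.05,
                       out_vcf = NULL) {
  tumor_calls <- runCall(tumor_pileup, calibration)
  germ_calls <- runCall(germline_pileup, calibration)
  tc <- tumor_calls[!is.na(tumor_calls$called) & tumor_calls$called &
                      tumor_calls$prevalence >= min_prevalence, ]
  som <- callSomatic(tc, germline_pileup, germ_calls)
  som <- filterCrossSpecies(som, cross_species_mask)
  if (!is.null(out_vcf)) writeSomaticVcf(som, out_vcf)
  som
}

#' Evaluate performance over calibration/tested permutations
#'
#' For every ordered (calibration, tested) pool pair (self-pairs
#' excluded unless requested), calibrates on the first pool and calls
#' the second, reporting sensitivity (overall and per expected-prevalence
#' bin), PPV, specificity and the prevalence correlation. When a
#' \code{ladder} of target depths is given, both pools are binomially
#' thinned to each level and the calibration re-run at that level, so
#' the threshold always matches the depth it is applied at.
#'
#' @param pileups named list of pool [PileupTable-class] objects.
#' @param truths named list of matching [TruthSet-class] objects.
#' @param design the [AmpliconDesign-class].
#' @param ladder optional numeric vector of target mean depths.
#' @param seed integer seed for the thinning draws.
#' @param self_pairs include calibration == tested pairs (diagnostics
#'   only; default FALSE).
#' @return data.frame with one row per (pair, depth level) and metric
#'   columns.
#' @export
runEvaluate <- function(pileups, truths, design, ladder = NULL, seed = 1L,
                        self_pairs = FALSE) {
  stopifnot(length(pileups) == length(truths),
            identical(names(pileups), names(truths)))
  if (length(pileups) < 2L && !self_pairs)
    stop("need at least two pools (or set self_pairs = TRUE)")
  nm <- names(pileups)
  pairs <- expand.grid(calibration = nm, tested = nm,
                       stringsAsFactors = FALSE)
  if (!self_pairs) pairs <- pairs[pairs$calibration != pairs$tested, ]
  levels <- if (is.null(ladder)) NA_real_ else ladder
  out <- list()
  k <- 0L
  for (li in seq_along(levels)) {
    lev <- levels[li]
    for (pi in seq_len(nrow(pairs))) {
      calnm <- pairs$calibration[pi]; tstnm <- pairs$tested[pi]
      calp <- pileups[[calnm]]; tstp <- pileups[[tstnm]]
      if (!is.na(lev)) {
        calp <- downsamplePileup(calp, lev, seed = seed + 1000L * li + pi)
        tstp <- downsamplePileup(tstp, lev,
                                 seed = seed + 1000L * li + 500L + pi)
      }
      art <- runCalibrate(design, calp, truths[[calnm]])
      calls <- runCall(tstp, art)
      perf <- evaluatePerformance(calls, truths[[tstnm]], art$n_assayed,
                                  pileup = tstp)
      k <- k + 1L
      out[[k]] <- data.frame(
        calibration = calnm, tested = tstnm, mean_depth = lev,
        sensitivity = perf$sensitivity,
        sens_1 = perf$sensitivity_by_bin[["1%"]],
        sens_5 = perf$sensitivity_by_bin[["5%"]],
        sens_20 = perf$sensitivity_by_bin[["20%"]],
        sens_74 = perf$sensitivity_by_bin[["74%"]],
        ppv = perf$ppv, specificity = perf$specificity,
        prevalence_r = perf$prevalence_r,
        coverage_uniformity = perf$coverage_uniformity,
        tp = perf$tp, fp = perf$fp, fn = perf$fn,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
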