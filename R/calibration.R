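#' Matthews correlation coefficient
#'
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' with the usual convention that any zero factor in the denominator
#' yields 0. Used because the calibration truth is heavily imbalanced
#' (hundreds of true variants against tens of thousands of invariant
#' bases), where accuracy-style metrics are uninformative.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (vectorized).
#' @return MCC value(s) in [-1, 1].
#' @export
matthewsCorrelation <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  if (any(tp + fp + tn + fn == 0))
    warning("all four confusion counts are zero; returning 0")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  num <- tp * tn - fp * fn
  ifelse(den == 0, 0, num / sqrt(den))
}

#' Select the calling threshold by maximizing MCC on calibration truth
#'
#' Candidates from running the calling pass on the calibration sample
#' itself are ranked by combined p-value. Every distinct candidate
#' p-value is tried as a threshold (call a candidate when
#' \code{p <= t}); true positives are calls matching a calibration
#' variant (position and allele), false positives are other calls, false
#' negatives are truth variants not called, and true negatives are the
#' remaining assayed invariant bases. The threshold maximizing the MCC is
#' returned, ties broken toward the smallest (most stringent) threshold.
#'
#' @param candidates data.frame of tested candidates with columns
#'   \code{chrom}, \code{pos}, \code{alt}, \code{p} (e.g. the
#'   \code{status == "TESTED"} rows of [callVariants()]).
#' @param truth a [TruthSet-class] for the calibration sample.
#' @param n_assayed total number of assayed (target, non-primer) bases,
#'   the denominator from which true negatives are counted; see
#'   [assayedPositions()].
#' @return a [ThresholdResult-class].
#' @export
selectThreshold <- function(candidates, truth, n_assayed) {
  stopifnot(is(truth, "TruthSet"))
  tv <- truthVariants(truth)
  sub <- if ("sub_detectable" %in% names(tv)) tv$sub_detectable
         else rep(FALSE, nrow(tv))
  tv <- tv[!rep_len(sub, nrow(tv)), , drop = FALSE]
  if (nrow(tv) == 0L) stop("truth set is empty")
  cand <- candidates[!is.na(candidates$p), ]
  if (nrow(cand) == 0L) stop("no candidates to threshold")
  truthkey <- .varKey(tv$chrom, tv$pos, tv$alt)
  candkey <- .varKey(cand$chrom, cand$pos, cand$alt)
  is_tp <- candkey %in% truthkey
  if (!any(is_tp))
    stop("no candidate overlaps the truth set; cannot calibrate")
  n_truth <- nrow(tv)
  n_neg <- n_assayed - n_truth

  o <- order(cand$p)
  p_sorted <- cand$p[o]
  tp_cum <- cumsum(is_tp[o])
  fp_cum <- cumsum(!is_tp[o])
  last <- !duplicated(p_sorted, fromLast = TRUE)   # last index of each p
  thr <- p_sorted[last]
  tp <- tp_cum[last]
  fp <- fp_cum[last]
  fn <- n_truth - tp
  tn <- n_neg - fp
  mcc <- matthewsCorrelation(tp, fp, tn, fn)
  best <- which(mcc == max(mcc))[1]   # thresholds ascending: first = smallest
  new("ThresholdResult", p_threshold = thr[best], mcc = mcc[best],
      tp = as.numeric(tp[best]), fp = as.numeric(fp[best]),
      tn = as.numeric(tn[best]), fn = as.numeric(fn[best]))
}

#' Coverage floor from the calibration sample (Filter 5)
#'
#' The nearest-rank 5th percentile of collapsed (direction-merged)
#' per-base depth across all bases of the calibration sample. Tested
#' positions with collapsed depth strictly below this floor are excluded
#' from calling, preventing bias from coverage discrepancies between the
#' calibration and tested samples; a base exactly at the floor is
#' retained.
#'
#' @param x the calibration [PileupTable-class].
#' @param probs percentile (default 0.05).
#' @return the depth threshold (a single number).
#' @export
coverageFloor <- function(x, probs = 0.05) {
  depths <- collapsedDepth(x)$depth
  if (!length(depths)) stop("empty pileup: no coverage to rank")
  s <- sort(depths)
  s[max(1L, ceiling(probs * length(s)))]
}

#' Detect recurrently noisy positions from control samples (Filter 7)
#'
#' Sequence context (GC content, low complexity) causes systematic noise
#' at specific positions. For each control (germline blood) sample and
#' each position, the local error rate is the pooled non-reference
#' fraction over the 10 positions upstream and 10 downstream (truncated
#' at amplicon boundaries; positions with fewer than \code{min_flank}
#' available flanking positions per side are unassessable and skipped).
#' The position's own non-reference count is tested against that local
#' rate with an upper-tail binomial test; it is noisy in that control
#' when \code{p < alpha} (the per-amplicon Bonferroni-corrected level as
#' used operationally, 5e-4). Positions noisy in at least
#' \code{min_recurrence} controls are masked from candidate lists.
#'
#' @param controls list of at least \code{min_recurrence}
#'   [PileupTable-class] control samples on the same design.
#' @param design the [AmpliconDesign-class].
#' @param window flanking positions per side (default 10).
#' @param alpha per-position significance level (default 5e-4).
#' @param min_recurrence controls in which a position must be noisy to be
#'   masked (default 3).
#' @param min_flank minimum available flanking positions per side
#'   (default 5).
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{n_controls_noisy} for masked positions; per-control p-values
#'   are attached as attribute \code{"per_control"} for audit.
#' @export
detectSystematicNoise <- function(controls, design, window = 10L,
                                  alpha = 5e-4, min_recurrence = 3L,
                                  min_flank = 5L) {
  if (length(controls) < min_recurrence)
    stop("need at least ", min_recurrence, " control samples (got ",
         length(controls), "); lower min_recurrence explicitly if intended")
  dd <- designTable(design)
  audit <- list()
  tallies <- list()
  for (ci in seq_along(controls)) {
    ctrl <- controls[[ci]]
    stopifnot(is(ctrl, "PileupTable"))
    pd <- data.table::as.data.table(pileupData(ctrl))
    m <- match(pd$amplicon_id, dd$amplicon_id)
    refcnt <- as.matrix(pd[, .COUNT_COLS, with = FALSE])[
      cbind(seq_len(nrow(pd)), match(pd$ref, .BASES))]
    pd$altn <- pd$depth - refcnt
    # collapse directions within amplicon: local context is positional
    cp <- pd[, list(depth = sum(depth), altn = sum(altn)),
             by = c("amplicon_id", "chrom", "pos")]
    cp <- cp[order(cp$amplicon_id, cp$pos), ]
    res <- lapply(split(seq_len(nrow(cp)), cp$amplicon_id), function(ii) {
      n <- length(ii)
      dep <- cp$depth[ii]; altn <- cp$altn[ii]
      pvals <- rep(NA_real_, n)
      for (j in seq_len(n)) {
        lo <- max(1L, j - window); hi <- min(n, j + window)
        left <- j - lo; right <- hi - j
        if (left < min_flank || right < min_flank) next
        fl <- setdiff(lo:hi, j)
        fd <- sum(dep[fl]); fa <- sum(altn[fl])
        if (fd == 0L) next
        rate <- max(fa / fd, .P_MIN)
        if (rate >= 1) rate <- 1 - 1e-12
        pvals[j] <- pbinom(altn[j] - 1, dep[j], rate, lower.tail = FALSE)
      }
      data.frame(chrom = cp$chrom[ii], pos = cp$pos[ii], p = pvals,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$noisy <- !is.na(res$p) & res$p < alpha
    audit[[ci]] <- res
    tallies[[ci]] <- res[res$noisy, c("chrom", "pos")]
  }
  all_noisy <- do.call(rbind, tallies)
  if (is.null(all_noisy) || nrow(all_noisy) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      n_controls_noisy = integer())
  } else {
    tab <- table(.posKey(all_noisy$chrom, all_noisy$pos))
    rec <- names(tab)[tab >= min_recurrence]
    if (length(rec)) {
      parts <- strsplit(rec, ":", fixed = TRUE)
      out <- data.frame(
        chrom = vapply(parts, function(z)
          paste(z[-length(z)], collapse = ":"), character(1)),
        pos = as.integer(vapply(parts, function(z) z[length(z)],
                                character(1))),
        n_controls_noisy = as.integer(tab[rec]),
        stringsAsFactors = FALSE)
      out <- out[order(out$chrom, out$pos), ]
      rownames(out) <- NULL
    } else {
      out <- data.frame(chrom = character(), pos = integer(),
                        n_controls_noisy = integer())
    }
  }
  attr(out, "per_control") <- audit
  out
}

#' Evaluate calling performance against a truth set
#'
#' Computes sensitivity (overall and per expected-prevalence bin), PPV,
#' specificity over assayed non-truth bases, the Pearson correlation of
#' observed versus expected prevalence among detected truth variants, and
#' (when the pileup is supplied) amplicon-wise coverage uniformity (the
#' fraction of amplicons within 0.5-2x of the mean amplicon coverage).
#' Truth variants below the assay's 1% design floor
#' (\code{sub_detectable}) are excluded from the sensitivity denominator.
#'
#' @param calls data.frame from [callVariants()] (rows with
#'   \code{called == TRUE} are treated as calls).
#' @param truth a [TruthSet-class].
#' @param n_assayed number of assayed (target, non-primer) bases.
#' @param pileup optional [PileupTable-class] for coverage uniformity.
#' @return named list of metrics and confusion counts; undefined metrics
#'   (e.g. PPV with zero calls) are \code{NA}.
#' @export
evaluatePerformance <- function(calls, truth, n_assayed, pileup = NULL) {
  stopifnot(is(truth, "TruthSet"))
  tv <- truthVariants(truth)
  sub <- if ("sub_detectable" %in% names(tv)) tv$sub_detectable
         else rep(FALSE, nrow(tv))
  tv <- tv[!rep_len(sub, nrow(tv)), , drop = FALSE]
  called <- calls[!is.na(calls$called) & calls$called, ]
  truthkey <- .varKey(tv$chrom, tv$pos, tv$alt)
  callkey <- .varKey(called$chrom, called$pos, called$alt)
  # a call anywhere at a truth position with the wrong allele is neither
  # TP nor clean: count it as FP like any other spurious call
  tp_mask <- callkey %in% truthkey
  tp <- sum(tp_mask)
  fp <- sum(!tp_mask)
  fn <- sum(!(truthkey %in% callkey))
  tn <- n_assayed - nrow(tv) - fp

  bins <- c(`1%` = 0.01, `5%` = 0.05, `20%` = 0.20, `74%` = 0.74)
  cuts <- c(-Inf, 0.03, 0.125, 0.47, Inf)
  tv$bin <- names(bins)[findInterval(tv$expected_prevalence, cuts)]
  det <- truthkey %in% callkey
  sens_by_bin <- vapply(names(bins), function(b) {
    i <- tv$bin == b
    if (!any(i)) NA_real_ else mean(det[i])
  }, numeric(1))

  # prevalence correlation among detected truth variants
  mm <- match(truthkey, callkey)
  obs <- called$prevalence[mm[det]]
  expct <- tv$expected_prevalence[det]
  r <- if (sum(det) >= 3) cor(expct, obs) else NA_real_

  uniformity <- NA_real_
  if (!is.null(pileup)) {
    pd <- data.table::as.data.table(pileupData(pileup))
    ad <- pd[, list(cov = mean(depth)), by = c("amplicon_id", "direction")]
    ad <- ad[, list(cov = sum(cov)), by = "amplicon_id"]  # F+R per amplicon
    mu <- mean(ad$cov)
    uniformity <- mean(ad$cov >= 0.5 * mu & ad$cov <= 2 * mu)
  }
  list(
    sensitivity = if (nrow(tv)) tp / nrow(tv) else NA_real_,
    sensitivity_by_bin = sens_by_bin,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    prevalence_r = r,
    coverage_uniformity = uniformity,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_truth = nrow(tv), n_calls = nrow(called))
}
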