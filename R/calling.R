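#' Upper-tail binomial p-value for excess alternative alleles
#'
#' Probability of observing \code{X} or more alternative calls among
#' \code{N} under the error rate \code{E}: \eqn{P(B \ge X)} for
#' \eqn{B \sim Binomial(N, E)}. The tail includes X, so \code{X = 0}
#' yields exactly 1 and p-values rank candidates coherently.
#'
#' @param X alternative-allele count(s), \code{0 <= X <= N}.
#' @param N read depth(s).
#' @param E error rate(s) in (0, 1).
#' @return p-value(s) in (0, 1], clamped below at 1e-300.
#' @export
binomialTailPvalue <- function(X, N, E) {
  if (any(X > N)) stop("X must not exceed N")
  if (any(X < 0 | N < 0)) stop("negative counts")
  if (any(E <= 0 | E >= 1)) stop("E must lie strictly within (0, 1)")
  p <- pbinom(X - 1, N, E, lower.tail = FALSE)
  .clampP(p)
}

#' Combine per-direction p-values with a depth-weighted Stouffer Z-score
#'
#' Each direction's p-value is mapped to a Z-score
#' \eqn{Z_i = \Phi^{-1}(1 - p_i)} and the directions are combined as
#' \eqn{Z = (N_f Z_f + N_r Z_r) / \sqrt{N_f^2 + N_r^2}}, weighting by
#' read depth; the combined p-value is \eqn{1 - \Phi(Z)}. When only one
#' direction carries evidence (absent, zero depth, or rejected by the
#' strand-consistency filter) the other direction's p-value is returned
#' unchanged. All arguments are vectorized.
#'
#' @param p_f,p_r per-direction p-values in (0, 1]; \code{NA} when the
#'   direction is absent.
#' @param N_f,N_r per-direction read depths (0 or \code{NA} when absent).
#' @return combined p-value(s) in (0, 1].
#' @export
combineStouffer <- function(p_f, N_f, p_r, N_r) {
  n <- max(length(p_f), length(p_r), length(N_f), length(N_r))
  p_f <- rep_len(p_f, n); p_r <- rep_len(p_r, n)
  N_f <- rep_len(as.numeric(N_f), n); N_r <- rep_len(as.numeric(N_r), n)
  has_f <- !is.na(p_f) & !is.na(N_f) & N_f > 0
  has_r <- !is.na(p_r) & !is.na(N_r) & N_r > 0
  if (any(!has_f & !has_r))
    stop("at least one direction must carry evidence")
  out <- numeric(n)
  only_f <- has_f & !has_r
  only_r <- has_r & !has_f
  both <- has_f & has_r
  out[only_f] <- p_f[only_f]
  out[only_r] <- p_r[only_r]
  if (any(both)) {
    zf <- qnorm(.clampP(p_f[both], upper = 1 - 1e-16), lower.tail = FALSE)
    zr <- qnorm(.clampP(p_r[both], upper = 1 - 1e-16), lower.tail = FALSE)
    z <- (N_f[both] * zf + N_r[both] * zr) / sqrt(N_f[both]^2 + N_r[both]^2)
    out[both] <- pnorm(z, lower.tail = FALSE)
  }
  .clampP(out)
}

#' Pooled prevalence estimate
#'
#' The variant-allele prevalence is the pooled alternative count over the
#' pooled depth of the accepted directions only; a direction rejected by
#' the strand-consistency filter contributes nothing.
#'
#' @param X_f,N_f,X_r,N_r per-direction evidence (use \code{NA} or 0
#'   depth for an absent direction).
#' @param f_accepted,r_accepted logical vectors marking accepted
#'   directions.
#' @return prevalence estimate(s) in [0, 1].
#' @export
estimatePrevalence <- function(X_f, N_f, X_r, N_r,
                               f_accepted = TRUE, r_accepted = TRUE) {
  n <- max(length(X_f), length(X_r))
  X_f <- rep_len(as.numeric(X_f), n); N_f <- rep_len(as.numeric(N_f), n)
  X_r <- rep_len(as.numeric(X_r), n); N_r <- rep_len(as.numeric(N_r), n)
  f_accepted <- rep_len(f_accepted, n) & !is.na(N_f) & N_f > 0
  r_accepted <- rep_len(r_accepted, n) & !is.na(N_r) & N_r > 0
  X <- ifelse(f_accepted, X_f, 0) + ifelse(r_accepted, X_r, 0)
  N <- ifelse(f_accepted, N_f, 0) + ifelse(r_accepted, N_r, 0)
  if (any(N == 0))
    stop("zero accepted depth: no direction available for prevalence")
  X / N
}

# Aggregate a pileup to one record per (chrom, pos, direction), merging
# observations of the same position from overlapping amplicons (counts
# summed, smallest read position kept), and flag primer positions.
.positionTable <- function(x, design) {
  pd <- data.table::as.data.table(pileupData(x))
  dd <- designTable(design)
  m <- match(pd$amplicon_id, dd$amplicon_id)
  if (anyNA(m))
    stop("pileup refers to amplicons absent from the design: ",
         paste(head(unique(pd$amplicon_id[is.na(m)]), 3), collapse = ", "))
  pd$in_primer <- pd$pos <= dd$fwd_primer_end[m] |
    pd$pos >= dd$rev_primer_start[m]
  agg <- pd[, c(list(amplicon_id = amplicon_id[1], ref = ref[1],
                     read_pos = min(read_pos), depth = sum(depth),
                     in_primer = all(in_primer)),
                lapply(.SD, sum)),
            by = c("chrom", "pos", "direction"),
            .SDcols = .COUNT_COLS]
  agg
}

#' Prefilter candidate positions (Filters 1-4)
#'
#' Screens pileup positions before any statistics:
#' \describe{
#'   \item{Filter 1 (PRIMER)}{positions inside a primer span are removed
#'     (primer bases are synthesized, not sampled from the template).}
#'   \item{Filter 2 (MIN_ALT_FRAC)}{positions whose pooled non-reference
#'     fraction is below \code{minAltFrac} (default 0.2%) are removed;
#'     a fraction exactly at the cutoff is retained.}
#'   \item{Filter 3 (READ_END)}{positions covered by a single direction
#'     at a read position beyond \code{maxReadPosSingle} (default 100)
#'     are removed, avoiding the elevated late-cycle error rates.}
#'   \item{Filter 4 (DIRECTION_REJECTED_F/R)}{at dual-direction positions
#'     where the two directions disagree about a candidate allele
#'     (its fraction exceeds \code{minAltFrac} in one direction only),
#'     a direction is rejected when its coverage is under a tenth of the
#'     other's, or when it observes the position later in the read.}
#' }
#' Every non-reference allele at a surviving position becomes a candidate
#' row; removed positions are retained with \code{status = "FILTERED"}
#' and their triggering flag, so filter accounting conserves positions.
#'
#' @param x a [PileupTable-class].
#' @param design the matching [AmpliconDesign-class].
#' @param minAltFrac Filter 2 cutoff (default 0.002).
#' @param maxReadPosSingle Filter 3 cutoff (default 100).
#' @return data.frame of candidate and filtered rows; candidate rows are
#'   one per (position, alternative allele) with per-direction evidence
#'   and acceptance flags. Applying the function to already-surviving
#'   evidence changes nothing (it is idempotent).
#' @export
applyPrefilters <- function(x, design, minAltFrac = 0.002,
                            maxReadPosSingle = 100L) {
  agg <- .positionTable(x, design)
  f <- agg[agg$direction == "F", ]
  r <- agg[agg$direction == "R", ]
  pos <- merge(
    data.table::setnames(
      f[, c("chrom", "pos", "amplicon_id", "ref", "read_pos", "depth",
            "in_primer", .COUNT_COLS), with = FALSE],
      c("read_pos", "depth", .COUNT_COLS),
      c("read_pos_f", "N_f", paste0(.COUNT_COLS, "_f"))),
    data.table::setnames(
      r[, c("chrom", "pos", "amplicon_id", "ref", "read_pos", "depth",
            "in_primer", .COUNT_COLS), with = FALSE],
      c("read_pos", "depth", .COUNT_COLS),
      c("read_pos_r", "N_r", paste0(.COUNT_COLS, "_r"))),
    by = c("chrom", "pos"), all = TRUE, suffixes = c("_f", "_r"))
  pos$amplicon_id <- ifelse(is.na(pos$amplicon_id_f),
                            pos$amplicon_id_r, pos$amplicon_id_f)
  pos$ref <- ifelse(is.na(pos$ref_f), pos$ref_r, pos$ref_f)
  pos$in_primer <- ifelse(is.na(pos$in_primer_f), FALSE, pos$in_primer_f) |
    ifelse(is.na(pos$in_primer_r), FALSE, pos$in_primer_r)
  for (cc in c(paste0(.COUNT_COLS, "_f"), paste0(.COUNT_COLS, "_r"),
               "N_f", "N_r"))
    pos[[cc]][is.na(pos[[cc]])] <- 0L

  refi <- match(pos$ref, .BASES)
  cf <- as.matrix(pos[, paste0(.COUNT_COLS, "_f"), with = FALSE])
  cr <- as.matrix(pos[, paste0(.COUNT_COLS, "_r"), with = FALSE])
  nidx <- cbind(seq_len(nrow(pos)), refi)
  total_depth <- pos$N_f + pos$N_r
  total_alt <- total_depth - (cf[nidx] + cr[nidx])

  flag <- rep(NA_character_, nrow(pos))
  flag[pos$in_primer] <- "PRIMER"
  open <- is.na(flag)
  low <- open & total_alt / pmax(total_depth, 1L) < minAltFrac
  flag[low] <- "MIN_ALT_FRAC"
  open <- is.na(flag)
  single <- (pos$N_f == 0L) != (pos$N_r == 0L)
  srp <- ifelse(pos$N_f > 0L, pos$read_pos_f, pos$read_pos_r)
  end <- open & single & srp > maxReadPosSingle
  flag[end] <- "READ_END"

  filtered <- data.frame(
    chrom = pos$chrom, pos = pos$pos, amplicon_id = pos$amplicon_id,
    ref = pos$ref, alt = NA_character_,
    read_pos_f = pos$read_pos_f, read_pos_r = pos$read_pos_r,
    X_f = NA_integer_, N_f = pos$N_f, X_r = NA_integer_, N_r = pos$N_r,
    f_accepted = NA, r_accepted = NA,
    flags = flag, status = "FILTERED", stringsAsFactors = FALSE)[!is.na(flag), ]

  keep <- is.na(flag)
  pos <- pos[keep, ]
  cf <- cf[keep, , drop = FALSE]
  cr <- cr[keep, , drop = FALSE]

  # expand to one row per non-reference allele
  out <- NULL
  if (nrow(pos)) {
    rows <- lapply(seq_along(.BASES), function(bi) {
      sel <- which(match(pos$ref, .BASES) != bi)
      if (!length(sel)) return(NULL)
      data.frame(
        chrom = pos$chrom[sel], pos = pos$pos[sel],
        amplicon_id = pos$amplicon_id[sel], ref = pos$ref[sel],
        alt = .BASES[bi],
        read_pos_f = pos$read_pos_f[sel], read_pos_r = pos$read_pos_r[sel],
        X_f = cf[sel, bi], N_f = pos$N_f[sel],
        X_r = cr[sel, bi], N_r = pos$N_r[sel],
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    dual <- out$N_f > 0L & out$N_r > 0L
    frac_f <- ifelse(out$N_f > 0L, out$X_f / out$N_f, 0)
    frac_r <- ifelse(out$N_r > 0L, out$X_r / out$N_r, 0)
    inconsistent <- dual & ((frac_f > minAltFrac) != (frac_r > minAltFrac))
    rej_f <- inconsistent & (out$N_f < 0.1 * out$N_r |
                               out$read_pos_f > out$read_pos_r)
    rej_r <- inconsistent & (out$N_r < 0.1 * out$N_f |
                               out$read_pos_r > out$read_pos_f)
    out$f_accepted <- out$N_f > 0L & !rej_f
    out$r_accepted <- out$N_r > 0L & !rej_r
    fl <- character(nrow(out))
    fl[rej_f] <- "DIRECTION_REJECTED_F"
    fl[rej_r] <- paste0(ifelse(fl[rej_r] == "", "",
                               paste0(fl[rej_r], ",")),
                        "DIRECTION_REJECTED_R")
    out$flags <- ifelse(fl == "", NA_character_, fl)
    out$status <- ifelse(out$f_accepted | out$r_accepted,
                         "TESTED", "FILTERED")
  }
  res <- rbind(filtered, out)
  res <- res[order(res$chrom, res$pos, res$alt, na.last = TRUE), ]
  rownames(res) <- NULL
  res
}

#' Test candidate positions against the error model
#'
#' Runs the full per-sample calling pass: prefilters (Filters 1-4), the
#' per-direction binomial tail test against the error model's smoothed
#' rates, depth-weighted Stouffer combination across directions, pooled
#' prevalence estimation, and, when supplied, the coverage floor
#' (Filter 5, positions below the calibration sample's 5th depth
#' percentile), the MCC-selected significance threshold (Filter 6) and
#' the systematic-noise mask (Filter 7). Each tested position is reported
#' once, for its best-supported alternative allele (smallest combined
#' p-value; ties broken by the larger pooled count, then alphabetically).
#'
#' @param x a [PileupTable-class] for the sample to analyze.
#' @param design the [AmpliconDesign-class].
#' @param model an [ErrorModel-class] trained on the run's calibration
#'   sample.
#' @param threshold optional p-value threshold (a [ThresholdResult-class]
#'   or a number); candidates with \code{p <= threshold} are
#'   \code{called}.
#' @param coverage_floor optional minimum collapsed depth (Filter 5);
#'   positions strictly below it are flagged \code{LOW_COVERAGE}.
#' @param noise_mask optional data.frame of recurrently noisy positions
#'   (\code{chrom}, \code{pos}); flagged \code{NOISY_POSITION}.
#' @param minAltFrac,maxReadPosSingle passed to [applyPrefilters()].
#' @return data.frame with one row per position: filtered positions carry
#'   their flag; tested positions carry per-direction evidence, p-values,
#'   the combined p-value, the prevalence estimate and \code{called}.
#' @export
callVariants <- function(x, design, model, threshold = NULL,
                         coverage_floor = NULL, noise_mask = NULL,
                         minAltFrac = 0.002, maxReadPosSingle = 100L) {
  stopifnot(is(model, "ErrorModel"))
  cand <- applyPrefilters(x, design, minAltFrac = minAltFrac,
                          maxReadPosSingle = maxReadPosSingle)
  tested <- cand[cand$status == "TESTED", ]
  filtered <- cand[cand$status == "FILTERED" & is.na(cand$alt), ]
  # positions whose every allele lost both directions to Filter 4 are
  # reported once, as filtered, so position accounting is conserved
  lost <- cand[cand$status == "FILTERED" & !is.na(cand$alt), ]
  lost <- lost[!(.posKey(lost$chrom, lost$pos) %in%
                   .posKey(tested$chrom, tested$pos)), ]
  if (nrow(lost)) {
    lost <- lost[!duplicated(.posKey(lost$chrom, lost$pos)), ]
    lost$alt <- NA_character_
    filtered <- rbind(filtered, lost)
  }

  if (nrow(tested)) {
    # Filter 5: coverage floor on collapsed (F+R) depth
    if (!is.null(coverage_floor)) {
      low <- tested$N_f + tested$N_r < coverage_floor
      if (any(low)) {
        lowpos <- unique(tested[low, c("chrom", "pos")])
        add <- tested[low & !duplicated(.posKey(tested$chrom, tested$pos)), ]
        add$alt <- NA_character_
        add$flags <- "LOW_COVERAGE"
        add$status <- "FILTERED"
        filtered <- rbind(filtered, add)
        tested <- tested[!low, ]
      }
    }
    # Filter 7: systematic-noise mask
    if (!is.null(noise_mask) && nrow(noise_mask) && nrow(tested)) {
      noisy <- .posKey(tested$chrom, tested$pos) %in%
        .posKey(noise_mask$chrom, noise_mask$pos)
      if (any(noisy)) {
        add <- tested[noisy & !duplicated(.posKey(tested$chrom, tested$pos)), ]
        add$alt <- NA_character_
        add$flags <- "NOISY_POSITION"
        add$status <- "FILTERED"
        filtered <- rbind(filtered, add)
        tested <- tested[!noisy, ]
      }
    }
  }

  if (nrow(tested)) {
    use_f <- tested$f_accepted & tested$N_f > 0L
    use_r <- tested$r_accepted & tested$N_r > 0L
    tested$p_f <- NA_real_
    tested$p_r <- NA_real_
    if (any(use_f))
      tested$p_f[use_f] <- binomialTailPvalue(
        tested$X_f[use_f], tested$N_f[use_f],
        errorRate(model, "F", tested$read_pos_f[use_f],
                  tested$ref[use_f], tested$alt[use_f]))
    if (any(use_r))
      tested$p_r[use_r] <- binomialTailPvalue(
        tested$X_r[use_r], tested$N_r[use_r],
        errorRate(model, "R", tested$read_pos_r[use_r],
                  tested$ref[use_r], tested$alt[use_r]))
    tested$p <- combineStouffer(tested$p_f,
                                ifelse(use_f, tested$N_f, 0L),
                                tested$p_r,
                                ifelse(use_r, tested$N_r, 0L))
    tested$prevalence <- estimatePrevalence(
      tested$X_f, tested$N_f, tested$X_r, tested$N_r, use_f, use_r)
    pooledX <- ifelse(use_f, tested$X_f, 0L) + ifelse(use_r, tested$X_r, 0L)

    # best allele per position: smallest p, then larger count, then A<C<G<T
    o <- order(tested$chrom, tested$pos, tested$p, -pooledX, tested$alt)
    tested <- tested[o, ]
    tested <- tested[!duplicated(.posKey(tested$chrom, tested$pos)), ]

    thr <- if (is(threshold, "ThresholdResult")) threshold@p_threshold
           else threshold
    if (!is.null(thr)) {
      tested$called <- tested$p <= thr
      tested$flags <- ifelse(!tested$called & is.na(tested$flags),
                             "ABOVE_THRESHOLD", tested$flags)
    } else {
      tested$called <- NA
    }
  } else {
    tested$p_f <- tested$p_r <- tested$p <- tested$prevalence <- numeric(0)
    tested$called <- logical(0)
  }
  if (nrow(filtered)) {
    filtered$p_f <- filtered$p_r <- filtered$p <- NA_real_
    filtered$prevalence <- NA_real_
    filtered$called <- FALSE
  }
  res <- rbind(tested, filtered)
  res <- res[order(res$chrom, res$pos), ]
  rownames(res) <- NULL
  res
}
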