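#' @import methods
#' @importFrom stats pbinom qnorm pnorm rbinom rpois rlnorm runif cor quantile
#' @importFrom utils read.delim write.table head
NULL

# Nucleotide alphabet and the fixed sequencing read length (cycles 1..122)
# used throughout: the assay sequences 122 informative cycles from each
# amplicon end, and the error model is stratified per cycle.
.BASES <- c("A", "C", "G", "T")
.READ_LEN <- 122L
.COUNT_COLS <- paste0("count_", .BASES)
.PILEUP_COLS <- c("amplicon_id", "direction", "chrom", "pos", "read_pos",
                  "ref", .COUNT_COLS, "depth")

#' AmpliconDesign: targets and primer spans of a multiplex amplicon panel
#'
#' Holds one row per amplicon: the target interval, the forward and reverse
#' primer spans flanking it, and the genomic coordinate at which sequencing
#' starts in each direction (the outer primer ends, since reads are primed
#' from the amplicon ends). All coordinates are 1-based inclusive.
#'
#' @slot design data.frame with columns \code{amplicon_id}, \code{chrom},
#'   \code{target_start}, \code{target_end}, \code{fwd_primer_start},
#'   \code{fwd_primer_end}, \code{rev_primer_start}, \code{rev_primer_end},
#'   \code{fwd_read_start}, \code{rev_read_start}, \code{overlapping},
#'   \code{fully_coverable}.
#'
#' @seealso [readAmpliconDesign()], [simulateDesign()]
#' @export
setClass("AmpliconDesign", representation(design = "data.frame"))

setValidity("AmpliconDesign", function(object) {
  d <- object@design
  need <- c("amplicon_id", "chrom", "target_start", "target_end",
            "fwd_primer_start", "fwd_primer_end",
            "rev_primer_start", "rev_primer_end",
            "fwd_read_start", "rev_read_start")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$amplicon_id))
    return("duplicated amplicon_id")
  bad <- which(!(d$fwd_primer_start <= d$fwd_primer_end &
                 d$fwd_primer_end == d$target_start - 1L &
                 d$target_start <= d$target_end &
                 d$rev_primer_start == d$target_end + 1L &
                 d$rev_primer_start <= d$rev_primer_end))
  if (length(bad))
    return(paste0("inconsistent amplicon geometry (primers must flank the target) for: ",
                  paste(d$amplicon_id[head(bad, 5)], collapse = ", ")))
  TRUE
})

#' @describeIn AmpliconDesign number of amplicons
#' @param x,object an \code{AmpliconDesign}
#' @export
setMethod("length", "AmpliconDesign", function(x) nrow(x@design))

#' Accessor for the design table
#' @param x an \code{AmpliconDesign}
#' @return data.frame of amplicon records (1-based inclusive coordinates)
#' @export
designTable <- function(x) {
  stopifnot(is(x, "AmpliconDesign"))
  x@design
}

setMethod("show", "AmpliconDesign", function(object) {
  d <- object@design
  cat("AmpliconDesign with", nrow(d), "amplicons on",
      length(unique(d$chrom)), "sequence(s)\n")
  cat("  target length:", paste(range(d$target_end - d$target_start + 1L),
                                collapse = "-"), "bp\n")
  if (any(d$overlapping))
    cat("  ", sum(d$overlapping), "amplicons overlap another target\n")
  if (any(!d$fully_coverable))
    cat("  ", sum(!d$fully_coverable),
        "amplicons contain target bases unreachable within",
        .READ_LEN, "cycles (uncoverable)\n")
})

#' PileupTable: per-direction base counts along amplicons
#'
#' One row ("column" of the pileup) per (amplicon, direction, genomic
#' position): the read position (sequencing cycle, 1-122), the reference
#' base, and counts of A/C/G/T base calls passing the quality cutoff.
#' Forward- and reverse-read observations of the same genomic position are
#' kept as separate rows, since the sequencing error rate depends strongly
#' on read direction and cycle.
#'
#' @slot data data.frame with columns \code{amplicon_id},
#'   \code{direction} (\code{"F"}/\code{"R"}), \code{chrom}, \code{pos}
#'   (1-based), \code{read_pos}, \code{ref}, \code{count_A..count_T},
#'   \code{depth}.
#' @slot sample_id character scalar.
#' @slot provenance list of free-form metadata (source file, trim length,
#'   quality cutoff, ...).
#'
#' @seealso [buildPileup()], [readPileup()], [simulatePileup()]
#' @export
setClass("PileupTable",
         representation(data = "data.frame", sample_id = "character",
                        provenance = "list"))

setValidity("PileupTable", function(object) {
  d <- object@data
  if (!all(.PILEUP_COLS %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(.PILEUP_COLS, names(d)), collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (!all(d$direction %in% c("F", "R")))
    return("direction must be 'F' or 'R'")
  if (!all(d$read_pos >= 1L & d$read_pos <= .READ_LEN))
    return(sprintf("read_pos must lie in [1, %d]", .READ_LEN))
  if (!all(d$ref %in% .BASES))
    return("ref must be one of A/C/G/T")
  cnt <- as.matrix(d[, .COUNT_COLS])
  if (any(cnt < 0L)) return("negative counts")
  if (!all(rowSums(cnt) == d$depth))
    return("depth must equal the sum of the four base counts")
  key <- paste(d$amplicon_id, d$direction, d$pos)
  if (anyDuplicated(key))
    return("duplicate (amplicon_id, direction, pos) keys")
  TRUE
})

#' Accessor for the pileup data
#' @param x a \code{PileupTable}
#' @export
pileupData <- function(x) {
  stopifnot(is(x, "PileupTable"))
  x@data
}

#' Accessor for the sample identifier
#' @param x a \code{PileupTable}
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "PileupTable"))
  x@sample_id
}

setMethod("show", "PileupTable", function(object) {
  d <- object@data
  cat("PileupTable for sample", sQuote(object@sample_id), "\n")
  cat(" ", nrow(d), "pileup columns,",
      length(unique(paste(d$chrom, d$pos))), "genomic positions,",
      length(unique(d$amplicon_id)), "amplicons\n")
  if (nrow(d))
    cat("  mean column depth:", round(mean(d$depth), 1), "\n")
})

#' ErrorModel: smoothed empirical sequencing-error rates
#'
#' Error rates stratified by read direction, read position (1-122) and
#' substitution type (reference base to alternative base; 12 ordered types
#' per direction), estimated from invariant positions of a calibration
#' sample and smoothed across read positions where depth is limited.
#'
#' @slot bins data.frame over the full 2 x 122 x 12 grid with columns
#'   \code{direction}, \code{read_pos}, \code{ref}, \code{alt},
#'   \code{mismatches}, \code{depth}, \code{raw_rate}, \code{smoothed_rate}.
#' @slot rates numeric array \code{[direction, read_pos, ref, alt]} for
#'   fast lookup; bins without data carry the floor rate.
#' @slot avg_depth mean bin depth used as the smoothing trigger.
#' @slot floor_rate pseudo-rate substituted for empty strata.
#' @slot sample_id calibration sample the model was trained on.
#'
#' @seealso [trainErrorModel()], [errorRate()]
#' @export
setClass("ErrorModel",
         representation(bins = "data.frame", rates = "array",
                        avg_depth = "numeric", floor_rate = "numeric",
                        sample_id = "character"))

setValidity("ErrorModel", function(object) {
  b <- object@bins
  if (nrow(b) != 2L * .READ_LEN * 12L)
    return("bins must cover the full 2 x 122 x 12 grid")
  nsub <- table(b$direction, b$read_pos)
  if (!all(nsub == 12L))
    return("each (direction, read_pos) must have exactly 12 substitution types")
  if (any(b$alt == b$ref)) return("alt must differ from ref")
  E <- b$smoothed_rate
  if (any(E < 0 | E > 1, na.rm = TRUE)) return("smoothed rates outside [0,1]")
  if (object@floor_rate <= 0) return("floor_rate must be positive")
  TRUE
})

setMethod("show", "ErrorModel", function(object) {
  b <- object@bins
  cat("ErrorModel trained on sample", sQuote(object@sample_id), "\n")
  cat("  2 directions x", .READ_LEN, "read positions x 12 substitution types\n")
  cat("  average bin depth:", format(object@avg_depth, digits = 4),
      "| floor rate:", format(object@floor_rate, digits = 3), "\n")
  cat("  smoothed rate range:",
      paste(format(range(b$smoothed_rate), digits = 3), collapse = " - "), "\n")
  cat(" ", sum(b$depth < object@avg_depth), "bins smoothed (depth below average)\n")
})

#' ErrorProfile: generative per-cycle substitution rates for the simulator
#'
#' A synthetic substitution-rate field over (direction, read position,
#' reference base, alternative base) used by [simulatePileup()]. Two
#' presets are provided: \code{"GAII"}-like (rates 0.05-0.3% with an
#' up-to-threefold inflation after cycle 100 for A/T reference bases,
#' emulating late-cycle chemistry decay) and \code{"MiSeq"}-like (flat
#' 0.05-0.15%). The rates are plausibility presets, not measurements.
#'
#' @slot rates numeric array \code{[2, 122, 4, 4]} indexed by direction
#'   (F, R), read position, reference and alternative base.
#' @slot preset name of the preset.
#' @export
setClass("ErrorProfile",
         representation(rates = "array", preset = "character"))

setValidity("ErrorProfile", function(object) {
  r <- object@rates
  if (!identical(dim(r), c(2L, .READ_LEN, 4L, 4L)))
    return("rates must be a [2, 122, 4, 4] array")
  ok <- TRUE
  for (i in 1:4) if (any(!is.na(r[, , i, i]))) ok <- FALSE
  if (!ok) return("diagonal (ref == alt) entries must be NA")
  v <- r[!is.na(r)]
  if (any(v <= 0 | v >= 0.05))
    return("substitution rates must lie in (0, 0.05)")
  TRUE
})

setMethod("show", "ErrorProfile", function(object) {
  v <- object@rates[!is.na(object@rates)]
  cat("ErrorProfile preset", sQuote(object@preset), "\n")
  cat("  per-cycle substitution rates:",
      paste(format(range(v), digits = 3), collapse = " - "), "\n")
})

#' TruthSet: known-variant positions with expected prevalences
#'
#' The calibration truth: positions carrying a known variant allele at a
#' known expected prevalence in a (pooled) sample, plus the full set of
#' positions to mask during error-model training (every position known to
#' be polymorphic in any pool member, whether or not it is variant in this
#' particular pool).
#'
#' @slot variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{expected_prevalence},
#'   \code{sub_detectable} (logical: below the 1% assay floor).
#' @slot masked data.frame with columns \code{chrom}, \code{pos}.
#' @slot sample_id pool identifier.
#' @export
setClass("TruthSet",
         representation(variants = "data.frame", masked = "data.frame",
                        sample_id = "character"))

setValidity("TruthSet", function(object) {
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "expected_prevalence")
  if (!all(need %in% names(v)))
    return(paste("missing columns:", paste(setdiff(need, names(v)), collapse = ", ")))
  if (nrow(v) && any(v$expected_prevalence <= 0 | v$expected_prevalence > 1))
    return("expected prevalences must lie in (0, 1]")
  if (!all(c("chrom", "pos") %in% names(object@masked)))
    return("masked must have chrom and pos columns")
  TRUE
})

#' Accessor for the truth variant table
#' @param x a \code{TruthSet}
#' @export
truthVariants <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@variants
}

#' Accessor for the masked-position table
#' @param x a \code{TruthSet}
#' @export
maskedPositions <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@masked
}

setMethod("show", "TruthSet", function(object) {
  v <- object@variants
  cat("TruthSet", sQuote(object@sample_id), "with", nrow(v),
      "known variants,", nrow(object@masked), "masked positions\n")
  if (nrow(v)) {
    tab <- table(signif(v$expected_prevalence, 2))
    cat("  expected prevalences:",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
})

#' ThresholdResult: the MCC-selected significance threshold
#'
#' @slot p_threshold the p-value threshold (candidates with p <= threshold
#'   are called).
#' @slot mcc Matthews correlation coefficient at the threshold.
#' @slot tp,fp,tn,fn confusion counts at the threshold on the calibration
#'   sample.
#' @export
setClass("ThresholdResult",
         representation(p_threshold = "numeric", mcc = "numeric",
                        tp = "numeric", fp = "numeric",
                        tn = "numeric", fn = "numeric"))

setValidity("ThresholdResult", function(object) {
  if (object@mcc < -1 || object@mcc > 1) return("mcc outside [-1, 1]")
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0))
    return("negative confusion counts")
  TRUE
})

setMethod("show", "ThresholdResult", function(object) {
  cat("ThresholdResult: call at p <=", format(object@p_threshold, digits = 4),
      "\n  MCC =", round(object@mcc, 4),
      sprintf("(TP %d, FP %d, TN %d, FN %d)\n",
              as.integer(object@tp), as.integer(object@fp),
              as.integer(object@tn), as.integer(object@fn)))
})
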