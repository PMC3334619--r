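#' Classify tumor calls as somatic by germline comparison
#'
#' Each statistically called tumor variant is compared with the matched
#' germline sample at the same position: the call is
#' \describe{
#'   \item{UNASSESSABLE}{when the germline position is not highly covered
#'     (collapsed depth of 10 or fewer reads, strict "> 10" rule) or is
#'     absent from the germline pileup;}
#'   \item{GERMLINE_EVIDENCE}{when the germline sample was itself called
#'     variant for this allele by the same statistical assessment, or
#'     shows the alternative allele at a pooled ratio of 20% or more
#'     (an obvious germline variant that merely failed the statistics);}
#'   \item{SOMATIC}{otherwise.}
#' }
#'
#' @param tumor_calls data.frame from [callVariants()] on the tumor
#'   sample; rows with \code{called == TRUE} are classified.
#' @param germline_pileup [PileupTable-class] of the matched germline.
#' @param germline_calls data.frame from [callVariants()] on the germline
#'   sample, run with the same calibration artifacts.
#' @param min_germline_depth germline collapsed depth must strictly
#'   exceed this (default 10).
#' @param max_germline_ratio germline alternative-allele ratio at or
#'   above this is germline evidence (default 0.20).
#' @return data.frame of the called tumor variants with added columns
#'   \code{germline_depth}, \code{germline_alt_ratio},
#'   \code{germline_called} and \code{status}.
#' @export
callSomatic <- function(tumor_calls, germline_pileup, germline_calls,
                        min_germline_depth = 10L,
                        max_germline_ratio = 0.20) {
  stopifnot(is(germline_pileup, "PileupTable"))
  calls <- tumor_calls[!is.na(tumor_calls$called) & tumor_calls$called, ]
  if (nrow(calls) == 0L) {
    calls$germline_depth <- integer(0)
    calls$germline_alt_ratio <- numeric(0)
    calls$germline_called <- logical(0)
    calls$status <- character(0)
    return(calls)
  }
  gp <- data.table::as.data.table(pileupData(germline_pileup))
  gcol <- gp[, lapply(.SD, sum), by = c("chrom", "pos"),
             .SDcols = c(.COUNT_COLS, "depth")]
  m <- match(.posKey(calls$chrom, calls$pos), .posKey(gcol$chrom, gcol$pos))
  gdepth <- ifelse(is.na(m), 0L, gcol$depth[m])
  cntm <- as.matrix(gcol[, .COUNT_COLS, with = FALSE])
  galt <- rep(NA_real_, nrow(calls))
  ok <- !is.na(m)
  galt[ok] <- cntm[cbind(m[ok], match(calls$alt[ok], .BASES))]
  gratio <- ifelse(gdepth > 0, galt / gdepth, NA_real_)

  gcalled_keys <- character(0)
  if (!is.null(germline_calls)) {
    gc <- germline_calls[!is.na(germline_calls$called) &
                           germline_calls$called, ]
    gcalled_keys <- .varKey(gc$chrom, gc$pos, gc$alt)
  }
  gcalled <- .varKey(calls$chrom, calls$pos, calls$alt) %in% gcalled_keys

  status <- ifelse(
    is.na(m) | gdepth <= min_germline_depth, "UNASSESSABLE",
    ifelse(gcalled | (!is.na(gratio) & gratio >= max_germline_ratio),
           "GERMLINE_EVIDENCE", "SOMATIC"))
  calls$germline_depth <- as.integer(gdepth)
  calls$germline_alt_ratio <- gratio
  calls$germline_called <- gcalled
  calls$status <- status
  rownames(calls) <- NULL
  calls
}

#' Load a cross-species (host/graft) mismatch mask
#'
#' Xenograft samples can carry host (e.g. mouse) DNA whose amplification
#' produces apparent variants wherever the host and graft reference
#' genomes mismatch. The mask is a TSV of such positions (columns
#' \code{chrom}, \code{pos}, graft-genome coordinates, 1-based); it is
#' restricted to positions inside the design's amplicons, duplicates are
#' removed, and positions outside every amplicon are dropped with a
#' warning.
#'
#' @param path mask TSV.
#' @param design the [AmpliconDesign-class].
#' @return data.frame with columns \code{chrom}, \code{pos}.
#' @export
readCrossSpeciesMask <- function(path, design) {
  d <- .readTsv(path, c("chrom", "pos"), what = "cross-species mask",
                colClasses = c(chrom = "character"))
  d$chrom <- as.character(d$chrom)
  d$pos <- as.integer(d$pos)
  d <- unique(d[, c("chrom", "pos")])
  if (nrow(d) == 0L) return(d)
  dp <- .designPositions(design)
  inside <- .posKey(d$chrom, d$pos) %in% .posKey(dp$chrom, dp$pos)
  if (any(!inside))
    warning(sum(!inside), " mask position(s) outside all amplicons dropped")
  d <- d[inside, ]
  rownames(d) <- NULL
  d
}

#' Remove host-genome mismatch positions from somatic calls
#'
#' Calls at masked positions are re-labeled \code{HOST_MISMATCH}; calls
#' anywhere else are untouched (exact-position semantics).
#'
#' @param calls data.frame from [callSomatic()].
#' @param mask data.frame from [readCrossSpeciesMask()].
#' @return the calls with updated \code{status}.
#' @export
filterCrossSpecies <- function(calls, mask) {
  if (nrow(calls) == 0L || is.null(mask) || nrow(mask) == 0L) return(calls)
  hit <- .posKey(calls$chrom, calls$pos) %in% .posKey(mask$chrom, mask$pos)
  calls$status[hit] <- "HOST_MISMATCH"
  calls
}

#' Write somatic calls as VCF 4.2
#'
#' Emits one record per called tumor variant with INFO keys PREV (tumor
#' prevalence), GDP (germline depth), GAR (germline alternative-allele
#' ratio), DPF/DPR (per-direction depths), XF/XR (per-direction
#' alternative counts) and PF/PR/PCOMB (per-direction and combined
#' p-values). The FILTER column is PASS for somatic calls and GERMLINE,
#' UNASSESSABLE or HOST_MISMATCH otherwise. A TSV mirror with identical
#' content is written alongside when \code{tsv_mirror} is TRUE.
#'
#' @param calls data.frame from [callSomatic()] (possibly after
#'   [filterCrossSpecies()]).
#' @param path output VCF path.
#' @param sample_id sample name for the header.
#' @param tsv_mirror also write \code{<path>.tsv} (default TRUE).
#' @return invisibly, the VCF path.
#' @export
writeSomaticVcf <- function(calls, path, sample_id = "tumor",
                            tsv_mirror = TRUE) {
  filt <- c(SOMATIC = "PASS", GERMLINE_EVIDENCE = "GERMLINE",
            UNASSESSABLE = "UNASSESSABLE", HOST_MISMATCH = "HOST_MISMATCH")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ampliCall %s",
            as.character(utils::packageVersion("ampliCall"))),
    "##FILTER=<ID=GERMLINE,Description=\"Variant evidence in matched germline\">",
    "##FILTER=<ID=UNASSESSABLE,Description=\"Germline coverage 10 or fewer reads\">",
    "##FILTER=<ID=HOST_MISMATCH,Description=\"Host/graft genome mismatch position\">",
    "##INFO=<ID=PREV,Number=1,Type=Float,Description=\"Estimated variant prevalence in tumor\">",
    "##INFO=<ID=GDP,Number=1,Type=Integer,Description=\"Germline collapsed depth\">",
    "##INFO=<ID=GAR,Number=1,Type=Float,Description=\"Germline alternative allele ratio\">",
    "##INFO=<ID=DPF,Number=1,Type=Integer,Description=\"Forward-read depth\">",
    "##INFO=<ID=DPR,Number=1,Type=Integer,Description=\"Reverse-read depth\">",
    "##INFO=<ID=XF,Number=1,Type=Integer,Description=\"Forward-read alternative count\">",
    "##INFO=<ID=XR,Number=1,Type=Integer,Description=\"Reverse-read alternative count\">",
    "##INFO=<ID=PF,Number=1,Type=Float,Description=\"Forward-read p-value\">",
    "##INFO=<ID=PR,Number=1,Type=Float,Description=\"Reverse-read p-value\">",
    "##INFO=<ID=PCOMB,Number=1,Type=Float,Description=\"Combined p-value\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  fmtNum <- function(v) ifelse(is.na(v), ".", format(v, digits = 6,
                                                     scientific = TRUE,
                                                     trim = TRUE))
  fmtInt <- function(v) ifelse(is.na(v), ".", as.character(as.integer(v)))
  recs <- character(0)
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos), ]
    info <- paste0(
      "PREV=", ifelse(is.na(calls$prevalence), ".",
                      sprintf("%.6g", calls$prevalence)),
      ";GDP=", fmtInt(calls$germline_depth),
      ";GAR=", ifelse(is.na(calls$germline_alt_ratio), ".",
                      sprintf("%.6g", calls$germline_alt_ratio)),
      ";DPF=", fmtInt(calls$N_f), ";DPR=", fmtInt(calls$N_r),
      ";XF=", fmtInt(calls$X_f), ";XR=", fmtInt(calls$X_r),
      ";PF=", fmtNum(calls$p_f), ";PR=", fmtNum(calls$p_r),
      ";PCOMB=", fmtNum(calls$p))
    qual <- ifelse(calls$p <= 0, "999",
                   sprintf("%.1f", pmin(-10 * log10(calls$p), 999)))
    recs <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  qual, unname(filt[calls$status]), info, sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  if (tsv_mirror) .writeTsv(calls, paste0(path, ".tsv"))
  invisible(path)
}
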