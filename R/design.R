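#' Construct an AmpliconDesign from a data.frame
#'
#' Validates the geometry (primer spans must immediately flank the target
#' interval), derives the per-direction sequencing start coordinates (the
#' outer primer ends), and flags amplicons whose targets overlap another
#' amplicon's target and amplicons containing target bases unreachable
#' within the read length in either direction.
#'
#' @param d data.frame with columns \code{amplicon_id}, \code{chrom},
#'   \code{target_start}, \code{target_end}, \code{fwd_primer_start},
#'   \code{fwd_primer_end}, \code{rev_primer_start}, \code{rev_primer_end}
#'   (1-based inclusive).
#' @return an [AmpliconDesign-class] object.
#' @export
AmpliconDesign <- function(d) {
  need <- c("amplicon_id", "chrom", "target_start", "target_end",
            "fwd_primer_start", "fwd_primer_end",
            "rev_primer_start", "rev_primer_end")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  d <- d[, need]
  d$amplicon_id <- as.character(d$amplicon_id)
  d$chrom <- as.character(d$chrom)
  for (cc in need[-(1:2)]) d[[cc]] <- as.integer(d[[cc]])
  tl <- d$target_end - d$target_start + 1L
  if (any(tl > 250L))
    warning(sum(tl > 250L), " amplicon(s) have targets longer than 250 bp; ",
            "the assay is designed around ~200 bp amplicons")
  # sequencing begins at the outer primer ends
  d$fwd_read_start <- d$fwd_primer_start
  d$rev_read_start <- d$rev_primer_end

  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$target_start, d$target_end))
  ov <- GenomicRanges::countOverlaps(gr, gr) > 1L
  d$overlapping <- as.logical(ov)

  # a target base is coverable if within read length of either read start;
  # the only gap can lie strictly between the two read footprints
  max_f <- d$fwd_read_start + .READ_LEN - 1L   # last base the F read reaches
  min_r <- d$rev_read_start - .READ_LEN + 1L   # first base the R read reaches
  d$fully_coverable <- (max_f >= min_r - 1L) |
    (d$target_end <= max_f) | (d$target_start >= min_r)
  rownames(d) <- NULL
  new("AmpliconDesign", design = d)
}

#' Read an amplicon design table
#'
#' Reads a tab-separated design file (one amplicon per row, 1-based
#' inclusive coordinates, '#'-prefixed header lines permitted) and
#' validates it. Overlapping amplicons are permitted and kept distinct;
#' they are flagged in the \code{overlapping} column.
#'
#' @param path path to the design TSV with columns \code{amplicon_id},
#'   \code{chrom}, \code{target_start}, \code{target_end},
#'   \code{fwd_primer_start}, \code{fwd_primer_end},
#'   \code{rev_primer_start}, \code{rev_primer_end}.
#' @return an [AmpliconDesign-class] object.
#' @export
readAmpliconDesign <- function(path) {
  d <- .readTsv(path, c("amplicon_id", "chrom", "target_start", "target_end",
                        "fwd_primer_start", "fwd_primer_end",
                        "rev_primer_start", "rev_primer_end"),
                what = "design",
                colClasses = c(amplicon_id = "character",
                               chrom = "character"))
  bad <- which(is.na(d$target_start) | is.na(d$target_end))
  if (length(bad))
    stop("design ", path, ": malformed row(s) ", paste(bad, collapse = ", "))
  AmpliconDesign(d)
}

#' Write an amplicon design table
#' @param design an [AmpliconDesign-class]
#' @param path output TSV path
#' @export
writeAmpliconDesign <- function(design, path) {
  stopifnot(is(design, "AmpliconDesign"))
  d <- designTable(design)
  .writeTsv(d[, c("amplicon_id", "chrom", "target_start", "target_end",
                  "fwd_primer_start", "fwd_primer_end",
                  "rev_primer_start", "rev_primer_end")], path)
}

# All (chrom, pos, amplicon_id, in_primer) positions spanned by the
# amplicons (primers included); used for primer flagging, mask
# restriction and assayed-base accounting.
.designPositions <- function(design) {
  d <- designTable(design)
  res <- lapply(seq_len(nrow(d)), function(i) {
    pos <- seq.int(d$fwd_primer_start[i], d$rev_primer_end[i])
    data.frame(amplicon_id = d$amplicon_id[i], chrom = d$chrom[i], pos = pos,
               in_primer = pos <= d$fwd_primer_end[i] |
                 pos >= d$rev_primer_start[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Assayed (target, non-primer) positions of a design
#'
#' @param design an [AmpliconDesign-class]
#' @return data.frame of distinct \code{chrom}, \code{pos} target positions
#'   outside every primer span. These are the positions over which
#'   specificity and assessability are accounted.
#' @export
assayedPositions <- function(design) {
  dp <- .designPositions(design)
  # a base is assayed if it is target in at least one amplicon
  dt <- data.table::as.data.table(dp)
  key <- target <- NULL
  dt[, target := !in_primer]
  out <- dt[, list(assayed = any(target)), by = c("chrom", "pos")]
  as.data.frame(out[out$assayed, c("chrom", "pos")])
}
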