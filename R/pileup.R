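#' Construct a PileupTable
#'
#' @param data data.frame with the pileup columns (see
#'   [PileupTable-class]).
#' @param sample_id sample identifier.
#' @param provenance free-form metadata list.
#' @return a validated [PileupTable-class].
#' @export
PileupTable <- function(data, sample_id = "sample", provenance = list()) {
  data <- as.data.frame(data)[, .PILEUP_COLS]
  data$amplicon_id <- as.character(data$amplicon_id)
  data$direction <- as.character(data$direction)
  data$chrom <- as.character(data$chrom)
  data$ref <- as.character(data$ref)
  for (cc in c("pos", "read_pos", .COUNT_COLS, "depth"))
    data[[cc]] <- as.integer(data[[cc]])
  rownames(data) <- NULL
  new("PileupTable", data = data, sample_id = as.character(sample_id),
      provenance = provenance)
}

#' Read a pileup table from TSV
#'
#' The dialect is one header line and tab-separated columns
#' \code{amplicon_id}, \code{direction} (F|R), \code{chrom}, \code{pos}
#' (1-based), \code{read_pos}, \code{ref}, \code{count_A}, \code{count_C},
#' \code{count_G}, \code{count_T}, \code{depth}. Rows whose depth does not
#' equal the sum of the four counts are rejected with the offending row
#' number.
#'
#' @param path input TSV.
#' @param sample_id sample identifier to attach (defaults to the file
#'   name without extension).
#' @return a [PileupTable-class].
#' @export
readPileup <- function(path, sample_id = NULL) {
  d <- .readTsv(path, .PILEUP_COLS, what = "pileup",
                colClasses = c(amplicon_id = "character",
                               direction = "character",
                               chrom = "character", ref = "character"))
  bad <- which(rowSums(as.matrix(d[, .COUNT_COLS])) != d$depth)
  if (length(bad))
    stop("pileup ", path, ": depth does not equal the sum of counts at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  PileupTable(d, sample_id = sample_id,
              provenance = list(source = path))
}

#' Write a pileup table to TSV
#'
#' \code{writePileup} followed by [readPileup()] reproduces the table
#' field-by-field (bit-exact round trip).
#'
#' @param x a [PileupTable-class]
#' @param path output TSV path
#' @export
writePileup <- function(x, path) {
  stopifnot(is(x, "PileupTable"))
  .writeTsv(pileupData(x), path)
}

#' Build a per-direction pileup from aligned single-end reads
#'
#' Reads a BAM (or SAM, converted on the fly) of single-end alignments and
#' tallies, for every (amplicon, direction, position), the number of
#' A/C/G/T base calls with PHRED quality strictly greater than
#' \code{minQuality}. Reads whose alignment contains an insertion or
#' deletion are excluded (substitution-only analysis), as are clipped
#' reads. Each read is assigned to the amplicon (and direction) whose
#' sequencing start coordinate matches the read's 5' alignment start
#' within \code{tolerance} (exact match by default); unassigned reads are
#' counted and reported, not piled. Reads are trimmed to \code{trimLen}
#' sequencing cycles.
#'
#' @param file BAM or SAM path.
#' @param design an [AmpliconDesign-class].
#' @param reference reference bases: either a named
#'   \code{Biostrings::DNAStringSet} (names = chromosomes) or a data.frame
#'   with columns \code{chrom}, \code{pos}, \code{ref}.
#' @param minQuality PHRED cutoff; only calls with quality strictly
#'   greater than this are counted (default 20).
#' @param trimLen number of sequencing cycles retained per read
#'   (default and maximum 122).
#' @param tolerance allowed distance (bp) between a read's 5' start and an
#'   amplicon's sequencing start (default 0).
#' @param sample_id sample identifier.
#' @return a [PileupTable-class]; the provenance records the counts of
#'   gapped, clipped and unassigned reads.
#' @export
buildPileup <- function(file, design, reference, minQuality = 20L,
                        trimLen = .READ_LEN, tolerance = 0L,
                        sample_id = NULL) {
  stopifnot(is(design, "AmpliconDesign"))
  if (trimLen > .READ_LEN || trimLen < 1L)
    stop("trimLen must lie in [1, ", .READ_LEN, "]")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(file))
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(file)[[1]]$targets
  dd <- designTable(design)
  if (!any(unique(dd$chrom) %in% names(hdr)))
    stop("reference name mismatch: none of the design chromosomes (",
         paste(unique(dd$chrom), collapse = ", "),
         ") are present in the alignment header")

  prm <- Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "qwidth", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(file, param = prm)[[1]]
  n_in <- length(b$pos)

  gapped <- grepl("[IDN]", b$cigar)
  clipped <- !gapped & grepl("[SHP]", b$cigar)
  keep <- !gapped & !clipped & !is.na(b$pos)
  chrom <- as.character(b$rname)[keep]
  strand <- as.character(b$strand)[keep]
  start <- b$pos[keep]
  width <- b$qwidth[keep]
  seqc <- as.character(b$seq)[keep]
  qInt <- lapply(as.character(b$qual)[keep],
                 function(s) utf8ToInt(s) - 33L)

  # assign reads to amplicons by exact (within tolerance) 5' start match
  five <- ifelse(strand == "+", start, start + width - 1L)
  dirn <- ifelse(strand == "+", "F", "R")
  akey <- character(length(five))
  tolseq <- seq.int(-tolerance, tolerance)
  fmap <- rmap <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dd))) {
    for (t in tolseq) {
      assign(.posKey(dd$chrom[i], dd$fwd_read_start[i] + t),
             dd$amplicon_id[i], envir = fmap)
      assign(.posKey(dd$chrom[i], dd$rev_read_start[i] + t),
             dd$amplicon_id[i], envir = rmap)
    }
  }
  readkey <- .posKey(chrom, five)
  akey <- vapply(seq_along(readkey), function(i) {
    env <- if (dirn[i] == "F") fmap else rmap
    if (exists(readkey[i], envir = env, inherits = FALSE))
      get(readkey[i], envir = env) else NA_character_
  }, character(1))
  unassigned <- sum(is.na(akey))
  asn <- !is.na(akey)

  counts <- list()
  if (any(asn)) {
    idx <- which(asn)
    len <- pmin(width[idx], .READ_LEN)   # cycles beyond 122 never counted
    rid <- rep.int(idx, len)
    off <- sequence(len)                 # aligned offset, reference order
    cyc <- ifelse(strand[rid] == "+", off, width[rid] - off + 1L)
    base <- substring(seqc[rid], off, off)
    q <- unlist(lapply(seq_along(idx), function(j)
      qInt[[idx[j]]][seq_len(len[j])]), use.names = FALSE)
    ok <- q > minQuality & cyc <= trimLen & base %in% .BASES
    tt <- data.table::data.table(
      amplicon_id = akey[rid][ok], direction = dirn[rid][ok],
      chrom = chrom[rid][ok], pos = start[rid][ok] + off[ok] - 1L,
      base = base[ok])
    counts <- tt[, list(n = .N),
                 by = c("amplicon_id", "direction", "chrom", "pos", "base")]
  }
  if (!length(counts) || nrow(counts) == 0L) {
    warning("no reads could be assigned to any amplicon")
    empty <- data.frame(amplicon_id = character(), direction = character(),
                        chrom = character(), pos = integer(),
                        read_pos = integer(), ref = character(),
                        count_A = integer(), count_C = integer(),
                        count_G = integer(), count_T = integer(),
                        depth = integer(), stringsAsFactors = FALSE)
    return(PileupTable(empty, sample_id = sample_id,
                       provenance = list(source = file, n_reads = n_in,
                                         gapped = sum(gapped),
                                         clipped = sum(clipped),
                                         unassigned = unassigned,
                                         trim_len = trimLen,
                                         min_quality = minQuality)))
  }
  wide <- data.table::dcast(counts,
                            amplicon_id + direction + chrom + pos ~ base,
                            value.var = "n", fill = 0L)
  for (bb in .BASES) if (is.null(wide[[bb]])) wide[[bb]] <- 0L
  out <- as.data.frame(wide)
  names(out)[match(.BASES, names(out))] <- .COUNT_COLS
  out$depth <- as.integer(rowSums(out[, .COUNT_COLS]))

  # clip to the amplicon span and attach read positions and reference bases
  m <- match(out$amplicon_id, dd$amplicon_id)
  inside <- out$pos >= dd$fwd_primer_start[m] & out$pos <= dd$rev_primer_end[m]
  out <- out[inside, ]
  m <- m[inside]
  out$read_pos <- ifelse(out$direction == "F",
                         out$pos - dd$fwd_read_start[m] + 1L,
                         dd$rev_read_start[m] - out$pos + 1L)
  out <- out[out$read_pos >= 1L & out$read_pos <= trimLen, ]
  out$ref <- .lookupReference(reference, out$chrom, out$pos)
  out <- out[!is.na(out$ref), ]
  out <- out[order(out$amplicon_id, out$direction, out$pos), ]
  PileupTable(out, sample_id = sample_id,
              provenance = list(source = file, n_reads = n_in,
                                gapped = sum(gapped), clipped = sum(clipped),
                                unassigned = unassigned, trim_len = trimLen,
                                min_quality = minQuality))
}

# reference lookup for data.frame or DNAStringSet representations
.lookupReference <- function(reference, chrom, pos) {
  if (is.data.frame(reference)) {
    m <- match(.posKey(chrom, pos), .posKey(reference$chrom, reference$pos))
    as.character(reference$ref[m])
  } else if (is(reference, "DNAStringSet")) {
    out <- rep(NA_character_, length(pos))
    for (ch in unique(chrom)) {
      i <- chrom == ch
      if (ch %in% names(reference)) {
        sq <- reference[[ch]]
        p <- pos[i]
        valid <- p >= 1L & p <= length(sq)
        v <- rep(NA_character_, sum(i))
        if (any(valid)) {
          chars <- strsplit(as.character(sq), "")[[1]]
          v[valid] <- chars[p[valid]]
        }
        out[i] <- v
      }
    }
    out
  } else stop("reference must be a data.frame or a DNAStringSet")
}

#' Thin a pileup to a lower mean depth
#'
#' Emulates lower sequencing depth (higher multiplexing) by binomially
#' thinning every base count with retention probability
#' \code{targetMeanDepth / current mean column depth}; thinning counts is
#' equivalent in distribution to sampling reads for all pileup-level
#' statistics. The retention probability is capped at 1 with a warning.
#'
#' @param x a [PileupTable-class].
#' @param targetMeanDepth desired mean per-column depth (> 0).
#' @param seed integer seed; the result is deterministic for a fixed seed.
#' @return a thinned [PileupTable-class].
#' @export
downsamplePileup <- function(x, targetMeanDepth, seed) {
  stopifnot(is(x, "PileupTable"), targetMeanDepth > 0)
  d <- pileupData(x)
  if (nrow(d) == 0L) stop("cannot downsample an empty pileup")
  p <- targetMeanDepth / mean(d$depth)
  if (p > 1) {
    warning("target mean depth exceeds the current mean depth; ",
            "retention probability capped at 1")
    p <- 1
  }
  .withSeed(seed, {
    for (cc in .COUNT_COLS)
      d[[cc]] <- rbinom(nrow(d), d[[cc]], p)
  })
  d$depth <- as.integer(rowSums(d[, .COUNT_COLS]))
  prov <- x@provenance
  prov$downsampled_to <- targetMeanDepth
  PileupTable(d, sample_id = sampleId(x), provenance = prov)
}

#' Collapsed (direction-merged) per-base depth
#'
#' Base-wise coverage merges forward and reverse observations of the same
#' genomic position; amplicon-wise accounting keeps overlapping amplicons
#' separate.
#'
#' @param x a [PileupTable-class].
#' @return data.frame with \code{chrom}, \code{pos}, \code{depth},
#'   \code{alt_count} (total non-reference calls).
#' @export
collapsedDepth <- function(x) {
  stopifnot(is(x, "PileupTable"))
  d <- data.table::as.data.table(pileupData(x))
  if (nrow(d) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      depth = integer(), alt_count = integer()))
  refcnt <- as.matrix(d[, .COUNT_COLS, with = FALSE])[
    cbind(seq_len(nrow(d)), match(d$ref, .BASES))]
  d$alt <- d$depth - refcnt
  out <- d[, list(depth = sum(depth), alt_count = sum(alt)),
           by = c("chrom", "pos")]
  as.data.frame(out)
}
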