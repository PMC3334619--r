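#' Restrict a pileup to invariant training sites
#'
#' Error-model training uses only positions believed to be invariant:
#' known polymorphic positions are masked outright, and remaining columns
#' are dropped when their non-reference fraction exceeds
#' \code{maxAltFrac} (likely an unannotated variant or an upstream PCR
#' error) or their depth is below \code{minDepth}.
#'
#' @param x a [PileupTable-class].
#' @param mask known-variant positions: a data.frame with \code{chrom},
#'   \code{pos}, or a [TruthSet-class] (its masked set is used).
#' @param maxAltFrac maximum tolerated non-reference fraction
#'   (default 0.05).
#' @param minDepth minimum column depth (default 10; columns covered by
#'   fewer reads are dropped).
#' @return a [PileupTable-class] restricted to invariant columns.
#' @export
collectInvariantSites <- function(x, mask, maxAltFrac = 0.05,
                                  minDepth = 10L) {
  stopifnot(is(x, "PileupTable"))
  if (is(mask, "TruthSet")) mask <- maskedPositions(mask)
  d <- pileupData(x)
  if (nrow(d) == 0L) stop("cannot train on an empty pileup")
  maskkey <- if (nrow(mask)) .posKey(mask$chrom, mask$pos) else character()
  refcnt <- as.matrix(d[, .COUNT_COLS])[
    cbind(seq_len(nrow(d)), match(d$ref, .BASES))]
  altfrac <- ifelse(d$depth > 0, (d$depth - refcnt) / d$depth, 0)
  keep <- !(.posKey(d$chrom, d$pos) %in% maskkey) &
    altfrac <= maxAltFrac & d$depth >= minDepth
  if (!any(keep))
    stop("no invariant sites remain after masking and filtering; ",
         "cannot train an error model")
  PileupTable(d[keep, ], sample_id = sampleId(x),
              provenance = c(x@provenance, list(invariant_only = TRUE)))
}

#' Estimate raw per-bin error rates
#'
#' Groups all invariant-site observations into bins keyed by read
#' direction, read position (1-122) and substitution type (4 reference
#' bases x 3 alternatives = 12 ordered types per direction), and estimates
#' each bin's error rate as total mismatching calls over total calls.
#' Bins with no contributing columns have depth 0 and an undefined
#' (\code{NA}) rate.
#'
#' @param invariant a [PileupTable-class] from [collectInvariantSites()].
#' @return data.frame over the full 2 x 122 x 12 grid with columns
#'   \code{direction}, \code{read_pos}, \code{ref}, \code{alt},
#'   \code{mismatches}, \code{depth}, \code{raw_rate}.
#' @export
estimateRawErrorRates <- function(invariant) {
  stopifnot(is(invariant, "PileupTable"))
  d <- data.table::as.data.table(pileupData(invariant))
  grid <- expand.grid(direction = c("F", "R"), read_pos = seq_len(.READ_LEN),
                      ref = .BASES, alt = .BASES,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  grid <- grid[order(grid$direction, grid$read_pos, grid$ref, grid$alt), ]
  if (nrow(d)) {
    long <- data.table::melt(
      d[, c("direction", "read_pos", "ref", "depth", .COUNT_COLS),
        with = FALSE],
      id.vars = c("direction", "read_pos", "ref", "depth"),
      measure.vars = .COUNT_COLS, variable.name = "altcol",
      value.name = "n")
    long$alt <- .BASES[match(long$altcol, .COUNT_COLS)]
    long <- long[long$alt != long$ref, ]
    agg <- long[, list(mismatches = sum(n), bindepth = sum(depth)),
                by = c("direction", "read_pos", "ref", "alt")]
    m <- match(paste(grid$direction, grid$read_pos, grid$ref, grid$alt),
               paste(agg$direction, agg$read_pos, agg$ref, agg$alt))
    grid$mismatches <- ifelse(is.na(m), 0L, agg$mismatches[m])
    grid$depth <- ifelse(is.na(m), 0L, agg$bindepth[m])
  } else {
    grid$mismatches <- 0L
    grid$depth <- 0L
  }
  grid$raw_rate <- ifelse(grid$depth > 0, grid$mismatches / grid$depth, NA_real_)
  rownames(grid) <- NULL
  grid
}

#' Smooth low-depth error-rate bins across read positions
#'
#' Within each (reference, alternative, direction) stratum, a read
#' position whose bin depth reaches the average bin depth keeps its raw
#' rate. Otherwise neighboring read positions are accumulated outward
#' (k+1, k-1, k+2, k-2, ...) until the summed depth exceeds the average,
#' and the smoothed rate is the weighted mean
#' \deqn{E = \sum_j e_j n_j r_j / \sum_j n_j r_j}
#' with depth weights \eqn{n_j} and reciprocal-distance weights
#' \eqn{r_j = 1/(|j-k|+1)} (1 for the position itself, 1/2 and 1/3 for the
#' first and second neighbors). Strata with no data anywhere receive the
#' model's floor rate.
#'
#' @param raw bin table from [estimateRawErrorRates()].
#' @param avg_depth smoothing trigger; defaults to the mean depth over all
#'   bins of the grid.
#' @param sample_id calibration sample identifier recorded in the model.
#' @return an [ErrorModel-class].
#' @export
smoothErrorRates <- function(raw, avg_depth = mean(raw$depth),
                             sample_id = "calibration") {
  stopifnot(all(c("direction", "read_pos", "ref", "alt",
                  "mismatches", "depth", "raw_rate") %in% names(raw)))
  raw <- raw[order(raw$direction, raw$ref, raw$alt, raw$read_pos), ]
  E <- rep(NA_real_, nrow(raw))
  idx <- split(seq_len(nrow(raw)),
               paste(raw$direction, raw$ref, raw$alt))
  for (ii in idx) {
    n <- raw$depth[ii]
    e <- raw$raw_rate[ii]
    K <- length(ii)   # read positions 1..K in order
    Ek <- numeric(K)
    for (k in seq_len(K)) {
      if (n[k] >= avg_depth && n[k] > 0) {
        Ek[k] <- e[k]
        next
      }
      js <- k
      tot <- n[k]
      dd <- 1L
      while (tot <= avg_depth && (k - dd >= 1L || k + dd <= K)) {
        nb <- c(k - dd, k + dd)
        nb <- nb[nb >= 1L & nb <= K]
        js <- c(js, nb)
        tot <- tot + sum(n[nb])
        dd <- dd + 1L
      }
      use <- js[n[js] > 0 & !is.na(e[js])]
      if (!length(use)) {
        Ek[k] <- NA_real_
      } else {
        r <- 1 / (abs(use - k) + 1)
        w <- n[use] * r
        Ek[k] <- sum(e[use] * w) / sum(w)
      }
    }
    E[ii] <- Ek
  }
  raw$smoothed_rate <- E
  pos_rates <- E[!is.na(E) & E > 0]
  floor_rate <- if (length(pos_rates)) min(pos_rates) / 2 else 1e-6
  if (anyNA(E))
    warning(sum(is.na(E)), " empty error bins set to the floor rate ",
            format(floor_rate, digits = 3))
  raw$smoothed_rate[is.na(raw$smoothed_rate)] <- floor_rate

  # fast-lookup array; zero rates are floored so that the binomial test is
  # always well defined
  rates <- array(NA_real_, dim = c(2L, .READ_LEN, 4L, 4L),
                 dimnames = list(c("F", "R"), NULL, .BASES, .BASES))
  rates[cbind(match(raw$direction, c("F", "R")), raw$read_pos,
              match(raw$ref, .BASES), match(raw$alt, .BASES))] <-
    pmax(raw$smoothed_rate, floor_rate)
  rownames(raw) <- NULL
  new("ErrorModel", bins = raw, rates = rates, avg_depth = avg_depth,
      floor_rate = floor_rate, sample_id = sample_id)
}

#' Train an error model from a calibration pileup
#'
#' Convenience wrapper chaining [collectInvariantSites()],
#' [estimateRawErrorRates()] and [smoothErrorRates()].
#'
#' @inheritParams collectInvariantSites
#' @return an [ErrorModel-class].
#' @export
trainErrorModel <- function(x, mask, maxAltFrac = 0.05, minDepth = 10L) {
  inv <- collectInvariantSites(x, mask, maxAltFrac = maxAltFrac,
                               minDepth = minDepth)
  raw <- estimateRawErrorRates(inv)
  smoothErrorRates(raw, sample_id = sampleId(x))
}

#' Look up smoothed error rates
#'
#' Vectorized lookup of the smoothed substitution rate for
#' (direction, read position, reference, alternative). The lookup is total
#' over its domain: bins without training data return the model's floor
#' rate, and every returned rate is strictly positive.
#'
#' @param model an [ErrorModel-class].
#' @param direction "F" or "R" (recycled).
#' @param read_pos read position 1-122.
#' @param ref,alt reference and alternative bases (must differ).
#' @return numeric vector of rates in (0, 1).
#' @export
errorRate <- function(model, direction, read_pos, ref, alt) {
  stopifnot(is(model, "ErrorModel"))
  if (any(ref == alt)) stop("alt must differ from ref")
  if (any(read_pos < 1L | read_pos > .READ_LEN))
    stop("read_pos outside [1, ", .READ_LEN, "]")
  model@rates[cbind(match(direction, c("F", "R")), read_pos,
                    match(ref, .BASES), match(alt, .BASES))]
}

#' Serialize / deserialize an error model as TSV
#'
#' The on-disk form carries one row per bin (direction, read_pos, ref,
#' alt, mismatches, depth, raw_rate, smoothed_rate) plus header comments
#' recording the average depth, floor rate and calibration sample, so a
#' trained model can be audited and reused across runs.
#'
#' @param model an [ErrorModel-class].
#' @param path TSV path.
#' @export
writeErrorModel <- function(model, path) {
  stopifnot(is(model, "ErrorModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_id=%s", model@sample_id),
    sprintf("# avg_depth=%.17g", model@avg_depth),
    sprintf("# floor_rate=%.17g", model@floor_rate)), con)
  write.table(model@bins, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeErrorModel
#' @export
readErrorModel <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- sub("^# ", "", hdr)
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  bins <- .readTsv(path, c("direction", "read_pos", "ref", "alt",
                           "mismatches", "depth", "raw_rate",
                           "smoothed_rate"), what = "error model",
                   colClasses = c(direction = "character",
                                  ref = "character", alt = "character"))
  m <- smoothErrorRates(bins[, c("direction", "read_pos", "ref", "alt",
                                 "mismatches", "depth", "raw_rate")],
                        avg_depth = as.numeric(vals[["avg_depth"]]),
                        sample_id = vals[["sample_id"]])
  m
}
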