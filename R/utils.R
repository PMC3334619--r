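# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so seeded package functions never disturb
# the user's random sequence.
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

.posKey <- function(chrom, pos) paste(chrom, pos, sep = ":")

.varKey <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

# Strict TSV reader used for all of the package's tabular dialects.
# colClasses pins columns whose values ("T", "F") would otherwise be
# type-converted to logicals.
.readTsv <- function(path, required, what = "file", colClasses = NA) {
  if (!file.exists(path)) stop(what, " not found: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = colClasses)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(what, " ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  d
}

.writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Clamp p-values away from 0 and 1 before normal-quantile transformation,
# keeping Stouffer Z-scores finite.
.P_MIN <- 1e-300
.clampP <- function(p, upper = 1) pmin(pmax(p, .P_MIN), upper)
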