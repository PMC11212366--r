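#' @useDynLib introscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats runif rnorm rpois rgeom rlnorm optim cor.test quantile sd
#' @importFrom utils head tail write.table read.table modifyList
NULL

# Single-seed stream splitting: every stochastic stage derives its own
# 32-bit seed from (master seed, stage label) so stages can be re-run or
# reordered without perturbing each other's draws.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 2147483563
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Intervals are data.tables with columns chrom, start, end; 0-based half-open
# throughout the package (BED convention).
new_intervals <- function(chrom = character(), start = integer(), end = integer(), ...) {
  dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), ...)
  if (nrow(dt) && any(dt$end <= dt$start)) stop("intervals must satisfy end > start")
  dt
}

interval_total_length <- function(x) if (nrow(x) == 0L) 0 else sum(as.numeric(x$end - x$start))

# Total overlap (in bases) of each row of `x` with the union of `y`.
overlap_bases <- function(x, y) {
  if (nrow(x) == 0L) return(numeric(0))
  out <- numeric(nrow(x))
  if (nrow(y) == 0L) return(out)
  ym <- merge_intervals(y)
  for (cc in unique(x$chrom)) {
    xi <- which(x$chrom == cc)
    yc <- ym[ym$chrom == cc]
    if (nrow(yc) == 0L) next
    for (i in xi) {
      ov <- pmin(x$end[i], yc$end) - pmax(x$start[i], yc$start)
      out[i] <- sum(pmax(ov, 0))
    }
  }
  out
}

# Sort and merge overlapping/adjacent intervals into a disjoint set.
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  x <- x[order(chrom, start, end)]
  keep <- x[, {
    s <- start; e <- end
    ns <- integer(0); ne <- integer(0)
    cs <- s[1]; ce <- e[1]
    if (.N > 1L) for (i in 2L:.N) {
      if (s[i] <= ce) ce <- max(ce, e[i]) else { ns <- c(ns, cs); ne <- c(ne, ce); cs <- s[i]; ce <- e[i] }
    }
    list(start = c(ns, cs), end = c(ne, ce))
  }, by = chrom]
  keep[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
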