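# Introgression tract calling and filtering.
#
# A tract is a maximal run of >= 2 consecutive SNV sites whose averaged
# introgression posterior meets the threshold; its span is first through
# last qualifying site, half-open. Tracts are then filtered on per-species
# mean depth (inclusive [min_depth, max_depth]) and split at ungenotyped
# gaps longer than max_gap.

#' Call introgression tracts from a posterior track
#'
#' @param track data.table with columns `chrom`, `pos` (0-based, sorted
#'   within chromosome), `posterior`.
#' @param threshold posterior probability threshold in (0, 1]; sites at or
#'   above it qualify.
#' @param min_sites minimum qualifying sites per tract (single-site runs
#'   are discarded under the default).
#' @return data.table of class `introgression_tracts`: chrom, start, end
#'   (half-open), n_sites, mean_posterior.
#' @export
call_tracts <- function(track, threshold = 0.9, min_sites = 2L) {
  stopifnot(threshold > 0, threshold <= 1)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), mean_posterior = numeric())
  if (is.null(track) || nrow(track) == 0L) return(as_tracts(empty))
  track <- as.data.table(track)[order(chrom, pos)]
  out <- track[, {
    q <- posterior >= threshold
    r <- rle(q)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_sites
    if (any(keep)) {
      si <- starts[keep]; ei <- ends[keep]
      list(start = pos[si], end = pos[ei] + 1L,
           n_sites = ei - si + 1L,
           mean_posterior = vapply(seq_along(si), function(k)
             mean(posterior[si[k]:ei[k]]), numeric(1)))
    } else list(start = integer(0), end = integer(0), n_sites = integer(0),
                mean_posterior = numeric(0))
  }, by = chrom]
  as_tracts(out)
}

as_tracts <- function(x) {
  setattr(x, "class", unique(c("introgression_tracts", class(x))))
  x
}

#' Filter tracts on per-species mean coverage depth
#'
#' A tract is kept iff the length-weighted mean depth of every species over
#' its span lies in the inclusive interval `[min_depth, max_depth]`.
#'
#' @param tracts tracts as returned by [call_tracts()].
#' @param depth data.table chrom/start/end plus one `depth_<taxon>` column
#'   per species (piecewise-constant coverage windows).
#' @param min_depth,max_depth inclusive bounds (default 5 and 100).
#' @return filtered tracts with `mean_depth_<taxon>` columns attached.
#' @export
filter_by_depth <- function(tracts, depth, min_depth = 5, max_depth = 100) {
  if (nrow(tracts) == 0L) return(tracts)
  dcols <- grep("^depth_", names(depth), value = TRUE)
  if (!length(dcols)) stop("coverage-data error: no depth_<taxon> columns")
  md <- tract_mean_depth(tracts, depth, dcols)
  out <- cbind(as.data.table(tracts), md)
  keep <- rep(TRUE, nrow(out))
  for (cl in names(md)) keep <- keep & md[[cl]] >= min_depth & md[[cl]] <= max_depth
  as_tracts(out[keep])
}

tract_mean_depth <- function(tracts, depth, dcols) {
  res <- matrix(NA_real_, nrow(tracts), length(dcols),
                dimnames = list(NULL, sub("^depth_", "mean_depth_", dcols)))
  for (i in seq_len(nrow(tracts))) {
    d <- depth[chrom == tracts$chrom[i] & end > tracts$start[i] & start < tracts$end[i]]
    if (nrow(d) == 0L) stop("coverage-data error: tract outside depth track domain")
    w <- pmin(d$end, tracts$end[i]) - pmax(d$start, tracts$start[i])
    if (sum(w) < tracts$end[i] - tracts$start[i])
      stop("coverage-data error: tract not fully covered by depth windows")
    for (k in seq_along(dcols)) res[i, k] <- sum(w * d[[dcols[k]]]) / sum(w)
  }
  as.data.table(res)
}

#' Split tracts at large ungenotyped gaps
#'
#' Any tract overlapping a gap of more than `max_gap` bases between adjacent
#' genotyped positions (invariant sites included) is split at the gap;
#' resulting pieces are re-checked against the minimum-site rule.
#'
#' @param tracts tracts to trim.
#' @param genotyped data.table of all genotyped positions (`chrom`, `pos`).
#' @param track the posterior track the tracts were called from (used to
#'   recompute per-piece site counts and mean posteriors).
#' @param max_gap gap threshold in bases; a gap qualifies when the count of
#'   ungenotyped bases between adjacent genotypes exceeds it (strict).
#' @param min_sites minimum sites per surviving piece.
#' @return trimmed tracts (depth columns, if present, are dropped;
#'   re-filter depth after trimming if required).
#' @export
trim_gaps <- function(tracts, genotyped, track, max_gap = 25000, min_sites = 2L) {
  if (nrow(tracts) == 0L) return(tracts)
  track <- as.data.table(track)
  pieces <- vector("list", nrow(tracts))
  for (i in seq_len(nrow(tracts))) {
    cc <- tracts$chrom[i]; st <- tracts$start[i]; en <- tracts$end[i]
    g <- sort(genotyped[chrom == cc]$pos)
    gi <- which(diff(g) - 1L > max_gap)
    gs <- g[gi]; ge <- g[gi + 1L]            # gap = (gs, ge) exclusive
    inside <- gs >= st & ge <= en
    sites <- track[chrom == cc & pos >= st & pos < en]
    if (!any(inside)) {
      pieces[[i]] <- data.table(chrom = cc, start = st, end = en,
                                n_sites = nrow(sites),
                                mean_posterior = mean(sites$posterior))
      next
    }
    seg <- findInterval(sites$pos, sort(gs[inside]) + 0.5)
    pieces[[i]] <- sites[, .(chrom = cc, start = pos[1L],
                             end = pos[.N] + 1L, n_sites = .N,
                             mean_posterior = mean(posterior)), by = seg][, seg := NULL]
  }
  out <- rbindlist(pieces)[n_sites >= min_sites][order(chrom, start)]
  as_tracts(out)
}

#' Genome-level tract summary
#'
#' @param tracts filtered tracts.
#' @param genome named vector of chromosome lengths.
#' @param annotation a `genome_annotation` (for the coding fraction), or
#'   `NULL` to skip CDS metrics.
#' @return list: `n_tracts`, `n_gt_10kb`, `mean_length`, `median_length`,
#'   `pct_genome`, `pct_cds`, and `per_scaffold` (chrom, length,
#'   pct_introgressed, n_tracts).
#' @export
summarize_tracts <- function(tracts, genome, annotation = NULL) {
  tl <- if (nrow(tracts)) as.numeric(tracts$end - tracts$start) else numeric(0)
  per <- data.table(chrom = names(genome), length = as.numeric(genome))
  tb <- if (nrow(tracts)) as.data.table(tracts)[, .(bases = sum(as.numeric(end - start)),
                                                    n = .N), by = chrom]
        else data.table(chrom = character(), bases = numeric(), n = integer())
  per <- merge(per, tb, by = "chrom", all.x = TRUE)
  per[is.na(bases), bases := 0][is.na(n), n := 0L]
  per[, pct_introgressed := 100 * bases / length]
  pct_cds <- NA_real_
  if (!is.null(annotation)) {
    cds <- merge_intervals(annotation$cds[, .(chrom, start, end)])
    tot_cds <- interval_total_length(cds)
    pct_cds <- if (tot_cds > 0) 100 * sum(overlap_bases(cds, as.data.table(tracts))) / tot_cds else 0
  }
  list(n_tracts = nrow(tracts),
       n_gt_10kb = sum(tl > 10000),
       mean_length = if (length(tl)) mean(tl) else 0,
       median_length = if (length(tl)) stats::median(tl) else 0,
       pct_genome = 100 * sum(tl) / sum(genome),
       pct_cds = pct_cds,
       per_scaffold = per[, .(chrom, length, n_tracts = n, pct_introgressed)])
}

#' Scaffold-level introgression vs gene density correlation
#'
#' Spearman rank correlation between per-scaffold percent introgressed and
#' per-scaffold genes per Mb, with a two-sided p-value.
#'
#' @param pct_introgressed,genes_per_mb numeric vectors, one value per
#'   scaffold (>= 3 scaffolds).
#' @return list with `rho` and `p_value`.
#' @export
scaffold_density_correlation <- function(pct_introgressed, genes_per_mb) {
  stopifnot(length(pct_introgressed) == length(genes_per_mb))
  if (length(pct_introgressed) < 3L) stop("need at least 3 scaffolds")
  if (stats::var(pct_introgressed) == 0 || stats::var(genes_per_mb) == 0)
    stop("undefined-correlation error: constant vector")
  ct <- suppressWarnings(stats::cor.test(pct_introgressed, genes_per_mb,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
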