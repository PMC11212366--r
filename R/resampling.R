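# Resampling machinery: pooled bootstrap comparison of means, constrained
# interval permutation, feature-density bootstrap/permutation comparison,
# gene-family enrichment sampling, and the chromosome-absence block test.

new_resampling_result <- function(observed, null_values, p_value = NA_real_,
                                  seed = NA_integer_, extra = list()) {
  structure(c(list(observed = observed, null_values = null_values,
                   p_value = p_value,
                   ci95 = stats::quantile(null_values, c(0.025, 0.975), names = FALSE),
                   null_mean = mean(null_values), null_sd = stats::sd(null_values),
                   n_replicates = length(null_values), seed = seed), extra),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("observed = %.6g  null mean = %.6g  95%% CI [%.6g, %.6g]",
              x$observed, x$null_mean, x$ci95[1], x$ci95[2]))
  if (!is.na(x$p_value)) cat(sprintf("  p = %.4g", x$p_value))
  cat(sprintf("  (n = %d, seed = %s)\n", x$n_replicates, x$seed))
  invisible(x)
}

#' Pooled bootstrap comparison of two means
#'
#' Pools both groups, draws pairs of resamples (with replacement, of the
#' two original sizes) from the pool, and uses the differences of resample
#' means as the null distribution for the observed difference
#' mean(a) - mean(b). The two-sided p-value carries the +1/(n+1)
#' finite-sample correction.
#'
#' @param values_a,values_b numeric vectors (NAs dropped).
#' @param n_boot number of bootstrap pairs.
#' @param seed integer seed.
#' @return a `resampling_result` (observed difference, null differences,
#'   p-value).
#' @export
bootstrap_mean_diff_test <- function(values_a, values_b, n_boot = 100000L, seed = 1L) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b)) stop("input error: empty group")
  obs <- mean(values_a) - mean(values_b)
  pool <- c(values_a, values_b)
  na <- length(values_a); nb <- length(values_b)
  nulls <- with_seed(seed, {
    out <- numeric(n_boot)
    chunk <- max(1L, min(n_boot, as.integer(2e7 / (na + nb))))
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      ma <- matrix(pool[sample.int(na + nb, k * na, replace = TRUE)], na)
      mb <- matrix(pool[sample.int(na + nb, k * nb, replace = TRUE)], nb)
      out[done + seq_len(k)] <- colMeans(ma) - colMeans(mb)
      done <- done + k
    }
    out
  })
  p <- (1 + sum(abs(nulls) >= abs(obs))) / (n_boot + 1)
  new_resampling_result(obs, nulls, p, seed)
}

#' Permute intervals into background regions
#'
#' Each replicate places intervals of exactly the template lengths and
#' count, each fully inside one background region, with start positions
#' uniform over all feasible placements; intervals within a replicate may
#' not overlap one another.
#'
#' @param template_intervals intervals whose lengths/count are reproduced.
#' @param background_regions disjoint regions to place into.
#' @param seed integer seed.
#' @param n_sets number of replicate interval sets.
#' @param max_tries placement retries per interval before failing.
#' @return list of `n_sets` interval data.tables.
#' @export
shuffle_intervals <- function(template_intervals, background_regions, seed = 1L,
                              n_sets = 1L, max_tries = 1000L) {
  bg <- merge_intervals(as.data.table(background_regions)[, .(chrom, start, end)])
  lens <- sort(as.integer(template_intervals$end - template_intervals$start),
               decreasing = TRUE)
  if (length(lens) && max(lens) > max(bg$end - bg$start))
    stop("placement error: template length ", max(lens),
         " exceeds longest background region")
  with_seed(seed, {
    lapply(seq_len(n_sets), function(rep_i) {
      placed <- data.table(chrom = character(), start = integer(), end = integer())
      for (len in lens) {
        feas <- bg$end - bg$start - len + 1L
        ok_regions <- which(feas > 0L)
        success <- FALSE
        for (try_i in seq_len(max_tries)) {
          ri <- if (length(ok_regions) == 1L) ok_regions else
            sample(ok_regions, 1L, prob = feas[ok_regions])
          st <- bg$start[ri] + sample.int(feas[ri], 1L) - 1L
          en <- st + len
          if (nrow(placed)) {
            cl <- placed[chrom == bg$chrom[ri]]
            if (nrow(cl) && any(st < cl$end & en > cl$start)) next
          }
          placed <- rbind(placed, data.table(chrom = bg$chrom[ri], start = st, end = en))
          success <- TRUE
          break
        }
        if (!success)
          stop("placement error: could not place interval of length ", len)
      }
      placed[order(chrom, start)]
    })
  })
}

#' Feature density of an interval set
#'
#' @param intervals interval data.table (chrom/start/end).
#' @param annotation a `genome_annotation`.
#' @param psg_ids character vector of positively-selected gene ids.
#' @return list: `genes_per_mb` (genes with strictly more than half their
#'   bases inside the intervals, per Mb of interval), `coding_fraction`
#'   (coding bases in intervals / interval bases), `psg_per_mb` (PSGs with
#'   any overlap, per Mb).
#' @export
feature_density <- function(intervals, annotation, psg_ids = character()) {
  tot <- interval_total_length(intervals)
  if (tot <= 0) stop("domain error: zero total interval length")
  mb <- tot / 1e6
  iv <- merge_intervals(as.data.table(intervals)[, .(chrom, start, end)])
  gi <- assign_gene_introgression(annotation, iv)
  n_genes <- sum(gi$introgressed)
  cds <- merge_intervals(annotation$cds[, .(chrom, start, end)])
  coding <- sum(overlap_bases(iv, cds))
  psg <- annotation$genes[gene_id %in% psg_ids]
  n_psg <- if (nrow(psg)) sum(overlap_bases(psg, iv) > 0) else 0L
  list(genes_per_mb = n_genes / mb, coding_fraction = coding / tot,
       psg_per_mb = n_psg / mb)
}

#' Bootstrap vs permutation comparison of tract feature densities
#'
#' Bootstraps the observed tracts with replacement (`n_boot`
#' pseudoreplicates; mean and SD per metric) and builds permutation nulls
#' by placing equally-sized interval sets into the species-tree background
#' (`n_perm` replicates; percentile 95% CI). A metric is flagged when the
#' bootstrap mean falls outside the null CI.
#'
#' @param observed_tracts tract intervals.
#' @param background species-tree background regions.
#' @param annotation a `genome_annotation`.
#' @param psg_ids positively-selected gene ids.
#' @param n_boot,n_perm replicate counts.
#' @param seed integer seed.
#' @return data.table with one row per metric: bootstrap mean/sd, null CI,
#'   `outside_ci` flag.
#' @export
density_permutation_test <- function(observed_tracts, background, annotation,
                                     psg_ids = character(), n_boot = 1000L,
                                     n_perm = 1000L, seed = 1L) {
  tr <- as.data.table(observed_tracts)[, .(chrom, start, end)]
  metrics <- c("genes_per_mb", "coding_fraction", "psg_per_mb")
  boot <- with_seed(derive_seed(seed, "density_boot"), {
    vapply(seq_len(n_boot), function(i) {
      bs <- tr[sample.int(nrow(tr), nrow(tr), replace = TRUE)]
      unlist(feature_density(bs, annotation, psg_ids))
    }, numeric(3))
  })
  perm_sets <- shuffle_intervals(tr, background, seed = derive_seed(seed, "density_perm"),
                                 n_sets = n_perm)
  perm <- vapply(perm_sets, function(s) unlist(feature_density(s, annotation, psg_ids)),
                 numeric(3))
  out <- data.table(metric = metrics,
                    observed = unlist(feature_density(tr, annotation, psg_ids)),
                    boot_mean = rowMeans(boot),
                    boot_sd = apply(boot, 1, stats::sd),
                    null_lo = apply(perm, 1, stats::quantile, 0.025),
                    null_hi = apply(perm, 1, stats::quantile, 0.975))
  out[, outside_ci := boot_mean < null_lo | boot_mean > null_hi]
  out[]
}

#' Gene-family enrichment among introgressed genes
#'
#' Draws `n_draws` random gene sets of the same size as the introgressed
#' set (without replacement, from all genes) and counts family members in
#' each; fold enrichment is the observed family count over the null mean.
#'
#' @param introgressed_gene_ids,all_gene_ids,family_ids character vectors
#'   (`introgressed` and `family` subsets of `all`).
#' @param n_draws number of random draws.
#' @param seed integer seed.
#' @return a `resampling_result` with extra fields `fold` and
#'   `observed_count`.
#' @export
gene_family_enrichment <- function(introgressed_gene_ids, all_gene_ids, family_ids,
                                   n_draws = 1000L, seed = 1L) {
  if (!length(family_ids)) stop("domain error: empty family set")
  stopifnot(all(introgressed_gene_ids %in% all_gene_ids),
            all(family_ids %in% all_gene_ids))
  k <- length(introgressed_gene_ids)
  obs <- sum(introgressed_gene_ids %in% family_ids)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i)
      sum(sample(all_gene_ids, k) %in% family_ids), numeric(1))
  })
  fold <- if (mean(nulls) > 0) obs / mean(nulls) else NA_real_
  new_resampling_result(obs, nulls, seed = seed,
                        extra = list(fold = fold, observed_count = obs))
}

#' Chromosome-absence block test
#'
#' Splits the genome into non-overlapping blocks, repeatedly samples
#' `n_draw` blocks without replacement, and reports how often at least one
#' (and at least two) chromosomes receive no sampled block.
#'
#' @param chromosome_lengths named vector of chromosome lengths.
#' @param block_size block size in bases (blocks = floor(length/size)).
#' @param n_draw blocks sampled per iteration.
#' @param n_iter iterations.
#' @param seed integer seed.
#' @return list: `freq_ge1`, `freq_ge2`, `n_blocks`, counts per iteration
#'   summary.
#' @export
chromosome_absence_test <- function(chromosome_lengths, block_size = 10000L,
                                    n_draw = 164L, n_iter = 10000L, seed = 1L) {
  nb <- floor(chromosome_lengths / block_size)
  if (any(nb < 1)) stop("each chromosome must yield at least one block")
  B <- sum(nb)
  if (n_draw > B) stop("input error: n_draw exceeds total block count")
  chrom_of <- rep.int(seq_along(nb), nb)
  absent <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      hit <- tabulate(chrom_of[sample.int(B, n_draw)], nbins = length(nb))
      sum(hit == 0L)
    }, numeric(1))
  })
  list(freq_ge1 = mean(absent >= 1), freq_ge2 = mean(absent >= 2),
       n_blocks = B, n_absent = absent, seed = seed)
}
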