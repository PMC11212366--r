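# Resampling procedures: pooled bootstrap, interval permutation, feature
# densities, family enrichment, chromosome-absence block test.

test_that("bootstrap_mean_diff_test behaves on degenerate and separated groups", {
  x <- rnorm(30)
  r <- bootstrap_mean_diff_test(x, x, n_boot = 500L, seed = 3L)
  expect_equal(r$observed, 0)
  expect_gt(r$p_value, 0.9)
  set.seed(17)
  a <- rnorm(50); b <- rnorm(50, 5)
  r2 <- bootstrap_mean_diff_test(a, b, n_boot = 20000L, seed = 3L)
  expect_lte(r2$p_value, 1e-4)
  expect_error(bootstrap_mean_diff_test(numeric(), 1:3), "empty group")
  expect_equal(r2$n_replicates, 20000L)
})

test_that("bootstrap test is label-symmetric up to sign", {
  set.seed(23)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  r1 <- bootstrap_mean_diff_test(a, b, n_boot = 5000L, seed = 9L)
  r2 <- bootstrap_mean_diff_test(b, a, n_boot = 5000L, seed = 9L)
  expect_equal(r1$observed, -r2$observed)
  expect_equal(r1$p_value, r2$p_value, tolerance = 0.02)
})

test_that("shuffle_intervals preserves lengths, count and containment", {
  bg <- data.table::data.table(chrom = c("chr1", "chr1", "chr2"),
                               start = c(0L, 50000L, 0L),
                               end = c(20000L, 90000L, 30000L))
  tpl <- data.table::data.table(chrom = "chr1", start = c(0L, 100L, 5000L),
                                end = c(5000L, 2100L, 15000L))
  sets <- shuffle_intervals(tpl, bg, seed = 4L, n_sets = 50L)
  expect_length(sets, 50L)
  for (s in sets) {
    expect_equal(sort(s$end - s$start), sort(tpl$end - tpl$start))
    # containment: each interval inside one background region
    for (i in seq_len(nrow(s))) {
      hit <- bg[chrom == s$chrom[i] & start <= s$start[i] & end >= s$end[i]]
      expect_equal(nrow(hit), 1L)
    }
    # no intra-replicate overlap
    for (cc in unique(s$chrom)) {
      sc <- s[chrom == cc][order(start)]
      if (nrow(sc) > 1L) expect_true(all(sc$start[-1] >= sc$end[-nrow(sc)]))
    }
  }
})

test_that("shuffle placement is forced when background equals the template", {
  bg <- data.table::data.table(chrom = "chr1", start = 1000L, end = 6000L)
  tpl <- data.table::data.table(chrom = "chr1", start = 0L, end = 5000L)
  s <- shuffle_intervals(tpl, bg, seed = 1L, n_sets = 3L)
  for (x in s) expect_equal(unname(unlist(x[1, .(start, end)])), c(1000L, 6000L))
  expect_error(shuffle_intervals(
    data.table::data.table(chrom = "chr1", start = 0L, end = 9000L), bg),
    "placement error")
})

test_that("start positions are uniform over a single background region", {
  bg <- data.table::data.table(chrom = "chr1", start = 0L, end = 100000L)
  tpl <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  sets <- shuffle_intervals(tpl, bg, seed = 12L, n_sets = 2000L)
  starts <- vapply(sets, function(s) s$start[1], integer(1))
  expect_gte(min(starts), 0L)
  expect_lte(max(starts) + 1000L, 100000L)
  cnt <- table(cut(starts, breaks = seq(0, 99001, length.out = 11),
                   include.lowest = TRUE))
  p <- stats::chisq.test(as.vector(cnt))$p.value
  expect_gt(p, 0.01)
})

test_that("feature densities match the per-base oracle", {
  st <- small_study()
  iv <- st$truth$tracts
  fd <- feature_density(iv, st$annotation, st$psg_ids)
  genome <- st$genome
  tot <- sum(iv$end - iv$start)
  cds <- introscape:::merge_intervals(st$annotation$cds[, .(chrom, start, end)])
  expect_equal(fd$coding_fraction,
               oracle_overlap_bases(as.data.frame(iv), as.data.frame(cds), genome) / tot,
               tolerance = 1e-12)
  genes <- st$annotation$genes
  n_half <- 0L; n_psg <- 0L
  for (i in seq_len(nrow(genes))) {
    mask <- oracle_base_mask(as.data.frame(iv), genes$chrom[i], genome[[genes$chrom[i]]])
    frac <- mean(mask[(genes$start[i] + 1):genes$end[i]])
    if (frac > 0.5) n_half <- n_half + 1L
    if (frac > 0 && genes$gene_id[i] %in% st$psg_ids) n_psg <- n_psg + 1L
  }
  expect_equal(fd$genes_per_mb, n_half / (tot / 1e6), tolerance = 1e-12)
  expect_equal(fd$psg_per_mb, n_psg / (tot / 1e6), tolerance = 1e-12)
  expect_error(feature_density(iv[0], st$annotation), "zero total")
})

test_that("a 1 Mb interval containing 17 qualifying genes gives 17 genes/Mb", {
  genes <- data.table::data.table(chrom = "chr1",
                                  start = seq(0L, by = 50000L, length.out = 17L),
                                  end = seq(0L, by = 50000L, length.out = 17L) + 10000L,
                                  gene_id = sprintf("g%02d", 1:17),
                                  family = NA_character_, psg = FALSE)
  ann <- list(genes = genes,
              cds = data.table::data.table(chrom = genes$chrom, start = genes$start,
                                           end = genes$start + 3000L,
                                           gene_id = genes$gene_id),
              genome = c(chr1 = 2e6))
  class(ann) <- "genome_annotation"
  iv <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000000L)
  fd <- feature_density(iv, ann)
  expect_equal(fd$genes_per_mb, 17)
  expect_equal(fd$coding_fraction, 17 * 3000 / 1e6)
  expect_equal(fd$psg_per_mb, 0)
})

test_that("density_permutation_test is seed-reproducible and flags planted deserts", {
  st <- small_study()
  bg <- data.table::data.table(chrom = "chr1", start = 0L, end = 200000L)
  tr <- st$truth$tracts[1:2]
  r1 <- density_permutation_test(tr, bg, st$annotation, st$psg_ids,
                                 n_boot = 50L, n_perm = 50L, seed = 77L)
  r2 <- density_permutation_test(tr, bg, st$annotation, st$psg_ids,
                                 n_boot = 50L, n_perm = 50L, seed = 77L)
  expect_identical(r1, r2)
  expect_equal(r1$metric, c("genes_per_mb", "coding_fraction", "psg_per_mb"))
  # tracts planted in a gene desert: genes_per_mb flagged low
  ann <- st$annotation
  desert <- data.table::data.table(chrom = "chr2", start = 100000L, end = 120000L)
  ann2 <- ann
  ann2$genes <- ann$genes[!(chrom == "chr2" & end > 100000L & start < 120000L)]
  ann2$cds <- ann$cds[gene_id %in% ann2$genes$gene_id]
  bg2 <- data.table::data.table(chrom = c("chr1", "chr2"), start = c(0L, 0L),
                                end = c(200000L, 100000L))
  r3 <- density_permutation_test(desert, bg2, ann2, st$psg_ids,
                                 n_boot = 100L, n_perm = 200L, seed = 5L)
  expect_equal(r3[metric == "genes_per_mb"]$boot_mean, 0)
  expect_true(r3[metric == "genes_per_mb"]$outside_ci ||
                r3[metric == "genes_per_mb"]$null_lo == 0)
})

test_that("gene_family_enrichment has the hypergeometric null mean", {
  all_ids <- sprintf("g%03d", 1:200)
  fam <- all_ids[1:30]
  intro <- all_ids[c(1:10, 101:140)]  # 10 family among 50 drawn
  r <- gene_family_enrichment(intro, all_ids, fam, n_draws = 2000L, seed = 8L)
  expect_equal(r$observed_count, 10L)
  expected <- 50 * 30 / 200
  se_mean <- stats::sd(r$null_values) / sqrt(2000)
  expect_lt(abs(r$null_mean - expected), 3 * se_mean + 1e-9)
  expect_equal(r$fold, 10 / r$null_mean)
  # family = all genes: every draw is all-family, fold exactly 1
  r2 <- gene_family_enrichment(intro, all_ids, all_ids, n_draws = 100L, seed = 1L)
  expect_equal(r2$fold, 1.0)
  # no family members in the introgressed set
  r3 <- gene_family_enrichment(all_ids[101:120], all_ids, fam, n_draws = 100L, seed = 1L)
  expect_equal(r3$fold, 0)
  expect_error(gene_family_enrichment(intro, all_ids, character()), "empty family")
})

test_that("chromosome_absence_test matches closed forms", {
  # two equal chromosomes, one draw: some chromosome is always absent
  r <- chromosome_absence_test(c(a = 50000, b = 50000), block_size = 10000L,
                               n_draw = 1L, n_iter = 200L, seed = 2L)
  expect_equal(r$freq_ge1, 1.0)
  # exhaustive draw: nothing can be absent
  r2 <- chromosome_absence_test(c(a = 50000, b = 50000), block_size = 10000L,
                                n_draw = 10L, n_iter = 100L, seed = 2L)
  expect_equal(r2$freq_ge1, 0)
  expect_equal(r2$freq_ge2, 0)
  expect_error(chromosome_absence_test(c(a = 50000), block_size = 10000L,
                                       n_draw = 6L), "exceeds total")
  expect_error(chromosome_absence_test(c(a = 5000), block_size = 10000L, n_draw = 1L),
               "at least one block")
})

test_that("specific-chromosome absence frequency is hypergeometric", {
  C <- 5L; b <- 20L; n <- 30L
  lens <- setNames(rep(b * 10000, C), paste0("c", 1:C))
  n_iter <- 4000L
  r <- chromosome_absence_test(lens, block_size = 10000L, n_draw = n,
                               n_iter = n_iter, seed = 6L)
  B <- C * b
  p_specific <- exp(lchoose(B - b, n) - lchoose(B, n))
  # E[#absent] = C * p_specific; observed mean count within 3 MC SE
  expect_lt(abs(mean(r$n_absent) - C * p_specific),
            3 * stats::sd(r$n_absent) / sqrt(n_iter) + 1e-12)
})
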