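# End-to-end pipeline: simulate -> detect -> call tracts -> background ->
# statistics -> resampling tests -> report.

#' Species-tree background regions
#'
#' Maximal runs of at least `min_sites` consecutive SNV sites whose
#' species-tree posterior (1 - introgression posterior) meets the
#' threshold, with the same span convention as tracts. Disjoint from the
#' introgression tracts by construction whenever both thresholds exceed
#' 0.5.
#'
#' @param track a `posterior_track`.
#' @param threshold species-tree posterior threshold.
#' @param min_sites minimum run length in sites.
#' @return interval data.table (chrom, start, end, n_sites,
#'   mean_posterior of the species tree).
#' @export
species_tree_background <- function(track, threshold = 0.9, min_sites = 2L) {
  flipped <- as.data.table(track)[, .(chrom, pos, posterior = 1 - posterior)]
  bg <- call_tracts(flipped, threshold, min_sites)
  setattr(bg, "class", setdiff(class(bg), "introgression_tracts"))
  bg
}

#' Run the full analysis on a synthetic study
#'
#' @param study an `intro_study` from [simulate_study()].
#' @param cfg a `run_config`; replicate counts default to full scale, so
#'   pass reduced values for desk-scale runs.
#' @return list of class `intro_run` with the fitted track, filtered
#'   tracts, background regions, per-interval divergence, per-gene rates,
#'   resampling results, and summary tables.
#' @export
run_pipeline <- function(study, cfg = run_config()) {
  stopifnot(inherits(study, "intro_study"), inherits(cfg, "run_config"))
  fit <- fit_phmm(study$alignment, n_restarts = cfg$n_restarts, seed = cfg$seed)
  run_pipeline_from_track(fit$track, study, cfg, fit = fit)
}

# The post-HMM part, reusable when a track already exists (CLI stages).
run_pipeline_from_track <- function(track, study, cfg, fit = NULL) {
  ann <- study$annotation
  gt <- study$genotypes
  # tract calling with the depth and gap filters, applied symmetrically to
  # the species-tree background
  shape_intervals <- function(raw) {
    x <- filter_by_depth(raw, study$depth, cfg$min_depth, cfg$max_depth)
    x <- trim_gaps(x, study$alignment$genotyped, track, cfg$max_gap)
    if (nrow(x)) filter_by_depth(x, study$depth, cfg$min_depth, cfg$max_depth) else x
  }
  tracts <- shape_intervals(call_tracts(track, cfg$threshold))
  background <- shape_intervals(species_tree_background(track, cfg$background_threshold))
  summary <- summarize_tracts(tracts, study$genome, ann)

  tr10 <- as.data.table(tracts)[end - start > cfg$min_tract_bases_10kb]
  results <- list()
  gmask <- mask_genotypes_for_dxy(gt)

  feasible <- nrow(tr10) > 0 && nrow(background) > 0 &&
    max(tr10$end - tr10$start) <= max(background$end - background$start)
  if (nrow(tr10) && nrow(background) && !feasible)
    message("skipping interval-permutation statistics: longest tract exceeds ",
            "the longest background region")
  if (feasible) {
    bg_sample <- shuffle_intervals(tr10, background,
                                   seed = derive_seed(cfg$seed, "bg_sample"), n_sets = 1L)[[1]]
    dxy_tr <- dxy_intervals(gmask, tr10)
    dxy_bg <- dxy_intervals(gmask, bg_sample)
    results$dxy <- bootstrap_mean_diff_test(dxy_tr, dxy_bg, cfg$n_boot_means,
                                            seed = derive_seed(cfg$seed, "dxy_boot"))
    results$dxy_values <- list(tracts = dxy_tr, background = dxy_bg,
                               background_sample = bg_sample)
    results$density <- density_permutation_test(tr10, background, ann,
                                                psg_ids = study$psg_ids,
                                                n_boot = cfg$n_boot_density,
                                                n_perm = cfg$n_perm, seed = cfg$seed)
    results$chrom_absence <- chromosome_absence_test(study$genome, cfg$block_size,
                                                     n_draw = nrow(tr10),
                                                     n_iter = cfg$n_block_iter,
                                                     seed = derive_seed(cfg$seed, "blocks"))
  }

  # rates of evolution: introgressed genes (> half bases in tracts) vs a
  # same-size random draw of background genes, both depth/stop filtered
  gi_tr <- assign_gene_introgression(ann, tracts)
  gi_bg <- assign_gene_introgression(ann, background)
  filt <- gene_filters(ann, study$depth, study$gene_seqs,
                       min_depth = cfg$gene_min_depth, max_depth = cfg$gene_max_depth)
  ok <- filt$gene_id[filt$pass]
  intro_genes <- intersect(gi_tr$gene_id[gi_tr$introgressed], ok)
  bg_genes <- intersect(gi_bg$gene_id[gi_bg$introgressed], ok)
  if (length(intro_genes) >= 2L && length(bg_genes) >= length(intro_genes)) {
    bg_pick <- with_seed(derive_seed(cfg$seed, "bg_genes"),
                         sample(bg_genes, length(intro_genes)))
    rate_of <- function(ids) {
      est <- lapply(ids, function(g) {
        sq <- study$gene_seqs[[g]]
        tryCatch(ng86_dnds(sq[1], sq[2]), error = function(e) NULL)
      })
      est <- Filter(Negate(is.null), est)
      data.table(dN = vapply(est, `[[`, numeric(1), "dN"),
                 dS = vapply(est, `[[`, numeric(1), "dS"),
                 omega = vapply(est, `[[`, numeric(1), "omega"))
    }
    ri <- rate_of(intro_genes); rb <- rate_of(bg_pick)
    for (m in c("dN", "dS", "omega")) {
      if (sum(!is.na(ri[[m]])) && sum(!is.na(rb[[m]])))
        results[[paste0("rates_", m)]] <-
          bootstrap_mean_diff_test(ri[[m]], rb[[m]], cfg$n_boot_means,
                                   seed = derive_seed(cfg$seed, paste0("rates_", m)))
    }
    results$rates_values <- list(introgressed = ri, background = rb,
                                 intro_genes = intro_genes, bg_genes = bg_pick)
  }

  # gene-family enrichment among genes overlapping tracts by >= 2 bases
  fam <- ann$genes$gene_id[!is.na(ann$genes$family)]
  ov_genes <- ann$genes$gene_id[overlap_bases(ann$genes, as.data.table(tracts)) >= 2]
  if (length(fam) && length(ov_genes))
    results$family <- gene_family_enrichment(ov_genes, ann$genes$gene_id, fam,
                                             n_draws = cfg$n_perm,
                                             seed = derive_seed(cfg$seed, "family"))

  # scaffold-level association between introgression and gene density
  per <- summary$per_scaffold
  gpm <- ann$genes[, .(n = .N), by = chrom]
  per <- merge(per, gpm, by = "chrom", all.x = TRUE)
  per[is.na(n), n := 0L]
  per[, genes_per_mb := n / (length / 1e6)]
  results$scaffold_cor <- if (nrow(per) >= 3L &&
                              stats::var(per$pct_introgressed) > 0 &&
                              stats::var(per$genes_per_mb) > 0)
    scaffold_density_correlation(per$pct_introgressed, per$genes_per_mb) else NULL

  structure(list(config = cfg, config_hash = config_hash(cfg), fit = fit,
                 track = track, tracts = tracts, background = background,
                 summary = summary, per_scaffold = per, results = results),
            class = "intro_run")
}

#' Write the run report files
#'
#' Emits `tracts.bed`, `background.bed`, `summary.tsv`, `per_scaffold.tsv`,
#' a Table-2-style `report.tsv` (tract metrics vs background null CIs) and
#' `tests.json` with every resampling result, each embedding the seed and
#' config hash.
#'
#' @param run an `intro_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(run$tracts, file.path(dir, "tracts.bed"))
  write_bed(run$background, file.path(dir, "background.bed"))
  s <- run$summary
  fwrite(data.table(item = c("n_tracts", "n_gt_10kb", "mean_length", "median_length",
                             "pct_genome", "pct_cds", "seed", "config_hash"),
                    value = c(s$n_tracts, s$n_gt_10kb, round(s$mean_length, 3),
                              round(s$median_length, 3), signif(s$pct_genome, 6),
                              signif(s$pct_cds, 6), run$config$seed, run$config_hash)),
         file.path(dir, "summary.tsv"), sep = "\t")
  fwrite(run$per_scaffold, file.path(dir, "per_scaffold.tsv"), sep = "\t")

  rows <- list()
  res <- run$results
  if (!is.null(res$dxy))
    rows$d_xy <- data.table(metric = "d_xy",
                            tract_value = signif(mean(res$dxy_values$tracts, na.rm = TRUE), 6),
                            null_lo = NA_real_, null_hi = NA_real_,
                            p_value = res$dxy$p_value)
  for (m in c("dN", "dS", "omega")) {
    r <- res[[paste0("rates_", m)]]
    if (!is.null(r))
      rows[[m]] <- data.table(metric = m,
                              tract_value = signif(mean(res$rates_values$introgressed[[m]],
                                                        na.rm = TRUE), 6),
                              null_lo = NA_real_, null_hi = NA_real_, p_value = r$p_value)
  }
  if (!is.null(res$density)) {
    d <- res$density
    rows$density <- data.table(metric = d$metric,
                               tract_value = signif(d$boot_mean, 6),
                               null_lo = signif(d$null_lo, 6),
                               null_hi = signif(d$null_hi, 6), p_value = NA_real_)
  }
  report <- if (length(rows)) rbindlist(rows, use.names = TRUE) else
    data.table(metric = character(), tract_value = numeric(),
               null_lo = numeric(), null_hi = numeric(), p_value = numeric())
  fwrite(report, file.path(dir, "report.tsv"), sep = "\t")

  tests <- list(seed = run$config$seed, config_hash = run$config_hash)
  strip <- function(r) r[setdiff(names(r), "null_values")]
  for (k in c("dxy", "rates_dN", "rates_dS", "rates_omega", "family"))
    if (!is.null(res[[k]])) tests[[k]] <- strip(res[[k]])
  if (!is.null(res$chrom_absence))
    tests$chrom_absence <- res$chrom_absence[c("freq_ge1", "freq_ge2", "n_blocks", "seed")]
  if (!is.null(res$scaffold_cor)) tests$scaffold_cor <- res$scaffold_cor
  if (!is.null(res$density)) tests$density <- res$density
  jsonlite::write_json(tests, file.path(dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

#' @export
print.intro_run <- function(x, ...) {
  s <- x$summary
  cat("Introgression scan run (seed", x$config$seed, ")\n")
  cat(sprintf("  tracts: %d (%d > 10 kb), %.3g%% of genome, %.3g%% of CDS\n",
              s$n_tracts, s$n_gt_10kb, s$pct_genome, s$pct_cds))
  cat(sprintf("  background regions: %d\n", nrow(x$background)))
  invisible(x)
}
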