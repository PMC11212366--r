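# Synthetic study generator.
#
# Emulates the data layout of a reference-anchored four-taxon introgression
# scan: a quartet SNV alignment simulated under a species tree
# (O,(P,(D,F))) with planted tracts evolving under the introgression tree
# (O,(F,(D,P))), diploid genotypes with quality fields, invariant genotyped
# positions, per-species depth tracks, and gene models with a multi-copy
# family and positively-selected-gene flags. Everything is a deterministic
# function of a single seed (stream-split per stage).

#' Simulation configuration
#'
#' Defaults describe the scaled-down stated world: SNV spacing 85 bp,
#' tract lengths log-normal around a 16.6 kb median / 22.9 kb mean,
#' per-species depth means matching the study's coverage table, and a
#' multi-copy gene family analogous to hyalin.
#'
#' @param seed master seed; fully determines all outputs.
#' @param chromosome_lengths named vector of chromosome lengths in bases.
#' @param snv_spacing_mean mean distance between SNV columns (bases).
#' @param invariant_spacing_mean mean distance between invariant genotyped
#'   positions (bases).
#' @param species_tree_branch_lengths,introgression_tree_branch_lengths
#'   named branch lengths (substitutions/site): terminal edges by taxon,
#'   `A1` the stem to the ingroup, `A2` the internal branch of the cherry.
#' @param tract_count number of planted introgression tracts.
#' @param tract_length_distribution log-normal `meanlog`/`sdlog` (bases).
#' @param tract_min_length lower truncation for tract lengths (bases).
#' @param heterozygosity_rate per-sample fraction of SNV genotypes that are
#'   heterozygous.
#' @param depth_model list of per-species `mean` and `sd` of read depth.
#' @param depth_window window size (bases) over which depth is constant.
#' @param gene_count,gene_length_distribution,family_gene_count,psg_fraction
#'   annotation parameters; `family_gene_count` genes carry the multi-copy
#'   family label.
#' @param gaps_per_mb expected number of large ungenotyped gaps per Mb.
#' @param indel_spacing_mean mean spacing between simulated indel positions.
#' @param quality_model mean/sd for GQ and RGQ fields.
#' @param gene_divergence pairwise O-F coding divergence parameters for
#'   background and introgressed genes (`t`: raw substitution attempts per
#'   base; `omega`: acceptance probability of nonsynonymous changes);
#'   `stop_rate`: fraction of genes planted with a premature stop codon.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosome_lengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6, chr4 = 1e6),
                       snv_spacing_mean = 85,
                       invariant_spacing_mean = 850,
                       species_tree_branch_lengths =
                         c(O = 0.022, A1 = 0.005, P = 0.018, A2 = 0.020, D = 0.010, F = 0.010),
                       introgression_tree_branch_lengths =
                         c(O = 0.022, A1 = 0.005, F = 0.018, A2 = 0.020, D = 0.010, P = 0.010),
                       tract_count = 20L,
                       tract_length_distribution = c(meanlog = log(16595), sdlog = 0.8),
                       tract_min_length = 200L,
                       heterozygosity_rate = 0.1,
                       depth_model = list(mean = c(O = 24.5, P = 11.9, D = 24.7, F = 32.1),
                                          sd = c(O = 6, P = 3, D = 6, F = 8)),
                       depth_window = 1000L,
                       gene_count = 120L,
                       gene_length_distribution = c(meanlog = log(5000), sdlog = 0.6),
                       family_gene_count = 6L,
                       psg_fraction = 0.1,
                       gaps_per_mb = 2.8,
                       indel_spacing_mean = 2000,
                       quality_model = list(gq_mean = 60, gq_sd = 20, rgq_mean = 60, rgq_sd = 20),
                       gene_divergence = list(t_background = 0.06, omega_background = 0.3,
                                              t_introgressed = 0.045, omega_introgressed = 0.2,
                                              stop_rate = 0.02)) {
  if (length(chromosome_lengths) == 0L) stop("configuration error: empty chromosome list")
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  stopifnot(snv_spacing_mean > 0, invariant_spacing_mean > 0,
            all(species_tree_branch_lengths >= 0),
            all(introgression_tree_branch_lengths >= 0),
            tract_count >= 0, heterozygosity_rate >= 0, heterozygosity_rate <= 1,
            gene_count >= 0, family_gene_count >= 0, psg_fraction >= 0, psg_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# geometric inter-arrival point process with mean spacing `mu` on [0, len)
sim_positions <- function(len, mu) {
  n_guess <- ceiling(len / mu * 1.25) + 50L
  pos <- cumsum(rgeom(n_guess, 1 / mu) + 1L)
  while (pos[length(pos)] < len) pos <- c(pos, pos[length(pos)] + cumsum(rgeom(n_guess, 1 / mu) + 1L))
  pos <- pos[pos <= len] - 1L  # 0-based
  as.integer(pos)
}

drop_in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0L || length(pos) == 0L) return(pos)
  keep <- rep(TRUE, length(pos))
  for (i in seq_len(nrow(iv))) keep[pos >= iv$start[i] & pos < iv$end[i]] <- FALSE
  pos[keep]
}

#' Simulate gene models, a multi-copy family, and PSG flags
#'
#' Genes are placed without overlap; `family_gene_count` genes carry the
#' family label, spread over at least two chromosomes with pairwise
#' same-chromosome gaps above 400 kb whenever the genome leaves room; a
#' `psg_fraction` of genes is flagged as positively selected.
#'
#' @param config a `sim_config`.
#' @return object of class `genome_annotation`: `genes` (chrom, start, end,
#'   gene_id, family, psg), `cds` (chrom, start, end, gene_id), and
#'   `genome` (chromosome lengths).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    lens <- config$chromosome_lengths
    ng <- config$gene_count
    if (ng == 0L) {
      ann <- list(genes = new_intervals(gene_id = character(), family = character(),
                                        psg = logical()),
                  cds = new_intervals(gene_id = character()), genome = lens)
      class(ann) <- "genome_annotation"
      return(ann)
    }
    gl <- pmax(300L, as.integer(round(rlnorm(ng, config$gene_length_distribution[["meanlog"]],
                                             config$gene_length_distribution[["sdlog"]]))))
    if (sum(as.numeric(gl)) > 0.7 * sum(lens))
      stop("sizing error: requested gene footprint exceeds genome size")
    # assign genes to chromosomes proportionally to length, then place each
    # chromosome's genes by distributing the free space among the gaps
    chrom_of <- sample(names(lens), ng, replace = TRUE, prob = lens / sum(lens))
    genes <- vector("list", length(lens))
    for (ci in seq_along(lens)) {
      cc <- names(lens)[ci]
      idx <- which(chrom_of == cc)
      if (!length(idx)) next
      li <- gl[idx]
      n <- length(li)
      free <- lens[[cc]] - sum(li)
      if (free < n + 1L) stop("sizing error: genes do not fit on ", cc)
      # split the free space into n+1 gaps (>= 1 base each) via sorted cuts
      cuts <- sort(runif(n, 0, 1))
      gaps <- as.integer(floor(diff(c(0, cuts, 1)) * (free - n - 1L))) + 1L
      starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0L, head(li, -1L)))
      genes[[ci]] <- data.table(chrom = cc, start = starts, end = starts + li,
                                gene_id = sprintf("gene%05d", idx))
    }
    genes <- rbindlist(genes)[order(chrom, start)]
    # multi-copy family: prefer spreading over chromosomes and keeping
    # same-chromosome pairs > 400 kb apart when the genome allows it
    genes[, family := NA_character_]
    nf <- min(config$family_gene_count, nrow(genes))
    if (nf > 0L) {
      ord <- sample.int(nrow(genes))
      picked <- integer(0)
      for (relax in c(FALSE, TRUE)) {
        for (i in ord) {
          if (length(picked) >= nf) break
          if (i %in% picked) next
          ok <- TRUE
          if (!relax) {
            same <- picked[genes$chrom[picked] == genes$chrom[i]]
            if (length(same)) {
              gap <- pmax(genes$start[i] - genes$end[same], genes$start[same] - genes$end[i])
              ok <- all(gap > 400000)
            }
            if (ok && length(picked) == nf - 1L && nf >= 2L &&
                length(unique(genes$chrom[c(picked, i)])) < 2L &&
                length(unique(genes$chrom)) >= 2L) ok <- FALSE
          }
          if (ok) picked <- c(picked, i)
        }
        if (length(picked) >= nf) break
      }
      genes$family[picked] <- "familyA"
    }
    genes[, psg := FALSE]
    npsg <- round(config$psg_fraction * nrow(genes))
    if (npsg > 0L) genes$psg[sample.int(nrow(genes), npsg)] <- TRUE
    # CDS: 1-4 exons per gene totalling ~half the gene span, frame-complete
    cds <- genes[, {
      glen <- end - start
      total <- max(150L, (as.integer(glen * 0.5) %/% 3L) * 3L)
      nex <- min(1L + rpois(1L, 1.2), 4L)
      exl <- rep(total %/% nex, nex); exl[1] <- exl[1] + total - sum(exl)
      room <- glen - sum(exl)
      cuts <- sort(runif(nex, 0, 1))
      gaps <- as.integer(floor(diff(c(0, cuts)) * (room / 1.5)))
      st <- start + cumsum(gaps) + cumsum(c(0L, head(exl, -1L)))
      list(start = as.integer(st), end = as.integer(st + exl))
    }, by = .(chrom, gene_id)]
    setcolorder(cds, c("chrom", "start", "end", "gene_id"))
    ann <- list(genes = genes, cds = cds[order(chrom, start)], genome = lens)
    class(ann) <- "genome_annotation"
    ann
  })
}

#' Simulate the quartet alignment, truth set, depth and quality fields
#'
#' SNV positions follow a geometric (Poisson-like) point process with the
#' configured mean spacing; columns inside planted tracts evolve under the
#' introgression tree, all others under the species tree (JC69 down the
#' tree). Diploid genotypes are heterozygous at the configured rate;
#' invariant genotyped positions, large ungenotyped gaps, per-species depth
#' windows, indel positions, and GQ/DP/RGQ fields are also emitted.
#'
#' @param config a `sim_config`.
#' @return list with `genotypes` (class `genotype_table`), `truth` (list
#'   with `tracts` intervals), `depth` (data.table chrom/start/end plus one
#'   depth column per taxon), and `alignment` (pseudo-haploid
#'   `site_alignment` over the SNV columns, heterozygotes already resolved
#'   under a derived seed).
#' @export
simulate_quartet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- config$chromosome_lengths
  truth <- with_seed(derive_seed(config$seed, "tracts"), plant_tracts(config))
  gt <- with_seed(derive_seed(config$seed, "quartet"), {
    sim_genotypes(config, truth)
  })
  depth <- with_seed(derive_seed(config$seed, "depth"), sim_depth(config))
  gt <- with_seed(derive_seed(config$seed, "quality"), add_quality(config, gt, depth))
  gt <- resolve_heterozygotes(gt, derive_seed(config$seed, "resolve"))
  aln <- as_site_alignment(gt)
  list(genotypes = gt, truth = truth, depth = depth, alignment = aln)
}

plant_tracts <- function(config) {
  lens <- config$chromosome_lengths
  n <- config$tract_count
  tracts <- new_intervals()
  if (n > 0L) {
    placed <- 0L; tries <- 0L
    rows <- vector("list", n)
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 1000L * n) stop("sizing error: unable to place non-overlapping tracts")
      len <- as.integer(round(rlnorm(1, config$tract_length_distribution[["meanlog"]],
                                     config$tract_length_distribution[["sdlog"]])))
      len <- max(len, config$tract_min_length %||% 200L)
      cc <- sample(names(lens), 1L, prob = lens / sum(lens))
      if (len >= lens[[cc]]) next
      st <- as.integer(floor(runif(1, 0, lens[[cc]] - len)))
      ok <- TRUE
      if (placed > 0L) {
        prev <- rbindlist(rows[seq_len(placed)])
        same <- prev[chrom == cc]
        # tracts kept >= 1 kb apart so truth labels are unambiguous
        if (nrow(same) && any(st < same$end + 1000L & st + len > same$start - 1000L)) ok <- FALSE
      }
      if (ok) { placed <- placed + 1L; rows[[placed]] <- data.table(chrom = cc, start = st, end = st + len) }
    }
    tracts <- rbindlist(rows)[order(chrom, start)]
  }
  list(tracts = tracts)
}

sim_genotypes <- function(config, truth) {
  lens <- config$chromosome_lengths
  per_chrom <- vector("list", length(lens))
  a1_all <- list(); a2_all <- list()
  for (ci in seq_along(lens)) {
    cc <- names(lens)[ci]
    L <- lens[[ci]]
    ngap <- rpois(1, config$gaps_per_mb * L / 1e6)
    gaps <- new_intervals()
    if (ngap > 0L) {
      glen <- as.integer(round(25000 * (1 + stats::rexp(ngap, 2))))
      gst <- as.integer(floor(runif(ngap, 0, pmax(1, L - glen))))
      gaps <- merge_intervals(new_intervals(chrom = cc, start = gst,
                                            end = pmin(gst + glen, as.integer(L))))
    }
    snv <- drop_in_intervals(sim_positions(L, config$snv_spacing_mean), gaps)
    inv <- drop_in_intervals(sim_positions(L, config$invariant_spacing_mean), gaps)
    inv <- setdiff(inv, snv)
    pos <- sort(c(snv, inv))
    is_snv <- pos %in% snv
    # tract membership of SNV columns
    tr <- truth$tracts[chrom == cc]
    intro <- rep(FALSE, length(pos))
    if (nrow(tr)) for (k in seq_len(nrow(tr)))
      intro[pos >= tr$start[k] & pos < tr$end[k]] <- TRUE
    a1 <- matrix(1L, 4, length(pos), dimnames = list(TAXA, NULL))
    n_sp <- sum(is_snv & !intro); n_in <- sum(is_snv & intro)
    if (n_sp) a1[, is_snv & !intro] <- sim_quartet_columns(n_sp, config$species_tree_branch_lengths,
                                                           cherry = c("D", "F"))
    if (n_in) a1[, is_snv & intro] <- sim_quartet_columns(n_in, config$introgression_tree_branch_lengths,
                                                          cherry = c("D", "P"))
    ninv <- sum(!is_snv)
    if (ninv) a1[, !is_snv] <- matrix(rep(sample.int(4L, ninv, replace = TRUE), each = 4L), 4L)
    # heterozygotes at SNV columns only
    a2 <- a1
    if (config$heterozygosity_rate > 0 && any(is_snv)) {
      het <- matrix(runif(4 * length(pos)) < config$heterozygosity_rate, 4)
      het[, !is_snv] <- FALSE
      if (any(het)) {
        shift <- sample.int(3L, sum(het), replace = TRUE)
        a2[het] <- ((a1[het] - 1L + shift) %% 4L) + 1L
      }
    }
    indels <- sim_positions(L, config$indel_spacing_mean)
    indels <- drop_in_intervals(indels, gaps)
    idist <- if (length(indels)) {
      iv <- findInterval(pos, indels)
      lo <- ifelse(iv == 0L, Inf, abs(pos - indels[pmax(iv, 1L)]))
      hi <- ifelse(iv >= length(indels), Inf, abs(indels[pmin(iv + 1L, length(indels))] - pos))
      as.integer(pmin(pmin(lo, hi), 10000))
    } else rep(10000L, length(pos))
    per_chrom[[ci]] <- list(cc = cc, chrom = rep(cc, length(pos)), pos = pos,
                            is_snv = is_snv, idist = idist, indels = indels)
    a1_all[[ci]] <- a1; a2_all[[ci]] <- a2
  }
  gt <- list(chrom = unlist(lapply(per_chrom, `[[`, "chrom")),
             pos = unlist(lapply(per_chrom, `[[`, "pos")),
             is_snv = unlist(lapply(per_chrom, `[[`, "is_snv")),
             a1 = do.call(cbind, a1_all), a2 = do.call(cbind, a2_all),
             indel_dist = unlist(lapply(per_chrom, `[[`, "idist")),
             indels = rbindlist(lapply(per_chrom, function(x)
               data.table(chrom = rep(x$cc, length(x$indels)), pos = x$indels))),
             taxa = TAXA, genome = lens)
  class(gt) <- "genotype_table"
  gt
}

sim_depth <- function(config) {
  lens <- config$chromosome_lengths
  out <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    cc <- names(lens)[ci]; L <- lens[[ci]]
    starts <- seq(0L, L - 1L, by = config$depth_window)
    ends <- pmin(starts + config$depth_window, L)
    dt <- data.table(chrom = cc, start = as.integer(starts), end = as.integer(ends))
    for (tx in TAXA) {
      dt[[paste0("depth_", tx)]] <- round(pmax(0, rnorm(length(starts),
                                                        config$depth_model$mean[[tx]],
                                                        config$depth_model$sd[[tx]])), 2)
    }
    out[[ci]] <- dt
  }
  rbindlist(out)
}

add_quality <- function(config, gt, depth) {
  n <- length(gt$pos)
  qm <- config$quality_model
  clamp <- function(x) pmin(pmax(as.integer(round(x)), 0L), 99L)
  gt$GQ <- matrix(clamp(rnorm(4 * n, qm$gq_mean, qm$gq_sd)), 4, dimnames = list(TAXA, NULL))
  gt$RGQ <- matrix(clamp(rnorm(4 * n, qm$rgq_mean, qm$rgq_sd)), 4, dimnames = list(TAXA, NULL))
  # DP drawn around the local window depth of each species
  widx <- config$depth_window
  gt$DP <- matrix(0L, 4, n, dimnames = list(TAXA, NULL))
  dsplit <- split(seq_len(n), gt$chrom)
  for (cc in names(dsplit)) {
    ii <- dsplit[[cc]]
    dep <- depth[chrom == cc]
    wi <- pmin(gt$pos[ii] %/% widx + 1L, nrow(dep))
    for (tx in TAXA)
      gt$DP[tx, ii] <- rpois(length(ii), dep[[paste0("depth_", tx)]][wi])
  }
  gt
}

#' Randomly resolve heterozygous genotypes to pseudo-haploid calls
#'
#' Each heterozygous genotype is replaced by one of its two alleles with
#' probability 1/2; homozygous genotypes are unchanged. Deterministic for a
#' given seed.
#'
#' @param gt a `genotype_table`.
#' @param seed integer seed.
#' @return the `genotype_table` with a `calls` matrix (4 x sites, integer
#'   base codes, NA = missing) added/replaced.
#' @export
resolve_heterozygotes <- function(gt, seed = 1L) {
  stopifnot(inherits(gt, "genotype_table"))
  rng <- range(c(gt$a1, gt$a2), na.rm = TRUE)
  if (rng[1] < 1L || rng[2] > 4L) stop("format error: non-nucleotide allele")
  with_seed(seed, {
    calls <- gt$a1
    het <- !is.na(gt$a1) & !is.na(gt$a2) & gt$a1 != gt$a2
    if (any(het)) {
      take2 <- runif(sum(het)) < 0.5
      calls[het][take2] <- gt$a2[het][take2]
    }
    calls[is.na(gt$a1) | is.na(gt$a2)] <- NA_integer_
    gt$calls <- calls
    gt
  })
}

#' Extract the SNV site alignment from a genotype table
#'
#' Keeps SNV columns where all four taxa have non-missing pseudo-haploid
#' calls; the full genotyped-position set is retained for gap logic.
#'
#' @param gt a `genotype_table` with resolved `calls`.
#' @return object of class `site_alignment`: `chrom`, `pos` (0-based),
#'   `bases` (4 x L character matrix), `genotyped` (data.table of all
#'   genotyped chrom/pos).
#' @export
as_site_alignment <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(gt$calls)) stop("genotype table has no resolved calls; run resolve_heterozygotes()")
  keep <- gt$is_snv & colSums(is.na(gt$calls)) == 0L
  bases <- matrix(BASES[gt$calls[, keep, drop = FALSE]], 4L, dimnames = list(TAXA, NULL))
  structure(list(chrom = gt$chrom[keep], pos = gt$pos[keep], bases = bases,
                 genotyped = data.table(chrom = gt$chrom, pos = gt$pos),
                 genome = gt$genome),
            class = "site_alignment")
}

# Pairwise O-F coding sequence simulation for dN/dS work. Each gene gets a
# random stop-free ancestral CDS; substitutions are proposed per base at
# rate t and accepted with probability 1 (synonymous) or omega
# (nonsynonymous); proposals creating stops are rejected. A small fraction
# of genes receives a planted premature stop to exercise the gene filters.
simulate_gene_sequences <- function(config, annotation, truth) {
  with_seed(derive_seed(config$seed, "gene_seqs"), {
    genes <- annotation$genes
    if (nrow(genes) == 0L) return(list())
    cdslen <- annotation$cds[, .(len = sum(end - start)), by = gene_id]
    gfrac <- assign_gene_introgression(annotation, truth$tracts)
    gd <- config$gene_divergence
    out <- vector("list", nrow(genes))
    names(out) <- genes$gene_id
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]
      len <- cdslen[gene_id == gid]$len
      ncod <- len %/% 3L
      intro <- gfrac$gene_fraction[gfrac$gene_id == gid] > 0.5
      t <- if (isTRUE(intro)) gd$t_introgressed else gd$t_background
      om <- if (isTRUE(intro)) gd$omega_introgressed else gd$omega_background
      anc <- random_cds(ncod)
      seqA <- mutate_cds(anc, t / 2, om)
      seqB <- mutate_cds(anc, t / 2, om)
      if (runif(1) < gd$stop_rate && ncod > 3L) {
        k <- sample(2:(ncod - 1L), 1L)
        seqB[(3 * k - 2):(3 * k)] <- c("T", "A", "A")
      }
      out[[gid]] <- c(O = paste(seqA, collapse = ""), F = paste(seqB, collapse = ""))
    }
    out
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(ncod) {
  if (ncod <= 0L) return(character(0))
  cods <- character(ncod)
  for (i in seq_len(ncod)) {
    repeat {
      cod <- sample(BASES, 3L, replace = TRUE)
      if (!(paste(cod, collapse = "") %in% STOP_CODONS)) break
    }
    cods[i] <- paste(cod, collapse = "")
  }
  unlist(strsplit(cods, ""))
}

mutate_cds <- function(seq, t, omega) {
  n <- length(seq)
  if (n == 0L) return(seq)
  nprop <- rpois(1, t * n)
  if (nprop == 0L) return(seq)
  sites <- sample.int(n, nprop, replace = TRUE)
  for (s in sites) {
    new <- sample(setdiff(BASES, seq[s]), 1L)
    ci <- (s - 1L) %/% 3L
    idx <- (ci * 3L + 1L):(ci * 3L + 3L)
    old_cod <- paste(seq[idx], collapse = "")
    cand <- seq; cand[s] <- new
    new_cod <- paste(cand[idx], collapse = "")
    if (new_cod %in% STOP_CODONS) next
    syn <- GENETIC_CODE_MAP[[old_cod]] == GENETIC_CODE_MAP[[new_cod]]
    if (syn || runif(1) < omega) seq[s] <- new
  }
  seq
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_annotation()], [simulate_quartet()] and per-gene
#' coding-sequence simulation into one object consumed by the rest of the
#' pipeline.
#'
#' @param config a `sim_config`.
#' @return object of class `intro_study` with elements `config`, `genome`,
#'   `annotation`, `genotypes`, `alignment`, `truth`, `depth`, `gene_seqs`,
#'   and `psg_ids`.
#' @export
simulate_study <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  q <- simulate_quartet(config)
  gseq <- simulate_gene_sequences(config, ann, q$truth)
  structure(list(config = config, genome = config$chromosome_lengths,
                 annotation = ann, genotypes = q$genotypes,
                 alignment = q$alignment, truth = q$truth, depth = q$depth,
                 gene_seqs = gseq, psg_ids = ann$genes$gene_id[ann$genes$psg]),
            class = "intro_study")
}

#' @export
print.intro_study <- function(x, ...) {
  cat("Synthetic introgression study\n")
  cat("  genome:", length(x$genome), "chromosome(s),",
      format(sum(x$genome), big.mark = ","), "bases\n")
  cat("  SNV columns:", length(x$alignment$pos),
      " genotyped positions:", nrow(x$alignment$genotyped), "\n")
  cat("  planted tracts:", nrow(x$truth$tracts),
      " genes:", nrow(x$annotation$genes), "\n")
  invisible(x)
}
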