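# Interval-level absolute divergence (d_XY) with invariant-site accounting,
# genotype masking, variant filtering, Nei-Gojobori (1986) pairwise dN/dS,
# and the gene-level coverage/stop-codon filters.

codon_table <- function() {
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  stats::setNames(aa, codons)
}
GENETIC_CODE_MAP <- codon_table()

#' Mask genotypes for divergence estimation
#'
#' Genotypes with GQ < 30, DP < 8, or RGQ < 30 are set to missing; sites are
#' retained (they stay in the d_XY denominator only when both taxa remain
#' called).
#'
#' @param gt a `genotype_table`.
#' @return the masked `genotype_table`.
#' @export
mask_genotypes_for_dxy <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  bad <- gt$GQ < 30L | gt$DP < 8L | gt$RGQ < 30L
  gt$a1[bad] <- NA_integer_
  gt$a2[bad] <- NA_integer_
  if (!is.null(gt$calls)) gt$calls[bad] <- NA_integer_
  gt
}

#' Variant-site quality filtering
#'
#' Masks variant-site genotypes with GQ < 20 or DP < 3, and drops SNV sites
#' within 3 bp (inclusive) of an indel. Invariant sites are untouched.
#'
#' @param gt a `genotype_table`.
#' @param indel_max_dist drop SNVs at distance <= this from an indel.
#' @return the filtered `genotype_table` (offending SNV rows removed).
#' @export
filter_variants <- function(gt, indel_max_dist = 3L) {
  stopifnot(inherits(gt, "genotype_table"))
  bad <- (gt$GQ < 20L | gt$DP < 3L) & rep(gt$is_snv, each = 4L)
  gt$a1[bad] <- NA_integer_
  gt$a2[bad] <- NA_integer_
  if (!is.null(gt$calls)) gt$calls[bad] <- NA_integer_
  keep <- !(gt$is_snv & gt$indel_dist <= indel_max_dist)
  subset_genotypes(gt, keep)
}

subset_genotypes <- function(gt, keep) {
  for (f in c("chrom", "pos", "is_snv", "indel_dist")) gt[[f]] <- gt[[f]][keep]
  for (f in c("a1", "a2", "GQ", "DP", "RGQ", "calls"))
    if (!is.null(gt[[f]])) gt[[f]] <- gt[[f]][, keep, drop = FALSE]
  gt
}

#' Absolute nucleotide divergence over an interval
#'
#' d_XY between two pseudo-haploid taxa: the fraction of sites where both
#' are called and differ, over all sites where both are called (invariant
#' genotyped sites included in the denominator).
#'
#' @param gt a `genotype_table` with resolved `calls`.
#' @param chrom,start,end half-open 0-based interval.
#' @param taxa length-2 character, taxa to compare (default O vs F).
#' @return list: `dxy` (NA when no comparable site), `n_diff`, `n_sites`.
#' @export
dxy <- function(gt, chrom, start, end, taxa = c("O", "F")) {
  stopifnot(inherits(gt, "genotype_table"), length(taxa) == 2L)
  if (end <= start) stop("domain error: empty interval")
  if (is.null(gt$calls)) stop("genotype table has no resolved calls")
  idx <- which(gt$chrom == chrom & gt$pos >= start & gt$pos < end)
  a <- gt$calls[taxa[1], idx]
  b <- gt$calls[taxa[2], idx]
  both <- !is.na(a) & !is.na(b)
  n <- sum(both)
  nd <- sum(a[both] != b[both])
  list(dxy = if (n > 0) nd / n else NA_real_, n_diff = nd, n_sites = n)
}

#' d_XY for a set of intervals
#' @param gt a `genotype_table` with resolved calls.
#' @param intervals data.table chrom/start/end.
#' @inheritParams dxy
#' @return numeric vector of per-interval d_XY (NA where undefined).
#' @export
dxy_intervals <- function(gt, intervals, taxa = c("O", "F")) {
  vapply(seq_len(nrow(intervals)), function(i)
    dxy(gt, intervals$chrom[i], intervals$start[i], intervals$end[i], taxa)$dxy,
    numeric(1))
}

# ---- Nei-Gojobori 1986 ---------------------------------------------------

codon_split <- function(x) {
  if (length(x) == 1L) x <- strsplit(toupper(x), "")[[1]]
  if (length(x) %% 3L != 0L) stop("aligned length not divisible by 3")
  apply(matrix(x, nrow = 3L), 2L, paste, collapse = "")
}

# synonymous site count of one codon: per position, the fraction of the
# three single-base changes that preserve the amino acid (changes creating
# stop codons count as nonsynonymous)
ng86_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_MAP[[codon]]
  s <- 0
  for (p in 1:3) for (nb in setdiff(BASES, substr(codon, p, p))) {
    alt <- codon
    substr(alt, p, p) <- nb
    if (GENETIC_CODE_MAP[[alt]] != "*" && GENETIC_CODE_MAP[[alt]] == aa) s <- s + 1 / 3
  }
  s
}

# average syn/nonsyn differences between two codons over all minimal
# mutational pathways; pathways passing through stop codons are excluded
# (all pathways are used if every one hits a stop)
ng86_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else if (k == 2L) list(pos, rev(pos)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) pos[o])
  path_counts <- function(order, allow_stop) {
    cur <- ca; sdd <- 0; ndd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (!allow_stop && GENETIC_CODE_MAP[[nxt]] == "*") return(NULL)
      if (GENETIC_CODE_MAP[[cur]] == GENETIC_CODE_MAP[[nxt]]) sdd <- sdd + 1 else ndd <- ndd + 1
      cur <- nxt
    }
    c(sd = sdd, nd = ndd)
  }
  res <- Filter(Negate(is.null), lapply(perms, path_counts, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, path_counts, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Synonymous and nonsynonymous site counts are averaged over both
#' sequences; differences are partitioned by averaging over all minimal
#' mutational pathways between differing codons; proportions are corrected
#' with the Jukes-Cantor formula d = -(3/4) ln(1 - 4p/3). Codons containing
#' non-ACGT characters in either sequence are removed before counting. A
#' trailing stop codon is trimmed; any other in-frame stop is an error.
#'
#' @param seq_a,seq_b aligned coding sequences (strings or character
#'   vectors), equal length divisible by 3.
#' @return object of class `rate_estimate`: `dN`, `dS`, `omega`,
#'   site/difference counts, `n_codons`, and flags `omega_undefined`,
#'   `saturated`.
#' @export
ng86_dnds <- function(seq_a, seq_b) {
  ca <- codon_split(seq_a)
  cb <- codon_split(seq_b)
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  n0 <- length(ca)
  if (n0 > 0L && (GENETIC_CODE_MAP[ca[n0]] == "*" || GENETIC_CODE_MAP[cb[n0]] == "*")) {
    ca <- ca[-n0]; cb <- cb[-n0]
  }
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (any(GENETIC_CODE_MAP[ca] == "*") || any(GENETIC_CODE_MAP[cb] == "*"))
    stop("gene-filter error: stop codon in frame")
  S <- (sum(vapply(ca, ng86_syn_sites, numeric(1))) +
        sum(vapply(cb, ng86_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  dif <- c(sd = 0, nd = 0)
  for (i in seq_along(ca)) if (ca[i] != cb[i]) dif <- dif + ng86_diffs(ca[i], cb[i])
  pS <- if (S > 0) dif[["sd"]] / S else 0
  pN <- if (N > 0) dif[["nd"]] / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  saturated <- is.na(dS) || is.na(dN)
  omega_undefined <- !saturated && dS == 0
  structure(list(dN = dN, dS = dS,
                 omega = if (!saturated && dS > 0) dN / dS else NA_real_,
                 N = N, S = S, Nd = dif[["nd"]], Sd = dif[["sd"]],
                 n_codons = length(ca),
                 omega_undefined = omega_undefined, saturated = saturated),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("NG86: dN = %.4g  dS = %.4g  dN/dS = %s  (%d codons)\n",
              x$dN, x$dS, if (is.na(x$omega)) "undefined" else sprintf("%.4g", x$omega),
              x$n_codons))
  invisible(x)
}

# ---- gene-level filters and introgression assignment --------------------

#' Coverage and stop-codon filters for rate-of-evolution genes
#'
#' A gene passes iff, for every species, its mean depth lies in the
#' inclusive interval `[min_depth, max_depth]`, at least 75% of its coding
#' bases are covered by >= 1 read and at least 50% by >= 10 reads, and
#' neither coding sequence contains a premature stop codon.
#'
#' @param annotation a `genome_annotation`.
#' @param depth depth windows (chrom/start/end/depth_<taxon>).
#' @param gene_seqs named list of per-gene coding sequence pairs (as from
#'   the generator); genes absent from the list skip the stop-codon check.
#' @param gene_ids genes to evaluate (default all).
#' @param min_depth,max_depth,min_breadth1,min_breadth10 filter parameters.
#' @return data.table: gene_id, pass, reasons (comma-joined machine codes
#'   among depth_low, depth_high, breadth1, breadth10, stop_codon).
#' @export
gene_filters <- function(annotation, depth, gene_seqs = list(),
                         gene_ids = NULL, min_depth = 10, max_depth = 100,
                         min_breadth1 = 0.75, min_breadth10 = 0.5) {
  genes <- annotation$genes
  if (!is.null(gene_ids)) genes <- genes[gene_id %in% gene_ids]
  dcols <- grep("^depth_", names(depth), value = TRUE)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    reasons <- character(0)
    span <- genes[i]
    d <- depth[chrom == span$chrom & end > span$start & start < span$end]
    w <- pmin(d$end, span$end) - pmax(d$start, span$start)
    for (cl in dcols) {
      m <- sum(w * d[[cl]]) / sum(w)
      if (m < min_depth) reasons <- union(reasons, "depth_low")
      if (m > max_depth) reasons <- union(reasons, "depth_high")
    }
    cds <- annotation$cds[gene_id == gid]
    cds_len <- sum(cds$end - cds$start)
    for (cl in dcols) {
      c1 <- 0; c10 <- 0
      for (k in seq_len(nrow(cds))) {
        dk <- depth[chrom == cds$chrom[k] & end > cds$start[k] & start < cds$end[k]]
        wk <- pmin(dk$end, cds$end[k]) - pmax(dk$start, cds$start[k])
        c1 <- c1 + sum(wk[dk[[cl]] >= 1])
        c10 <- c10 + sum(wk[dk[[cl]] >= 10])
      }
      if (c1 / cds_len < min_breadth1) reasons <- union(reasons, "breadth1")
      if (c10 / cds_len < min_breadth10) reasons <- union(reasons, "breadth10")
    }
    if (!is.null(gene_seqs[[gid]])) {
      for (sq in gene_seqs[[gid]]) {
        cod <- codon_split(sq)
        if (length(cod) > 1L && any(GENETIC_CODE_MAP[head(cod, -1L)] == "*", na.rm = TRUE))
          reasons <- union(reasons, "stop_codon")
      }
    }
    out[[i]] <- data.table(gene_id = gid, pass = length(reasons) == 0L,
                           reasons = paste(reasons, collapse = ","))
  }
  rbindlist(out)
}

#' Per-gene introgressed base fractions
#'
#' @param annotation a `genome_annotation`.
#' @param tracts tract intervals (chrom/start/end).
#' @return data.table: gene_id, gene_fraction, cds_fraction, introgressed
#'   (strictly more than half of gene bases in tracts).
#' @export
assign_gene_introgression <- function(annotation, tracts) {
  genes <- annotation$genes
  if (nrow(genes) == 0L)
    return(data.table(gene_id = character(), gene_fraction = numeric(),
                      cds_fraction = numeric(), introgressed = logical()))
  tr <- as.data.table(tracts)[, .(chrom, start, end)]
  gf <- overlap_bases(genes, tr) / (genes$end - genes$start)
  cds <- annotation$cds
  cdso <- overlap_bases(cds, tr)
  cf <- data.table(gene_id = cds$gene_id, ov = cdso,
                   len = cds$end - cds$start)[, .(cds_fraction = sum(ov) / sum(len)),
                                              by = gene_id]
  out <- data.table(gene_id = genes$gene_id, gene_fraction = gf)
  out <- merge(out, cf, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[is.na(cds_fraction), cds_fraction := 0]
  out[, introgressed := gene_fraction > 0.5]
  out[]
}
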