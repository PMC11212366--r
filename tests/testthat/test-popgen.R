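# d_XY, genotype masks, variant filters, NG86 dN/dS, gene filters.

toy_gt <- function(calls, chrom = "chr1", pos = seq_len(ncol(calls)) - 1L,
                   is_snv = rep(TRUE, ncol(calls))) {
  n <- ncol(calls)
  structure(list(chrom = rep(chrom, n), pos = as.integer(pos), is_snv = is_snv,
                 a1 = calls, a2 = calls,
                 GQ = matrix(99L, 4, n), DP = matrix(50L, 4, n),
                 RGQ = matrix(99L, 4, n), indel_dist = rep(10000L, n),
                 indels = data.table::data.table(chrom = character(), pos = integer()),
                 taxa = c("O", "P", "D", "F"), genome = c(chr1 = 1000),
                 calls = calls),
            class = "genotype_table")
}

code_mat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) match(strsplit(r, "")[[1]], BASES4)))
  rownames(m) <- c("O", "P", "D", "F")
  m
}

test_that("dxy implements the both-called rule", {
  gt <- toy_gt(code_mat("AAAA", "AAAA", "AAAA", "AAAT"))
  expect_equal(dxy(gt, "chr1", 0, 4, c("O", "F"))$dxy, 0.25)
  expect_equal(dxy(gt, "chr1", 0, 4, c("O", "P"))$dxy, 0)
  m <- code_mat("ACAG", "ACTG", "ACTG", "ACTG")
  m["O", 3] <- NA  # O = AC?G vs F = ACTG
  gt2 <- toy_gt(m)
  r <- dxy(gt2, "chr1", 0, 4, c("O", "F"))
  expect_equal(r$n_sites, 3L)
  expect_equal(r$dxy, 0)
  expect_error(dxy(gt, "chr1", 5, 5), "empty interval")
})

test_that("dxy is symmetric and unaffected by fully-missing sites", {
  set.seed(11)
  st <- small_study()
  gt <- st$genotypes
  iv <- c(0, 50000)
  a <- dxy(gt, "chr1", iv[1], iv[2], c("O", "F"))$dxy
  b <- dxy(gt, "chr1", iv[1], iv[2], c("F", "O"))$dxy
  expect_equal(a, b)
  # append fully-missing sites inside the interval
  gt2 <- gt
  n_add <- 5L
  add_na <- matrix(NA_integer_, 4, n_add)
  for (f in c("a1", "a2", "calls")) gt2[[f]] <- cbind(gt2[[f]], add_na)
  for (f in c("GQ", "DP", "RGQ")) gt2[[f]] <- cbind(gt2[[f]], matrix(0L, 4, n_add))
  gt2$chrom <- c(gt2$chrom, rep("chr1", n_add))
  gt2$pos <- c(gt2$pos, seq.int(iv[1] + 1L, by = 7L, length.out = n_add))
  gt2$is_snv <- c(gt2$is_snv, rep(TRUE, n_add))
  gt2$indel_dist <- c(gt2$indel_dist, rep(10000L, n_add))
  expect_equal(dxy(gt2, "chr1", iv[1], iv[2], c("O", "F"))$dxy, a)
})

test_that("interval dxy matches the naive site-loop oracle", {
  st <- small_study()
  gt <- mask_genotypes_for_dxy(st$genotypes)
  set.seed(21)
  for (i in 1:5) {
    s <- sample.int(15e4, 1); e <- s + sample.int(30000, 1)
    expect_equal(dxy(gt, "chr2", s, e)$dxy, oracle_dxy(gt, "chr2", s, e))
  }
})

test_that("dxy masking thresholds are strict (GQ<30 / DP<8 / RGQ<30)", {
  m <- code_mat("AAAA", "AAAA", "AAAA", "AAAA")
  gt <- toy_gt(m)
  gt$GQ[1, 1] <- 29L; gt$DP[2, 2] <- 7L; gt$RGQ[3, 3] <- 29L
  gt$GQ[4, 4] <- 30L; gt$DP[4, 4] <- 8L; gt$RGQ[4, 4] <- 30L  # boundary: kept
  out <- mask_genotypes_for_dxy(gt)
  expect_true(is.na(out$calls[1, 1]))
  expect_true(is.na(out$calls[2, 2]))
  expect_true(is.na(out$calls[3, 3]))
  expect_false(is.na(out$calls[4, 4]))
  # count of masked genotypes equals a naive scan
  st <- small_study()
  gm <- mask_genotypes_for_dxy(st$genotypes)
  naive <- st$genotypes$GQ < 30L | st$genotypes$DP < 8L | st$genotypes$RGQ < 30L
  expect_equal(sum(is.na(gm$a1)) - sum(is.na(st$genotypes$a1)),
               sum(naive & !is.na(st$genotypes$a1)))
})

test_that("variant filters mask GQ<20/DP<3 and drop SNVs within 3 bp of indels", {
  m <- code_mat("AAAAA", "AAAAA", "AAAAA", "TTTTT")
  gt <- toy_gt(m, pos = c(0L, 10L, 20L, 30L, 40L))
  gt$indel_dist <- c(3L, 4L, 10000L, 2L, 10000L)  # inclusive: <=3 dropped
  out <- filter_variants(gt)
  expect_equal(out$pos, c(10L, 20L, 40L))
  gt2 <- toy_gt(m, pos = c(0L, 10L, 20L, 30L, 40L))
  gt2$GQ[1, 1] <- 19L; gt2$DP[2, 2] <- 2L
  gt2$GQ[3, 3] <- 20L; gt2$DP[3, 3] <- 3L  # boundary kept
  out2 <- filter_variants(gt2)
  expect_true(is.na(out2$calls[1, 1]))
  expect_true(is.na(out2$calls[2, 2]))
  expect_false(is.na(out2$calls[3, 3]))
  # invariant sites are untouched by the variant-site filter
  gt3 <- toy_gt(m, is_snv = rep(FALSE, 5))
  gt3$GQ[, ] <- 5L
  expect_false(any(is.na(filter_variants(gt3)$calls)))
  # surviving-site count equals a brute-force distance scan
  st <- small_study()
  fv <- filter_variants(st$genotypes)
  keep_naive <- !(st$genotypes$is_snv & st$genotypes$indel_dist <= 3L)
  expect_equal(length(fv$pos), sum(keep_naive))
})

test_that("NG86 handles degenerate pairs analytically", {
  r <- ng86_dnds("ATGGCT", "ATGGCT")
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(r$omega_undefined)
  expect_true(is.na(r$omega))
  # third-position four-fold degenerate changes are purely synonymous
  r2 <- ng86_dnds("GGAGCAGTA", "GGTGCAGTA")
  expect_equal(r2$dN, 0)
  expect_gt(r2$dS, 0)
  # premature stop is an error
  expect_error(ng86_dnds("ATGTAAGCT", "ATGGCTGCT"), "stop codon")
  # trailing stop is trimmed
  expect_equal(ng86_dnds("ATGTAA", "ATGTAA")$n_codons, 1L)
  # ambiguity codons are removed before counting
  expect_equal(ng86_dnds("ATGNNNGCT", "ATGAAAGCT")$n_codons, 2L)
})

test_that("NG86 site counts satisfy N + S = 3 x codons", {
  set.seed(61)
  for (i in 1:10) {
    ncod <- 15L
    a <- paste(introscape:::random_cds(ncod), collapse = "")
    b <- paste(introscape:::random_cds(ncod), collapse = "")
    r <- tryCatch(ng86_dnds(a, b), error = function(e) NULL)
    if (is.null(r)) next
    expect_lt(abs(r$N + r$S - 3 * r$n_codons), 1e-9)
  }
})

test_that("NG86 matches the pathway-enumeration oracle on random 20-codon pairs", {
  set.seed(71)
  tested <- 0L
  while (tested < 8L) {
    anc <- introscape:::random_cds(20L)
    a <- paste(introscape:::mutate_cds(anc, 0.05, 0.5), collapse = "")
    b <- paste(introscape:::mutate_cds(anc, 0.05, 0.5), collapse = "")
    r <- tryCatch(ng86_dnds(a, b), error = function(e) NULL)
    if (is.null(r)) next
    o <- oracle_ng86(a, b)
    expect_lt(abs(r$S - o$S), 1e-10)
    expect_lt(abs(r$Nd - o$Nd), 1e-10)
    expect_lt(abs(r$Sd - o$Sd), 1e-10)
    if (!is.na(r$dN) && !is.na(o$dN)) expect_lt(abs(r$dN - o$dN), 1e-10)
    if (!is.na(r$dS) && !is.na(o$dS)) expect_lt(abs(r$dS - o$dS), 1e-10)
    tested <- tested + 1L
  }
})

test_that("gene filters evaluate all four criteria with strict boundaries", {
  genome <- c(chr1 = 100000)
  ann <- list(genes = data.table::data.table(chrom = "chr1", start = 10000L,
                                             end = 20000L, gene_id = "g1",
                                             family = NA_character_, psg = FALSE),
              cds = data.table::data.table(chrom = "chr1", start = 10000L,
                                           end = 16000L, gene_id = "g1"),
              genome = genome)
  class(ann) <- "genome_annotation"
  d <- flat_depth(genome, value = 9.9, window = 1000L)
  f <- gene_filters(ann, d)
  expect_false(f$pass)
  expect_match(f$reasons, "depth_low")
  d2 <- flat_depth(genome, value = 10, window = 1000L)   # boundary passes
  expect_true(gene_filters(ann, d2)$pass)
  # breadth-1: exactly 75% of CDS at >= 1 read passes, 66.7% fails
  d3 <- flat_depth(genome, value = 50, window = 500L)
  d3[start >= 14500 & start < 16000, depth_P := 0]   # 1500 of 6000 CDS bases
  f3 <- gene_filters(ann, d3)
  expect_true(f3$pass)
  d4 <- flat_depth(genome, value = 50, window = 500L)
  d4[start >= 14000 & start < 16000, depth_P := 0]   # 2000 of 6000
  f4 <- gene_filters(ann, d4)
  expect_false(f4$pass)
  expect_match(f4$reasons, "breadth1")
  # breadth-10: half the CDS below 10 reads passes, more fails
  d5 <- flat_depth(genome, value = 50, window = 1000L)
  d5[start >= 13000 & start < 16000, depth_D := 5]
  expect_true(gene_filters(ann, d5)$pass)
  d6 <- flat_depth(genome, value = 50, window = 1000L)
  d6[start >= 12000 & start < 16000, depth_D := 5]
  f6 <- gene_filters(ann, d6)
  expect_false(f6$pass)
  expect_match(f6$reasons, "breadth10")
  # stop codon
  seqs <- list(g1 = c(O = "ATGTAAGCTAAA", F = "ATGAAAGCTAAA"))
  f7 <- gene_filters(ann, d2, seqs)
  expect_false(f7$pass)
  expect_match(f7$reasons, "stop_codon")
})

test_that("gene filter decisions match a naive per-base recomputation", {
  st <- small_study()
  ann <- st$annotation
  f <- gene_filters(ann, st$depth, st$gene_seqs)
  dcols <- grep("^depth_", names(st$depth), value = TRUE)
  for (i in sample.int(nrow(ann$genes), 12)) {
    g <- ann$genes[i]
    base_depth <- sapply(dcols, function(cl) {
      v <- numeric(g$end - g$start)
      d <- st$depth[chrom == g$chrom]
      for (k in seq_len(nrow(d))) {
        lo <- max(d$start[k], g$start); hi <- min(d$end[k], g$end)
        if (hi > lo) v[(lo - g$start + 1):(hi - g$start)] <- d[[cl]][k]
      }
      v
    })
    cds <- ann$cds[gene_id == g$gene_id]
    cds_mask <- logical(g$end - g$start)
    for (k in seq_len(nrow(cds)))
      cds_mask[(cds$start[k] - g$start + 1):(cds$end[k] - g$start)] <- TRUE
    fail <- any(colMeans(base_depth) < 10) || any(colMeans(base_depth) > 100)
    for (cl in dcols) {
      cv <- base_depth[cds_mask, cl]
      if (mean(cv >= 1) < 0.75 || mean(cv >= 10) < 0.5) fail <- TRUE
    }
    sq <- st$gene_seqs[[g$gene_id]]
    has_stop <- any(sapply(sq, function(s) {
      cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      any(head(cod, -1) %in% c("TAA", "TAG", "TGA"))
    }))
    expect_equal(f$pass[f$gene_id == g$gene_id], !(fail || has_stop),
                 label = g$gene_id)
  }
})

test_that("gene introgression fractions match the per-base oracle", {
  st <- small_study()
  tracts <- st$truth$tracts
  gi <- assign_gene_introgression(st$annotation, tracts)
  for (i in sample.int(nrow(st$annotation$genes), 10)) {
    g <- st$annotation$genes[i]
    mask <- oracle_base_mask(as.data.frame(tracts), g$chrom, st$genome[[g$chrom]])
    frac <- mean(mask[(g$start + 1):g$end])
    expect_equal(gi$gene_fraction[gi$gene_id == g$gene_id], frac, tolerance = 1e-12)
  }
  # exactly half covered is NOT introgressed (strict >)
  ann <- list(genes = data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                                             gene_id = "g", family = NA_character_,
                                             psg = FALSE),
              cds = data.table::data.table(chrom = "chr1", start = 0L, end = 300L,
                                           gene_id = "g"),
              genome = c(chr1 = 10000))
  class(ann) <- "genome_annotation"
  half <- data.table::data.table(chrom = "chr1", start = 0L, end = 500L)
  gi2 <- assign_gene_introgression(ann, half)
  expect_equal(gi2$gene_fraction, 0.5)
  expect_false(gi2$introgressed)
  full <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(assign_gene_introgression(ann, full)$gene_fraction, 1.0)
})
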