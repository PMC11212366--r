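# File formats. Internal coordinates are 0-based half-open (BED); VCF and
# GFF3 are written/read 1-based. Strand is ignored throughout: every
# statistic in the pipeline is strand-agnostic.

# ---- FASTA / PHYLIP alignments ------------------------------------------

#' Write / read the SNV alignment with its position table
#'
#' The alignment is stored as sequential PHYLIP (taxa x SNV columns,
#' concatenated over chromosomes) alongside a two-column TSV mapping each
#' column to its genomic position; FASTA output is also supported.
#'
#' @param alignment a `site_alignment`.
#' @param path alignment file path; the position table goes to
#'   `<path>.pos.tsv`.
#' @param format `"phylip"` or `"fasta"`.
#' @export
write_alignment <- function(alignment, path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  m <- tolower(alignment$bases)
  rownames(m) <- TAXA
  bin <- ape::as.DNAbin(m)
  if (format == "phylip") ape::write.dna(bin, path, format = "sequential", colsep = "")
  else ape::write.FASTA(bin, path)
  pos <- data.table(chrom = alignment$chrom, pos = alignment$pos)
  fwrite(pos, paste0(path, ".pos.tsv"), sep = "\t")
  gen <- data.table(chrom = names(alignment$genome %||% character()),
                    length = as.integer(alignment$genome %||% integer()))
  fwrite(alignment$genotyped, paste0(path, ".genotyped.tsv"), sep = "\t")
  fwrite(gen, paste0(path, ".genome.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_alignment
#' @param path alignment file written by [write_alignment()].
#' @return a `site_alignment`.
#' @export
read_alignment <- function(path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  bin <- if (format == "phylip") ape::read.dna(path, format = "sequential")
         else ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(bin)))
  pos <- fread(paste0(path, ".pos.tsv"))
  gtp <- fread(paste0(path, ".genotyped.tsv"))
  gen <- fread(paste0(path, ".genome.tsv"))
  structure(list(chrom = as.character(pos$chrom), pos = as.integer(pos$pos),
                 bases = m[TAXA, , drop = FALSE],
                 genotyped = gtp[, .(chrom = as.character(chrom), pos = as.integer(pos))],
                 genome = stats::setNames(as.numeric(gen$length), gen$chrom)),
            class = "site_alignment")
}

# ---- VCF -----------------------------------------------------------------

#' Write a genotype table as a multi-sample VCF (invariant sites included)
#'
#' Emits GT:GQ:DP:RGQ FORMAT fields and an `IDIST` INFO key (distance to
#' the nearest indel) so the filtering rules survive a round trip. VCF
#' positions are 1-based.
#'
#' @param gt a `genotype_table`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(gt$genome),
                       as.integer(gt$genome)),
               "##INFO=<ID=IDIST,Number=1,Type=Integer,Description=\"Distance to nearest indel\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=RGQ,Number=1,Type=Integer,Description=\"Reference genotype quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", TAXA), collapse = "\t")), con)
  n <- length(gt$pos)
  if (n == 0L) return(invisible(path))
  lines <- character(n)
  for (i in seq_len(n)) {
    al <- c(gt$a1[, i], gt$a2[, i])
    ref <- al[!is.na(al)][1]
    alt <- setdiff(unique(al[!is.na(al)]), ref)
    allele_idx <- function(x) ifelse(is.na(x), ".", match(x, c(ref, alt)) - 1L)
    gtf <- paste0(allele_idx(gt$a1[, i]), "/", allele_idx(gt$a2[, i]))
    fm <- paste(gtf, gt$GQ[, i], gt$DP[, i], gt$RGQ[, i], sep = ":")
    lines[i] <- paste(c(gt$chrom[i], gt$pos[i] + 1L, ".", BASES[ref],
                        if (length(alt)) paste(BASES[alt], collapse = ",") else ".",
                        ".", "PASS", paste0("IDIST=", gt$indel_dist[i]), "GT:GQ:DP:RGQ", fm),
                      collapse = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a multi-sample VCF written by [write_vcf()]
#' @param path VCF path.
#' @return a `genotype_table` (without resolved calls).
#' @export
read_vcf <- function(path) {
  raw <- readLines(path)
  hdr <- grep("^##", raw)
  contig <- grep("^##contig", raw, value = TRUE)
  genome <- stats::setNames(as.numeric(sub(".*length=(\\d+).*", "\\1", contig)),
                            sub(".*ID=([^,>]+).*", "\\1", contig))
  cols <- strsplit(sub("^#", "", raw[length(hdr) + 1L]), "\t")[[1]]
  body <- raw[-seq_len(length(hdr) + 1L)]
  if (!length(body)) stop("parse error: VCF has no records")
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != length(cols)))
    stop("parse error at line ", length(hdr) + 1L + which(nf != length(cols))[1])
  m <- matrix(unlist(f), ncol = length(cols), byrow = TRUE)
  n <- nrow(m)
  chrom <- m[, 1]; pos <- as.integer(m[, 2]) - 1L
  ref <- m[, 4]; alt <- m[, 5]
  idist <- as.integer(sub("^IDIST=", "", m[, 8]))
  a1 <- a2 <- GQ <- DP <- RGQ <- matrix(NA_integer_, 4, n, dimnames = list(TAXA, NULL))
  alleles <- lapply(seq_len(n), function(i) {
    c(ref[i], if (alt[i] != ".") strsplit(alt[i], ",")[[1]])
  })
  for (ti in seq_along(TAXA)) {
    sm <- m[, 9L + ti]
    parts <- matrix(unlist(strsplit(sm, ":", fixed = TRUE)), ncol = 4L, byrow = TRUE)
    gtp <- strsplit(parts[, 1], "/", fixed = TRUE)
    for (i in seq_len(n)) {
      g <- gtp[[i]]
      codes <- match(alleles[[i]], BASES)
      a1[ti, i] <- if (g[1] == ".") NA_integer_ else codes[as.integer(g[1]) + 1L]
      a2[ti, i] <- if (g[2] == ".") NA_integer_ else codes[as.integer(g[2]) + 1L]
    }
    GQ[ti, ] <- as.integer(parts[, 2]); DP[ti, ] <- as.integer(parts[, 3])
    RGQ[ti, ] <- as.integer(parts[, 4])
  }
  gt <- list(chrom = chrom, pos = pos, is_snv = alt != ".",
             a1 = a1, a2 = a2, GQ = GQ, DP = DP, RGQ = RGQ,
             indel_dist = idist,
             indels = data.table(chrom = character(), pos = integer()),
             taxa = TAXA, genome = genome)
  class(gt) <- "genotype_table"
  gt
}

# ---- BED / GFF3 / depth --------------------------------------------------

#' Write intervals as BED3/BED6
#'
#' @param x interval data.table; if a `mean_posterior` column is present a
#'   BED6 is written with score = round(mean_posterior * 1000).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  x <- as.data.table(x)
  if ("mean_posterior" %in% names(x)) {
    out <- x[, .(chrom, start, end,
                 name = sprintf("tract%04d", .I),
                 score = as.integer(round(mean_posterior * 1000)),
                 strand = ".")]
  } else out <- x[, .(chrom, start, end)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#' @param path BED path.
#' @return interval data.table (plus score as mean_posterior for BED6).
#' @export
read_bed <- function(path) {
  x <- fread(path, header = FALSE)
  if (nrow(x) == 0L) return(new_intervals())
  out <- data.table(chrom = as.character(x$V1), start = as.integer(x$V2),
                    end = as.integer(x$V3))
  if (ncol(x) >= 5L) out[, mean_posterior := as.numeric(x$V5) / 1000]
  out
}

#' Write / read gene models as GFF3
#'
#' Gene rows carry `ID`, optional `family`, and `psg` attributes; CDS rows
#' point at their gene via `Parent`. GFF3 is 1-based inclusive.
#'
#' @param annotation a `genome_annotation`.
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", names(annotation$genome),
                     as.integer(annotation$genome)), con)
  g <- annotation$genes
  if (nrow(g)) {
    attrs <- sprintf("ID=%s;psg=%s%s", g$gene_id, ifelse(g$psg, "1", "0"),
                     ifelse(is.na(g$family), "", paste0(";family=", g$family)))
    writeLines(sprintf("%s\tintroscape\tgene\t%d\t%d\t.\t+\t.\t%s",
                       g$chrom, g$start + 1L, g$end, attrs), con)
    cds <- annotation$cds
    writeLines(sprintf("%s\tintroscape\tCDS\t%d\t%d\t.\t+\t0\tParent=%s",
                       cds$chrom, cds$start + 1L, cds$end, cds$gene_id), con)
  }
  invisible(path)
}

#' @rdname write_gff3
#' @return a `genome_annotation`.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  sr <- grep("^##sequence-region", raw, value = TRUE)
  parts <- strsplit(sr, " +")
  genome <- stats::setNames(vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
                            vapply(parts, function(p) p[2], character(1)))
  body_idx <- which(!startsWith(raw, "#") & nzchar(raw))
  body <- raw[body_idx]
  if (!length(body)) {
    ann <- list(genes = new_intervals(gene_id = character(), family = character(),
                                      psg = logical()),
                cds = new_intervals(gene_id = character()), genome = genome)
    class(ann) <- "genome_annotation"
    return(ann)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stop("parse error at GFF3 line ", body_idx[bad[1]])
  m <- matrix(unlist(f), ncol = 9L, byrow = TRUE)
  attr_get <- function(a, key) {
    pat <- paste0("(^|;)", key, "=[^;]*")
    found <- grepl(pat, a)
    out <- rep(NA_character_, length(a))
    out[found] <- sub(paste0(".*", key, "="),
                      "", regmatches(a, regexpr(pat, a)))
    out
  }
  is_gene <- m[, 3] == "gene"
  ga <- m[is_gene, 9]
  genes <- data.table(chrom = m[is_gene, 1],
                      start = as.integer(m[is_gene, 4]) - 1L,
                      end = as.integer(m[is_gene, 5]),
                      gene_id = attr_get(ga, "ID"),
                      family = attr_get(ga, "family"),
                      psg = attr_get(ga, "psg") == "1")
  is_cds <- m[, 3] == "CDS"
  cds <- data.table(chrom = m[is_cds, 1],
                    start = as.integer(m[is_cds, 4]) - 1L,
                    end = as.integer(m[is_cds, 5]),
                    gene_id = attr_get(m[is_cds, 9], "Parent"))
  ann <- list(genes = genes[order(chrom, start)], cds = cds[order(chrom, start)],
              genome = genome)
  class(ann) <- "genome_annotation"
  ann
}

#' Write / read depth tracks (bedGraph-like TSV)
#' @param depth data.table chrom/start/end/depth_<taxon>...
#' @param path output path.
#' @export
write_depth <- function(depth, path) {
  fwrite(depth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) fread(path)

#' Write / read a posterior track TSV (chrom, pos, posterior)
#' @param track a `posterior_track`.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  fwrite(as.data.table(track), path, sep = "\t")
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  tr <- fread(path)
  setattr(tr, "class", c("posterior_track", class(tr)))
  tr
}

# ---- run configuration ---------------------------------------------------

#' Default run configuration
#'
#' Replicate counts default to the full-scale study design (100 restarts,
#' 1,000 permutations, 100,000 bootstrap pairs, 10,000 block iterations);
#' scale them down for desk-scale runs.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1L, threshold = 0.9, background_threshold = 0.9,
              min_depth = 5, max_depth = 100, max_gap = 25000L,
              n_restarts = 100L, n_perm = 1000L, n_boot_density = 1000L,
              n_boot_means = 100000L, n_block_iter = 10000L,
              block_size = 10000L, min_tract_bases_10kb = 10000L,
              gene_min_depth = 10, gene_max_depth = 100)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$threshold > 0, cfg$threshold <= 1, cfg$n_restarts >= 1)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as a DCF key: value file
#' @param path file path.
#' @export
read_run_config <- function(path) {
  d <- read.dcf(path)
  vals <- lapply(stats::setNames(as.list(d[1, ]), colnames(d)), function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  write.dcf(data.frame(lapply(unclass(cfg), as.character), check.names = FALSE), path)
  invisible(path)
}

# order-stable hash of a configuration list, embedded in every report
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  u <- utf8ToInt(s)
  sprintf("%08x", sum(u * seq_along(u)) %% 2147483647)
}
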