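# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: likelihoods by explicit enumeration over node
# states, HMM posteriors by summing over all hidden paths, interval
# statistics by per-base vectors.

BASES4 <- c("A", "C", "G", "T")

jc_p <- function(t) {
  e <- exp(-4 * t / 3)
  m <- matrix((1 - e) / 4, 4, 4)
  diag(m) <- (1 + 3 * e) / 4
  m
}

# Likelihood of a column on an arbitrary rooted ape tree by enumeration
# over the states of every internal node and every missing tip.
oracle_site_lik <- function(column, tree) {
  ntip <- length(tree$tip.label)
  if (!is.null(names(column))) column <- column[tree$tip.label]
  code <- match(toupper(column), BASES4)
  nnode <- ntip + tree$Nnode
  free <- c(which(is.na(code)), (ntip + 1L):nnode)  # nodes to enumerate
  fixed <- setdiff(seq_len(ntip), free)
  Pm <- lapply(tree$edge.length, jc_p)
  total <- 0
  grid <- rep(1L, length(free))
  repeat {
    st <- integer(nnode)
    st[fixed] <- code[fixed]
    st[free] <- grid
    p <- 0.25  # root prior
    for (k in seq_len(nrow(tree$edge)))
      p <- p * Pm[[k]][st[tree$edge[k, 1]], st[tree$edge[k, 2]]]
    total <- total + p
    # odometer increment
    i <- 1L
    while (i <= length(free)) {
      grid[i] <- grid[i] + 1L
      if (grid[i] <= 4L) break
      grid[i] <- 1L; i <- i + 1L
    }
    if (i > length(free)) break
    if (length(free) == 0L) break
  }
  total
}

# Exact HMM posteriors / log-likelihood by enumeration over all K^L paths.
oracle_hmm_enum <- function(emis, trans, init) {
  K <- nrow(emis); L <- ncol(emis)
  g <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  p <- init[g[, 1]] * emis[cbind(g[, 1], 1)]
  if (L > 1) for (t in 2:L)
    p <- p * trans[cbind(g[, t - 1], g[, t])] * emis[cbind(g[, t], t)]
  tot <- sum(p)
  post <- matrix(0, K, L)
  for (t in 1:L) for (s in 1:K) post[s, t] <- sum(p[g[, t] == s]) / tot
  list(posterior = post, loglik = log(tot))
}

# Independent NG86: literal recursion over mutation orderings, straight
# re-derivation of codon site fractions from the genetic code.
oracle_codon_aa <- local({
  b <- c("T", "C", "A", "G")
  cods <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  setNames(aa, cods)
})

oracle_ng86 <- function(sa, sb) {
  split_cod <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split_cod(toupper(sa)); cb <- split_cod(toupper(sb))
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[ok]; cb <- cb[ok]
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) {
      cur <- substr(cod, p, p)
      for (nb in setdiff(BASES4, cur)) {
        alt <- cod; substr(alt, p, p) <- nb
        if (oracle_codon_aa[[alt]] != "*" &&
            oracle_codon_aa[[alt]] == oracle_codon_aa[[cod]]) s <- s + 1/3
      }
    }
    s
  }
  # recursive enumeration of pathways between two codons
  paths <- function(cur, target, allow_stop) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dp)) return(list(c(s = 0, n = 0)))
    out <- list()
    for (p in dp) {
      nxt <- cur; substr(nxt, p, p) <- substr(target, p, p)
      if (!allow_stop && oracle_codon_aa[[nxt]] == "*") next
      step <- if (oracle_codon_aa[[cur]] == oracle_codon_aa[[nxt]]) c(s = 1, n = 0) else c(s = 0, n = 1)
      for (rest in paths(nxt, target, allow_stop)) out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  S <- (sum(vapply(ca, syn_sites, numeric(1))) + sum(vapply(cb, syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    pl <- paths(ca[i], cb[i], allow_stop = FALSE)
    if (!length(pl)) pl <- paths(ca[i], cb[i], allow_stop = TRUE)
    avg <- Reduce(`+`, pl) / length(pl)
    Sd <- Sd + avg[["s"]]; Nd <- Nd + avg[["n"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(if (S > 0) Sd / S else 0), dN = jc(if (N > 0) Nd / N else 0))
}

# Per-base interval coverage of a chromosome as a logical vector.
oracle_base_mask <- function(intervals, chrom, len) {
  v <- logical(len)
  iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    lo <- max(iv$start[i], 0) + 1L
    hi <- min(iv$end[i], len)
    if (hi >= lo) v[lo:hi] <- TRUE
  }
  v
}

# Naive per-base overlap of two interval sets (total shared bases).
oracle_overlap_bases <- function(x, y, genome) {
  tot <- 0
  for (cc in names(genome)) {
    mx <- oracle_base_mask(x, cc, genome[[cc]])
    my <- oracle_base_mask(y, cc, genome[[cc]])
    tot <- tot + sum(mx & my)
  }
  tot
}

# Naive d_XY over an interval by looping sites.
oracle_dxy <- function(gt, chrom, start, end, taxa = c("O", "F")) {
  nd <- 0L; n <- 0L
  for (i in seq_along(gt$pos)) {
    if (gt$chrom[i] != chrom || gt$pos[i] < start || gt$pos[i] >= end) next
    a <- gt$calls[taxa[1], i]; b <- gt$calls[taxa[2], i]
    if (is.na(a) || is.na(b)) next
    n <- n + 1L
    if (a != b) nd <- nd + 1L
  }
  if (n == 0) NA_real_ else nd / n
}
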