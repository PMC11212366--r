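# Phylogenetic machinery: JC69 substitution model, Felsenstein pruning on
# arbitrary rooted trees (ape phylo), and a vectorized pattern-likelihood
# kernel for the fixed four-taxon triplet used by the HMM.
#
# Taxa are ordered O, P, D, F throughout:
#   O  outgroup
#   P  first-diverging ingroup lineage (introgression donor/recipient)
#   D  sister to F under the species tree; exchanges alleles with P
#   F  sister to D under the species tree
# Species tree:       (O,(P,(D,F)))
# Introgression tree: (O,(F,(D,P)))

TAXA <- c("O", "P", "D", "F")
BASES <- c("A", "C", "G", "T")

#' Jukes-Cantor transition probability matrix
#'
#' @param t branch length in expected substitutions per site.
#' @return 4x4 matrix of P(child base | parent base, t).
#' @export
jc69_pmat <- function(t) {
  if (t < 0) stop("negative branch length")
  e <- exp(-4 * t / 3)
  m <- matrix((1 - e) / 4, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- (1 + 3 * e) / 4
  m
}

base_code <- function(x) {
  code <- match(toupper(x), BASES)
  code[is.na(code)] <- 5L  # anything not A/C/G/T is treated as missing
  code
}

#' Site likelihood by Felsenstein pruning under JC69
#'
#' Computes the probability of one alignment column on a rooted tree with
#' uniform stationary base frequencies. Missing bases (`NA`, `"N"`, `"-"`)
#' are marginalized over.
#'
#' @param column character vector of bases, named by tip label or given in
#'   `tree$tip.label` order.
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param branch_lengths optional replacement for `tree$edge.length`.
#' @return the site likelihood (a probability).
#' @export
site_likelihood <- function(column, tree, branch_lengths = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!is.null(branch_lengths)) tree$edge.length <- branch_lengths
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ntip <- length(tree$tip.label)
  if (!is.null(names(column))) column <- column[tree$tip.label]
  if (length(column) != ntip) stop("column length must equal number of tips")
  code <- base_code(column)

  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  L <- matrix(1, nnode, 4)
  for (i in seq_len(ntip)) if (code[i] <= 4L) { L[i, ] <- 0; L[i, code[i]] <- 1 }
  # postorder edge ordering: every edge below a child precedes the edge to
  # its parent, so one accumulation sweep completes the conditionals
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; chd <- tree$edge[k, 2]
    P <- jc69_pmat(tree$edge.length[k])
    L[par, ] <- L[par, ] * as.vector(P %*% L[chd, ])
  }
  root <- ntip + 1L
  sum(0.25 * L[root, ])
}

# ---- fixed-quartet pattern machinery ------------------------------------

# Encode alignment columns (codes 1..4 = ACGT, 5 = missing) as pattern ids
# in base 5. `bases` is a 4 x L matrix with rows O, P, D, F.
encode_patterns <- function(bases) {
  stopifnot(nrow(bases) == 4L)
  code <- matrix(base_code(bases), 4L)
  idx <- (code[1, ] - 1L) * 125L + (code[2, ] - 1L) * 25L + (code[3, ] - 1L) * 5L + code[4, ]
  idx
}

all_pattern_codes <- function(ids) {
  # inverse of encode_patterns for a vector of pattern ids
  x <- ids - 1L
  o <- x %/% 125L; x <- x %% 125L
  p <- x %/% 25L;  x <- x %% 25L
  d <- x %/% 5L;   f <- x %% 5L
  cbind(O = o + 1L, P = p + 1L, D = d + 1L, F = f + 1L)
}

# Likelihood of each pattern on the rooted triplet (O,(solo,(c1,c2))) where
# {c1, c2} is the cherry. Terminal branches t_term (length-4, order O,P,D,F
# or scalar), internal branch t_int, stem branch t_stem.
quartet_pattern_liks <- function(pattern_ids, cherry, t_term, t_int, t_stem = 0) {
  codes <- all_pattern_codes(pattern_ids)
  if (length(t_term) == 1L) t_term <- rep(t_term, 4L)
  names(t_term) <- TAXA
  solo <- setdiff(c("P", "D", "F"), cherry)
  tipc <- function(tax) {
    P <- jc69_pmat(t_term[[tax]])
    rbind(t(P), rep(1, 4))[codes[, tax], , drop = FALSE]  # npat x 4
  }
  Ccherry <- tipc(cherry[1]) * tipc(cherry[2])
  Pint <- jc69_pmat(t_int)
  A1 <- (Ccherry %*% t(Pint)) * tipc(solo)
  if (t_stem > 0) A1 <- A1 %*% t(jc69_pmat(t_stem))
  root <- A1 * tipc("O")
  as.vector(rowSums(root) / 4)
}

# ape trees for the six (parent, gene tree) states and for simulation
quartet_tree <- function(cherry, t_term, t_int, t_stem = 0) {
  if (length(t_term) == 1L) t_term <- rep(t_term, 4L)
  names(t_term) <- TAXA
  solo <- setdiff(c("P", "D", "F"), cherry)
  nwk <- sprintf("(O:%.17g,(%s:%.17g,(%s:%.17g,%s:%.17g):%.17g):%.17g);",
                 t_term[["O"]], solo, t_term[[solo]],
                 cherry[1], t_term[[cherry[1]]], cherry[2], t_term[[cherry[2]]],
                 t_int, t_stem)
  ape::read.tree(text = nwk)
}

# ---- column simulation ---------------------------------------------------

jc69_mutate <- function(code, t) {
  n <- length(code)
  e <- exp(-4 * t / 3)
  stay <- runif(n) < (1 + 3 * e) / 4
  out <- code
  jump <- which(!stay)
  if (length(jump)) {
    shift <- sample.int(3L, length(jump), replace = TRUE)
    out[jump] <- ((code[jump] - 1L + shift) %% 4L) + 1L
  }
  out
}

# Simulate n columns down a rooted quartet tree described by named branch
# lengths bl = c(O=,A1=,P=,A2=,D=,F=) with shape (O,(P,(D,F))) after
# relabeling: `order` gives which taxon sits in each structural slot.
# Returns a 4 x n integer matrix (rows O,P,D,F, codes 1..4).
sim_quartet_columns <- function(n, bl, cherry = c("D", "F")) {
  solo <- setdiff(c("P", "D", "F"), cherry)
  root <- sample.int(4L, n, replace = TRUE)
  a1 <- jc69_mutate(root, bl[["A1"]])
  a2 <- jc69_mutate(a1, bl[["A2"]])
  out <- matrix(0L, 4L, n, dimnames = list(TAXA, NULL))
  out["O", ] <- jc69_mutate(root, bl[["O"]])
  out[solo, ] <- jc69_mutate(a1, bl[[solo]])
  out[cherry[1], ] <- jc69_mutate(a2, bl[[cherry[1]]])
  out[cherry[2], ] <- jc69_mutate(a2, bl[[cherry[2]]])
  out
}
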