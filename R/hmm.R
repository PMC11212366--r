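# Two-parent-tree phylogenetic HMM.
#
# Hidden states are (parent tree, gene tree) pairs. Each parent tree
# (species or introgression) hosts the three rooted triplet gene-tree
# topologies, so incomplete lineage sorting is absorbed by within-parent
# gene-tree switching rather than being mistaken for introgression.
# State order used everywhere:
#   1 species/DF  2 species/DP  3 species/PF
#   4 intro/DF    5 intro/DP    6 intro/PF
# The concordant gene tree of each parent (species: DF cherry; introgression:
# DP cherry) carries internal branch t_minor + delta; the two discordant
# (ILS) gene trees carry t_minor. Constraining the concordant internal branch
# to be the longer one removes the label-swap symmetry between parents.

CHERRIES <- list(c("D", "F"), c("D", "P"), c("P", "F"))
STATE_TOPO <- c(1L, 2L, 3L, 1L, 2L, 3L)          # gene-tree topology per state
STATE_PARENT <- c(1L, 1L, 1L, 2L, 2L, 2L)        # 1 species, 2 introgression
STATE_CONCORDANT <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)

#' HMM parameter set
#'
#' @param gamma per-site probability of switching parent tree (spread
#'   uniformly over the other parent's three gene-tree states).
#' @param alpha probability of switching gene tree within the current parent
#'   (uniform over the other two topologies).
#' @param t_term shared terminal branch length (substitutions/site).
#' @param t_minor internal branch length of the discordant (ILS) gene trees.
#' @param delta excess internal branch length of each parent's concordant
#'   gene tree (concordant internal branch = t_minor + delta, delta >= 0).
#' @param init initial distribution over the 6 states.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(gamma, alpha, t_term, t_minor, delta,
                       init = rep(1 / 6, 6)) {
  stopifnot(gamma >= 0, gamma <= 1, alpha >= 0, alpha <= 1,
            t_term >= 0, t_minor >= 0, delta >= 0,
            length(init) == 6L, all(init >= 0))
  if (abs(sum(init) - 1) > 1e-9) stop("initial distribution must sum to 1")
  structure(list(gamma = gamma, alpha = alpha, t_term = t_term,
                 t_minor = t_minor, delta = delta, init = init),
            class = "hmm_params")
}

#' Transition matrix implied by an `hmm_params` object
#' @param params an `hmm_params` object.
#' @return 6x6 row-stochastic matrix.
#' @export
transition_matrix <- function(params) {
  g <- params$gamma; a <- params$alpha
  M <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    M[i, j] <- if (STATE_PARENT[i] != STATE_PARENT[j]) g / 3
    else if (i == j) (1 - g) * (1 - a)
    else (1 - g) * a / 2
  }
  M
}

# Emission probabilities for each state over a set of site patterns.
# Returns a 6 x npat matrix. Tip contributions are shared across states
# (common terminal branch length) and cherry products cached per topology;
# the two discordant PF states have identical emissions.
state_emissions <- function(pattern_ids, params) {
  codes <- all_pattern_codes(pattern_ids)
  tip <- rbind(t(jc69_pmat(params$t_term)), rep(1, 4))
  TC <- lapply(TAXA, function(tx) tip[codes[, tx], , drop = FALSE])
  names(TC) <- TAXA
  Pmin <- t(jc69_pmat(params$t_minor))
  Pmaj <- t(jc69_pmat(params$t_minor + params$delta))
  cherry_prod <- lapply(CHERRIES, function(ch) TC[[ch[1]]] * TC[[ch[2]]])
  E <- matrix(0, 6, length(pattern_ids))
  done <- rep(FALSE, 6)
  for (s in 1:6) {
    if (done[s]) next
    topo <- STATE_TOPO[s]
    solo <- setdiff(c("P", "D", "F"), CHERRIES[[topo]])
    Pint <- if (STATE_CONCORDANT[s]) Pmaj else Pmin
    E[s, ] <- rowSums((cherry_prod[[topo]] %*% Pint) * TC[[solo]] * TC[["O"]]) / 4
    # share with any identical (topology, internal-length) state
    twin <- which(STATE_TOPO == topo & STATE_CONCORDANT == STATE_CONCORDANT[s])
    for (s2 in setdiff(twin, s)) { E[s2, ] <- E[s, ]; done[s2] <- TRUE }
  }
  E
}

# data-driven starting value for the shared terminal branch length: half
# the JC-corrected mean pairwise mismatch over the six taxon pairs
init_t_term <- function(bases) {
  code <- matrix(base_code(bases), 4L)
  prs <- utils::combn(4L, 2L)
  p <- mean(apply(prs, 2L, function(ij) {
    ok <- code[ij[1], ] <= 4L & code[ij[2], ] <= 4L
    if (!any(ok)) return(0)
    mean(code[ij[1], ok] != code[ij[2], ok])
  }))
  p <- min(p, 0.70)
  max(-0.75 * log(1 - 4 * p / 3) / 2, 1e-4)
}

#' Forward-backward posterior decoding
#'
#' Runs the scaled forward-backward algorithm over the SNV columns of one
#' chromosome and returns per-site state posteriors and the total
#' log-likelihood.
#'
#' @param alignment a `site_alignment` (single chromosome) or a 4 x L
#'   character matrix with rows O, P, D, F.
#' @param params an `hmm_params` object.
#' @return list with `posterior` (6 x L matrix), `loglik`, and `xi`
#'   (expected transition counts, 6 x 6).
#' @export
forward_backward <- function(alignment, params) {
  bases <- alignment_bases(alignment)
  if (ncol(bases) < 1L) stop("alignment must contain at least one SNV column")
  pat <- encode_patterns(bases)
  upat <- sort(unique(pat))
  map <- match(pat, upat)
  E <- state_emissions(upat, params)
  res <- .fb_core(E[, map, drop = FALSE], transition_matrix(params), params$init)
  res
}

alignment_bases <- function(alignment) {
  if (inherits(alignment, "site_alignment")) alignment$bases
  else if (is.matrix(alignment)) {
    if (nrow(alignment) != 4L) stop("alignment matrix must have 4 rows (O,P,D,F)")
    alignment
  } else stop("alignment must be a site_alignment or a 4 x L matrix")
}

# One Baum-Welch run from given starting parameters on a single chromosome.
# Branch lengths are re-estimated each M-step by bounded quasi-Newton
# maximization of the expected complete-data emission term. During a short
# warm-up the transition parameters are held at their starting values while
# the branch lengths adapt: updating gamma/alpha from the still-uninformative
# early posteriors tends to freeze the chain into a symmetric local optimum
# (delta ~ 0 or gamma ~ 0) before the emission asymmetry can emerge.
baum_welch <- function(bases, start, max_iter = 500L, tol = 1e-6,
                       bl_bounds = c(1e-6, 5), warmup = 10L) {
  pat <- encode_patterns(bases)
  upat <- sort(unique(pat))
  map <- match(pat, upat)
  params <- start
  # tempered warm-up: a high drawn parent-switch rate smears the early
  # posteriors so badly that EM settles into a labile fixed point; running
  # the first iterations at a sticky gamma lets the genome segment first
  params$gamma <- min(params$gamma, 0.02)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    E <- state_emissions(upat, params)
    fb <- .fb_pat(E, map, transition_matrix(params), params$init)
    ll_trace <- c(ll_trace, fb$loglik)
    if (iter > warmup + 1L && is.finite(ll_old) && abs(fb$loglik - ll_old) < tol) break
    ll_old <- fb$loglik

    xi <- fb$xi
    cross <- STATE_PARENT[row(xi)] != STATE_PARENT[col(xi)]
    stay <- row(xi) == col(xi)
    n_cross <- sum(xi[cross])
    n_stay <- sum(xi[stay])
    n_ws <- sum(xi[!cross & !stay])
    gamma <- if (n_cross + n_stay + n_ws > 0)
      n_cross / (n_cross + n_stay + n_ws) else params$gamma
    # identifiability floors: a chain that can never switch gene tree
    # (alpha -> 0) lets one parent impersonate the other through a
    # permanently-occupied discordant state, and gamma -> 0 freezes a
    # single parent over the whole chromosome; both make the parent
    # labels meaningless. The floored ratios remain the constrained
    # M-step optimum (the expected-count objective is concave).
    gamma <- min(max(gamma, GAMMA_FLOOR), 1)
    if (iter > warmup) {
      alpha <- if (n_stay + n_ws > 0) n_ws / (n_stay + n_ws) else params$alpha
      alpha <- min(max(alpha, ALPHA_FLOOR), 1)
      init <- pmax(fb$posterior[, 1], 0) / sum(fb$posterior[, 1])
    } else {
      alpha <- params$alpha; init <- params$init
    }

    W <- fb$W  # nupat x 6 expected pattern counts (from the C++ core)
    # branch lengths reparameterized as (t_term, delta, s) with
    # t_minor = s * delta, s in [0,1]: the discordant (ILS) internal branch
    # may not exceed the concordant excess. This regularization removes the
    # mirror degeneracy in which the parents swap roles by expressing each
    # other's concordant topology through a long discordant branch.
    lower <- c(bl_bounds[1], bl_bounds[1], 0)
    upper <- c(bl_bounds[2], bl_bounds[2], 1)
    obj <- function(theta) {
      # optim's finite-difference gradient may probe just outside the box
      theta <- pmin(pmax(theta, lower), upper)
      p2 <- params
      p2$t_term <- theta[1]; p2$delta <- theta[2]; p2$t_minor <- theta[2] * theta[3]
      sum(W * t(log(pmax(state_emissions(upat, p2), 1e-300))))
    }
    cur <- c(params$t_term, params$delta,
             if (params$delta > 0) min(params$t_minor / params$delta, 1) else 0)
    opt <- stats::optim(cur, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(fnscale = -1, maxit = 15))
    theta <- if (opt$value >= obj(cur)) opt$par else cur
    theta <- pmin(pmax(theta, lower), upper)
    params <- hmm_params(gamma, alpha, theta[1], theta[2] * theta[3], theta[2],
                         init = init)
  }
  E <- state_emissions(upat, params)
  fb <- .fb_pat(E, map, transition_matrix(params), params$init)
  list(params = params, posterior = fb$posterior, loglik = fb$loglik,
       loglik_trace = ll_trace, n_iter = length(ll_trace))
}

# gamma/alpha span sticky-to-labile chains; t_term starts at the data
# scale (halved JC pairwise distance) so early E-steps are informative;
# delta is started away from 0 because delta = 0 is a symmetric saddle
# (the two parents become exchangeable) that Baum-Welch escapes only very
# slowly
GAMMA_FLOOR <- 1e-4
ALPHA_FLOOR <- 0.2

draw_start_params <- function(bases) {
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  t0 <- init_t_term(bases)
  delta <- lu(5e-3, 0.3)
  hmm_params(gamma = max(lu(1e-5, 0.5), GAMMA_FLOOR),
             alpha = max(lu(1e-5, 0.5), ALPHA_FLOOR),
             t_term = t0 * lu(0.5, 2), t_minor = delta * runif(1),
             delta = delta)
}

#' Fit the introgression HMM with random restarts
#'
#' Runs Baum-Welch from `n_restarts` random starting points on each
#' chromosome and averages the per-site introgression posterior (the summed
#' posterior of the three introgression-parent states) across restarts.
#' Averaging over restarts guards against individual runs stalling in local
#' optima of the likelihood surface.
#'
#' @param alignment a `site_alignment` (may span several chromosomes).
#' @param n_restarts number of random restarts per chromosome.
#' @param seed master RNG seed; every restart derives its own stream.
#' @param max_iter,tol Baum-Welch stopping rule (|delta log-lik| < tol).
#' @return an object of class `phmm_fit` with elements `track` (a
#'   `posterior_track` data.table: chrom, pos, posterior), `restarts`
#'   (per-chromosome list of per-restart fits), `n_restarts`, `seed`.
#' @export
fit_phmm <- function(alignment, n_restarts = 100L, seed = 1L,
                     max_iter = 500L, tol = 1e-6) {
  stopifnot(inherits(alignment, "site_alignment"), n_restarts >= 1L)
  if (length(alignment$pos) == 0L) stop("alignment has zero usable columns")
  chroms <- unique(alignment$chrom)
  tracks <- vector("list", length(chroms))
  restarts <- list()
  for (ci in seq_along(chroms)) {
    cc <- chroms[ci]
    idx <- which(alignment$chrom == cc)
    bases <- alignment$bases[, idx, drop = FALSE]
    acc <- numeric(length(idx))
    fits <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      rfit <- with_seed(derive_seed(seed, paste0("phmm/", cc, "/restart", r)), {
        start <- draw_start_params(bases)
        baum_welch(bases, start, max_iter = max_iter, tol = tol)
      })
      acc <- acc + colSums(rfit$posterior[4:6, , drop = FALSE])
      fits[[r]] <- rfit[c("params", "loglik", "loglik_trace", "n_iter")]
    }
    tracks[[ci]] <- data.table(chrom = cc, pos = alignment$pos[idx],
                               posterior = acc / n_restarts)
    restarts[[cc]] <- fits
  }
  track <- rbindlist(tracks)
  setattr(track, "class", c("posterior_track", class(track)))
  structure(list(track = track, restarts = restarts,
                 n_restarts = n_restarts, seed = seed),
            class = "phmm_fit")
}

#' @export
print.phmm_fit <- function(x, ...) {
  cat("Phylogenetic HMM fit:", length(x$restarts), "chromosome(s),",
      x$n_restarts, "restart(s)\n")
  cat("  sites:", nrow(x$track),
      " mean introgression posterior:", round(mean(x$track$posterior), 4), "\n")
  invisible(x)
}
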