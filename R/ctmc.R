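#' Build a reversible rate matrix from exchangeabilities and composition
#'
#' Constructs the generator Q = c S Pi of the reversible substitution model:
#' q_ij = c s_ij pi_j for i != j, diagonal set to negative row sums, with
#' the constant c chosen so the total rate sum_i pi_i (-q_ii) equals 0.01
#' (one expected substitution per 100 sites per unit time).  Detailed
#' balance holds by construction since S is symmetric.
#'
#' @param S 20x20 symmetric non-negative exchangeability matrix (diagonal
#'   ignored).
#' @param pi stationary composition (zero components are perturbed to 1e-6
#'   and renormalised, with a warning).
#' @return A [RateMatrix-class].
#' @export
buildRateMatrix <- function(S, pi) {
  stopifnot(is.matrix(S), identical(dim(S), c(20L, 20L)))
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-12)))
    stop("exchangeability matrix must be symmetric")
  if (any(S[row(S) != col(S)] < 0)) stop("exchangeabilities must be >= 0")
  pi <- positiveComposition(pi)
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  total <- sum(pi * rowSums(Q))
  if (total <= 0) stop("all-zero exchangeability matrix: total rate is 0")
  Q <- Q * (RATE_NORM / total)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(AA_ORDER, AA_ORDER)
  names(pi) <- AA_ORDER
  new("RateMatrix", Q = Q, pi = pi)
}

## Symmetric eigendecomposition of a reversible generator:
## B = D^{1/2} Q D^{-1/2} is symmetric, so P(t) = D^{-1/2} U e^{Lt} U' D^{1/2}.
## Numerically stable and cheap to re-exponentiate at many times.
rateEigen <- function(Q, pi) {
  d <- sqrt(pi)
  B <- (d * Q) %*% diag(1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, d = d)
}

transitionFromEigen <- function(edec, t) {
  if (t == 0) return(diag(20L))
  P <- (edec$vectors * rep(exp(edec$values * t), each = 20L)) %*% t(edec$vectors)
  P <- (1 / edec$d) * P %*% diag(edec$d)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q a [RateMatrix-class].
#' @param t evolutionary time (>= 0), in units of one expected change per
#'   100 sites.
#' @return 20x20 row-stochastic matrix.
#' @export
transitionMatrix <- function(Q, t) {
  stopifnot(is(Q, "RateMatrix"))
  if (t < 0) stop("t must be >= 0")
  edec <- rateEigen(Q@Q, Q@pi)
  P <- transitionFromEigen(edec, t)
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

#' Stationary distribution of a generator
#'
#' Left null vector of Q, normalised to sum 1.  Flags generators whose
#' stationary distribution is not unique (reducible chains).
#'
#' @param Q a [RateMatrix-class] or a bare 20x20 generator matrix.
#' @return Named composition vector.
#' @export
stationaryDistribution <- function(Q) {
  m <- if (is(Q, "RateMatrix")) Q@Q else Q
  e <- eigen(t(m))
  ev <- Re(e$values)
  null_idx <- which(abs(ev) < 1e-9)
  if (length(null_idx) > 1L)
    stop("stationary distribution not unique (reducible rate matrix)")
  if (!length(null_idx)) null_idx <- which.min(abs(ev))
  v <- Re(e$vectors[, null_idx])
  v <- v / sum(v)
  if (any(v < -1e-8)) stop("invalid stationary vector")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), AA_ORDER)
}

## ---- Felsenstein pruning ----

## Compress alignment columns to unique patterns; gaps and 'X' are missing
## data.  Returns integer matrix (tips x patterns; 0 = missing) and weights.
columnPatterns <- function(aln, tipLabels) {
  m <- alignmentMatrix(aln)
  if (!all(rownames(m) %in% tipLabels))
    stop("alignment ids not in tree: ",
         paste(setdiff(rownames(m), tipLabels), collapse = ", "))
  m <- m[tipLabels[tipLabels %in% rownames(m)], , drop = FALSE]
  if (nrow(m) == 0L) stop("no alignment sequences match the tree")
  idx <- matrix(match(m, AA_ORDER), nrow = nrow(m))
  idx[is.na(idx)] <- 0L
  rownames(idx) <- rownames(m)
  key <- apply(idx, 2L, paste, collapse = ",")
  uk <- !duplicated(key)
  list(patterns = idx[, uk, drop = FALSE],
       weights = as.numeric(table(key)[key[uk]]))
}

#' Pruning log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein's post-order pruning algorithm for the reversible model: the
#' log-probability of all alignment columns given the tree, the generator Q
#' and root prior pi = composition(Q).  Gap and 'X' characters are treated
#' as missing data (all-ones partial likelihoods).  Columns are compressed
#' to unique site patterns and partial likelihoods are rescaled per node,
#' so deep trees do not underflow.
#'
#' @param aln equal-width [Biostrings::AAStringSet]; names must be a subset
#'   of the tree's tip labels (tips without sequence are treated as missing).
#' @param tree a `"phylo"` tree with branch lengths in units of one expected
#'   change per 100 sites.
#' @param Q a [RateMatrix-class].
#' @return Total log-likelihood (natural log).
#' @export
prunedLogLikelihood <- function(aln, tree, Q) {
  stopifnot(is(Q, "RateMatrix"))
  if (!all(names(aln) %in% tree$tip.label))
    stop("alignment ids not in tree: ",
         paste(setdiff(names(aln), tree$tip.label), collapse = ", "))
  edec <- rateEigen(Q@Q, Q@pi)
  prunedLogLikEigen(aln, tree, edec, Q@pi)
}

## Internal pruning core parameterised by a precomputed eigendecomposition;
## reused by the MCMC sampler where only the exchangeabilities change.
prunedLogLikEigen <- function(aln, tree, edec, pi, pat = NULL) {
  if (is.null(pat)) pat <- columnPatterns(aln, tree$tip.label)
  patterns <- pat$patterns; weights <- pat$weights
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  npat <- ncol(patterns)
  tree <- ape::reorder.phylo(tree, "postorder")
  ## partial likelihood per node: 20 x npat; log scaling factor per pattern
  L <- vector("list", ntip + nnode)
  logscale <- numeric(npat)
  tipOf <- match(tree$tip.label, rownames(patterns))
  for (k in seq_len(ntip)) {
    M <- matrix(0, 20L, npat)
    if (is.na(tipOf[k])) M[] <- 1        # tip without sequence: missing
    else {
      st <- patterns[tipOf[k], ]
      miss <- st == 0L
      if (any(miss)) M[, miss] <- 1
      if (any(!miss)) M[cbind(st[!miss], which(!miss))] <- 1
    }
    L[[k]] <- M
  }
  edges <- tree$edge
  elen <- tree$edge.length
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1L]; child <- edges[i, 2L]
    P <- transitionFromEigen(edec, elen[i])
    contrib <- P %*% L[[child]]
    if (is.null(L[[parent]])) L[[parent]] <- contrib
    else L[[parent]] <- L[[parent]] * contrib
    ## rescale the parent's partials after combining all processed children
    mx <- apply(L[[parent]], 2L, max)
    pos <- mx > 0 & mx < 1e-50
    if (any(pos)) {
      L[[parent]][, pos] <- L[[parent]][, pos] / rep(mx[pos], each = 20L)
      logscale[pos] <- logscale[pos] + log(mx[pos])
    }
  }
  root <- edges[nrow(edges), 1L]
  site_lik <- as.numeric(pi %*% L[[root]])
  site_ll <- ifelse(site_lik > 0, log(site_lik) + logscale, -Inf)
  sum(weights * site_ll)
}
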