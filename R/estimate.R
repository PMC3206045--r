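#' Prior specification for the exchangeability MCMC
#'
#' Default prior: independent log-normal densities on each off-diagonal
#' exchangeability, centred at the Adachi et al. reference value
#' ([referenceExchangeabilities()]) with standard deviation `concentration`
#' on the log scale; entries where the reference is 0 fall back to a flat
#' (scale-free) density.  `mode = "uniform"` uses the flat density
#' everywhere.
#'
#' @param mode `"reference"` or `"uniform"`.
#' @param concentration log-scale standard deviation (> 0).
#' @return A list with elements `mode`, `reference`, `concentration`.
#' @export
priorSpec <- function(mode = c("reference", "uniform"), concentration = 1) {
  mode <- match.arg(mode)
  stopifnot(concentration > 0)
  ref <- if (mode == "reference") referenceExchangeabilities() else NULL
  list(mode = mode, reference = ref, concentration = concentration)
}

## Log prior density of an exchangeability matrix (upper triangle only).
logPriorDensity <- function(S, prior) {
  if (prior$mode == "uniform") return(0)
  ut <- upper.tri(S)
  s <- S[ut]; r <- prior$reference[ut]
  ok <- r > 0
  sum(stats::dlnorm(s[ok], meanlog = log(r[ok]),
                    sdlog = prior$concentration, log = TRUE))
}

#' Metropolis-Hastings sampling of exchangeabilities
#'
#' Samples the posterior over the 190 off-diagonal exchangeabilities of the
#' reversible substitution model, given a fixed alignment and tree.  Each
#' step picks one random off-diagonal entry and proposes a multiplicative
#' log-normal move (with the Hastings correction s'/s); the target is the
#' pruning likelihood of the alignment (with Q rebuilt from the current
#' exchangeabilities and the alignment composition) times the prior
#' density.  The chain is deterministic given `seed`.
#'
#' @param aln equal-width [Biostrings::AAStringSet] (ids must be tree tips).
#' @param tree `"phylo"` tree with branch lengths (units: expected changes
#'   per 100 sites).
#' @param prior a [priorSpec()] list.
#' @param nSteps total Metropolis-Hastings steps (>= 1).
#' @param burnInFraction fraction of initial steps discarded.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param proposalScale sd of the log-normal multiplicative proposal; 0
#'   freezes the chain at its initialisation.
#' @param seed RNG seed.
#' @param init optional initial exchangeability matrix (defaults to the
#'   prior reference, or all-ones for the uniform prior).
#' @return A [PosteriorSample-class].
#' @export
mcmcSampleRates <- function(aln, tree, prior = priorSpec(),
                            nSteps = 1e5, burnInFraction = 0.2, thin = 50,
                            proposalScale = 2.5, seed = 1L, init = NULL) {
  stopifnot(nSteps >= 1, burnInFraction >= 0, burnInFraction < 1, thin >= 1,
            proposalScale >= 0)
  pi <- positiveComposition(composition(aln))
  if (is.null(init)) {
    init <- if (prior$mode == "reference") prior$reference
            else matrix(1, 20L, 20L, dimnames = list(AA_ORDER, AA_ORDER))
    diag(init) <- 0
  }
  S <- init
  S[S <= 0 & row(S) != col(S)] <- 1e-4   # keep the chain off the boundary
  diag(S) <- 0
  pat <- columnPatterns(aln, tree$tip.label)
  loglik <- function(S) {
    Q <- buildRateMatrix(S, pi)
    prunedLogLikEigen(aln, tree, rateEigen(Q@Q, Q@pi), Q@pi, pat = pat)
  }
  set.seed(seed)
  cur_ll <- loglik(S)
  cur_lp <- logPriorDensity(S, prior)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  burn <- floor(nSteps * burnInFraction)
  draws <- list(); trace <- numeric()
  accepted <- 0L
  for (step in seq_len(nSteps)) {
    k <- sample.int(nrow(ut), 1L)
    i <- ut[k, 1L]; j <- ut[k, 2L]
    old <- S[i, j]
    fac <- if (proposalScale == 0) 1 else exp(stats::rnorm(1L, 0, proposalScale))
    newv <- old * fac
    Sp <- S; Sp[i, j] <- Sp[j, i] <- newv
    prop_ll <- loglik(Sp)
    prop_lp <- logPriorDensity(Sp, prior)
    ## Hastings ratio of the multiplicative log-normal proposal = new/old
    log_alpha <- (prop_ll + prop_lp) - (cur_ll + cur_lp) + log(newv / old)
    if (is.finite(log_alpha) && log(stats::runif(1L)) < log_alpha) {
      S <- Sp; cur_ll <- prop_ll; cur_lp <- prop_lp
      accepted <- accepted + 1L
    }
    if (step > burn && (step - burn) %% thin == 0L) {
      draws[[length(draws) + 1L]] <- S
      trace[length(trace) + 1L] <- cur_ll + cur_lp
    }
  }
  if (!length(draws)) { draws <- list(S); trace <- cur_ll + cur_lp }
  acc <- accepted / nSteps
  if (nSteps >= 1000 && acc < 0.005)
    stop(sprintf("MCMC chain essentially frozen (acceptance %.2f%%); ",
                 100 * acc),
         "check the proposal scale and the data/tree compatibility")
  new("PosteriorSample", draws = draws, logPost = trace,
      acceptanceRate = acc, pi = pi)
}

#' Posterior-mean rate matrix
#'
#' Element-wise mean of the retained exchangeability draws, rebuilt into a
#' normalised reversible [RateMatrix-class] with the supplied composition.
#'
#' @param sample a [PosteriorSample-class] with >= 1 draw.
#' @param pi composition (defaults to the sample's).
#' @return A [RateMatrix-class].
#' @export
posteriorMeanRates <- function(sample, pi = composition(sample)) {
  draws <- sample@draws
  if (!length(draws)) stop("empty posterior sample")
  S <- Reduce(`+`, draws) / length(draws)
  buildRateMatrix(S, pi)
}

#' Valid-pair weights of an alignment
#'
#' For each residue pair (i, j), the average over alignment columns of the
#' number of sequence pairs in which the two residues actually co-occur,
#' normalised by the total number of sequence pairs N(N-1)/2:
#' w_ij = (1/C) sum_k cnt_k(i,j) / (N(N-1)/2), with cnt_k(i,j) =
#' n_i(k) n_j(k) for i != j and choose(n_i(k), 2) on the diagonal.  Gaps
#' and 'X' are excluded from the counts.  Used to down-weight rate entries
#' for pairs rarely observed together ([applyValidPairs()]).
#'
#' @param aln equal-width [Biostrings::AAStringSet] with >= 2 sequences.
#' @return Symmetric 20x20 matrix of weights in \[0, 1\].
#' @export
validPairWeights <- function(aln) {
  m <- alignmentMatrix(aln)
  N <- nrow(m)
  if (N < 2L) stop("valid-pair weights need at least 2 sequences")
  C <- ncol(m)
  npairs <- N * (N - 1) / 2
  W <- matrix(0, 20L, 20L, dimnames = list(AA_ORDER, AA_ORDER))
  for (k in seq_len(C)) {
    n <- tabulate(match(m[, k], AA_ORDER), nbins = 20L)
    cnt <- outer(n, n)
    diag(cnt) <- n * (n - 1) / 2
    W <- W + cnt / npairs
  }
  pmin(pmax(W / C, 0), 1)
}

#' Apply the valid-pairs correction to a rate matrix
#'
#' Element-wise modulation of the off-diagonal rates by the symmetric
#' weight matrix W, with the diagonal reset to negative row sums and the
#' total rate renormalised to 0.01.  Detailed balance is preserved when W
#' is symmetric.
#'
#' @param Q a [RateMatrix-class].
#' @param W symmetric 20x20 weight matrix in \[0, 1\]
#'   (see [validPairWeights()]).
#' @return A corrected [RateMatrix-class].
#' @export
applyValidPairs <- function(Q, W) {
  stopifnot(is(Q, "RateMatrix"), is.matrix(W),
            identical(dim(W), c(20L, 20L)))
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12)))
    stop("weight matrix must be symmetric")
  if (all(W == 0)) stop("weight matrix is zero everywhere")
  pi <- Q@pi
  Qw <- Q@Q * W
  ## recover exchangeabilities of the weighted rates and rebuild, which
  ## renormalises and restores exact detailed balance
  S <- sweep(Qw, 2L, pi, "/")
  S <- (S + t(S)) / 2
  diag(S) <- 0
  buildRateMatrix(S, pi)
}

#' Average rate and weight matrices across proteins
#'
#' Element-wise mean of the per-protein generators and of the per-protein
#' valid-pair weight matrices, followed by the valid-pairs correction of
#' the mean generator with the mean weights under a common (pooled)
#' composition.  The mean generator is projected back onto reversibility
#' with respect to the pooled composition via
#' s_ij = (pi_i q_ij + pi_j q_ji) / (2 pi_i pi_j), which is the identity
#' when the per-protein matrices share that composition.
#'
#' @param rateList list of [RateMatrix-class] objects (>= 1).
#' @param weightList parallel list of 20x20 weight matrices.
#' @param pi pooled composition for the final matrix.
#' @return A [RateMatrix-class].
#' @export
averageRateMatrices <- function(rateList, weightList, pi) {
  stopifnot(length(rateList) >= 1L, length(rateList) == length(weightList))
  pi <- positiveComposition(pi)
  Qbar <- Reduce(`+`, lapply(rateList, rates)) / length(rateList)
  Wbar <- Reduce(`+`, weightList) / length(weightList)
  S <- (pi * Qbar + t(pi * Qbar)) / (2 * outer(pi, pi))
  diag(S) <- 0
  dimnames(S) <- list(AA_ORDER, AA_ORDER)
  applyValidPairs(buildRateMatrix(S, pi), Wbar)
}
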