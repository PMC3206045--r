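## Round half away from zero (so e.g. 1.5 -> 2, -1.5 -> -2), the convention
## used when integerising log-odds scores.
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive an integer log-odds scoring matrix at evolutionary time t
#'
#' The Karlin-style log-odds construction: s_ij = round(log2(P_ij(t) /
#' pi_j) / scaleBits), with P(t) the transition matrix of the rate model at
#' time t.  For a reversible model the pre-rounding scores are symmetric,
#' and the same rounding (half away from zero) yields a symmetric integer
#' matrix.  Transition entries that are numerically zero are floored at
#' `minScore` with a warning.
#'
#' @param Q a [RateMatrix-class].
#' @param time evolutionary time (> 0), in units of one expected change per
#'   100 sites; published bbTM matrices use t = 40 for the all-TM and
#'   interior-facing sets and t = 36 for the lipid-facing set.
#' @param scaleBits bits per score unit (default 0.5, the half-bit scale).
#' @param minScore floor for log-of-zero entries (default -16).
#' @return A [ScoringMatrix-class].
#' @export
deriveScoringMatrix <- function(Q, time, scaleBits = 0.5, minScore = -16L) {
  stopifnot(is(Q, "RateMatrix"))
  if (time <= 0) stop("time must be > 0")
  P <- transitionMatrix(Q, time)
  pi <- Q@pi
  odds <- sweep(P, 2L, pi, "/")
  ## reversibility makes the log-odds symmetric up to round-off; average to
  ## remove floating-point asymmetry before rounding
  lo <- suppressWarnings(log2(odds))
  lo <- (lo + t(lo)) / 2
  s <- roundHalfAway(lo / scaleBits)
  zero <- !is.finite(s)
  if (any(zero)) {
    warning(sum(zero), " zero transition entr(ies) floored at score ", minScore)
    s[zero] <- minScore
  }
  s[s < minScore] <- minScore
  storage.mode(s) <- "integer"
  dimnames(s) <- list(AA_ORDER, AA_ORDER)
  new("ScoringMatrix", scores = s, time = time, scaleBits = scaleBits, pi = pi)
}

#' Scoring matrix from a file or bare integer matrix
#'
#' Wraps a 20x20 symmetric integer matrix (e.g. read back from an NCBI
#' matrix file) as a [ScoringMatrix-class].
#'
#' @param scores 20x20 symmetric integer matrix with canonical dimnames.
#' @param time nominal evolutionary time (metadata; default NA stored as 1).
#' @param scaleBits bits per score unit.
#' @param pi background composition.
#' @return A [ScoringMatrix-class].
#' @export
asScoringMatrix <- function(scores, time = 1, scaleBits = 0.5,
                            pi = rep(1 / 20, 20)) {
  storage.mode(scores) <- "integer"
  new("ScoringMatrix", scores = scores[AA_ORDER, AA_ORDER], time = time,
      scaleBits = scaleBits, pi = checkComposition(pi))
}

#' Expected score of a matrix under a background composition
#'
#' sum_ij pi_i pi_j s_ij.  A usable local-alignment scoring matrix must
#' have a strictly negative expected score.
#'
#' @param matrix a [ScoringMatrix-class] or bare 20x20 matrix.
#' @param pi background composition (defaults to the matrix's own).
#' @return Scalar expected score.
#' @export
expectedScore <- function(matrix, pi = NULL) {
  s <- if (is(matrix, "ScoringMatrix")) matrix@scores else matrix
  if (is.null(pi)) {
    if (!is(matrix, "ScoringMatrix")) stop("pi required for a bare matrix")
    pi <- matrix@pi
  }
  pi <- checkComposition(pi)
  as.numeric(pi %*% s %*% pi)
}

#' Karlin-Altschul parameters of a scoring matrix
#'
#' Solves for lambda > 0 in sum_ij pi_i pi_j exp(lambda s_ij) = 1 by
#' bisection, and computes K by the standard ungapped series approximation
#' (Karlin-Altschul): with delta the greatest common divisor of the score
#' support, H = lambda sum_ij pi_i pi_j s_ij exp(lambda s_ij) the relative
#' entropy, and sigma = sum_k (1/k) (P(S_k >= 0) + E(exp(lambda S_k);
#' S_k < 0)) accumulated over k-fold convolutions of the score
#' distribution,
#' K = delta lambda exp(-2 sigma) / (H (1 - exp(-delta lambda))).
#'
#' @param matrix a [ScoringMatrix-class] or bare integer matrix.
#' @param pi background composition (defaults to the matrix's own).
#' @return A [KarlinAltschul-class].
#' @export
karlinAltschulParams <- function(matrix, pi = NULL) {
  s <- if (is(matrix, "ScoringMatrix")) matrix@scores else matrix
  if (is.null(pi)) {
    if (!is(matrix, "ScoringMatrix")) stop("pi required for a bare matrix")
    pi <- matrix@pi
  }
  pi <- checkComposition(pi)
  if (expectedScore(s, pi) >= 0 || !any(s > 0))
    stop("invalid scoring matrix: expected score must be negative ",
         "with at least one positive entry")
  pp <- outer(pi, pi)
  f <- function(lam) sum(pp * exp(lam * s)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-8
  if (f(lo) >= 0) stop("cannot bracket lambda")
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  lambda <- (lo + hi) / 2
  H <- lambda * sum(pp * s * exp(lambda * s))
  ## score distribution on the integer lattice
  vals <- sort(unique(as.vector(s)))
  p <- vapply(vals, function(v) sum(pp[s == v]), numeric(1))
  delta <- Reduce(function(a, b) {
    while (b) { t <- b; b <- a %% b; a <- t }; a
  }, abs(vals[vals != 0]))
  low <- min(vals); high <- max(vals)
  ## distribution of S_k by iterated convolution, on support k*low .. k*high
  sigma <- 0
  pk <- numeric(high - low + 1L)            # offset: index 1 <-> score `low`
  pk[vals - low + 1L] <- p
  base <- pk
  kmax <- 100L
  for (k in seq_len(kmax)) {
    if (k > 1L) {
      newlen <- length(pk) + length(base) - 1L
      conv <- numeric(newlen)
      nz <- which(base > 0)
      for (i in nz) conv[seq_along(pk) + i - 1L] <-
          conv[seq_along(pk) + i - 1L] + pk * base[i]
      pk <- conv
    }
    sc <- seq(k * low, k * high)
    neg <- sc < 0
    term <- sum(pk[neg] * exp(lambda * sc[neg])) + sum(pk[!neg])
    sigma <- sigma + term / k
    if (term / k < 1e-9) break
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-delta * lambda)))
  new("KarlinAltschul", lambda = lambda, K = K, H = H)
}
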