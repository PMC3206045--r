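#' @import methods
NULL

setOldClass("phylo")
setOldClass("hclust")

#' RateMatrix: reversible instantaneous substitution-rate matrix
#'
#' A 20x20 generator Q of a reversible continuous-time Markov chain over
#' amino acids, together with its stationary composition pi.  Off-diagonal
#' entries are the instantaneous rates of i -> j substitution; rows sum to
#' zero; detailed balance pi_i q_ij = pi_j q_ji holds; and the matrix is
#' normalised so the expected number of substitutions per site per unit time,
#' sum_i pi_i (-q_ii), equals 0.01 (one change per 100 sites).
#'
#' @slot Q 20x20 numeric matrix, canonical residue dimnames.
#' @slot pi Named numeric vector of 20 stationary frequencies.
#' @export
setClass("RateMatrix", representation(Q = "matrix", pi = "numeric"))

setValidity("RateMatrix", function(object) {
  Q <- object@Q; pi <- object@pi
  msg <- character()
  if (!is.numeric(Q) || !identical(dim(Q), c(20L, 20L)))
    return("Q must be a 20x20 numeric matrix")
  if (!identical(rownames(Q), AA_ORDER) || !identical(colnames(Q), AA_ORDER))
    msg <- c(msg, "Q dimnames must be the canonical residue order")
  off <- Q[row(Q) != col(Q)]
  if (any(off < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
  if (max(abs(rowSums(Q))) > 1e-10) msg <- c(msg, "rows must sum to 0")
  if (length(pi) != 20L || abs(sum(pi) - 1) > 1e-8 || any(pi <= 0))
    msg <- c(msg, "pi must be 20 positive frequencies summing to 1")
  else {
    db <- pi * Q - t(pi * Q)
    if (max(abs(db)) > 1e-10) msg <- c(msg, "detailed balance violated")
    if (abs(sum(pi * -diag(Q)) - RATE_NORM) > 1e-10)
      msg <- c(msg, sprintf("total rate must be %g", RATE_NORM))
  }
  if (length(msg)) msg else TRUE
})

#' ScoringMatrix: integer log-odds scoring matrix
#'
#' Symmetric 20x20 integer matrix of half-bit (by default) log-odds scores
#' s_ij derived from transition probabilities at evolutionary time t, the
#' persisted/bbTM-family deliverable of the package.
#'
#' @slot scores 20x20 integer matrix, symmetric.
#' @slot time Evolutionary time (units of 1 expected change per 100 sites).
#' @slot scaleBits Bits per score unit (0.5 = half-bit scale).
#' @slot pi Background composition the scores were derived against.
#' @export
setClass("ScoringMatrix",
         representation(scores = "matrix", time = "numeric",
                        scaleBits = "numeric", pi = "numeric"))

setValidity("ScoringMatrix", function(object) {
  s <- object@scores
  msg <- character()
  if (!identical(dim(s), c(20L, 20L)))
    return("scores must be a 20x20 matrix")
  if (!identical(rownames(s), AA_ORDER) || !identical(colnames(s), AA_ORDER))
    msg <- c(msg, "score dimnames must be the canonical residue order")
  if (any(s != round(s))) msg <- c(msg, "scores must be integers")
  if (!isTRUE(all.equal(s, t(s)))) msg <- c(msg, "scores must be symmetric")
  if (length(object@time) != 1L || object@time <= 0)
    msg <- c(msg, "time must be a positive scalar")
  if (length(object@scaleBits) != 1L || object@scaleBits <= 0)
    msg <- c(msg, "scaleBits must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' TMAnnotation: transmembrane strand segments with facing labels
#'
#' Per-template annotation of membrane-embedded beta-strand segments on the
#' ungapped template sequence (0-based, half-open coordinates), with one
#' facing label per transmembrane position: \code{"I"} for residues facing
#' the barrel interior, \code{"O"} for residues facing the lipid.
#'
#' @slot proteinId Template protein identifier.
#' @slot segments data.frame with columns strand, start, end (0-based,
#'   half-open), sorted and disjoint.
#' @slot facing Character vector over \{"I","O"\}, one element per TM
#'   position in segment order.
#' @export
setClass("TMAnnotation",
         representation(proteinId = "character", segments = "data.frame",
                        facing = "character"))

setValidity("TMAnnotation", function(object) {
  seg <- object@segments
  msg <- character()
  if (!all(c("strand", "start", "end") %in% names(seg)))
    return("segments needs columns strand, start, end")
  if (nrow(seg)) {
    if (any(seg$end <= seg$start)) msg <- c(msg, "segments must have end > start")
    if (is.unsorted(seg$start, strictly = TRUE) && nrow(seg) > 1)
      msg <- c(msg, "segments must be sorted by start")
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))
      msg <- c(msg, "segments overlap")
  }
  width <- sum(seg$end - seg$start)
  if (length(object@facing) != width)
    msg <- c(msg, sprintf("facing length %d != total segment width %d",
                          length(object@facing), width))
  if (!all(object@facing %in% c("I", "O")))
    msg <- c(msg, "facing labels must be 'I' or 'O'")
  if (length(msg)) msg else TRUE
})

#' PosteriorSample: retained draws from the rate-matrix MCMC
#'
#' @slot draws List of 20x20 symmetric exchangeability matrices (retained,
#'   post burn-in, thinned).
#' @slot logPost Numeric vector of log-posterior values, one per draw.
#' @slot acceptanceRate Overall Metropolis-Hastings acceptance rate.
#' @slot pi Composition used to build Q during sampling.
#' @export
setClass("PosteriorSample",
         representation(draws = "list", logPost = "numeric",
                        acceptanceRate = "numeric", pi = "numeric"))

setValidity("PosteriorSample", function(object) {
  if (length(object@draws) != length(object@logPost))
    return("logPost trace length must equal number of retained draws")
  TRUE
})

#' KarlinAltschul: ungapped local-alignment score statistics
#'
#' @slot lambda Scale parameter solving sum pi_i pi_j exp(lambda s_ij) = 1.
#' @slot K Prefactor of the e-value formula E = K m n exp(-lambda S).
#' @slot H Relative entropy (nats per aligned pair) of the target vs
#'   background distribution.
#' @export
setClass("KarlinAltschul",
         representation(lambda = "numeric", K = "numeric", H = "numeric"))

## ---- accessors ----

#' @describeIn RateMatrix-class the 20x20 generator matrix
#' @param object,x an object of the documented class
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @export
setMethod("rates", "RateMatrix", function(object) object@Q)

#' Stationary composition associated with an object
#' @param object a RateMatrix, ScoringMatrix or PosteriorSample
#' @export
setGeneric("composition", function(object) standardGeneric("composition"))
#' @export
setMethod("composition", "RateMatrix", function(object) object@pi)
#' @export
setMethod("composition", "ScoringMatrix", function(object) object@pi)
#' @export
setMethod("composition", "PosteriorSample", function(object) object@pi)

#' Integer score table of a ScoringMatrix
#' @param object a ScoringMatrix
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @export
setMethod("scores", "ScoringMatrix", function(object) object@scores)

#' Evolutionary time at which a ScoringMatrix was derived
#' @param object a ScoringMatrix
#' @export
setGeneric("evolTime", function(object) standardGeneric("evolTime"))
#' @export
setMethod("evolTime", "ScoringMatrix", function(object) object@time)

#' Strand segments of a TMAnnotation
#' @param object a TMAnnotation
#' @export
setGeneric("tmSegments", function(object) standardGeneric("tmSegments"))
#' @export
setMethod("tmSegments", "TMAnnotation", function(object) object@segments)

#' Facing labels ("I"/"O") of a TMAnnotation, one per TM position
#' @param object a TMAnnotation
#' @export
setGeneric("facingLabels", function(object) standardGeneric("facingLabels"))
#' @export
setMethod("facingLabels", "TMAnnotation", function(object) object@facing)

#' Retained exchangeability draws of a PosteriorSample
#' @param object a PosteriorSample
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))
#' @export
setMethod("posteriorDraws", "PosteriorSample", function(object) object@draws)

#' Metropolis-Hastings acceptance rate of a PosteriorSample
#' @param object a PosteriorSample
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))
#' @export
setMethod("acceptanceRate", "PosteriorSample", function(object) object@acceptanceRate)

## ---- show methods ----

setMethod("show", "RateMatrix", function(object) {
  cat("RateMatrix: 20x20 reversible generator,",
      sprintf("%g expected substitutions/site/unit time\n", RATE_NORM))
  top <- displayRates(object)
  ut <- which(upper.tri(top), arr.ind = TRUE)
  v <- top[ut]
  ord <- order(v, decreasing = TRUE)[seq_len(5L)]
  cat("  largest rates (x", format(DISPLAY_SCALE, scientific = FALSE), "): ",
      paste(sprintf("%s-%s %.0f", AA_ORDER[ut[ord, 1]], AA_ORDER[ut[ord, 2]],
                    v[ord]), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ScoringMatrix", function(object) {
  cat(sprintf("ScoringMatrix: t = %g, %g bits/unit, score range [%d, %d]\n",
              object@time, object@scaleBits, min(object@scores),
              max(object@scores)))
})

setMethod("show", "TMAnnotation", function(object) {
  f <- object@facing
  cat(sprintf("TMAnnotation '%s': %d strands, %d TM residues (%d in, %d out)\n",
              object@proteinId, nrow(object@segments), length(f),
              sum(f == "I"), sum(f == "O")))
})

setMethod("show", "PosteriorSample", function(object) {
  cat(sprintf("PosteriorSample: %d retained draws, acceptance %.1f%%\n",
              length(object@draws), 100 * object@acceptanceRate))
})

setMethod("show", "KarlinAltschul", function(object) {
  cat(sprintf("KarlinAltschul: lambda = %.4f, K = %.4f, H = %.4f\n",
              object@lambda, object@K, object@H))
})

#' Display-scaled rate table
#'
#' Off-diagonal instantaneous rates multiplied by the display factor 1e4
#' (bringing them to the magnitude of published per-pair substitution-rate
#' values); the diagonal is returned as NA.
#'
#' @param object a RateMatrix
#' @param scale display multiplier (default 1e4)
#' @return 20x20 numeric matrix with NA diagonal.
#' @export
displayRates <- function(object, scale = DISPLAY_SCALE) {
  stopifnot(is(object, "RateMatrix"))
  m <- object@Q * scale
  diag(m) <- NA_real_
  m
}
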