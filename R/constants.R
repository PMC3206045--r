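#' @keywords internal
#' @import methods
#' @importClassesFrom Biostrings AAStringSet AAString
"_PACKAGE"

## Canonical residue ordering used everywhere in the package: the classic
## PAM order, which is also the row/column order of NCBI matrix files.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Characters legal in sequence records: residues, gap, unknown.
AA_ALLOWED <- c(AA_ORDER, "-", "X")

## Rate matrices are normalised so that one unit of evolutionary time equals
## 0.01 expected substitutions per site, i.e. one expected residue change per
## 100 sites.  Evolutionary times such as t = 40 are expressed in this unit.
RATE_NORM <- 0.01

## Rates are reported/displayed multiplied by this factor, which brings them
## onto the magnitude of published per-pair values (e.g. V-I in the hundreds).
DISPLAY_SCALE <- 1e4

#' GES hydrophobicity scale
#'
#' Per-residue transfer free energies of the Goldman-Engelman-Steitz (GES)
#' hydrophobicity scale, in kcal/mol, with positive values hydrophobic and
#' negative values polar.  Returned in the package's canonical residue order.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' gesScale()[["L"]]
gesScale <- function() {
  c(A = 1.6, R = -12.3, N = -4.8, D = -9.2, C = 2.0,
    Q = -4.1, E = -8.2, G = 1.0, H = -3.0, I = 3.1,
    L = 2.8, K = -8.8, M = 3.4, F = 3.7, P = -0.2,
    S = 0.6, T = 1.2, W = 1.9, Y = -0.7, V = 2.6)[AA_ORDER]
}

#' Reference exchangeabilities (Adachi-Hasegawa mitochondrial model)
#'
#' Symmetric 20x20 exchangeability matrix of the Adachi et al. mtREV24 model,
#' fetched from \pkg{phangorn}'s packaged model set and re-scaled so the mean
#' off-diagonal entry is 1.  Used as the centre of the default log-normal
#' prior on exchangeabilities in [mcmcSampleRates()].
#'
#' @return 20x20 symmetric numeric matrix, zero diagonal, dimnames in
#'   canonical residue order.
#' @export
referenceExchangeabilities <- function() {
  getModelAA <- get("getModelAA", envir = asNamespace("phangorn"))
  Q <- NULL; bf <- NULL
  eval(getModelAA("mtREV24", bf = TRUE, Q = TRUE))
  S <- matrix(0, 20L, 20L, dimnames = list(AA_ORDER, AA_ORDER))
  S[lower.tri(S)] <- Q
  S <- S + t(S)
  S / mean(S[upper.tri(S)])
}

## Internal: validate and normalise a composition vector.
checkComposition <- function(pi, tol = 1e-8) {
  stopifnot(is.numeric(pi), length(pi) == 20L, all(pi >= 0))
  if (is.null(names(pi))) names(pi) <- AA_ORDER
  pi <- pi[AA_ORDER]
  if (anyNA(pi)) stop("composition vector must be named by the 20 residues")
  s <- sum(pi)
  if (abs(s - 1) > tol) stop("composition must sum to 1 (got ", format(s), ")")
  pi / s
}

## Internal: perturb zero components to keep the generator irreducible, as
## rate construction requires a strictly positive composition.
positiveComposition <- function(pi, eps = 1e-6) {
  pi <- checkComposition(pi, tol = 1e-6)
  if (any(pi <= 0)) {
    warning("zero composition components perturbed to ", eps,
            " and renormalized")
    pi[pi <= 0] <- eps
    pi <- pi / sum(pi)
  }
  pi
}
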