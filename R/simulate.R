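#' Simulate an alignment along a tree under a rate model
#'
#' Evolves `nColumns` independent sites down the tree: the root state is
#' drawn from the stationary composition, and each child state from the
#' parent's row of the transition matrix at the branch length.  Sites are
#' i.i.d. (no among-site rate variation), matching the estimation model.
#' Deterministic given `seed`.
#'
#' @param tree `"phylo"` tree with branch lengths (units: expected changes
#'   per 100 sites).
#' @param Q a [RateMatrix-class].
#' @param nColumns number of alignment columns (>= 1).
#' @param seed RNG seed.
#' @return An [Biostrings::AAStringSet] of ungapped leaf sequences named by
#'   tip label.
#' @export
simulateAlignment <- function(tree, Q, nColumns, seed = 1L) {
  stopifnot(is(Q, "RateMatrix"), nColumns >= 1)
  set.seed(seed)
  pi <- Q@pi
  edec <- rateEigen(Q@Q, pi)
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  edges <- tree$edge[rev(seq_len(nrow(tree$edge))), , drop = FALSE]  # preorder
  elen <- rev(tree$edge.length)
  root <- edges[1L, 1L]
  states <- matrix(0L, ntip + tree$Nnode, nColumns)
  states[root, ] <- sample.int(20L, nColumns, replace = TRUE, prob = pi)
  Pcache <- list()
  for (i in seq_len(nrow(edges))) {
    key <- format(elen[i], digits = 12)
    P <- Pcache[[key]]
    if (is.null(P)) P <- Pcache[[key]] <- transitionFromEigen(edec, elen[i])
    parent_states <- states[edges[i, 1L], ]
    child <- integer(nColumns)
    for (a in unique(parent_states)) {
      idx <- parent_states == a
      child[idx] <- sample.int(20L, sum(idx), replace = TRUE, prob = P[a, ])
    }
    states[edges[i, 2L], ] <- child
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(s)
    paste(AA_ORDER[s], collapse = ""))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- tree$tip.label
  out
}

#' Composition-preserving sequence shuffle
#'
#' Uniform random permutation of the residues of a sequence (Fisher-Yates,
#' via [sample()]), preserving length and amino-acid composition exactly.
#' Deterministic given `seed`.
#'
#' @param seq character sequence (or AAString).
#' @param seed RNG seed.
#' @return Shuffled character sequence.
#' @export
shuffleSequence <- function(seq, seed = 1L) {
  seq <- as.character(seq)
  if (!nchar(seq)) stop("cannot shuffle an empty sequence")
  set.seed(seed)
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

#' Build a shuffled decoy database
#'
#' One composition-preserving shuffle per input record, with ids suffixed
#' `"_shuffled"`.  Per-record seeds are derived from the master seed and the
#' record index, so records are independently and reproducibly shuffled.
#'
#' @param records an [Biostrings::AAStringSet].
#' @param seed master RNG seed.
#' @return An [Biostrings::AAStringSet] of decoys.
#' @export
makeDecoyDatabase <- function(records, seed = 1L) {
  if (!length(records)) stop("empty input database")
  shuffled <- vapply(seq_along(records), function(i) {
    sub_seed <- (as.double(seed) * 48271 + i * 7919) %% 2147483647
    shuffleSequence(as.character(records[[i]]), seed = as.integer(sub_seed))
  }, character(1))
  out <- Biostrings::AAStringSet(shuffled)
  names(out) <- paste0(names(records), "_shuffled")
  out
}
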