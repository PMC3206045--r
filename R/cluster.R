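#' Substitution profiles of the 20 residues
#'
#' For each residue, its 19 off-diagonal instantaneous rates toward the
#' other residues, in display units.  Returned as a 20x20 matrix with NA on
#' the diagonal, so that row i holds residue i's profile; distances between
#' profiles are taken by [profileDistances()].
#'
#' @param Q a [RateMatrix-class].
#' @param scale display multiplier (default 1e4).
#' @return 20x20 numeric matrix with NA diagonal.
#' @export
substitutionProfiles <- function(Q, scale = DISPLAY_SCALE) {
  displayRates(Q, scale)
}

#' Euclidean distances between substitution profiles
#'
#' The distance between residues i and j is computed over the 18 shared
#' coordinates, excluding positions i and j: each residue's profile has no
#' self-coordinate, so the i -> j rate sits at different positions in the
#' two 19-vectors, and a strict 19-dimensional comparison would misalign
#' coordinates.  Dropping both residues' own coordinates compares like with
#' like.
#'
#' @param profiles 20x20 profile matrix from [substitutionProfiles()]
#'   (NA diagonal allowed) or a [RateMatrix-class].
#' @return Symmetric 20x20 distance matrix with zero diagonal.
#' @export
profileDistances <- function(profiles) {
  if (is(profiles, "RateMatrix")) profiles <- substitutionProfiles(profiles)
  stopifnot(is.matrix(profiles), identical(dim(profiles), c(20L, 20L)))
  labs <- rownames(profiles)
  if (is.null(labs)) labs <- AA_ORDER
  D <- matrix(0, 20L, 20L, dimnames = list(labs, labs))
  for (i in 1:19) for (j in (i + 1):20) {
    keep <- setdiff(seq_len(20L), c(i, j))
    D[i, j] <- D[j, i] <- sqrt(sum((profiles[i, keep] - profiles[j, keep])^2))
  }
  D
}

#' Single-linkage clustering of residue profiles
#'
#' Agglomerative single-linkage clustering of the 20 residues by profile
#' distance, via [stats::hclust()]; merge heights equal the minimum
#' inter-cluster element distance and are non-decreasing.
#'
#' @param distances 20x20 symmetric distance matrix
#'   (see [profileDistances()]), or a [RateMatrix-class].
#' @return An [stats::hclust] object (leaf labels = residues).
#' @export
profileLinkage <- function(distances) {
  if (is(distances, "RateMatrix"))
    distances <- profileDistances(substitutionProfiles(distances))
  stats::hclust(stats::as.dist(distances), method = "single")
}

#' Newick export of a clustering tree
#'
#' Converts an [stats::hclust] dendrogram to Newick, writing merge heights
#' as branch lengths.
#'
#' @param h an hclust object.
#' @param path optional output file; when NULL the Newick string is
#'   returned.
#' @return The Newick string (invisibly, when `path` is given).
#' @export
linkageNewick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' First-merge order of two leaf groups in a dendrogram
#'
#' Utility for dendrogram sanity checks: the merge height at which leaves
#' `a` and `b` first share a cluster.
#'
#' @param h an hclust object.
#' @param a,b leaf labels.
#' @return The merge height.
#' @export
joinHeight <- function(h, a, b) {
  n <- length(h$labels)
  members <- as.list(seq_len(n))          # positive = merged cluster index
  get_leaves <- function(idx) {
    if (idx < 0) h$labels[-idx] else attr(members[[idx]], "leaves")
  }
  for (k in seq_len(nrow(h$merge))) {
    l1 <- if (h$merge[k, 1] < 0) h$labels[-h$merge[k, 1]] else
      attr(members[[h$merge[k, 1]]], "leaves")
    l2 <- if (h$merge[k, 2] < 0) h$labels[-h$merge[k, 2]] else
      attr(members[[h$merge[k, 2]]], "leaves")
    leaves <- c(l1, l2)
    x <- list(k); attr(x[[1]], "leaves") <- leaves
    members[[k]] <- x[[1]]
    if (a %in% leaves && b %in% leaves) return(h$height[k])
  }
  stop("labels never join")
}
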