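#' Smith-Waterman local alignment with a custom scoring matrix
#'
#' Optimal local alignment of two ungapped protein sequences under the
#' supplied scoring matrix and affine gap penalties (a gap of length L
#' costs `gapOpen + L * gapExtend`), via
#' [Biostrings::pairwiseAlignment()].  When no alignment scores above 0 the
#' empty local alignment is reported (score 0, length 0).
#'
#' @param query,subject ungapped sequences (character or AAString).
#' @param matrix a [ScoringMatrix-class].
#' @param gapOpen,gapExtend affine gap penalties (positive costs; defaults
#'   11 and 1).
#' @return List with `score`, `length` (alignment columns, gaps included)
#'   and `identity` (percent, NA for the empty alignment).
#' @export
localAlign <- function(query, subject, matrix, gapOpen = 11, gapExtend = 1) {
  query <- toupper(as.character(query)); subject <- toupper(as.character(subject))
  if (!nchar(query) || !nchar(subject)) stop("empty sequence")
  s <- if (is(matrix, "ScoringMatrix")) matrix@scores else matrix
  pa <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                      substitutionMatrix = s,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExtend)
  sc <- Biostrings::score(pa)
  len <- nchar(as.character(Biostrings::pattern(pa)))
  if (sc <= 0 || len == 0L)
    return(list(score = 0, length = 0L, identity = NA_real_))
  list(score = sc, length = len,
       identity = percentIdentity(as.character(Biostrings::pattern(pa)),
                                  as.character(Biostrings::subject(pa))))
}

#' E-value of a local alignment score
#'
#' E = K m n exp(-lambda S): the expected number of chance hits of score
#' >= S in a search of a length-m query against n database residues.
#'
#' @param score alignment raw score.
#' @param m query length (>= 1).
#' @param n total database residue count (>= 1).
#' @param params a [KarlinAltschul-class].
#' @return E-value (> 0).
#' @export
evalueOf <- function(score, m, n, params) {
  stopifnot(m >= 1, n >= 1, is(params, "KarlinAltschul"))
  params@K * m * n * exp(-params@lambda * score)
}

#' Filter hits by e-value and minimum alignment length
#'
#' Keeps hits with `e_value < eThreshold` and alignment length >=
#' `minLength`.  The default minimum of 10 residues reflects the shortest
#' biologically meaningful match for a beta-barrel: one two-strand hairpin
#' at about five matched residues per strand.
#'
#' @param hits data.frame with columns `e_value` and `length`.
#' @param eThreshold e-value cutoff (default 1e-4).
#' @param minLength minimum alignment length (default 10).
#' @return Filtered data.frame.
#' @export
filterHits <- function(hits, eThreshold = 1e-4, minLength = 10L) {
  if (!nrow(hits)) return(hits)
  hits[hits$e_value < eThreshold & hits$length >= minLength, , drop = FALSE]
}

#' Cumulative hit counts per e-value threshold
#'
#' For each threshold (sorted most stringent first, i.e. ascending), the
#' number of hits with e-value below it; counts are non-decreasing down the
#' ladder by construction.
#'
#' @param hits data.frame with column `e_value` (already length-filtered).
#' @param thresholds ascending e-value thresholds.
#' @return data.frame with columns `threshold` and `count`.
#' @export
cumulativeHitTable <- function(hits,
                               thresholds = c(1e-25, 1e-20, 1e-15, 1e-10,
                                              1e-8, 1e-6, 1e-5, 1e-4)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be sorted most stringent (smallest) first")
  counts <- vapply(thresholds, function(th)
    if (nrow(hits)) sum(hits$e_value < th) else 0L, numeric(1))
  data.frame(threshold = thresholds, count = as.integer(counts))
}

## Run one query against one database; returns a hits data.frame.
searchDatabase <- function(query, queryId, db, matrix, ka, nResidues,
                           gapOpen, gapExtend) {
  rows <- lapply(seq_along(db), function(j) {
    al <- localAlign(query, as.character(db[[j]]), matrix,
                     gapOpen = gapOpen, gapExtend = gapExtend)
    if (al$length == 0L) return(NULL)
    e <- evalueOf(al$score, nchar(query), nResidues, ka)
    data.frame(query_id = queryId, subject_id = names(db)[j],
               score = al$score,
               bit_score = (ka@lambda * al$score - log(ka@K)) / log(2),
               e_value = e, length = al$length, identity = al$identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), bit_score = numeric(),
                      e_value = numeric(), length = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  out
}

#' Evaluate a scoring matrix against positive and decoy databases
#'
#' Aligns every query against every sequence of a positive database and of
#' a decoy database, assigns Karlin-Altschul e-values (n = total residue
#' count of the respective database), applies the e-value and minimum-
#' length filters, and tabulates cumulative hit counts per threshold for
#' the two databases separately.  Matrices whose expected score is
#' non-negative are refused up front.
#'
#' @param queries named [Biostrings::AAStringSet] (e.g. concatenated TM
#'   segments of template proteins).
#' @param positiveDb,decoyDb named [Biostrings::AAStringSet] databases.
#' @param matrix a [ScoringMatrix-class].
#' @param gapOpen,gapExtend affine gap penalties.
#' @param thresholds ascending e-value ladder for the tables.
#' @param eThreshold,minLength hit filters (see [filterHits()]).
#' @return List with elements `positive` and `decoy` (cumulative
#'   [cumulativeHitTable()] tables), `positiveHits`, `decoyHits` (filtered
#'   hit data.frames) and `params` (the [KarlinAltschul-class] used).
#' @export
evaluateMatrix <- function(queries, positiveDb, decoyDb, matrix,
                           gapOpen = 11, gapExtend = 1,
                           thresholds = c(1e-25, 1e-20, 1e-15, 1e-10,
                                          1e-8, 1e-6, 1e-5, 1e-4),
                           eThreshold = 1e-4, minLength = 10L) {
  stopifnot(length(queries) >= 1, length(positiveDb) >= 1,
            length(decoyDb) >= 1)
  if (expectedScore(matrix) >= 0)
    stop("invalid scoring matrix: expected score must be negative for ",
         "local-alignment statistics")
  ka <- karlinAltschulParams(matrix)
  run <- function(db) {
    nres <- sum(Biostrings::width(db))
    hits <- do.call(rbind, lapply(seq_along(queries), function(i)
      searchDatabase(as.character(queries[[i]]), names(queries)[i], db,
                     matrix, ka, nres, gapOpen, gapExtend)))
    filterHits(hits, eThreshold = max(thresholds, eThreshold),
               minLength = minLength)
  }
  pos <- run(positiveDb)
  dec <- run(decoyDb)
  list(positive = cumulativeHitTable(pos, thresholds),
       decoy = cumulativeHitTable(dec, thresholds),
       positiveHits = pos, decoyHits = dec, params = ka)
}
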