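## Column-matrix view of an equal-width AAStringSet alignment.
alignmentMatrix <- function(aln) {
  stopifnot(is(aln, "AAStringSet"))
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L) stop("alignment has ragged lengths")
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  m
}

asAlignment <- function(m) {
  Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
}

#' Extract transmembrane alignment columns
#'
#' Selects the alignment columns whose template (first-sequence) ungapped
#' position lies in a transmembrane segment of the annotation, optionally
#' restricted to interior-facing or lipid-facing positions, concatenated in
#' template order.  Columns where the template carries a gap are never TM
#' columns.
#'
#' @param aln equal-width [Biostrings::AAStringSet]; the first sequence is
#'   the annotated template.
#' @param ann a [TMAnnotation-class] in the template's ungapped coordinates.
#' @param facing `"all"`, `"in"` (barrel interior) or `"out"` (lipid-facing).
#' @return Sub-alignment as an [Biostrings::AAStringSet] (width may be 0).
#' @export
extractTMColumns <- function(aln, ann, facing = c("all", "in", "out")) {
  facing <- match.arg(facing)
  m <- alignmentMatrix(aln)
  tmpl <- m[1L, ]
  ungapped_cols <- which(tmpl != "-")       # column index per template position
  seg <- ann@segments
  tm_pos <- unlist(lapply(seq_len(nrow(seg)), function(i)
    seq.int(seg$start[i], seg$end[i] - 1L)), use.names = FALSE)
  if (length(tm_pos) && max(tm_pos) >= length(ungapped_cols))
    stop(sprintf("annotation position %d beyond template length %d",
                 max(tm_pos), length(ungapped_cols)))
  keep <- switch(facing,
                 all = rep(TRUE, length(tm_pos)),
                 `in` = ann@facing == "I",
                 out = ann@facing == "O")
  cols <- ungapped_cols[tm_pos[keep] + 1L]
  sub <- m[, cols, drop = FALSE]
  out <- Biostrings::AAStringSet(apply(sub, 1L, paste, collapse = ""))
  if (ncol(sub) == 0L)
    out <- Biostrings::AAStringSet(rep("", nrow(m)))
  names(out) <- rownames(m)
  out
}

#' @describeIn composition amino-acid composition of an alignment: relative
#'   frequencies of the 20 residues across all sequences, gaps and 'X'
#'   excluded.
#' @export
setMethod("composition", "AAStringSet", function(object) {
  chars <- unlist(strsplit(as.character(object), ""), use.names = FALSE)
  chars <- chars[chars %in% AA_ORDER]
  if (!length(chars)) stop("alignment contains no residues (all gaps/'X')")
  tab <- table(factor(chars, levels = AA_ORDER))
  stats::setNames(as.numeric(tab) / length(chars), AA_ORDER)
})

#' Mean GES hydrophobicity
#'
#' Mean per-residue Goldman-Engelman-Steitz transfer free energy of the
#' residues in `x` (kcal/mol; positive hydrophobic, negative polar).  Gaps
#' and 'X' are ignored.
#'
#' @param x character vector of sequences, or an [Biostrings::AAStringSet].
#' @param scale the hydrophobicity scale; defaults to [gesScale()].
#' @return Scalar mean transfer free energy.
#' @export
gesHydrophobicity <- function(x, scale = gesScale()) {
  if (is(x, "AAStringSet") || is(x, "AAString")) x <- as.character(x)
  chars <- unlist(strsplit(toupper(x), ""), use.names = FALSE)
  chars <- chars[chars %in% AA_ORDER]
  if (!length(chars)) stop("no residues to score")
  mean(scale[chars])
}

#' Per-protein dataset statistics
#'
#' Computes, for one template protein, the counts and GES hydrophobicity
#' summaries of its transmembrane partition: number of TM residues, total
#' residues, strands, interior-facing and lipid-facing residues, and the
#' mean GES hydrophobicity of the template's TM residues overall and per
#' facing class.
#'
#' @param aln alignment whose first sequence is the template.
#' @param ann a [TMAnnotation-class].
#' @param totalLength total residue count of the (full-length) template
#'   protein; defaults to the template's ungapped length in `aln`.
#' @return One-row data.frame with columns `protein`, `n_tm`, `n_total`,
#'   `n_strands`, `n_in`, `n_out`, `hydro_all`, `hydro_in`, `hydro_out`.
#' @export
datasetStats <- function(aln, ann, totalLength = NULL) {
  m <- alignmentMatrix(aln)
  tmpl_full <- paste(m[1L, m[1L, ] != "-"], collapse = "")
  if (is.null(totalLength)) totalLength <- nchar(tmpl_full)
  seg <- ann@segments
  tm_pos <- unlist(lapply(seq_len(nrow(seg)), function(i)
    seq.int(seg$start[i], seg$end[i] - 1L)), use.names = FALSE)
  tm_res <- strsplit(tmpl_full, "")[[1]][tm_pos + 1L]
  fac <- ann@facing
  data.frame(protein = ann@proteinId,
             n_tm = length(tm_pos),
             n_total = totalLength,
             n_strands = nrow(seg),
             n_in = sum(fac == "I"),
             n_out = sum(fac == "O"),
             hydro_all = gesHydrophobicity(paste(tm_res, collapse = "")),
             hydro_in = gesHydrophobicity(paste(tm_res[fac == "I"], collapse = "")),
             hydro_out = gesHydrophobicity(paste(tm_res[fac == "O"], collapse = "")),
             stringsAsFactors = FALSE)
}

#' Aggregate per-protein statistics across templates
#'
#' Arithmetic means of the per-protein columns, rounded the way summary
#' tables of template sets are conventionally printed: residue/strand counts
#' to the nearest integer, hydrophobicities to two decimals.  Also reports
#' the total strand count across proteins.
#'
#' @param stats data.frame of [datasetStats()] rows (one per protein).
#' @return List with `mean` (one-row data.frame of rounded means) and
#'   `total_strands` (sum over proteins).
#' @export
aggregateStats <- function(stats) {
  stopifnot(nrow(stats) >= 1L)
  mean_row <- data.frame(
    n_tm = round(mean(stats$n_tm)),
    n_total = round(mean(stats$n_total)),
    n_strands = round(mean(stats$n_strands)),
    n_in = round(mean(stats$n_in)),
    n_out = round(mean(stats$n_out)),
    hydro_all = round(mean(stats$hydro_all), 2),
    hydro_in = round(mean(stats$hydro_in), 2),
    hydro_out = round(mean(stats$hydro_out), 2))
  list(mean = mean_row, total_strands = sum(stats$n_strands))
}

#' Percent sequence identity
#'
#' Identities divided by the number of comparable (non-double-gap) columns,
#' times 100.  Unaligned sequences are first globally aligned with a
#' BLOSUM62 Needleman-Wunsch alignment.
#'
#' @param a,b sequences (character or AAString); equal lengths if `aligned`.
#' @param aligned are `a` and `b` already aligned to each other?
#' @return Identity in \[0, 100\].
#' @export
percentIdentity <- function(a, b, aligned = TRUE) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!aligned) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = get("BLOSUM62"),
                                        gapOpening = 11, gapExtension = 1)
    a <- as.character(Biostrings::pattern(pa))
    b <- as.character(Biostrings::subject(pa))
  }
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  comparable <- !(ca == "-" & cb == "-")
  if (!any(comparable)) stop("no comparable columns")
  100 * sum(ca == cb & ca != "-" & comparable) / sum(comparable)
}

#' Select homologs by identity bins
#'
#' Implements the template-homolog selection rule: within each 10%-identity
#' bin from \[30, 40) up to \[80, 90), keep at most two hits (highest identity
#' first; ties broken by input order); discard hits outside \[30, 90) and
#' hits with more than two gaps in any transmembrane segment.
#'
#' @param hits data.frame with columns `id` and `identity` (percent).
#' @param gapsPerSegment list (parallel to `hits` rows) of integer vectors
#'   giving the gap count in each TM segment of that hit's alignment; or
#'   NULL to skip the gap filter.
#' @param maxGaps maximum allowed gaps per segment (default 2).
#' @param binBreaks lower bin edges (default `seq(30, 80, 10)`), each bin 10
#'   wide, upper bound exclusive.
#' @param perBin hits kept per bin (default 2).
#' @return Character vector of selected ids.
#' @export
selectHomologs <- function(hits, gapsPerSegment = NULL, maxGaps = 2L,
                           binBreaks = seq(30, 80, 10), perBin = 2L) {
  stopifnot(all(hits$identity >= 0), all(hits$identity <= 100))
  keep_gap <- if (is.null(gapsPerSegment)) rep(TRUE, nrow(hits))
              else vapply(gapsPerSegment,
                          function(g) !length(g) || max(g) <= maxGaps,
                          logical(1))
  selected <- character()
  for (lo in binBreaks) {
    in_bin <- which(hits$identity >= lo & hits$identity < lo + 10 & keep_gap)
    if (!length(in_bin)) next
    ord <- in_bin[order(-hits$identity[in_bin], in_bin)]
    selected <- c(selected, hits$id[utils::head(ord, perBin)])
  }
  selected
}
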