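#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file of amino-acid sequences, upper-casing residues and
#' rejecting any character outside the 20 canonical residues, the gap '-'
#' and the unknown code 'X'.  Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] with one element per record.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  bad <- validateFastaLines(lines)
  if (!is.null(bad))
    stop(sprintf("parse error at line %d of %s: %s", bad$line, path, bad$why))
  x <- Biostrings::readAAStringSet(path)
  x <- Biostrings::AAStringSet(toupper(as.character(x)))
  ## keep only the first whitespace-delimited token as the id, FASTA-style
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

## Scan FASTA lines for structural problems and illegal residues; returns
## NULL if clean, else list(line=, why=).
validateFastaLines <- function(lines) {
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^>", ln)) {
      if (nchar(sub("\\s.*$", "", sub("^>", "", ln))) == 0L)
        return(list(line = i, why = "empty record id"))
      seen_header <- TRUE
    } else if (nzchar(trimws(ln))) {
      if (!seen_header)
        return(list(line = i, why = "sequence data before first '>' header"))
      chars <- strsplit(toupper(trimws(ln)), "")[[1]]
      illegal <- setdiff(chars, AA_ALLOWED)
      if (length(illegal))
        return(list(line = i,
                    why = paste0("illegal residue character(s): ",
                                 paste(unique(illegal), collapse = ", "))))
    }
  }
  if (!seen_header) return(list(line = 1L, why = "no FASTA records"))
  NULL
}

#' Read a multiple sequence alignment
#'
#' Reads a gapped protein alignment in FASTA or Clustal format and checks
#' that all sequences have equal length.
#'
#' @param path Path to the alignment file.
#' @param dialect `"fasta"` or `"clustal"`.
#' @return An equal-width [Biostrings::AAStringSet] (the labeled alignment).
#' @export
readAlignment <- function(path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  x <- switch(dialect,
              fasta = readProteinFasta(path),
              clustal = readClustal(path))
  w <- Biostrings::width(x)
  if (length(unique(w)) > 1L) {
    off <- names(x)[w != stats::median(w)]
    stop("alignment has ragged sequence lengths; offending ids: ",
         paste(off, collapse = ", "))
  }
  if (length(x) == 0L || w[1] < 1L) stop("empty alignment")
  x
}

## Minimal Clustal block-format parser: a header line, then blocks of
## "<name><whitespace><chunk>" lines separated by blank lines; conservation
## lines (leading whitespace) are skipped.
readClustal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[[1]], ignore.case = TRUE))
    stop("not a Clustal file (missing CLUSTAL header line): ", path)
  seqs <- list()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next                  # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)", ln))[[1]]
    if (length(m) < 3L) next
    chunk <- toupper(gsub("[0-9]", "", m[[3]]))  # strip trailing counters
    illegal <- setdiff(strsplit(chunk, "")[[1]], c(AA_ALLOWED, "."))
    if (length(illegal))
      stop(sprintf("parse error at line %d of %s: illegal residue character(s): %s",
                   i, path, paste(unique(illegal), collapse = ", ")))
    chunk <- gsub("\\.", "-", chunk)
    nm <- m[[2]]
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]], chunk)
  }
  if (!length(seqs)) stop("no sequences found in Clustal file: ", path)
  Biostrings::AAStringSet(unlist(seqs))
}

#' Read a phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the checks the estimation pipeline needs:
#' leaf names must be unique, branch lengths non-negative; a missing branch
#' length is replaced by 0 with a warning.
#'
#' @param path Path to a Newick file (or use `text=` to pass a string).
#' @param text Optional Newick string instead of a file.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
readNewickTree <- function(path, text = NULL) {
  tr <- if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  } else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  miss <- is.na(tr$edge.length) | is.nan(tr$edge.length)
  if (any(miss)) {
    warning(sum(miss), " missing branch length(s) defaulted to 0")
    tr$edge.length[miss] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

#' Write a phylogenetic tree to Newick
#'
#' @param tree a `"phylo"` object
#' @param path output file
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a scoring matrix in NCBI matrix text format
#'
#' The format read by standard search tools: '#'-prefixed comment lines, a
#' header row of one-letter codes, then one labelled row of whitespace-
#' separated integers per residue.
#'
#' @param matrix a [ScoringMatrix-class] (or a bare symmetric integer
#'   20x20 matrix with canonical dimnames).
#' @param path output file.
#' @param comments character vector of comment lines (written verbatim after
#'   a '# ' prefix).
#' @export
writeScoringMatrix <- function(matrix, path, comments = character()) {
  s <- if (is(matrix, "ScoringMatrix")) matrix@scores else matrix
  if (!is.matrix(s) || !identical(dim(s), c(20L, 20L)))
    stop("scoring matrix must be 20x20")
  if (any(s != round(s))) stop("scoring matrix entries must be integers")
  if (!isTRUE(all.equal(s, t(s))))
    stop("scoring matrix must be symmetric")
  if (!identical(rownames(s), AA_ORDER)) s <- s[AA_ORDER, AA_ORDER]
  con <- file(path, "w")
  on.exit(close(con))
  if (is(matrix, "ScoringMatrix"))
    comments <- c(comments,
                  sprintf("evolutionary time t = %g (units: expected changes per 100 sites)",
                          matrix@time),
                  sprintf("scale = %g bits per score unit", matrix@scaleBits))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines(paste0("  ", paste(sprintf("%3s", AA_ORDER), collapse = " ")), con)
  for (i in seq_len(20L))
    writeLines(paste0(AA_ORDER[i], " ",
                      paste(sprintf("%3d", as.integer(s[i, ])), collapse = " ")),
               con)
  invisible(path)
}

#' Read a scoring matrix in NCBI matrix text format
#'
#' @param path matrix file.
#' @return A list with `scores` (20x20 integer matrix in canonical order)
#'   and `comments` (comment lines with the '#' prefix stripped).
#' @export
readScoringMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- sub("^#\\s?", "", lines[grepl("^#", lines)])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 21L) stop("malformed matrix file: ", path)
  header <- strsplit(trimws(body[[1]]), "\\s+")[[1]]
  if (length(header) != 20L || anyDuplicated(header) ||
      !all(header %in% AA_ORDER))
    stop("matrix header must list the 20 canonical one-letter codes")
  s <- matrix(NA_integer_, 20L, 20L, dimnames = list(header, header))
  for (i in seq_len(20L)) {
    f <- strsplit(trimws(body[[i + 1L]]), "\\s+")[[1]]
    if (length(f) != 21L) stop("malformed matrix row: ", body[[i + 1L]])
    vals <- suppressWarnings(as.integer(f[-1]))
    if (anyNA(vals)) stop("non-integer score in row ", f[[1]])
    s[f[[1]], ] <- vals
  }
  s <- s[AA_ORDER, AA_ORDER]
  list(scores = s, comments = comments)
}

#' Read a transmembrane annotation file
#'
#' Tab-separated rows: `protein_id  strand_index  start  end  facing`, with
#' 0-based half-open `[start, end)` coordinates on the ungapped template
#' sequence and `facing` a string over \{I, O\} of length `end - start`.
#'
#' @param path annotation TSV.
#' @return A [TMAnnotation-class] (single protein per file).
#' @export
readTMAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("protein_id", "strand", "start", "end",
                                        "facing"),
                          colClasses = c("character", "integer", "integer",
                                         "integer", "character"))
  if (length(unique(df$protein_id)) != 1L)
    stop("annotation file must describe a single protein")
  TMAnnotation(df$protein_id[[1]],
               strand = df$strand, start = df$start, end = df$end,
               facing = df$facing)
}

#' Construct a TMAnnotation
#'
#' @param proteinId template identifier.
#' @param strand integer strand indices.
#' @param start,end 0-based half-open segment coordinates.
#' @param facing per-segment facing strings over \{I, O\}, each of length
#'   `end - start`.
#' @return A [TMAnnotation-class].
#' @export
TMAnnotation <- function(proteinId, strand, start, end, facing) {
  stopifnot(length(strand) == length(start), length(start) == length(end),
            length(end) == length(facing))
  o <- order(start)
  strand <- strand[o]; start <- start[o]; end <- end[o]; facing <- facing[o]
  for (i in seq_along(facing))
    if (nchar(facing[[i]]) != end[[i]] - start[[i]])
      stop(sprintf("facing string length %d != segment width %d (strand %d)",
                   nchar(facing[[i]]), end[[i]] - start[[i]], strand[[i]]))
  ann <- new("TMAnnotation", proteinId = proteinId,
             segments = data.frame(strand = strand, start = start, end = end),
             facing = strsplit(paste(facing, collapse = ""), "")[[1]])
  validObject(ann)
  ann
}

#' Write a TMAnnotation to TSV
#'
#' @param ann a [TMAnnotation-class]
#' @param path output file
#' @export
writeTMAnnotation <- function(ann, path) {
  seg <- ann@segments
  fac <- ann@facing
  off <- cumsum(c(0L, seg$end - seg$start))
  rows <- vapply(seq_len(nrow(seg)), function(i) {
    paste(ann@proteinId, seg$strand[i], seg$start[i], seg$end[i],
          paste(fac[(off[i] + 1L):off[i + 1L]], collapse = ""), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
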