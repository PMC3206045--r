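#' Write an estimated rate matrix as TSV
#'
#' 20x20 table of off-diagonal instantaneous rates in display units
#' (x 1e4), with the composition and any provenance recorded in '#'
#' comment lines.
#'
#' @param Q a [RateMatrix-class].
#' @param path output file.
#' @param provenance extra comment lines.
#' @export
writeRateTable <- function(Q, path, provenance = character()) {
  stopifnot(is(Q, "RateMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in provenance) writeLines(paste("#", cm), con)
  writeLines(paste("# rates in units of", format(DISPLAY_SCALE),
                   "x expected changes per 100 sites"), con)
  writeLines(paste("# pi:", paste(format(Q@pi, digits = 10), collapse = " ")),
             con)
  m <- Q@Q * DISPLAY_SCALE
  writeLines(paste(c("", AA_ORDER), collapse = "\t"), con)
  for (i in seq_len(20L))
    writeLines(paste(c(AA_ORDER[i], format(m[i, ], digits = 8)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a rate matrix TSV written by [writeRateTable()]
#'
#' @param path rate table file.
#' @return A [RateMatrix-class].
#' @export
readRateTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pil <- grep("^# pi:", lines, value = TRUE)
  if (!length(pil)) stop("rate table lacks the '# pi:' composition line")
  pi <- as.numeric(strsplit(sub("^# pi:\\s*", "", pil[[1]]), "\\s+")[[1]])
  body <- lines[!grepl("^#", lines)]
  m <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                         header = TRUE, row.names = 1L)
  m <- as.matrix(m)[AA_ORDER, AA_ORDER] / DISPLAY_SCALE
  names(pi) <- AA_ORDER
  S <- sweep(m, 2L, pi, "/")
  S <- (S + t(S)) / 2
  diag(S) <- 0
  buildRateMatrix(S, pi)
}

#' Read a flat key=value run configuration file
#'
#' Lines of `key = value`; '#' comments ignored.  Comma-separated values
#' become vectors.  Paths are interpreted relative to the config file's
#' directory.
#'
#' @param path config file.
#' @return Named list of (character) values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(x)
    c(trimws(x[[1]]), trimws(paste(x[-1], collapse = "="))))
  cfg <- stats::setNames(lapply(kv, function(x)
    trimws(strsplit(x[[2]], ",")[[1]])), vapply(kv, `[[`, "", 1L))
  attr(cfg, "dir") <- dirname(normalizePath(path))
  cfg
}

configHash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

#' Run the full estimation pipeline
#'
#' For each template protein (alignment + tree + TM annotation) and each
#' facing class, extracts the TM sub-alignment, samples the posterior over
#' exchangeabilities, applies the valid-pairs correction, averages across
#' proteins, derives the scoring matrix at the configured evolutionary
#' time, and clusters the substitution profiles.  All outputs carry
#' provenance comment headers (seed, config hash); a stage failure aborts
#' with an error naming the stage.
#'
#' @param config list with elements `alignments`, `trees`, `annotations`
#'   (parallel path vectors), and optionally `facings` (default all three),
#'   `times` (named, default all=40, in=40, out=36), `nSteps`,
#'   `burnInFraction`, `thin`, `proposalScale`, `priorMode`, `seed`,
#'   `outDir`.  Alternatively the path of a [readRunConfig()] file.
#' @return Invisible manifest: named list of written file paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- normaliseConfig(readRunConfig(config))
  defaults <- list(facings = c("all", "in", "out"),
                   times = c(all = 40, `in` = 40, out = 36),
                   nSteps = 2000, burnInFraction = 0.2, thin = 10,
                   proposalScale = 0.3, priorMode = "reference", seed = 1L,
                   outDir = "bbtm_out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  np <- length(config$alignments)
  stage("io_formats", {
    stopifnot(np >= 1, length(config$trees) == np)
    alns <- lapply(config$alignments, readAlignment)
    trees <- lapply(config$trees, readNewickTree)
  })
  stage("tm_dataset", {
    if (is.null(config$annotations) || length(config$annotations) != np)
      stop("annotation paths missing or not one per protein")
    anns <- lapply(config$annotations, readTMAnnotation)
  })
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(sprintf("bbTM pipeline seed=%s config=%s", config$seed,
                    configHash(config[setdiff(names(config), "outDir")])),
            sprintf("run at %s", format(Sys.time(), "%Y-%m-%d")))
  manifest <- list()
  prior <- priorSpec(config$priorMode)
  for (facing in config$facings) {
    rateL <- list(); weightL <- list(); pooled <- NULL
    for (p in seq_len(np)) {
      sub <- stage("tm_dataset", extractTMColumns(alns[[p]], anns[[p]], facing))
      if (Biostrings::width(sub)[1] == 0L)
        stop(sprintf("pipeline stage 'tm_dataset' failed: no %s-facing columns for protein %d",
                     facing, p), call. = FALSE)
      est <- stage("rate_estimation", {
        smp <- mcmcSampleRates(sub, trees[[p]], prior = prior,
                               nSteps = as.numeric(config$nSteps),
                               burnInFraction = as.numeric(config$burnInFraction),
                               thin = as.numeric(config$thin),
                               proposalScale = as.numeric(config$proposalScale),
                               seed = as.integer(config$seed) + 1000L * p +
                                 match(facing, c("all", "in", "out")))
        message(sprintf("protein %d facing %s: %d columns, acceptance %.1f%%",
                        p, facing, Biostrings::width(sub)[1],
                        100 * acceptanceRate(smp)))
        list(Q = posteriorMeanRates(smp), W = validPairWeights(sub))
      })
      rateL[[p]] <- est$Q; weightL[[p]] <- est$W
      pooled <- if (is.null(pooled)) composition(sub) * length(sub)
                else pooled + composition(sub) * length(sub)
      qp <- file.path(config$outDir,
                      sprintf("protein%d_%s_Q.tsv", p, facing))
      writeRateTable(est$Q, qp, provenance = prov)
      manifest[[sprintf("rates_protein%d_%s", p, facing)]] <- qp
    }
    avg <- stage("rate_estimation",
                 averageRateMatrices(rateL, weightL, pooled / sum(pooled)))
    qa <- file.path(config$outDir, sprintf("bbTM_%s_Q.tsv", facing))
    writeRateTable(avg, qa, provenance = prov)
    manifest[[paste0("rates_", facing)]] <- qa
    sm <- stage("scoring_matrices",
                deriveScoringMatrix(avg, time = config$times[[facing]]))
    mp <- file.path(config$outDir, sprintf("bbTM_%s.mat", facing))
    writeScoringMatrix(sm, mp, comments = prov)
    manifest[[paste0("matrix_", facing)]] <- mp
    nw <- file.path(config$outDir, sprintf("cluster_%s.nwk", facing))
    stage("profile_clustering", linkageNewick(profileLinkage(avg), nw))
    manifest[[paste0("cluster_", facing)]] <- nw
  }
  mpath <- file.path(config$outDir, "manifest.tsv")
  utils::write.table(data.frame(key = names(manifest),
                                path = unlist(manifest)),
                     mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$manifest <- mpath
  invisible(manifest)
}

## Coerce the character-valued flat-file config into typed fields.
normaliseConfig <- function(cfg) {
  dir <- attr(cfg, "dir")
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(dir, p))
  out <- list()
  if (!is.null(cfg$alignments)) out$alignments <- rel(cfg$alignments)
  if (!is.null(cfg$trees)) out$trees <- rel(cfg$trees)
  if (!is.null(cfg$annotations)) out$annotations <- rel(cfg$annotations)
  if (!is.null(cfg$facings)) out$facings <- cfg$facings
  if (!is.null(cfg$times))
    out$times <- stats::setNames(as.numeric(cfg$times),
                                 c("all", "in", "out")[seq_along(cfg$times)])
  for (nm in c("nSteps", "burnInFraction", "thin", "proposalScale", "seed"))
    if (!is.null(cfg[[nm]])) out[[nm]] <- as.numeric(cfg[[nm]])
  if (!is.null(cfg$priorMode)) out$priorMode <- cfg$priorMode
  if (!is.null(cfg$outDir)) out$outDir <- rel(cfg$outDir)
  out
}
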