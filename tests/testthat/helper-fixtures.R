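AA <- get("AA_ORDER", asNamespace("bbTM"))

## random strictly-positive composition
randomComposition <- function(seed = 1) {
  set.seed(seed)
  p <- runif(20, 0.2, 1)
  stats::setNames(p / sum(p), AA)
}

## random dense reversible RateMatrix
randomRateMatrix <- function(seed = 1) {
  set.seed(seed)
  S <- matrix(runif(400, 0.05, 2), 20, 20)
  S <- S + t(S); diag(S) <- 0
  dimnames(S) <- list(AA, AA)
  buildRateMatrix(S, randomComposition(seed + 1))
}

## ground-truth generator used in recovery experiments: WAG exchangeabilities
## (distinct from the mtREV prior centre) with their own equilibrium
wagRateMatrix <- function() {
  getModelAA <- get("getModelAA", envir = asNamespace("phangorn"))
  Q <- NULL; bf <- NULL
  invisible(eval(getModelAA("WAG", bf = TRUE, Q = TRUE)))
  S <- matrix(0, 20, 20, dimnames = list(AA, AA))
  S[lower.tri(S)] <- Q
  S <- S + t(S)
  S <- S / mean(S[upper.tri(S)])
  buildRateMatrix(S, stats::setNames(bf, AA))
}

writeTempFasta <- function(named_seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(named_seqs)),
                             unname(named_seqs))), path)
  path
}

asAln <- function(named_seqs) {
  x <- Biostrings::AAStringSet(unname(named_seqs))
  names(x) <- names(named_seqs)
  x
}

## ---- independent oracles ----

## matrix exponential by truncated Taylor series
seriesExpm <- function(M, t, kmax = 40) {
  acc <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(kmax)) {
    term <- term %*% (M * t) / k
    acc <- acc + term
  }
  acc
}

## pruning-free likelihood: enumerate all internal-node state assignments
enumLogLikelihood <- function(aln, tree, Q) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  pi <- composition(Q)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) {
    P1 <- seriesExpm(rates(Q), t, kmax = 60)
    dimnames(P1) <- list(AA, AA); P1
  })
  root <- ntip + 1L
  total <- 0
  for (col in seq_len(ncol(m))) {
    states <- match(m[, col], AA)            # NA = missing
    lik <- 0
    grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
    for (g in seq_len(nrow(grid))) {
      assign_int <- grid[g, ]
      p <- unname(pi[assign_int[1]])         # root prior (root = ntip+1)
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        ps <- assign_int[par - ntip]
        if (ch <= ntip) {
          cs <- states[match(tree$tip.label[ch], rownames(m))]
          p <- p * (if (is.na(cs)) 1 else P[[e]][ps, cs])
        } else {
          p <- p * P[[e]][ps, assign_int[ch - ntip]]
        }
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

## exhaustive local alignment: enumerate all substring pairs and all affine
## alignment paths between them (no dynamic programming)
bruteLocalAlign <- function(a, b, s, gapOpen, gapExtend) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- 0
  enum <- function(i, j, iend, jend, sc, last) {
    if (i > iend && j > jend) { best <<- max(best, sc); return(invisible()) }
    if (i <= iend && j <= jend)
      enum(i + 1, j + 1, iend, jend, sc + s[a[i], b[j]], "m")
    if (i <= iend)
      enum(i + 1, j, iend, jend,
           sc - gapExtend - if (last == "d") 0 else gapOpen, "d")
    if (j <= jend)
      enum(i, j + 1, iend, jend,
           sc - gapExtend - if (last == "i") 0 else gapOpen, "i")
    invisible()
  }
  for (i1 in seq_along(a)) for (i2 in i1:length(a))
    for (j1 in seq_along(b)) for (j2 in j1:length(b))
      enum(i1, j1, i2, j2, 0, "m")
  best
}

## brute-force single linkage over a labelled distance matrix
bruteSingleLinkage <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1) {
    bestd <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        d <- min(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; bi <- i; bj <- j }
      }
    merges[[length(merges) + 1]] <-
      list(a = clusters[[bi]], b = clusters[[bj]], height = bestd)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  merges
}

## valid-pair weights by explicit enumeration of all unordered sequence pairs
bruteValidPairWeights <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  N <- nrow(m); C <- ncol(m)
  W <- matrix(0, 20, 20, dimnames = list(AA, AA))
  for (k in seq_len(C)) {
    cnt <- matrix(0, 20, 20, dimnames = list(AA, AA))
    for (p in seq_len(N - 1)) for (q in (p + 1):N) {
      x <- m[p, k]; y <- m[q, k]
      if (!(x %in% AA) || !(y %in% AA)) next
      cnt[x, y] <- cnt[x, y] + 1
      if (x != y) cnt[y, x] <- cnt[y, x] + 1
    }
    W <- W + cnt / (N * (N - 1) / 2)
  }
  W / C
}

## the narrative lipid-facing rate fixture as a display-rate profile matrix
narrativeOutRates <- function() {
  path <- system.file("extdata", "tm_out_rates_narrative.tsv",
                      package = "bbTM")
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  R <- matrix(0, 20, 20, dimnames = list(AA, AA))
  for (k in seq_len(nrow(df)))
    R[df$a[k], df$b[k]] <- R[df$b[k], df$a[k]] <- df$rate[k]
  diag(R) <- NA
  R
}

## printed per-template statistics table (input data for aggregation checks)
templateStatsTable <- function() {
  utils::read.table(system.file("extdata", "template_tm_stats.tsv",
                                package = "bbTM"),
                    header = TRUE, stringsAsFactors = FALSE)
}

## small synthetic template alignment + annotation shaped like an 8-strand
## barrel: `nIn`/`nOut` interior/lipid residues over `nStrands` strands
barrelFixture <- function(nStrands = 8, strandLens = NULL, totalLength = 172,
                          seed = 5) {
  set.seed(seed)
  if (is.null(strandLens))
    strandLens <- rep(10L, nStrands) + c(rep(2L, 2), rep(0L, nStrands - 2))
  tm <- sum(strandLens)
  stopifnot(totalLength >= tm + nStrands * 2)
  gaplen <- (totalLength - tm) %/% (nStrands + 1)
  starts <- integer(nStrands); pos <- gaplen
  for (i in seq_len(nStrands)) { starts[i] <- pos; pos <- pos + strandLens[i] + gaplen }
  facing <- vapply(strandLens, function(L)
    paste(rep_len(c("I", "O"), L), collapse = ""), character(1))
  ann <- TMAnnotation("toy", strand = seq_len(nStrands), start = starts,
                      end = starts + strandLens, facing = facing)
  tmpl <- paste(sample(AA, totalLength, replace = TRUE), collapse = "")
  hom <- vapply(1:2, function(i)
    paste(sample(AA, totalLength, replace = TRUE), collapse = ""), character(1))
  aln <- asAln(c(toy = tmpl, hom1 = hom[1], hom2 = hom[2]))
  list(aln = aln, ann = ann)
}
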