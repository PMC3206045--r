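test_that("valid-pair weights match explicit pair enumeration", {
  ## one column holding one (i, j) pair out of one possible pair
  w <- validPairWeights(asAln(c(x = "A", y = "V")))
  expect_equal(w["A", "V"], 1)
  expect_equal(w["V", "A"], 1)
  ## all-identical column never certifies a heterogeneous pair
  w2 <- validPairWeights(asAln(c(x = "L", y = "L", z = "L")))
  expect_equal(unname(w2["L", AA != "L"]), rep(0, 19))
  expect_equal(w2["L", "L"], 1)
  ## random alignments (with gaps) vs brute-force pair enumeration
  set.seed(12)
  for (rep in 1:3) {
    seqs <- vapply(1:4, function(i)
      paste(sample(c(AA, "-"), 5, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- paste0("s", 1:4)
    aln <- asAln(seqs)
    expect_equal(validPairWeights(aln), bruteValidPairWeights(aln),
                 tolerance = 1e-12)
  }
  expect_error(validPairWeights(asAln(c(only = "ACD"))), "at least 2")
})

test_that("valid-pair weights ignore sequence order and column order", {
  set.seed(41)
  seqs <- vapply(1:5, function(i)
    paste(sample(AA, 8, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:5)
  aln <- asAln(seqs)
  w <- validPairWeights(aln)
  expect_equal(validPairWeights(aln[c(3, 1, 5, 2, 4)]), w)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  shuf <- asAln(vapply(seqs, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), character(1)))
  expect_equal(validPairWeights(shuf), w)
})

test_that("the valid-pairs correction modulates, zeroes and rebalances", {
  Q <- randomRateMatrix(8)
  W1 <- matrix(1, 20, 20, dimnames = list(AA, AA))
  expect_equal(rates(applyValidPairs(Q, W1)), rates(Q), tolerance = 1e-12)
  W0 <- W1; W0["A", "V"] <- W0["V", "A"] <- 0
  Qc <- applyValidPairs(Q, W0)
  expect_equal(rates(Qc)["A", "V"], 0)
  expect_equal(rates(Qc)["V", "A"], 0)
  expect_true(validObject(Qc))              # balance + normalisation restored
  expect_error(applyValidPairs(Q, W1 * 0), "zero everywhere")
  Wbad <- W1; Wbad[1, 2] <- 0.5
  expect_error(applyValidPairs(Q, Wbad), "symmetric")
})

test_that("posterior means reduce to draws and averaging is idempotent", {
  Q <- randomRateMatrix(3)
  pi <- composition(Q)
  S1 <- matrix(1, 20, 20); diag(S1) <- 0; dimnames(S1) <- list(AA, AA)
  S2 <- S1 * 3; S2["A", "V"] <- S2["V", "A"] <- 9
  smp1 <- new("PosteriorSample", draws = list(S1), logPost = 0,
              acceptanceRate = 1, pi = pi)
  expect_equal(rates(posteriorMeanRates(smp1)),
               rates(buildRateMatrix(S1, pi)), tolerance = 1e-12)
  smp2 <- new("PosteriorSample", draws = list(S1, S2), logPost = c(0, 0),
              acceptanceRate = 1, pi = pi)
  expect_equal(rates(posteriorMeanRates(smp2)),
               rates(buildRateMatrix((S1 + S2) / 2, pi)), tolerance = 1e-12)
  expect_error(posteriorMeanRates(new("PosteriorSample", draws = list(),
                                      logPost = numeric(),
                                      acceptanceRate = 0, pi = pi)),
               "empty")
  ## duplicating a protein leaves the average unchanged
  W <- matrix(0.5, 20, 20, dimnames = list(AA, AA))
  one <- averageRateMatrices(list(Q), list(W), pi)
  three <- averageRateMatrices(list(Q, Q, Q), list(W, W, W), pi)
  expect_equal(rates(one), rates(three), tolerance = 1e-12)
  expect_equal(rates(one), rates(applyValidPairs(Q, W)), tolerance = 1e-12)
})

test_that("averaging elevates both proteins' fast pairs at half strength", {
  pi <- rep(1 / 20, 20)
  base <- matrix(1, 20, 20); diag(base) <- 0; dimnames(base) <- list(AA, AA)
  Sa <- base; Sa["A", "V"] <- Sa["V", "A"] <- 21
  Sb <- base; Sb["W", "Y"] <- Sb["Y", "W"] <- 21
  Qa <- buildRateMatrix(Sa, pi); Qb <- buildRateMatrix(Sb, pi)
  W1 <- matrix(1, 20, 20, dimnames = list(AA, AA))
  avg <- averageRateMatrices(list(Qa, Qb), list(W1, W1), pi)
  r <- rates(avg)
  expect_equal(r["A", "V"], r["W", "Y"], tolerance = 1e-12)
  expect_gt(r["A", "V"], r["A", "R"])
  ## pre-normalisation each elevated pair averages to (21+1)/2 = 11x baseline
  expect_equal(r["A", "V"] / r["A", "R"], 11, tolerance = 1e-10)
})

test_that("a zero-width proposal freezes the chain at its initialisation", {
  Q <- randomRateMatrix(19)
  tree <- readNewickTree(text = "((a:10,b:10):5,(c:10,d:10):5);")
  aln <- simulateAlignment(tree, Q, 40, seed = 2)
  smp <- mcmcSampleRates(aln, tree, prior = priorSpec("uniform"),
                         nSteps = 50, burnInFraction = 0, thin = 5,
                         proposalScale = 0, seed = 4)
  draws <- posteriorDraws(smp)
  expect_gt(length(draws), 1)
  for (d in draws) expect_equal(d, draws[[1]])
})

test_that("the sampler is reproducible bit-for-bit under a fixed seed", {
  Q <- randomRateMatrix(29)
  tree <- readNewickTree(text = "((a:15,b:15):5,(c:15,d:15):5);")
  aln <- simulateAlignment(tree, Q, 60, seed = 5)
  run <- function() mcmcSampleRates(aln, tree, prior = priorSpec("reference"),
                                    nSteps = 300, thin = 10, seed = 99)
  s1 <- run(); s2 <- run()
  expect_identical(posteriorDraws(s1), posteriorDraws(s2))
  expect_identical(s1@logPost, s2@logPost)
  expect_identical(acceptanceRate(s1), acceptanceRate(s2))
  expect_gt(acceptanceRate(s1), 0.005)
  expect_true(all(is.finite(s1@logPost)))
})

test_that("posterior mean rates satisfy every rate-matrix invariant", {
  Q <- randomRateMatrix(37)
  tree <- readNewickTree(text = "((a:15,b:15):5,(c:15,d:15):5);")
  aln <- simulateAlignment(tree, Q, 50, seed = 8)
  smp <- mcmcSampleRates(aln, tree, nSteps = 200, thin = 20, seed = 11)
  Qh <- posteriorMeanRates(smp)
  expect_true(validObject(Qh))
  expect_s4_class(Qh, "RateMatrix")
})
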