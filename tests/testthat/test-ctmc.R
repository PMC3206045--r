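test_that("rate matrix construction normalises and balances by construction", {
  pi <- rep(1 / 20, 20)
  S <- matrix(1, 20, 20); diag(S) <- 0; dimnames(S) <- list(AA, AA)
  Q <- buildRateMatrix(S, pi)
  off <- rates(Q)[row(rates(Q)) != col(rates(Q))]
  ## uniform pi, equal exchangeabilities: every off-diagonal = 0.01/19
  expect_equal(unname(off), rep(0.01 / 19, 380), tolerance = 1e-12)
  Q2 <- randomRateMatrix(4)
  expect_true(validObject(Q2))
  db <- composition(Q2) * rates(Q2)
  expect_lt(max(abs(db - t(db))), 1e-12)
  expect_equal(sum(composition(Q2) * -diag(rates(Q2))), 0.01)
})

test_that("a single exchangeable pair yields exactly two nonzero rates", {
  S <- matrix(0, 20, 20, dimnames = list(AA, AA))
  S["A", "V"] <- S["V", "A"] <- 1
  Q <- buildRateMatrix(S, rep(1 / 20, 20))
  off <- rates(Q); diag(off) <- 0
  expect_equal(sum(off != 0), 2)
  expect_error(buildRateMatrix(S * 0, rep(1 / 20, 20)), "all-zero")
})

test_that("zero composition components are perturbed with a warning", {
  pi <- c(0, rep(1 / 19, 19))
  S <- matrix(1, 20, 20); diag(S) <- 0; dimnames(S) <- list(AA, AA)
  expect_warning(Q <- buildRateMatrix(S, pi), "perturbed")
  expect_true(all(composition(Q) > 0))
})

test_that("stationary distribution inverts construction and the long-time limit", {
  Q <- randomRateMatrix(7)
  expect_equal(stationaryDistribution(Q), composition(Q), tolerance = 1e-8)
  ## rows of P(large t) converge to pi
  P <- transitionMatrix(Q, 1e4)
  expect_lt(max(abs(sweep(P, 2, composition(Q)))), 1e-6)
})

test_that("transition matrices are stochastic and match the series oracle", {
  Q <- randomRateMatrix(2)
  expect_equal(transitionMatrix(Q, 0), diag(20), ignore_attr = TRUE)
  for (t in c(0.5, 3, 40)) {
    P <- transitionMatrix(Q, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_lt(max(abs(transitionMatrix(Q, 0.5) -
                      seriesExpm(rates(Q), 0.5))), 1e-9)
  expect_error(transitionMatrix(Q, -1), ">= 0")
})

test_that("Chapman-Kolmogorov and reversibility hold across times", {
  Q <- randomRateMatrix(13)
  pi <- composition(Q)
  for (st in list(c(1, 2), c(10, 35), c(80, 20))) {
    Pa <- transitionMatrix(Q, st[1]); Pb <- transitionMatrix(Q, st[2])
    expect_lt(max(abs(Pa %*% Pb - transitionMatrix(Q, sum(st)))), 1e-8)
    expect_lt(max(abs(pi * Pa - t(pi * Pa))), 1e-8)
  }
})

test_that("pruning equals exhaustive ancestral-state enumeration", {
  Q <- randomRateMatrix(21)
  tree3 <- readNewickTree(text = "(a:3,b:5,c:2);")
  tree4 <- readNewickTree(text = "((a:4,b:6):3,(c:2,d:8):5);")
  set.seed(31)
  for (tree in list(tree3, tree4)) {
    seqs <- vapply(tree$tip.label, function(x)
      paste(sample(AA, 4, replace = TRUE), collapse = ""), character(1))
    aln <- asAln(seqs)
    expect_equal(prunedLogLikelihood(aln, tree, Q),
                 enumLogLikelihood(aln, tree, Q), tolerance = 1e-8)
  }
})

test_that("missing data marginalises out (gap and X columns)", {
  Q <- randomRateMatrix(6)
  tree <- readNewickTree(text = "((a:4,b:6):3,(c:2,d:8):5);")
  aln <- asAln(c(a = "A-", b = "AX", c = "A-", d = "AX"))
  aln_first <- asAln(c(a = "A", b = "A", c = "A", d = "A"))
  expect_equal(prunedLogLikelihood(aln, tree, Q),
               prunedLogLikelihood(aln_first, tree, Q), tolerance = 1e-10)
})

test_that("degenerate trees give the stationary log-probability", {
  Q <- randomRateMatrix(17)
  tree1 <- readNewickTree(text = "(a:2.5);")
  expect_equal(prunedLogLikelihood(asAln(c(a = "W")), tree1, Q),
               log(composition(Q)[["W"]]), tolerance = 1e-10)
  tree0 <- readNewickTree(text = "((a:0,b:0):0,c:0);")
  expect_equal(prunedLogLikelihood(asAln(c(a = "M", b = "M", c = "M")),
                                   tree0, Q),
               log(composition(Q)[["M"]]), tolerance = 1e-10)
  expect_lte(prunedLogLikelihood(asAln(c(a = "M", b = "M", c = "L")),
                                 tree0, Q), -700)
})

test_that("likelihood is invariant to leaf order and re-rooting", {
  Q <- randomRateMatrix(23)
  tree <- readNewickTree(text = "((a:4,b:6):3,(c:2,d:8):5);")
  set.seed(5)
  seqs <- vapply(tree$tip.label, function(x)
    paste(sample(AA, 6, replace = TRUE), collapse = ""), character(1))
  aln <- asAln(seqs)
  base <- prunedLogLikelihood(aln, tree, Q)
  expect_equal(prunedLogLikelihood(aln[c(3, 1, 4, 2)], tree, Q), base,
               tolerance = 1e-10)
  rerooted <- ape::root(ape::unroot(tree), outgroup = "c", resolve.root = TRUE)
  expect_equal(prunedLogLikelihood(aln, rerooted, Q), base, tolerance = 1e-8)
  bad <- aln; names(bad)[1] <- "zzz"
  expect_error(prunedLogLikelihood(bad, tree, Q), "zzz")
})
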