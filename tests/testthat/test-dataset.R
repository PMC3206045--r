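test_that("TM column extraction partitions into in- and out-facing sets", {
  fx <- barrelFixture()
  all_cols <- extractTMColumns(fx$aln, fx$ann, "all")
  in_cols <- extractTMColumns(fx$aln, fx$ann, "in")
  out_cols <- extractTMColumns(fx$aln, fx$ann, "out")
  expect_equal(Biostrings::width(all_cols)[1], 84)
  expect_equal(Biostrings::width(in_cols)[1], 42)
  expect_equal(Biostrings::width(out_cols)[1], 42)
  expect_equal(Biostrings::width(in_cols)[1] + Biostrings::width(out_cols)[1],
               Biostrings::width(all_cols)[1])
  ## column multiset: in + out residues = all residues, per sequence
  for (i in seq_along(all_cols)) {
    expect_equal(sort(strsplit(paste0(as.character(in_cols[[i]]),
                                      as.character(out_cols[[i]])), "")[[1]]),
                 sort(strsplit(as.character(all_cols[[i]]), "")[[1]]))
  }
})

test_that("empty annotations yield width-0 alignments", {
  fx <- barrelFixture()
  empty <- new("TMAnnotation", proteinId = "toy",
               segments = data.frame(strand = integer(), start = integer(),
                                     end = integer()),
               facing = character())
  out <- extractTMColumns(fx$aln, empty, "all")
  expect_equal(Biostrings::width(out)[1], 0)
})

test_that("annotations beyond the template length are rejected", {
  aln <- asAln(c(t = "ACDEF", h = "ACDEF"))
  ann <- TMAnnotation("t", strand = 1L, start = 2L, end = 8L,
                      facing = "IOIOIO")
  expect_error(extractTMColumns(aln, ann), "beyond template length")
})

test_that("template gap columns are never TM columns", {
  ## template ungapped position 2 ('D') sits in alignment column 4
  aln <- asAln(c(t = "AC-DEF", h = "ACWDEF"))
  ann <- TMAnnotation("t", strand = 1L, start = 2L, end = 4L, facing = "IO")
  out <- extractTMColumns(aln, ann, "all")
  expect_equal(as.character(out), c(t = "DE", h = "DE"))
})

test_that("composition equals brute-force letter counting", {
  expect_equal(unname(composition(asAln(c(a = "AAAA")))["A"]), 1)
  two <- composition(asAln(c(x = "AR", y = "RA")))
  expect_equal(unname(two[c("A", "R")]), c(0.5, 0.5))
  set.seed(11)
  seqs <- vapply(1:4, function(i)
    paste(sample(c(AA, "-", "X"), 30, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:4)
  got <- composition(asAln(seqs))
  chars <- unlist(strsplit(seqs, ""))
  chars <- chars[chars %in% AA]
  expect_equal(got, table(factor(chars, levels = AA))[AA] / length(chars),
               ignore_attr = TRUE)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_error(composition(asAln(c(a = "--X"))), "no residues")
})

test_that("GES hydrophobicity is the configured scale value and is linear", {
  expect_equal(gesHydrophobicity("LLLL"), gesScale()[["L"]])
  mixed <- gesHydrophobicity("LLWA")
  expect_equal(mixed, (2 * gesScale()[["L"]] + gesScale()[["W"]] +
                         gesScale()[["A"]]) / 4)
  expect_equal(gesHydrophobicity("L-X-W"),
               mean(gesScale()[c("L", "W")]))
  expect_error(gesHydrophobicity("---"), "no residues")
})

test_that("aggregating the printed template table reproduces its mean row", {
  tab <- templateStatsTable()
  agg <- aggregateStats(tab)
  expect_equal(agg$total_strands, 170)
  expect_equal(agg$mean$n_tm, 152)
  expect_equal(agg$mean$n_total, 401)
  expect_equal(agg$mean$n_in, 75)
  expect_equal(agg$mean$n_out, 76)
  expect_equal(agg$mean$hydro_all, -0.49)
  expect_equal(agg$mean$hydro_in, -2.10)
  expect_equal(agg$mean$hydro_out, 1.08)
})

test_that("datasetStats counts the partition and scores the template", {
  fx <- barrelFixture()
  st <- datasetStats(fx$aln, fx$ann)
  expect_equal(st$n_tm, 84)
  expect_equal(st$n_in + st$n_out, st$n_tm)
  expect_equal(st$n_strands, 8)
  expect_equal(st$n_total, 172)
  tm_all <- as.character(extractTMColumns(fx$aln, fx$ann, "all")[[1]])
  expect_equal(st$hydro_all, gesHydrophobicity(tm_all))
})

test_that("percent identity matches brute-force column comparison", {
  expect_equal(percentIdentity("ACDEF", "ACDEF"), 100)
  expect_equal(percentIdentity("AC", "AG"), 50)
  set.seed(3)
  for (rep in 1:5) {
    a <- paste(sample(c(AA, "-"), 25, replace = TRUE), collapse = "")
    b <- paste(sample(c(AA, "-"), 25, replace = TRUE), collapse = "")
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    comp <- !(ca == "-" & cb == "-")
    expect_equal(percentIdentity(a, b),
                 100 * sum(ca == cb & ca != "-") / sum(comp))
  }
})

test_that("homolog selection honours bins, caps, ties and the gap rule", {
  hits <- data.frame(id = c("h95", "h85", "h84", "h83", "h35"),
                     identity = c(95, 85, 84, 83, 35))
  expect_equal(sort(selectHomologs(hits)), sort(c("h85", "h84", "h35")))
  expect_equal(selectHomologs(hits[0, ]), character())
  ## a 3-gap TM segment disqualifies a hit
  gaps <- list(c(0, 1), c(0, 3), c(1, 1), c(2, 2), c(0, 0))
  expect_equal(sort(selectHomologs(hits, gapsPerSegment = gaps)),
               sort(c("h84", "h83", "h35")))
  ## brute-force bin filter on random hit lists; never more than 12 selected
  set.seed(9)
  for (rep in 1:5) {
    n <- 40
    h <- data.frame(id = paste0("s", 1:n),
                    identity = round(runif(n, 0, 100), 1))
    got <- selectHomologs(h)
    manual <- character()
    for (lo in seq(30, 80, 10)) {
      inb <- h[h$identity >= lo & h$identity < lo + 10, ]
      inb <- inb[order(-inb$identity), ]
      manual <- c(manual, head(inb$id, 2))
    }
    expect_setequal(got, manual)
    expect_lte(length(got), 12)
  }
})
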