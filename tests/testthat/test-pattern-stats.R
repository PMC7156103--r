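test_that("site classification follows the A/B pattern definitions", {
  cases <- list(list(c("A", "B", "B"), "ABBA"),
                list(c("B", "A", "B"), "BABA"),
                list(c("B", "B", "A"), "BBAA"),
                list(c("A", "A", "B"), "OTHER"),   # singleton derived
                list(c("B", "A", "A"), "OTHER"),
                list(c("A", "A", "A"), "OTHER"),
                list(c("B", "B", "B"), "OTHER"))
  for (cs in cases)
    expect_equal(as.character(classifySite(cs[[1]][1], cs[[1]][2],
                                           cs[[1]][3])), cs[[2]])
  expect_error(classifySite("A", "B", "X"), "must be 'A' or 'B'")
})

test_that("pattern tallies match a per-record brute-force classification", {
  set.seed(14)
  st <- randomStates(1000)
  ps <- psFromStates(st)
  cnt <- countPatterns(ps)
  lab <- apply(st, 1, function(r) as.character(classifySite(r[1], r[2], r[3])))
  expect_equal(abba(cnt), sum(lab == "ABBA"))
  expect_equal(baba(cnt), sum(lab == "BABA"))
  expect_equal(bbaa(cnt), sum(lab == "BBAA"))
  expect_equal(patternTotal(countPatterns(psFromStates(randomStates(0)))), 0)

  # restriction to a window tallies only its sites
  win <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 100))
  c100 <- countPatterns(ps, window = win)
  expect_equal(patternTotal(c100),
               sum(lab[1:100] != "OTHER"))
})

test_that("D and Dp reproduce the published per-trio worked examples", {
  # genome-wide counts printed for the self-consistent trios
  expect_equal(round(computeD(PatternCounts(179196, 167118)), 3), 0.035)
  expect_equal(round(computeD(PatternCounts(180425, 167904)), 3), 0.036)
  expect_equal(round(computeD(PatternCounts(90995, 89367)), 3), 0.009)
  expect_equal(round(computeD(PatternCounts(11157, 11156)), 3), 0)
  expect_equal(round(computeDp(PatternCounts(179196, 167118, 676317)), 4),
               0.0118)
  expect_equal(round(computeDp(PatternCounts(120471, 106775, 491701)), 3),
               0.019)
  expect_equal(round(computeDp(PatternCounts(122803, 112923, 566678)), 4),
               0.0123)
})

test_that("D and Dp handle boundaries and undefined cases", {
  expect_equal(computeD(PatternCounts(5, 5)), 0)
  expect_equal(computeD(PatternCounts(5, 0)), 1)
  expect_equal(computeDp(PatternCounts(5, 5, 100)), 0)
  expect_warning(dval <- computeD(PatternCounts(0, 0, 10)), "undefined")
  expect_true(is.na(dval))
  expect_warning(dpval <- computeDp(PatternCounts(0, 0, 0)), "undefined")
  expect_true(is.na(dpval))
})

test_that("swapping P1 and P2 negates D and preserves Dp", {
  set.seed(21)
  for (i in 1:20) {
    a <- rpois(1, 50); b <- rpois(1, 50); s <- rpois(1, 200)
    if (a + b == 0) next
    expect_equal(computeD(PatternCounts(a, b)),
                 -computeD(PatternCounts(b, a)))
    expect_equal(computeDp(PatternCounts(a, b, s)),
                 computeDp(PatternCounts(b, a, s)))
  }
  # and through the polarization layer: reordering the trio swaps the counts
  sim <- simulateDataset(SimParams(gamma = 0.4, nLoci = 100,
                                   locusLength = 2000, seed = 8))
  c1 <- countPatterns(polarizeSites(sim$sites, c("P1", "P2", "P3", "O")))
  c2 <- countPatterns(polarizeSites(sim$sites, c("P2", "P1", "P3", "O")))
  expect_equal(abba(c1), baba(c2))
  expect_equal(baba(c1), abba(c2))
  expect_equal(computeD(c1), -computeD(c2))
  expect_equal(computeDp(c1), computeDp(c2))
})

test_that("Dp never exceeds |D|, with equality only when BBAA is absent", {
  set.seed(33)
  for (i in 1:50) {
    a <- rpois(1, 30); b <- rpois(1, 30); s <- rpois(1, 100)
    if (a + b == 0) next
    d <- computeD(PatternCounts(a, b)); dp <- computeDp(PatternCounts(a, b, s))
    expect_lte(dp, abs(d) + 1e-12)
    if (s == 0) expect_equal(dp, abs(d))
    if (s > 0 && a != b) expect_lt(dp, abs(d))
  }
})

test_that("window scan applies the strict SNP filter and z-score rule", {
  set.seed(55)
  # 50 windows of 1 kb; windows 1 and 2 get exactly 20 and 21 sites
  nWin <- 50
  perWin <- c(20L, 21L, sample(25:60, nWin - 2, replace = TRUE))
  states <- NULL; pos <- NULL
  for (w in seq_len(nWin)) {
    states <- rbind(states, randomStates(perWin[w], 0.35, 0.25, 0.4))
    pos <- c(pos, sort(sample((w - 1) * 1000 + (1:1000), perWin[w])))
  }
  ps <- psFromStates(states, pos = pos)
  win <- partitionWindows(ps, c(`1` = nWin * 1000), windowSize = 1000)
  sc <- windowScan(ps, win, minSnps = 20, zThreshold = 3)
  expect_false(sc$retained[1])   # exactly 20 informative sites: excluded
  expect_true(is.na(sc$z[1]))
  expect_true(sc$retained[2])    # 21: retained

  # arithmetic oracle: z = |d - mean(d)| / sd(d) over retained windows
  dr <- sc$d[sc$retained]
  expect_equal(sc$z[sc$retained], abs(dr - mean(dr)) / sd(dr))
  expect_equal(sc$outlier, !is.na(sc$z) & sc$z > 3)

  # pooled per-window counts conserve the whole-alignment tallies
  tot <- countPatterns(ps)
  expect_equal(sum(sc$abba), abba(tot))
  expect_equal(sum(sc$baba), baba(tot))
  expect_equal(sum(sc$bbaa), bbaa(tot))

  # identical d everywhere -> z = 0, no outliers
  stEq <- do.call(rbind, replicate(30, rbind(c("A", "B", "B"),
                                             c("A", "B", "B"),
                                             matrix(rep(c("B", "B", "A"),
                                                        each = 25), 25, 3,
                                                    byrow = FALSE)),
                                   simplify = FALSE))
  # 30 windows x 27 sites, each with abba=2, baba=0, bbaa=25
  posEq <- as.vector(vapply(seq_len(30), function(w)
    (w - 1) * 1000 + seq_len(27), numeric(27)))
  psEq <- psFromStates(stEq, pos = posEq)
  winEq <- partitionWindows(psEq, c(`1` = 30000), 1000)
  scEq <- windowScan(psEq, winEq, minSnps = 20)
  expect_true(all(scEq$z[scEq$retained] == 0))
  expect_false(any(scEq$outlier))
})

test_that("block bootstrap is deterministic and degenerates sensibly", {
  set.seed(77)
  states <- randomStates(2000, 0.3, 0.2, 0.4)
  ps <- psFromStates(states, pos = sort(sample.int(50000, 2000)))
  win <- partitionWindows(ps, c(`1` = 50000), 1000)
  b1 <- blockBootstrap(ps, win, nWindowsPerRep = 50, nReps = 200, seed = 3)
  b2 <- blockBootstrap(ps, win, nWindowsPerRep = 50, nReps = 200, seed = 3)
  for (sl in c("meanD", "bootMean", "sd", "se", "ci95", "pRaw", "pTwo"))
    expect_identical(slot(b1, sl), slot(b2, sl))
  expect_equal(b1@meanD, computeD(countPatterns(ps)))
  expect_equal(b1@se, b1@sd / sqrt(200))
  expect_lte(b1@ci95[1], b1@ci95[2])

  # identical windows: every replicate equals the empirical D, sd = 0,
  # and no replicate crosses zero
  stEq <- do.call(rbind, replicate(20, matrix(c("A", "B", "B"), 30, 3,
                                              byrow = TRUE),
                                   simplify = FALSE))
  posEq <- as.vector(vapply(seq_len(20), function(w)
    (w - 1) * 100 + seq_len(30), numeric(30)))
  psEq <- psFromStates(stEq, pos = posEq)
  winEq <- partitionWindows(psEq, c(`1` = 2000), 100)
  bEq <- blockBootstrap(psEq, winEq, nWindowsPerRep = 20, nReps = 100,
                        seed = 1)
  expect_equal(bEq@sd, 0)
  expect_equal(bEq@bootMean, bEq@meanD)
  expect_equal(bEq@pRaw, 1 / 101)   # zero opposite-side replicates
})

test_that("the bootstrap replicate mean tracks the empirical D", {
  sim <- simulateDataset(SimParams(gamma = 0.3, direction = "P2_to_P3",
                                   nLoci = 400, locusLength = 8000,
                                   seed = 12))
  ps <- polarizeSites(sim$sites, simTrio)
  b <- blockBootstrap(ps, sim$loci, nWindowsPerRep = 400, nReps = 200,
                      seed = 4)
  expect_lt(abs(b@bootMean - b@meanD), 2 * b@se)
  expect_gte(b@meanD, b@ci95[1] - 2 * b@sd)
  expect_lte(b@meanD, b@ci95[2] + 2 * b@sd)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(adjustPvalues(0.003, 17), 0.051)
  expect_equal(adjustPvalues(0.5, 17), 1)
  expect_equal(adjustPvalues(0, 5), 0)
  expect_equal(adjustPvalues(c(0.01, 0.2), 3), c(0.03, 0.6))
})
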