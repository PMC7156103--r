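test_that("scenario parameters are validated", {
  expect_error(SimParams(tM = 1.5), "tM < t12")
  expect_error(SimParams(gamma = 1.2), "gamma")
  expect_error(SimParams(t3 = 0.5), "tM < t12")
  p <- SimParams(gamma = 0.5, tM = 0.04)
  expect_s4_class(p, "SimParams")
})

test_that("gene-tree topology frequencies match the MSC closed forms", {
  # no introgression: P(P1P2 cherry) = 1 - (2/3) exp(-internal branch),
  # internal branch = (2.4 - 1.2)/2 = 0.6 in 2N units
  set.seed(101)
  n <- 10000
  trees <- replicate(n, geneTreeTopology(simulateGeneTree(SimParams())))
  pAB <- 1 - (2 / 3) * exp(-0.6)
  expect_lt(abs(mean(trees == "AB") - pAB), 4 * sqrt(pAB * (1 - pAB) / n))
  # the discordant classes are symmetric under ILS
  pDis <- (1 - pAB) / 2
  expect_lt(abs(mean(trees == "BC") - pDis), 4 * sqrt(pDis * (1 - pDis) / n))

  # full P3 -> P2 pulse at 0.04N generations: P2 and P3 share a population
  # from 0.02 (2N units) until the P3 merge at 1.2
  tr1 <- Dtrio:::.simTrees(n, SimParams(gamma = 1, tM = 0.04,
                                        direction = "P3_to_P2"))
  pBC <- 1 - (2 / 3) * exp(-(1.2 - 0.02))
  expect_lt(abs(mean(tr1$topology == "BC") - pBC),
            4 * sqrt(pBC * (1 - pBC) / n))
})

test_that("every genealogy respects the model structure", {
  set.seed(7)
  outLast <- 0
  for (i in 1:500) {
    g <- simulateGeneTree(SimParams(gamma = 0.5))
    m <- g@merges
    # root collects all four tips at or after the outgroup split (8 in 2N units)
    expect_gte(m[3, 3], 8)
    expect_true(!is.unsorted(m[, 3]))
    # coalescences happen only once the populations have merged
    expect_gte(m[1, 3], 0.1)
    if (bitwAnd(as.integer(m[3, 1]), 8L) == 8L ||
        bitwAnd(as.integer(m[3, 2]), 8L) == 8L)
      outLast <- outLast + 1
  }
  # the outgroup lineage joins last in virtually all genealogies (it can
  # join an uncoalesced ingroup lineage first only when the ingroup fails
  # to coalesce within the 6.8 units before the outgroup split)
  expect_gte(outLast / 500, 0.98)
})

test_that("a gene tree serializes to parseable ultrametric Newick", {
  set.seed(2)
  g <- simulateGeneTree(SimParams(gamma = 0.2))
  txt <- geneTreeNewick(g)
  tree <- ape::read.tree(text = txt)
  expect_setequal(tree$tip.label, c("P1", "P2", "P3", "O"))
  depths <- ape::node.depth.edgelength(tree)
  expect_lt(diff(range(depths[1:4])), 1e-8)   # tips equidistant from root
})

test_that("sequence evolution follows the Jukes-Cantor closed form", {
  # fixed caterpillar genealogy: P1-P2 path length 1.0 in 2N units
  g <- new("GeneTree", merges = matrix(c(1, 2, 0.5, 3, 4, 1, 7, 8, 2),
                                       3, 3, byrow = TRUE,
                                       dimnames = list(NULL,
                                         c("mask1", "mask2", "time"))))
  theta <- 0.2
  L <- 50000
  set.seed(31)
  seqs <- simulateLocusSequences(g, L, theta = theta)
  sm <- as.matrix(seqs)
  pObs <- mean(sm["P1", ] != sm["P2", ])
  d <- 1.0 * theta / 2                       # expected substitutions/site
  pExp <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(pObs - pExp), 4 * sqrt(pExp * (1 - pExp) / L))
  # a longer path saturates toward 3/4
  pObs13 <- mean(sm["P1", ] != sm["P3", ])
  d13 <- 2 * theta / 2
  pExp13 <- 0.75 * (1 - exp(-4 * d13 / 3))
  expect_lt(abs(pObs13 - pExp13), 4 * sqrt(pExp13 * (1 - pExp13) / L))

  # zero-length branches produce identical sequences
  g0 <- new("GeneTree", merges = matrix(c(1, 2, 0, 3, 4, 0, 7, 8, 0), 3, 3,
                                        byrow = TRUE))
  s0 <- simulateLocusSequences(g0, 500, theta = 0.5)
  expect_equal(length(unique(as.character(s0))), 1L)

  # determinism under a fixed seed
  set.seed(17); sA <- simulateLocusSequences(g, 1000, 0.1)
  set.seed(17); sB <- simulateLocusSequences(g, 1000, 0.1)
  expect_identical(as.character(sA), as.character(sB))
})

test_that("simulated datasets feed the counting pipeline coherently", {
  p <- SimParams(gamma = 0, nLoci = 600, locusLength = 4000, seed = 23)
  sim <- simulateDataset(p)
  expect_s4_class(sim$sites, "SiteMatrix")
  expect_equal(sampleNames(sim$sites), simTrio)
  expect_equal(length(sim$loci), 600L)
  # without gene flow, genome-wide D stays within 3 bootstrap SDs of zero
  ps <- polarizeSites(sim$sites, simTrio)
  b <- blockBootstrap(ps, sim$loci, nWindowsPerRep = 600, nReps = 300,
                      seed = 2)
  expect_lt(abs(b@meanD), 3 * b@sd)

  # determinism: the same params give the same dataset
  sim2 <- simulateDataset(p)
  expect_identical(siteCalls(sim2$sites), siteCalls(sim$sites))

  # more admixture, more Dp
  loDp <- simStats(SimParams(gamma = 0.05, nLoci = 400, locusLength = 4000,
                             seed = 41))["dp"]
  hiDp <- simStats(SimParams(gamma = 0.95, nLoci = 400, locusLength = 4000,
                             seed = 41))["dp"]
  expect_gt(hiDp, loDp)
})

test_that("relabeling P1 and P2 negates D and preserves Dp on average", {
  dv <- numeric(20); dpv <- numeric(20); dvSwap <- numeric(20)
  dpvSwap <- numeric(20)
  for (r in 1:20) {
    sim <- simulateDataset(SimParams(gamma = 0.3, direction = "P2_to_P3",
                                     nLoci = 200, locusLength = 2000,
                                     seed = 500 + r))
    c1 <- countPatterns(polarizeSites(sim$sites, simTrio))
    c2 <- countPatterns(polarizeSites(sim$sites, c("P2", "P1", "P3", "O")))
    dv[r] <- computeD(c1); dvSwap[r] <- computeD(c2)
    dpv[r] <- computeDp(c1); dpvSwap[r] <- computeDp(c2)
  }
  expect_equal(dvSwap, -dv)      # exact: ABBA and BABA swap roles
  expect_equal(dpvSwap, dpv)
})

test_that("without gene flow D is centred and Dp shows the folded bias", {
  n <- 50
  dv <- numeric(n); dpv <- numeric(n); ab <- numeric(n); tot <- numeric(n)
  for (r in 1:n) {
    sim <- simulateDataset(SimParams(gamma = 0, nLoci = 250,
                                     locusLength = 2000, seed = 900 + r))
    cnt <- countPatterns(polarizeSites(sim$sites, simTrio))
    dv[r] <- computeD(cnt); dpv[r] <- computeDp(cnt)
    ab[r] <- abba(cnt) + baba(cnt); tot[r] <- patternTotal(cnt)
  }
  expect_lt(abs(mean(dv)), 4 * sd(dv) / sqrt(n))
  # E|ABBA - BABA| ~ sqrt(2/pi) * sd(ABBA - BABA); under the null the
  # difference is close to a centred binomial difference with variance
  # ~ ABBA + BABA
  theo <- sqrt(2 / pi) * sqrt(mean(ab)) / mean(tot)
  expect_gt(mean(dpv), 0.3 * theo)
  expect_lt(mean(dpv), 3 * theo)
})

test_that("topology frequencies agree with an independent coalescent simulator", {
  # msprime as the cross-check oracle at three parameter points
  script <- '
import msprime, json, sys
def freqs(tm, t12, t3, tout, gamma, recipient, donor, n, seed):
    dem = msprime.Demography()
    for name in ["p1", "p2", "p3", "o", "anc12", "anc123", "root"]:
        dem.add_population(name=name, initial_size=0.5)
    if gamma > 0:
        dem.add_mass_migration(time=tm, source=recipient, dest=donor,
                               proportion=gamma)
    dem.add_population_split(time=t12, derived=["p1", "p2"],
                             ancestral="anc12")
    dem.add_population_split(time=t3, derived=["anc12", "p3"],
                             ancestral="anc123")
    dem.add_population_split(time=tout, derived=["anc123", "o"],
                             ancestral="root")
    dem.sort_events()
    reps = msprime.sim_ancestry(
        samples=[msprime.SampleSet(1, population=p, ploidy=1)
                 for p in ["p1", "p2", "p3", "o"]],
        demography=dem, num_replicates=n, random_seed=seed)
    out = {"AB": 0, "AC": 0, "BC": 0}
    for ts in reps:
        t = ts.first()
        tm12 = t.tmrca(0, 1); tm13 = t.tmrca(0, 2); tm23 = t.tmrca(1, 2)
        m = min(tm12, tm13, tm23)
        out["AB" if m == tm12 else ("AC" if m == tm13 else "BC")] += 1
    return {k: v / n for k, v in out.items()}
pts = [
    freqs(0.1, 0.6, 1.2, 8.0, 0.0, "p2", "p3", 20000, 11),
    freqs(0.1, 0.6, 1.2, 8.0, 0.5, "p2", "p3", 20000, 12),
    freqs(0.02, 0.6, 1.2, 8.0, 0.8, "p3", "p2", 20000, 13),
]
print(json.dumps(pts))
'
  pyOut <- system2("python", "-", input = script, stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(pyOut, collapse = ""),
                            simplifyDataFrame = FALSE)
  params <- list(SimParams(gamma = 0),
                 SimParams(gamma = 0.5, tM = 0.2, direction = "P3_to_P2"),
                 SimParams(gamma = 0.8, tM = 0.04, direction = "P2_to_P3"))
  set.seed(202)
  n <- 20000L
  for (i in seq_along(params)) {
    tr <- Dtrio:::.simTrees(n, params[[i]])
    for (lab in c("AB", "AC", "BC")) {
      pRef <- ref[[i]][[lab]]
      pOwn <- mean(tr$topology == lab)
      mcErr <- sqrt(pRef * (1 - pRef) / n + pOwn * (1 - pOwn) / n)
      expect_lt(abs(pOwn - pRef), 3.5 * mcErr + 1e-9)
    }
  }
})

test_that("a small validation grid behaves like the full design", {
  grid <- runDpValidation(directions = "P3_to_P2", timings = 0.2,
                          gammas = c(0.15, 0.45, 0.75), nReplicates = 6,
                          nLoci = 500, locusLength = 4000, seed = 77)
  expect_equal(nrow(grid), 3L)
  expect_equal(grid$nReplicates, rep(6L, 3))
  # Dp tracks gamma monotonically, underestimating where the bias is larger
  # than Monte-Carlo noise at this reduced size
  expect_true(all(diff(grid$meanDp) > 0))
  expect_true(all(grid$meanDp[2:3] < grid$gamma[2:3]))
  # D overestimates gamma for P3 -> P2 introgression at mid-range
  expect_gt(grid$meanD[2], grid$gamma[2])
})
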