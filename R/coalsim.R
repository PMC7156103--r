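# Four-taxon multispecies coalescent with one introgression pulse, plus
# Jukes-Cantor sequence evolution on the resulting genealogies.
#
# Time scale: user-facing split times are in N generations; internally all
# times are in 2N-generation coalescent units (pairwise coalescence rate 1),
# i.e. user values are halved. Tips are indexed 1=P1, 2=P2, 3=P3, 4=O and
# clusters encoded as bitmasks (P1=1, P2=2, P3=4, O=8).

.TIPMASK <- c(1L, 2L, 4L, 8L)
.BASES <- c("A", "C", "G", "T")

# Vectorised genealogy sampler: n independent loci under `params`.
# Returns per-locus merge triples (masks and times, time-ordered) and the
# first-merge mask (the locus topology: 3 = P1P2 cherry, 6 = P2P3, 5 = P1P3).
.simTrees <- function(n, params) {
  tm <- params@tM / 2; t12 <- params@t12 / 2
  t3 <- params@t3 / 2; tout <- params@tOut / 2
  gamma <- params@gamma
  p2toP3 <- params@direction == "P2_to_P3"

  moved <- stats::runif(n) < gamma
  # structured phase: the pulse makes P2 and P3 co-resident from tm until the
  # donor-side population merges (t12 when the recipient is P3, t3 otherwise)
  end0 <- if (p2toP3) t12 else t3
  e0 <- tm + stats::rexp(n)
  bc <- moved & e0 < end0                       # (P2,P3) cherry
  e1 <- t12 + stats::rexp(n)
  ab <- !moved & e1 < t3                        # (P1,P2) cherry
  hasCherry <- bc | ab
  cherryMask <- ifelse(bc, 6L, 3L)
  cherryTime <- ifelse(bc, e0, e1)
  # from time s all remaining ingroup lineages are co-resident
  s <- ifelse(moved & p2toP3, t12, t3)

  M1a <- integer(n); M1b <- integer(n); T1 <- numeric(n)
  M2a <- integer(n); M2b <- integer(n); T2 <- numeric(n)
  M3a <- integer(n); M3b <- integer(n); T3 <- numeric(n)

  # loci whose cherry already happened: one pairwise coalescence to go
  i2 <- which(hasCherry)
  if (length(i2)) {
    u2 <- s[i2] + stats::rexp(length(i2))
    ok <- u2 < tout
    j <- i2[ok]
    M1a[j] <- ifelse(cherryMask[j] == 6L, 2L, 1L)
    M1b[j] <- ifelse(cherryMask[j] == 6L, 4L, 2L)
    T1[j] <- cherryTime[j]
    M2a[j] <- cherryMask[j]
    M2b[j] <- ifelse(cherryMask[j] == 6L, 1L, 4L)
    T2[j] <- u2[ok]
    M3a[j] <- 7L; M3b[j] <- 8L
    T3[j] <- tout + stats::rexp(length(j))
    # tail: ingroup not fully coalesced by tout
    tail2 <- i2[!ok]
    for (i in tail2) {
      res <- .coalesceFree(list(cherryMask[i], 7L - cherryMask[i], 8L), tout)
      M1a[i] <- ifelse(cherryMask[i] == 6L, 2L, 1L)
      M1b[i] <- ifelse(cherryMask[i] == 6L, 4L, 2L)
      T1[i] <- cherryTime[i]
      M2a[i] <- res$ma[1]; M2b[i] <- res$mb[1]; T2[i] <- res$t[1]
      M3a[i] <- res$ma[2]; M3b[i] <- res$mb[2]; T3[i] <- res$t[2]
    }
  }

  # loci with three separate ingroup lineages at s
  i3 <- which(!hasCherry)
  if (length(i3)) {
    v1 <- s[i3] + stats::rexp(length(i3), rate = 3)
    pairPick <- sample.int(3L, length(i3), replace = TRUE)
    pa <- c(1L, 1L, 2L)[pairPick]; pb <- c(2L, 4L, 4L)[pairPick]
    u2 <- v1 + stats::rexp(length(i3))
    ok <- v1 < tout & u2 < tout
    j <- i3[ok]
    M1a[j] <- pa[ok]; M1b[j] <- pb[ok]; T1[j] <- v1[ok]
    M2a[j] <- pa[ok] + pb[ok]
    M2b[j] <- 7L - (pa[ok] + pb[ok])
    T2[j] <- u2[ok]
    M3a[j] <- 7L; M3b[j] <- 8L
    T3[j] <- tout + stats::rexp(length(j))
    # tail: 2 or 3 ingroup lineages remain at tout
    for (k in which(!ok)) {
      i <- i3[k]
      if (v1[k] < tout) {
        lin <- list(pa[k] + pb[k], 7L - (pa[k] + pb[k]), 8L)
        res <- .coalesceFree(lin, tout)
        M1a[i] <- pa[k]; M1b[i] <- pb[k]; T1[i] <- v1[k]
        M2a[i] <- res$ma[1]; M2b[i] <- res$mb[1]; T2[i] <- res$t[1]
        M3a[i] <- res$ma[2]; M3b[i] <- res$mb[2]; T3[i] <- res$t[2]
      } else {
        res <- .coalesceFree(list(1L, 2L, 4L, 8L), tout)
        M1a[i] <- res$ma[1]; M1b[i] <- res$mb[1]; T1[i] <- res$t[1]
        M2a[i] <- res$ma[2]; M2b[i] <- res$mb[2]; T2[i] <- res$t[2]
        M3a[i] <- res$ma[3]; M3b[i] <- res$mb[3]; T3[i] <- res$t[3]
      }
    }
  }
  list(m1a = M1a, m1b = M1b, t1 = T1, m2a = M2a, m2b = M2b, t2 = T2,
       m3a = M3a, m3b = M3b, t3 = T3,
       topology = c(`3` = "AB", `5` = "AC", `6` = "BC",
                    `9` = "other", `10` = "other", `12` = "other")[
                      as.character(M1a + M1b)])
}

# free coalescence among the given clusters from time t0 until one remains
.coalesceFree <- function(lineages, t0) {
  ma <- integer(0); mb <- integer(0); tt <- numeric(0)
  t <- t0
  while (length(lineages) > 1L) {
    k <- length(lineages)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    a <- lineages[[pick[1]]]; b <- lineages[[pick[2]]]
    ma <- c(ma, a); mb <- c(mb, b); tt <- c(tt, t)
    lineages <- c(lineages[-pick], list(a + b))
  }
  list(ma = ma, mb = mb, t = tt)
}

#' Simulate one four-tip genealogy
#'
#' Draws a single gene tree under the multispecies coalescent defined by
#' `params`: one haploid lineage per taxon; at the pulse time the recipient
#' lineage migrates (backwards in time) into the donor population with
#' probability `gamma`; within any population, lineage pairs coalesce at
#' rate 1 per 2N generations; populations merge at the split times.
#' Consumes the current RNG stream (seed externally for reproducibility).
#'
#' @param params a [SimParams-class].
#' @return a [GeneTree-class].
#' @examples
#' set.seed(1)
#' simulateGeneTree(SimParams(gamma = 0.3))
#' @export
simulateGeneTree <- function(params) {
  stopifnot(is(params, "SimParams"))
  s <- .simTrees(1L, params)
  new("GeneTree",
      merges = matrix(c(s$m1a, s$m1b, s$t1, s$m2a, s$m2b, s$t2,
                        s$m3a, s$m3b, s$t3),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(NULL, c("mask1", "mask2", "time"))))
}

#' Newick serialization of a GeneTree
#'
#' Branch lengths are in 2N coalescent units.
#'
#' @param tree a [GeneTree-class].
#' @return a single Newick string.
#' @export
geneTreeNewick <- function(tree) {
  stopifnot(is(tree, "GeneTree"))
  m <- tree@merges
  lab <- stats::setNames(tree@tips, .TIPMASK)
  birth <- stats::setNames(rep(0, 4), .TIPMASK)
  for (r in seq_len(3)) {
    a <- as.character(as.integer(m[r, 1])); b <- as.character(as.integer(m[r, 2]))
    t <- m[r, 3]
    u <- as.character(as.integer(m[r, 1]) + as.integer(m[r, 2]))
    lab[u] <- sprintf("(%s:%.12g,%s:%.12g)", lab[a], t - birth[a],
                      lab[b], t - birth[b])
    birth[u] <- t
  }
  paste0(lab[as.character(15L)], ";")
}

#' Gene-tree topology label
#'
#' The ingroup pair that coalesces first: `"AB"` for (P1,P2) — concordant
#' with the species branching order — `"BC"` for (P2,P3), `"AC"` for
#' (P1,P3), `"other"` if the first merge involves the outgroup.
#'
#' @param tree a [GeneTree-class].
#' @return a topology label string.
#' @export
geneTreeTopology <- function(tree) {
  m <- as.integer(tree@merges[1, 1] + tree@merges[1, 2])
  switch(as.character(m), `3` = "AB", `5` = "AC", `6` = "BC", "other")
}

# Edge table for mutation placement. For each locus: 4 tip edges + 2 internal
# edges, with descendant mask and per-site expected substitutions
# (branch length in 2N units x theta/2, with optional per-taxon tip rates
# applied to the pre-merge portion of each tip branch).
.treeEdgeRates <- function(tr, params) {
  n <- length(tr$t1)
  u1 <- tr$m1a + tr$m1b
  u2 <- tr$m2a + tr$m2b
  theta <- params@theta
  tips <- if (is.null(params@tipThetas)) rep(theta, 4) else params@tipThetas
  # species-merge time of each taxon's own population (2N units)
  mergeT <- c(params@t12, params@t12, params@t3, params@tOut) / 2

  mask <- matrix(0L, n, 6)
  rate <- matrix(0, n, 6)
  for (t in 1:4) {
    tipm <- .TIPMASK[t]
    death <- ifelse(bitwAnd(u1, tipm) > 0, tr$t1,
                    ifelse(bitwAnd(u2, tipm) > 0, tr$t2, tr$t3))
    own <- pmin(death, mergeT[t])
    mask[, t] <- tipm
    rate[, t] <- 0.5 * (tips[t] * own + theta * (death - own))
  }
  d1 <- ifelse(tr$m2a == u1 | tr$m2b == u1, tr$t2, tr$t3)
  mask[, 5] <- as.integer(u1); rate[, 5] <- 0.5 * theta * (d1 - tr$t1)
  mask[, 6] <- as.integer(u2); rate[, 6] <- 0.5 * theta * (tr$t3 - tr$t2)
  list(mask = mask, rate = rate)
}

# Draw mutations for all loci at once. Under Jukes-Cantor a mutation maps the
# current base b to (b + delta) mod 4 with delta uniform on {1,2,3}; offsets
# along a root-to-tip path are additive, so tip states follow from per-site
# offset sums without tracking mutation times.
.drawMutations <- function(edges, locusLength) {
  n <- nrow(edges$mask)
  nm <- stats::rpois(length(edges$rate),
                     as.numeric(edges$rate) * locusLength)
  tot <- sum(nm)
  if (tot == 0)
    return(list(locus = integer(0), site = integer(0), mask = integer(0),
                delta = integer(0)))
  locus <- rep(rep(seq_len(n), ncol(edges$mask)), nm)
  mask <- rep(as.integer(edges$mask), nm)
  site <- sample.int(locusLength, tot, replace = TRUE)
  delta <- sample.int(3L, tot, replace = TRUE)
  list(locus = locus, site = site, mask = mask, delta = delta)
}

# Resolve mutations into variable-site columns.
# Returns global site keys (sorted) and a sites x 4 character matrix.
.mutationsToSites <- function(mut, locusLength) {
  if (!length(mut$locus))
    return(list(key = numeric(0),
                calls = matrix(character(0), 0, 4)))
  key <- (mut$locus - 1) * as.numeric(locusLength) + mut$site
  contrib <- matrix(0, length(key), 4)
  for (t in 1:4)
    contrib[, t] <- mut$delta * (bitwAnd(mut$mask, .TIPMASK[t]) > 0)
  ord <- order(key)
  skey <- key[ord]
  first <- c(TRUE, skey[-1] != skey[-length(skey)])
  grp <- cumsum(first)
  sums <- rowsum(contrib[ord, , drop = FALSE], grp, reorder = FALSE)
  ukey <- skey[first]
  anc <- sample.int(4L, length(ukey), replace = TRUE) - 1L
  baseIdx <- (anc + sums) %% 4
  variable <- baseIdx[, 1] != baseIdx[, 2] | baseIdx[, 1] != baseIdx[, 3] |
    baseIdx[, 1] != baseIdx[, 4]
  # multiple hits can leave >2 alleles at a site; apply the biallelic filter
  # here so the output honours the SiteMatrix contract
  nd <- 1L + (baseIdx[, 2] != baseIdx[, 1]) +
    (baseIdx[, 3] != baseIdx[, 1] & baseIdx[, 3] != baseIdx[, 2]) +
    (baseIdx[, 4] != baseIdx[, 1] & baseIdx[, 4] != baseIdx[, 2] &
       baseIdx[, 4] != baseIdx[, 3])
  variable <- variable & nd == 2L
  calls <- matrix(.BASES[baseIdx[variable, , drop = FALSE] + 1],
                  ncol = 4)
  list(key = ukey[variable], calls = calls)
}

#' Simulate Jukes-Cantor sequences along one genealogy
#'
#' Places mutations on each branch by a Poisson process with per-site
#' expected substitutions equal to branch length (2N units) times `theta/2`,
#' resolving each substitution uniformly among the three alternative bases.
#' The root sequence is uniform over A/C/G/T. Consumes the current RNG
#' stream.
#'
#' @param tree a [GeneTree-class].
#' @param locusLength alignment length in bp.
#' @param theta population mutation parameter.
#' @return a [Biostrings::DNAStringSet] of 4 aligned sequences named after
#'   the tips.
#' @export
simulateLocusSequences <- function(tree, locusLength, theta = 0.001) {
  stopifnot(is(tree, "GeneTree"))
  params <- SimParams(theta = theta)  # only theta is read below
  tr <- list(m1a = tree@merges[1, 1], m1b = tree@merges[1, 2],
             t1 = tree@merges[1, 3],
             m2a = tree@merges[2, 1], m2b = tree@merges[2, 2],
             t2 = tree@merges[2, 3],
             m3a = tree@merges[3, 1], m3b = tree@merges[3, 2],
             t3 = tree@merges[3, 3])
  # tip branch rates are uniform theta here: bypass species-merge scaling
  u1 <- tr$m1a + tr$m1b; u2 <- tr$m2a + tr$m2b
  mask <- matrix(0L, 1, 6); rate <- matrix(0, 1, 6)
  for (t in 1:4) {
    tipm <- .TIPMASK[t]
    death <- if (bitwAnd(as.integer(u1), tipm) > 0) tr$t1
             else if (bitwAnd(as.integer(u2), tipm) > 0) tr$t2 else tr$t3
    mask[, t] <- tipm
    rate[, t] <- 0.5 * theta * death
  }
  d1 <- if (tr$m2a == u1 || tr$m2b == u1) tr$t2 else tr$t3
  mask[, 5] <- as.integer(u1); rate[, 5] <- 0.5 * theta * (d1 - tr$t1)
  mask[, 6] <- as.integer(u2); rate[, 6] <- 0.5 * theta * (tr$t3 - tr$t2)

  locusLength <- as.integer(locusLength)
  anc <- sample.int(4L, locusLength, replace = TRUE) - 1L
  seqIdx <- matrix(anc, locusLength, 4)
  mut <- .drawMutations(list(mask = mask, rate = rate), locusLength)
  if (length(mut$site)) {
    for (t in 1:4) {
      hit <- bitwAnd(mut$mask, .TIPMASK[t]) > 0
      if (any(hit)) {
        add <- rowsum(mut$delta[hit], mut$site[hit])
        sidx <- as.integer(rownames(add))
        seqIdx[sidx, t] <- (seqIdx[sidx, t] + add[, 1]) %% 4
      }
    }
  }
  out <- Biostrings::DNAStringSet(apply(seqIdx, 2, function(ix)
    paste(.BASES[ix + 1], collapse = "")))
  names(out) <- tree@tips
  out
}

#' Simulate a multi-locus four-taxon dataset
#'
#' Simulates `nLoci` independent non-recombining loci (genealogy plus
#' Jukes-Cantor sequences) and concatenates their variable columns into a
#' [SiteMatrix-class] with samples P1, P2, P3, O. Loci are laid out
#' consecutively on one synthetic chromosome `"sim"`; the per-locus
#' boundaries are returned as a `GRanges`, so the loci double as the
#' window tiling for bootstrap and D2 analyses.
#'
#' @param params a [SimParams-class]; `params@seed` seeds the simulation.
#' @return a list with elements `sites` (the `SiteMatrix`), `loci` (locus
#'   `GRanges`), `topology` (true per-locus gene-tree class, "AB"/"BC"/
#'   "AC"/"other"), and `params`.
#' @examples
#' d <- simulateDataset(SimParams(gamma = 0.2, nLoci = 50, locusLength = 2000))
#' d$sites
#' @export
simulateDataset <- function(params) {
  stopifnot(is(params, "SimParams"))
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(params@seed)
  n <- params@nLoci
  L <- params@locusLength
  tr <- .simTrees(n, params)
  edges <- .treeEdgeRates(tr, params)
  mut <- .drawMutations(edges, L)
  res <- .mutationsToSites(mut, L)
  calls <- res$calls
  colnames(calls) <- c("P1", "P2", "P3", "O")
  sm <- SiteMatrix(calls, chrom = "sim", pos = res$key)
  loci <- GenomicRanges::GRanges(
    "sim", IRanges::IRanges(start = (seq_len(n) - 1) * as.numeric(L) + 1,
                            width = L),
    seqlengths = c(sim = n * as.numeric(L)))
  S4Vectors::mcols(loci)$topology <- unname(tr$topology)
  list(sites = sm, loci = loci, topology = unname(tr$topology),
       params = params)
}

#' Accuracy grid for the admixture-proportion statistic
#'
#' Reruns the simulation design used to validate Dp as an estimator of the
#' admixture proportion: for every combination of introgression direction,
#' pulse timing and gamma, simulates replicate multi-locus datasets,
#' computes genome-wide D and Dp on each, and reports cell means.
#'
#' @param directions character, subset of `c("P3_to_P2", "P2_to_P3")`.
#' @param timings pulse times in N generations (default `c(0.2, 0.04)`).
#' @param gammas admixture proportions (default `seq(0.05, 0.95, by = 0.1)`).
#' @param nReplicates replicates per cell (100 in the full design).
#' @param nLoci,locusLength,theta locus settings (full design: 10000 loci of
#'   10 kb, theta 0.001).
#' @param seed integer master seed; every replicate derives its own child
#'   seed from it.
#' @return a `data.frame` with one row per (direction, timing, gamma) cell:
#'   mean and sd of D and Dp over replicates, and the replicate count.
#' @export
runDpValidation <- function(directions = c("P3_to_P2", "P2_to_P3"),
                            timings = c(0.2, 0.04),
                            gammas = seq(0.05, 0.95, by = 0.1),
                            nReplicates = 100, nLoci = 10000,
                            locusLength = 10000, theta = 0.001, seed = 1) {
  grid <- expand.grid(direction = directions, tM = timings, gamma = gammas,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    dd <- numeric(nReplicates); dp <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
      p <- SimParams(direction = grid$direction[g], tM = grid$tM[g],
                     gamma = grid$gamma[g], theta = theta,
                     locusLength = locusLength, nLoci = nLoci,
                     seed = .childSeed(seed, g * 100000 + r))
      sim <- simulateDataset(p)
      ps <- polarizeSites(sim$sites, c("P1", "P2", "P3", "O"))
      cnt <- countPatterns(ps)
      dd[r] <- computeD(cnt)
      dp[r] <- computeDp(cnt)
    }
    data.frame(direction = grid$direction[g], tM = grid$tM[g],
               gamma = grid$gamma[g], meanD = mean(dd), sdD = stats::sd(dd),
               meanDp = mean(dp), sdDp = stats::sd(dp),
               nReplicates = nReplicates)
  })
  do.call(rbind, out)
}
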