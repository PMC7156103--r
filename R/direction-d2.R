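# D2: topology-conditioned P1-P3 divergence contrast for inferring the
# primary direction of introgression (P2 -> P3 vs P3 -> P2).

#' Per-window gene-tree topology and pairwise divergences
#'
#' For each window, computes the three ingroup pairwise divergences
#' (p-distance: differing sites over the window span in bp; invariant
#' positions, absent from a `SiteMatrix`, contribute zero differences) and
#' labels the window by the ingroup pair with the smallest divergence:
#' `"AB"` (P1,P2; concordant with the species branching order), `"BC"`
#' (P2,P3; the introgression topology), or `"AC"` (P1,P3). Windows where
#' the margin between the two smallest divergences is zero (an exact tie)
#' or below `tieTolerance`, including empty windows, are `"unresolved"`.
#'
#' @param x a [SiteMatrix-class] containing the trio samples.
#' @param windows window `GRanges` (e.g. [partitionWindows()] output or the
#'   `loci` of [simulateDataset()]).
#' @param trio character(4): P1, P2, P3, outgroup sample identifiers.
#' @param tieTolerance minimum margin (substitutions/site) between the two
#'   smallest divergences for a window to be called (default 0: only exact
#'   ties are unresolved).
#' @return a `data.frame` with one row per window: `label`, divergences
#'   `dAB`, `dAC`, `dBC` (for pairs P1P2, P1P3, P2P3), and `nSites`
#'   (variable sites in the window).
#' @export
assignTopology <- function(x, windows, trio, tieTolerance = 0) {
  stopifnot(is(x, "SiteMatrix"), length(trio) == 4L)
  missing <- setdiff(trio, sampleNames(x))
  if (length(missing))
    stop("unknown sample ID(s): ", paste(missing, collapse = ", "))
  p1 <- x@calls[, trio[1]]; p2 <- x@calls[, trio[2]]; p3 <- x@calls[, trio[3]]
  hits <- GenomicRanges::findOverlaps(x@positions, windows)
  wid <- S4Vectors::subjectHits(hits); sid <- S4Vectors::queryHits(hits)
  nw <- length(windows)
  span <- GenomicRanges::width(windows)
  diffCount <- function(a, b) {
    d <- a[sid] != b[sid] & a[sid] != "N" & b[sid] != "N"
    tabulate(wid[d], nbins = nw)
  }
  dAB <- diffCount(p1, p2) / span
  dAC <- diffCount(p1, p3) / span
  dBC <- diffCount(p2, p3) / span
  dm <- cbind(AB = dAB, AC = dAC, BC = dBC)
  ord1 <- apply(dm, 1, which.min)
  smallest <- dm[cbind(seq_len(nw), ord1)]
  second <- apply(dm, 1, function(r) sort(r, partial = 2)[2])
  margin <- second - smallest
  label <- colnames(dm)[ord1]
  label[margin == 0 | margin < tieTolerance] <- "unresolved"
  data.frame(label = factor(label,
                            levels = c("AB", "AC", "BC", "unresolved")),
             dAB = dAB, dAC = dAC, dBC = dBC,
             nSites = tabulate(wid, nbins = nw))
}

#' The D2 statistic from labelled windows
#'
#' `D2 = dAC|AB - dAC|BC`: the mean P1-P3 divergence over species-topology
#' ("AB") windows minus the same mean over introgression-topology ("BC")
#' windows. Under the multispecies network coalescent D2 is expected to be
#' positive when introgression is primarily P2 -> P3; lineage-specific Ne
#' and admixture proportions away from 0.5 shift it, which is why
#' significance is assessed against a simulated null ([d2NullTest()]) rather
#' than against zero.
#'
#' @param windowTable output of [assignTopology()], optionally filtered
#'   (e.g. to windows passing a SNP-count threshold).
#' @param minSites windows with fewer variable sites are ignored
#'   (default 0).
#' @return a [D2Result-class] (with `pNull` unset). If either topology class
#'   is empty, `d2` is `NA` with a warning.
#' @export
computeD2 <- function(windowTable, minSites = 0) {
  wt <- windowTable[windowTable$nSites >= minSites, , drop = FALSE]
  abRows <- wt$label == "AB"; bcRows <- wt$label == "BC"
  nAb <- sum(abRows); nBc <- sum(bcRows)
  if (nAb == 0L || nBc == 0L) {
    warning("D2 undefined: a topology class is empty (AB: ", nAb,
            ", BC: ", nBc, " windows)")
    return(new("D2Result", dAcAb = NA_real_, dAcBc = NA_real_, d2 = NA_real_,
               nAb = as.integer(nAb), nBc = as.integer(nBc)))
  }
  dAcAb <- mean(wt$dAC[abRows])
  dAcBc <- mean(wt$dAC[bcRows])
  new("D2Result", dAcAb = dAcAb, dAcBc = dAcBc, d2 = dAcAb - dAcBc,
      nAb = as.integer(nAb), nBc = as.integer(nBc))
}

#' Convert split times from years to N-generation units
#'
#' Branch lengths in years are converted with `years / (generationTime * Ne)`
#' (years to generations, then to units of N generations). The 2N-scaled
#' coalescent units used internally by the simulator are half of these.
#'
#' @param years time in years.
#' @param Ne effective population size (default 1e6).
#' @param generationTime years per generation (default 2).
#' @return time in N generations, suitable for [SimParams()].
#' @export
yearsToNGen <- function(years, Ne = 1e6, generationTime = 2) {
  years / (generationTime * Ne)
}

#' Test an observed D2 against a simulated P3-into-P2 null
#'
#' Simulates `nReps` multi-locus datasets under P3 -> P2 introgression at
#' the trio's estimated admixture proportion (typically its Dp), computes
#' D2 on each exactly as for the observed data, and reports
#' `pNull = (#{null D2 >= observed} + 1) / (nValid + 1)`, one-sided toward
#' positive D2 (the P2 -> P3 signature). With `alternative = "two.sided"`
#' the tail is doubled and capped at 1.
#'
#' @param observed a [D2Result-class] or a single observed D2 value.
#' @param params a [SimParams-class] describing the null scenario: split
#'   times for the trio, `direction = "P3_to_P2"`, `gamma` set to the
#'   trio's estimated admixture proportion, `nLoci` matching the number of
#'   empirical windows and `locusLength` the window size. Use
#'   [yearsToNGen()] to convert clock-based split times.
#' @param nReps null replicates (default 1000).
#' @param tieTolerance,minSites passed to [assignTopology()] /
#'   [computeD2()], matching the observed analysis.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param seed integer master seed.
#' @return the observed [D2Result-class] with `pNull`, `nullMean`,
#'   `nullSd` and `nullQuantiles` filled in.
#' @export
d2NullTest <- function(observed, params, nReps = 1000, tieTolerance = 0,
                       minSites = 0, alternative = c("greater", "two.sided"),
                       seed = 1) {
  alternative <- match.arg(alternative)
  if (is.numeric(observed))
    observed <- new("D2Result", dAcAb = NA_real_, dAcBc = NA_real_,
                    d2 = as.numeric(observed), nAb = NA_integer_,
                    nBc = NA_integer_)
  stopifnot(is(observed, "D2Result"), is(params, "SimParams"))
  if (params@direction != "P3_to_P2")
    stop("the null scenario is P3 -> P2 introgression; set direction accordingly")
  nullD2 <- vapply(seq_len(nReps), function(r) {
    p <- params
    p@seed <- .childSeed(seed, r)
    sim <- simulateDataset(p)
    wt <- assignTopology(sim$sites, sim$loci, c("P1", "P2", "P3", "O"),
                         tieTolerance = tieTolerance)
    suppressWarnings(computeD2(wt, minSites = minSites)@d2)
  }, numeric(1))
  valid <- nullD2[!is.na(nullD2)]
  if (!length(valid)) stop("all null replicates had an undefined D2")
  p1s <- (sum(valid >= observed@d2) + 1) / (length(valid) + 1)
  pNull <- if (alternative == "greater") p1s else {
    pLo <- (sum(valid <= observed@d2) + 1) / (length(valid) + 1)
    min(1, 2 * min(p1s, pLo))
  }
  observed@pNull <- pNull
  observed@nullMean <- mean(valid)
  observed@nullSd <- stats::sd(valid)
  observed@nullQuantiles <- stats::quantile(valid,
                                            c(0.025, 0.25, 0.5, 0.75, 0.975))
  observed
}
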