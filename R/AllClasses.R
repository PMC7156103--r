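#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' SiteMatrix: per-sample allele calls at variant sites
#'
#' Holds single-character calls (A, C, G, T, or N for missing) for an ordered
#' set of samples at an ordered set of genomic sites in reference coordinates.
#' Sites are stored as a [GenomicRanges::GRanges] of width-1 positions
#' (1-based, as is conventional for `GRanges`); calls are a sites x samples
#' character matrix.
#'
#' Readers ([readAlignment()]) retain only variable, at-most-biallelic columns;
#' the constructor itself is permissive (any mix of A/C/G/T/N) so that small
#' hand-built matrices, e.g. for pairwise-distance computations over invariant
#' columns, are representable.
#'
#' @slot positions `GRanges` of site coordinates (width 1), sorted within
#'   chromosome.
#' @slot calls character matrix, one row per site, one column per sample;
#'   entries in `{A,C,G,T,N}`; column names are the sample identifiers.
#' @exportClass SiteMatrix
setClass("SiteMatrix",
  representation(positions = "GRanges", calls = "matrix"))

setValidity("SiteMatrix", function(object) {
  msg <- character()
  if (!is.character(object@calls))
    msg <- c(msg, "'calls' must be a character matrix")
  if (length(object@positions) != nrow(object@calls))
    msg <- c(msg, "number of positions must equal nrow(calls)")
  if (is.null(colnames(object@calls)))
    msg <- c(msg, "'calls' must have sample identifiers as column names")
  if (anyDuplicated(colnames(object@calls)))
    msg <- c(msg, "duplicated sample identifiers")
  bad <- !(object@calls %in% c("A", "C", "G", "T", "N"))
  if (any(bad))
    msg <- c(msg, "calls must be one of A, C, G, T, N")
  # strictly increasing positions within each chromosome
  ch <- as.character(GenomeInfoDb::seqnames(object@positions))
  po <- GenomicRanges::start(object@positions)
  if (length(po) > 1L) {
    same <- ch[-1L] == ch[-length(ch)]
    if (any(same & diff(po) <= 0))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' PolarizedSites: A/B-coded site states for one ordered trio
#'
#' Sites retained after polarizing a [SiteMatrix] against the outgroup of an
#' ordered quartet (P1, P2, P3, outgroup). Each record codes the P1/P2/P3
#' alleles as "A" (the outgroup, i.e. ancestral, allele) or "B" (derived).
#' Only sites with a non-missing outgroup call, no missing ingroup call, and
#' exactly two alleles across the four samples are retained; `dropped` tallies
#' the discarded sites by reason.
#'
#' @slot trio character(4): the P1, P2, P3 and outgroup sample identifiers.
#' @slot positions `GRanges` of retained sites, sorted.
#' @slot states character matrix (sites x 3, columns p1/p2/p3) of "A"/"B".
#' @slot dropped named integer vector of drop reasons
#'   (`outgroup_missing`, `ingroup_missing`, `not_biallelic`, `invariant`).
#' @exportClass PolarizedSites
setClass("PolarizedSites",
  representation(trio = "character", positions = "GRanges",
                 states = "matrix", dropped = "integer"))

setValidity("PolarizedSites", function(object) {
  msg <- character()
  if (length(object@trio) != 4L)
    msg <- c(msg, "'trio' must name exactly 4 samples (P1, P2, P3, outgroup)")
  if (nrow(object@states) != length(object@positions))
    msg <- c(msg, "states and positions disagree in length")
  if (ncol(object@states) != 3L)
    msg <- c(msg, "'states' must have 3 columns (p1, p2, p3)")
  if (any(!(object@states %in% c("A", "B"))))
    msg <- c(msg, "states must be 'A' or 'B'")
  if (length(msg)) msg else TRUE
})

#' PatternCounts: ABBA/BABA/BBAA tallies for one trio
#'
#' @slot abba,baba,bbaa nonnegative counts of the three pattern classes.
#' @exportClass PatternCounts
setClass("PatternCounts",
  representation(abba = "numeric", baba = "numeric", bbaa = "numeric"))

setValidity("PatternCounts", function(object) {
  v <- c(object@abba, object@baba, object@bbaa)
  if (length(v) != 3L || any(is.na(v)) || any(v < 0) || any(v != round(v)))
    "abba, baba, bbaa must be single nonnegative integers" else TRUE
})

#' BootstrapResult: block-bootstrap inference for Patterson's D
#'
#' @slot meanD Patterson's D of the full (unresampled) pattern counts.
#' @slot bootMean mean of the bootstrap-replicate D values.
#' @slot sd,se standard deviation of the replicate distribution and the
#'   standard error of the mean (`sd / sqrt(nReps)`).
#' @slot ci95 numeric(2), percentile 2.5%/97.5% bounds of the replicates.
#' @slot pRaw overlap-with-zero p-value: the fraction of replicates on the
#'   side of zero opposite to the sign of `meanD` (or equal to zero). When no
#'   replicate falls on the opposite side it is stored as `1/(nReps + 1)`.
#' @slot pTwo two-sided version, `min(1, 2 * pRaw)`; this is the calibrated
#'   p-value for the two-sided hypothesis D != 0.
#' @slot pAdj Bonferroni-adjusted `pRaw` (NA until [adjustPvalues()] is run).
#' @slot nReps,seed replicate count and RNG seed used.
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(meanD = "numeric", bootMean = "numeric", sd = "numeric",
                 se = "numeric", ci95 = "numeric", pRaw = "numeric",
                 pTwo = "numeric", pAdj = "numeric", nReps = "integer",
                 seed = "integer"))

#' SimParams: a four-taxon coalescent scenario with one introgression pulse
#'
#' Split times are given in units of N generations, matching the usual way
#' such scenarios are reported; internally the simulator works on the 2N
#' (pairwise-coalescence-rate-1) scale, i.e. printed values are halved.
#' `t12` is the P1-P2 split, `t3` the split of P3 from the P1/P2 ancestor,
#' `tOut` the outgroup split, and `tM` the time of the single instantaneous
#' introgression pulse (`tM < t12 < t3 < tOut`). `direction` names the
#' forward-in-time donor -> recipient pair, and `gamma` the admixture
#' proportion (probability that a recipient-lineage traces its ancestry
#' through the donor population at the pulse).
#'
#' `theta` is the population mutation parameter: per-site expected
#' substitutions on a branch equal branch length (2N units) times `theta/2`.
#' `tipThetas` optionally scales the terminal-branch mutation rate per taxon
#' (order P1, P2, P3, outgroup), applied to the portion of each tip branch
#' preceding that taxon's species merge; used to encode lineage-specific
#' heterozygosity proxies in D2 null simulations.
#'
#' @slot t12,t3,tOut,tM split and pulse times in N generations.
#' @slot direction `"P2_to_P3"` or `"P3_to_P2"`.
#' @slot gamma admixture proportion in `[0, 1]`.
#' @slot theta population mutation parameter (default 0.001).
#' @slot tipThetas per-taxon theta for tip branches, or NULL for `theta`.
#' @slot locusLength locus length in bp (default 10000).
#' @slot nLoci number of independent non-recombining loci (default 10000).
#' @slot seed integer RNG seed.
#' @exportClass SimParams
setClass("SimParams",
  representation(t12 = "numeric", t3 = "numeric", tOut = "numeric",
                 tM = "numeric", direction = "character", gamma = "numeric",
                 theta = "numeric", tipThetas = "numericOrNULL",
                 locusLength = "integer", nLoci = "integer", seed = "integer"),
  prototype(t12 = 1.2, t3 = 2.4, tOut = 16, tM = 0.2,
            direction = "P3_to_P2", gamma = 0, theta = 0.001,
            tipThetas = NULL, locusLength = 10000L, nLoci = 10000L,
            seed = 1L))

setValidity("SimParams", function(object) {
  msg <- character()
  if (!(object@tM < object@t12 && object@t12 < object@t3 &&
        object@t3 < object@tOut))
    msg <- c(msg, "times must satisfy tM < t12 < t3 < tOut")
  if (object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must lie in [0, 1]")
  if (!object@direction %in% c("P2_to_P3", "P3_to_P2"))
    msg <- c(msg, "direction must be 'P2_to_P3' or 'P3_to_P2'")
  if (object@theta <= 0) msg <- c(msg, "theta must be positive")
  if (!is.null(object@tipThetas) && length(object@tipThetas) != 4L)
    msg <- c(msg, "tipThetas must have length 4 (P1, P2, P3, outgroup)")
  if (object@locusLength < 1L) msg <- c(msg, "locusLength must be >= 1")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  if (length(msg)) msg else TRUE
})

#' GeneTree: one simulated four-tip genealogy
#'
#' A rooted ultrametric genealogy over tips P1, P2, P3, O. The tree is stored
#' as its three coalescence events, each merging two clusters of tips
#' (encoded as bitmasks over tips 1..4) at a time in 2N coalescent units.
#'
#' @slot merges numeric matrix (3 x 3, columns mask1/mask2/time): the
#'   clusters merged at each coalescence, in increasing time order.
#' @slot tips character(4), tip labels (P1, P2, P3, O).
#' @exportClass GeneTree
setClass("GeneTree",
  representation(merges = "matrix", tips = "character"),
  prototype(tips = c("P1", "P2", "P3", "O")))

setValidity("GeneTree", function(object) {
  m <- object@merges
  if (!is.numeric(m) || nrow(m) != 3L || ncol(m) != 3L)
    return("'merges' must be a 3 x 3 numeric matrix (mask1, mask2, time)")
  if (is.unsorted(m[, 3L]))
    return("merge times must be nondecreasing")
  if (bitwOr(as.integer(m[3L, 1L]), as.integer(m[3L, 2L])) != 15L)
    return("final merge must produce the root of all 4 tips")
  TRUE
})

#' D2Result: topology-conditioned divergence contrast
#'
#' For a trio with species topology ((P1,P2),P3), `dAcAb` is the mean P1-P3
#' divergence over windows whose genealogy matches the species branching
#' order ("AB" windows) and `dAcBc` the same mean over windows matching the
#' introgression topology ("BC" windows); `d2 = dAcAb - dAcBc`. Positive
#' values indicate introgression primarily from P2 into P3. `pNull` and the
#' null summary are filled by [d2NullTest()].
#'
#' @slot dAcAb,dAcBc mean P1-P3 divergence (substitutions/site) by topology.
#' @slot d2 their difference.
#' @slot nAb,nBc window counts in each topology class.
#' @slot pNull one-sided p-value against the simulated P3-into-P2 null
#'   (NA before [d2NullTest()]).
#' @slot nullMean,nullSd,nullQuantiles summary of the simulated null D2
#'   distribution.
#' @exportClass D2Result
setClass("D2Result",
  representation(dAcAb = "numeric", dAcBc = "numeric", d2 = "numeric",
                 nAb = "integer", nBc = "integer", pNull = "numeric",
                 nullMean = "numeric", nullSd = "numeric",
                 nullQuantiles = "numeric"),
  prototype(pNull = NA_real_, nullMean = NA_real_, nullSd = NA_real_,
            nullQuantiles = numeric()))
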