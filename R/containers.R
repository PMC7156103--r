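#' Construct a SiteMatrix
#'
#' @param calls character matrix of single-letter calls (`A/C/G/T/N`), one row
#'   per site, one column per sample; column names are sample identifiers.
#' @param chrom chromosome of each site (recycled if length 1).
#' @param pos 1-based position of each site; strictly increasing within a
#'   chromosome.
#' @return a [SiteMatrix-class] object.
#' @examples
#' m <- SiteMatrix(matrix(c("A","G","A","G","C","C","C","T"), 2,
#'                        dimnames = list(NULL, c("s1","s2","s3","s4"))),
#'                 chrom = "1", pos = c(10, 20))
#' nSites(m)
#' @export
SiteMatrix <- function(calls, chrom, pos) {
  calls <- as.matrix(calls)
  gr <- GenomicRanges::GRanges(rep(chrom, length.out = length(pos)),
                               IRanges::IRanges(pos, width = 1L))
  new("SiteMatrix", positions = gr, calls = calls)
}

#' @rdname nSites
#' @export
setMethod("nSites", "SiteMatrix", function(x) nrow(x@calls))

#' @rdname nSites
#' @export
setMethod("nSites", "PolarizedSites", function(x) nrow(x@states))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "SiteMatrix", function(x) colnames(x@calls))

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "SiteMatrix", function(x) x@positions)

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "PolarizedSites", function(x) x@positions)

#' Allele calls of a SiteMatrix
#' @param x a `SiteMatrix`.
#' @return the sites x samples character matrix of calls.
#' @export
siteCalls <- function(x) {
  stopifnot(is(x, "SiteMatrix"))
  x@calls
}

#' Polarized A/B states of a PolarizedSites object
#' @param x a `PolarizedSites`.
#' @return character matrix (sites x 3, columns p1/p2/p3) of "A"/"B".
#' @export
siteStates <- function(x) {
  stopifnot(is(x, "PolarizedSites"))
  x@states
}

#' Trio labels of a PolarizedSites object
#' @param x a `PolarizedSites`.
#' @return character(4): P1, P2, P3, outgroup sample identifiers.
#' @export
trioLabels <- function(x) {
  stopifnot(is(x, "PolarizedSites"))
  x@trio
}

#' Drop tallies from polarization
#' @param x a `PolarizedSites`.
#' @return named integer vector of sites dropped per reason.
#' @export
droppedSites <- function(x) {
  stopifnot(is(x, "PolarizedSites"))
  x@dropped
}

#' Construct site-pattern counts
#'
#' @param abba,baba,bbaa nonnegative counts of the ABBA, BABA and BBAA
#'   site-pattern classes for one ordered trio.
#' @return a [PatternCounts-class] object.
#' @examples
#' computeD(PatternCounts(abba = 179196, baba = 167118, bbaa = 676317))
#' @export
PatternCounts <- function(abba = 0, baba = 0, bbaa = 0) {
  new("PatternCounts", abba = as.numeric(abba), baba = as.numeric(baba),
      bbaa = as.numeric(bbaa))
}

#' Accessors for pattern counts
#' @param x a `PatternCounts`.
#' @return the requested count (or, for `patternTotal`, abba+baba+bbaa).
#' @name pattern-accessors
NULL

#' @rdname pattern-accessors
#' @export
abba <- function(x) x@abba
#' @rdname pattern-accessors
#' @export
baba <- function(x) x@baba
#' @rdname pattern-accessors
#' @export
bbaa <- function(x) x@bbaa
#' @rdname pattern-accessors
#' @export
patternTotal <- function(x) x@abba + x@baba + x@bbaa

#' Construct a coalescent scenario
#'
#' Defaults encode the validation design used throughout: P1-P2 split at 1.2N
#' generations, P3 at 2.4N, outgroup at 16N, pulse at 0.2N, Jukes-Cantor
#' mutation with theta = 0.001 on 10-kb loci. See [SimParams-class] for the
#' meaning of each field.
#'
#' @param t12,t3,tOut,tM split/pulse times in N generations.
#' @param direction `"P2_to_P3"` or `"P3_to_P2"` (forward in time).
#' @param gamma admixture proportion in `[0, 1]`.
#' @param theta population mutation parameter.
#' @param tipThetas optional per-taxon tip-branch theta (P1, P2, P3, O).
#' @param locusLength locus length in bp.
#' @param nLoci number of independent loci.
#' @param seed integer RNG seed.
#' @return a [SimParams-class] object.
#' @export
SimParams <- function(t12 = 1.2, t3 = 2.4, tOut = 16, tM = 0.2,
                      direction = c("P3_to_P2", "P2_to_P3"), gamma = 0,
                      theta = 0.001, tipThetas = NULL, locusLength = 10000,
                      nLoci = 10000, seed = 1) {
  direction <- match.arg(direction)
  new("SimParams", t12 = t12, t3 = t3, tOut = tOut, tM = tM,
      direction = direction, gamma = gamma, theta = theta,
      tipThetas = if (is.null(tipThetas)) NULL else as.numeric(tipThetas),
      locusLength = as.integer(locusLength), nLoci = as.integer(nLoci),
      seed = as.integer(seed))
}

setMethod("show", "SiteMatrix", function(object) {
  cat("SiteMatrix:", nSites(object), "sites x",
      ncol(object@calls), "samples\n")
  cat("  samples:", paste(utils::head(sampleNames(object), 6),
                          collapse = ", "),
      if (ncol(object@calls) > 6) "..." else "", "\n")
  cat("  chromosomes:",
      paste(GenomeInfoDb::seqlevels(object@positions), collapse = ", "), "\n")
})

setMethod("show", "PolarizedSites", function(object) {
  cat("PolarizedSites for trio (P1, P2, P3, O) =",
      paste(object@trio, collapse = ", "), "\n")
  cat("  retained sites:", nSites(object), "\n")
  if (sum(object@dropped) > 0) {
    cat("  dropped:",
        paste(names(object@dropped), object@dropped, collapse = "; "), "\n")
  }
})

setMethod("show", "PatternCounts", function(object) {
  cat(sprintf("PatternCounts: ABBA=%g BABA=%g BBAA=%g\n",
              object@abba, object@baba, object@bbaa))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf(
    "BootstrapResult: D=%.4g (boot sd %.3g, se %.3g)\n  95%% CI [%.4g, %.4g]  pRaw=%.4g  pTwo=%.4g  pAdj=%s  (%d reps, seed %d)\n",
    object@meanD, object@sd, object@se, object@ci95[1], object@ci95[2],
    object@pRaw, object@pTwo,
    if (is.na(object@pAdj)) "NA" else format(object@pAdj, digits = 4),
    object@nReps, object@seed))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: splits (N gens) t12=%g t3=%g tOut=%g; pulse tM=%g %s gamma=%g\n  theta=%g locus=%d bp x %d loci, seed %d\n",
    object@t12, object@t3, object@tOut, object@tM, object@direction,
    object@gamma, object@theta, object@locusLength, object@nLoci,
    object@seed))
})

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree:", geneTreeNewick(object), "\n")
})

setMethod("show", "D2Result", function(object) {
  cat(sprintf(
    "D2Result: dAC|AB=%.5g (%d windows)  dAC|BC=%.5g (%d windows)\n  D2=%.5g  pNull=%s\n",
    object@dAcAb, object@nAb, object@dAcBc, object@nBc, object@d2,
    if (is.na(object@pNull)) "NA (run d2NullTest)"
    else format(object@pNull, digits = 4)))
})
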