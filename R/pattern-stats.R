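#' Classify polarized sites into ABBA / BABA / BBAA / OTHER
#'
#' Site patterns are read over the ordered quartet (P1, P2, P3, outgroup)
#' with the outgroup always "A": `(A,B,B)` is ABBA, `(B,A,B)` is BABA,
#' `(B,B,A)` is BBAA. All-ancestral, all-derived and singleton-derived
#' patterns are uninformative and classified OTHER.
#'
#' @param p1,p2,p3 character vectors of "A"/"B" states (recycled to a common
#'   length), or a single sites x 3 matrix passed as `p1`.
#' @return factor with levels ABBA, BABA, BBAA, OTHER.
#' @examples
#' classifySite(c("A","B"), c("B","A"), c("B","B"))
#' @export
classifySite <- function(p1, p2 = NULL, p3 = NULL) {
  if (is.matrix(p1)) {
    p2 <- p1[, 2]; p3 <- p1[, 3]; p1 <- p1[, 1]
  }
  if (any(!(c(p1, p2, p3) %in% c("A", "B"))))
    stop("states must be 'A' or 'B'")
  out <- rep("OTHER", max(length(p1), length(p2), length(p3)))
  out[p1 == "A" & p2 == "B" & p3 == "B"] <- "ABBA"
  out[p1 == "B" & p2 == "A" & p3 == "B"] <- "BABA"
  out[p1 == "B" & p2 == "B" & p3 == "A"] <- "BBAA"
  factor(out, levels = c("ABBA", "BABA", "BBAA", "OTHER"))
}

#' Tally ABBA/BABA/BBAA patterns
#'
#' Counts the three informative site-pattern classes over the records of a
#' [PolarizedSites-class] object, optionally restricted to one window.
#' OTHER-class sites are not counted.
#'
#' @param x a `PolarizedSites` object.
#' @param window optional restriction: either a length-1 `GRanges` window or
#'   an integer vector of site indices (as stored in the `siteIdx` column of
#'   [partitionWindows()] output).
#' @param ... unused.
#' @return a [PatternCounts-class].
#' @rdname countPatterns
#' @export
setMethod("countPatterns", "PolarizedSites", function(x, window = NULL, ...) {
  st <- x@states
  if (!is.null(window)) {
    idx <- if (is(window, "GRanges")) {
      stopifnot(length(window) == 1L)
      S4Vectors::queryHits(GenomicRanges::findOverlaps(x@positions, window))
    } else as.integer(window)
    st <- st[idx, , drop = FALSE]
  }
  .countPatternsMatrix(st)
})

.countPatternsMatrix <- function(st) {
  if (!nrow(st)) return(PatternCounts(0, 0, 0))
  p1 <- st[, 1]; p2 <- st[, 2]; p3 <- st[, 3]
  PatternCounts(abba = sum(p1 == "A" & p2 == "B" & p3 == "B"),
                baba = sum(p1 == "B" & p2 == "A" & p3 == "B"),
                bbaa = sum(p1 == "B" & p2 == "B" & p3 == "A"))
}

#' Patterson's D statistic
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`. Positive values indicate an excess of
#' ABBA, i.e. allele exchange between P2 and P3; negative values an excess of
#' BABA (P1 with P3). Undefined (returned as `NA`, with a warning) when
#' `ABBA + BABA = 0`, which is distinct from a true 0.
#'
#' @param x a [PatternCounts-class], or the ABBA count.
#' @param baba,bbaa counts when `x` is given numerically.
#' @param ... unused.
#' @return a single numeric in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' computeD(PatternCounts(abba = 179196, baba = 167118))
#' @rdname computeD
#' @export
setMethod("computeD", "PatternCounts", function(x, ...) {
  if (x@abba + x@baba == 0) {
    warning("D undefined: ABBA + BABA = 0")
    return(NA_real_)
  }
  (x@abba - x@baba) / (x@abba + x@baba)
})

#' @rdname computeD
#' @export
setMethod("computeD", "numeric", function(x, baba, ...) {
  computeD(PatternCounts(abba = x, baba = baba))
})

#' The admixture-proportion statistic Dp
#'
#' `Dp = |ABBA - BABA| / (ABBA + BABA + BBAA)`: the net excess of one
#' discordant pattern as a proportion of all informative variable sites,
#' interpreted as the net fraction of the genome differentially introgressed
#' in the trio. Undefined (returned as `NA`, with a warning) when the
#' denominator is zero.
#'
#' @param x a [PatternCounts-class], or the ABBA count.
#' @param baba,bbaa counts when `x` is given numerically.
#' @param ... unused.
#' @return a single numeric in `[0, 1]`, or `NA` if undefined.
#' @examples
#' computeDp(PatternCounts(abba = 179196, baba = 167118, bbaa = 676317))
#' @rdname computeDp
#' @export
setMethod("computeDp", "PatternCounts", function(x, ...) {
  tot <- x@abba + x@baba + x@bbaa
  if (tot == 0) {
    warning("Dp undefined: ABBA + BABA + BBAA = 0")
    return(NA_real_)
  }
  abs(x@abba - x@baba) / tot
})

#' @rdname computeDp
#' @export
setMethod("computeDp", "numeric", function(x, baba, bbaa, ...) {
  computeDp(PatternCounts(abba = x, baba = baba, bbaa = bbaa))
})

# per-window counts as a windows x 3 matrix (abba, baba, bbaa); windows
# without precomputed siteIdx metadata are assigned by overlap
.windowCountMatrix <- function(x, windows) {
  idxl <- S4Vectors::mcols(windows)$siteIdx
  if (is.null(idxl)) {
    hits <- GenomicRanges::findOverlaps(x@positions, windows)
    idxl <- S4Vectors::split(S4Vectors::queryHits(hits),
                             factor(S4Vectors::subjectHits(hits),
                                    levels = seq_along(windows)))
  }
  st <- x@states
  isA <- st[, 1] == "A" & st[, 2] == "B" & st[, 3] == "B"
  isB <- st[, 1] == "B" & st[, 2] == "A" & st[, 3] == "B"
  isS <- st[, 1] == "B" & st[, 2] == "B" & st[, 3] == "A"
  grp <- rep(seq_along(idxl), lengths(idxl))
  flat <- unlist(idxl, use.names = FALSE)
  m <- matrix(0, length(windows), 3,
              dimnames = list(NULL, c("abba", "baba", "bbaa")))
  if (length(flat)) {
    m[, 1] <- tabulate(grp[isA[flat]], nbins = length(idxl))
    m[, 2] <- tabulate(grp[isB[flat]], nbins = length(idxl))
    m[, 3] <- tabulate(grp[isS[flat]], nbins = length(idxl))
  }
  m
}

#' Per-window D with outlier z-scores
#'
#' Computes pattern counts and D within each window. Windows whose
#' informative-site count (`ABBA + BABA + BBAA`) is not strictly greater
#' than `minSnps` still report their `d`, but are excluded from the z-score
#' computation and can never be outliers. For the retained windows,
#' `z = |d_w - mean(d)| / sd(d)` over retained windows, and a window is
#' flagged as an outlier when `z > zThreshold`.
#'
#' @param x a [PolarizedSites-class].
#' @param windows window `GRanges` from [partitionWindows()].
#' @param minSnps windows must have more than this many informative sites to
#'   enter the z-score computation (default 20; the filter is strict, so a
#'   window with exactly 20 is excluded).
#' @param zThreshold outlier threshold on z (default 3).
#' @return a `data.frame` with one row per window: chrom, start, end
#'   (1-based closed), abba, baba, bbaa, nSnps, d, retained, z, outlier.
#' @export
windowScan <- function(x, windows, minSnps = 20, zThreshold = 3) {
  cm <- .windowCountMatrix(x, windows)
  nSnps <- rowSums(cm)
  d <- ifelse(cm[, 1] + cm[, 2] > 0,
              (cm[, 1] - cm[, 2]) / (cm[, 1] + cm[, 2]), NA_real_)
  retained <- nSnps > minSnps & !is.na(d)
  z <- rep(NA_real_, length(d))
  if (sum(retained) >= 2L) {
    mu <- mean(d[retained]); sdev <- stats::sd(d[retained])
    if (sdev == 0) {
      z[retained] <- 0
    } else {
      z[retained] <- abs(d[retained] - mu) / sdev
    }
  }
  outlier <- !is.na(z) & z > zThreshold
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(windows)),
             start = GenomicRanges::start(windows),
             end = GenomicRanges::end(windows),
             abba = cm[, 1], baba = cm[, 2], bbaa = cm[, 3],
             nSnps = nSnps, d = d, retained = retained, z = z,
             outlier = outlier)
}

#' Block bootstrap for genome-wide D
#'
#' Resamples genomic windows with replacement to obtain the sampling
#' distribution of Patterson's D under linkage. Each replicate draws
#' `nWindowsPerRep` windows uniformly with replacement from the resampling
#' universe (by default, all tiled windows containing at least one
#' informative site), pools their pattern counts, and computes D. The
#' reported `meanD` is the D of the full empirical counts; sd, se and the
#' percentile 95% CI come from the replicate distribution.
#'
#' `pRaw` follows the overlap-with-zero rule: for empirical D > 0 it is the
#' fraction of replicates with D <= 0 (and vice versa); when no replicate
#' falls on the opposite side it is stored as `1/(nReps + 1)`. Because this
#' is a one-sided overlap probability, its null distribution is uniform on
#' (0, 0.5); the two-sided `pTwo = min(1, 2 * pRaw)` is the calibrated
#' p-value for testing D != 0 at a nominal level. For a statistically
#' calibrated bootstrap, set `nWindowsPerRep` equal to the number of
#' windows in the universe (resample size = sample size); the default of
#' 1000 reproduces the fixed-size 100-Mb resample design and is
#' conservative when the universe is larger.
#'
#' @param x a [PolarizedSites-class].
#' @param windows window `GRanges` from [partitionWindows()].
#' @param nWindowsPerRep windows drawn per replicate (default 1000).
#' @param nReps bootstrap replicates (default 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @param universe `"informative"` (default: windows with >= 1 informative
#'   site) or `"all"` (every tiled window).
#' @return a [BootstrapResult-class].
#' @export
blockBootstrap <- function(x, windows, nWindowsPerRep = 1000, nReps = 1000,
                           seed = 1, universe = c("informative", "all")) {
  universe <- match.arg(universe)
  cm <- .windowCountMatrix(x, windows)
  if (universe == "informative") cm <- cm[rowSums(cm) > 0, , drop = FALSE]
  if (!nrow(cm) || sum(cm[, 1] + cm[, 2]) == 0)
    stop("no windows with informative sites: bootstrap impossible")
  tot <- colSums(cm)
  empD <- (tot[1] - tot[2]) / (tot[1] + tot[2])

  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  nReps <- as.integer(nReps)
  idx <- sample.int(nrow(cm), nReps * nWindowsPerRep, replace = TRUE)
  rep_id <- rep(seq_len(nReps), each = nWindowsPerRep)
  ab <- rowsum(cm[idx, 1], rep_id)
  ba <- rowsum(cm[idx, 2], rep_id)
  ok <- (ab + ba) > 0
  if (!any(ok)) stop("all bootstrap replicates degenerate (no ABBA/BABA sites)")
  repD <- rep(NA_real_, nReps)
  repD[ok] <- (ab[ok] - ba[ok]) / (ab[ok] + ba[ok])
  repD <- repD[!is.na(repD)]

  opp <- if (empD > 0) sum(repD <= 0) else if (empD < 0) sum(repD >= 0)
         else length(repD)
  pRaw <- if (opp == 0) 1 / (length(repD) + 1) else opp / length(repD)
  new("BootstrapResult",
      meanD = as.numeric(empD), bootMean = mean(repD),
      sd = stats::sd(repD), se = stats::sd(repD) / sqrt(length(repD)),
      ci95 = unname(stats::quantile(repD, c(0.025, 0.975))),
      pRaw = pRaw, pTwo = min(1, 2 * pRaw), pAdj = NA_real_,
      nReps = nReps, seed = as.integer(seed))
}

#' Bonferroni adjustment
#'
#' `min(1, p * nTests)`, applied elementwise. Mirrors the multiple-test
#' correction over the battery of trios.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param nTests number of tests in the family.
#' @return adjusted p-values, capped at 1.
#' @examples
#' adjustPvalues(0.003, 17)
#' @export
adjustPvalues <- function(p, nTests) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), nTests >= 1)
  pmin(1, p * nTests)
}
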