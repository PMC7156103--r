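# A-priori trio structuring and the clade-wide hypothesis battery:
# sign tests on predicted D signs, regressions of Dp on genetic and
# geographic distance, and accession-disjoint trio subsets.

#' Pairwise genetic distance between two samples
#'
#' Proportion of compared sites (both calls non-missing) that differ, over
#' the sites stored in the matrix. For genome-wide distances the matrix
#' should hold all sites variable across the full sample panel, so that
#' sites invariant within the pair still enter the denominator.
#'
#' @param x a [SiteMatrix-class].
#' @param a,b sample identifiers.
#' @return proportion of differing sites; `NA` (with a warning) if no site
#'   is comparable.
#' @export
pairwiseGeneticDistance <- function(x, a, b) {
  stopifnot(is(x, "SiteMatrix"))
  missing <- setdiff(c(a, b), sampleNames(x))
  if (length(missing))
    stop("unknown sample ID(s): ", paste(missing, collapse = ", "))
  ca <- x@calls[, a]; cb <- x@calls[, b]
  comp <- ca != "N" & cb != "N"
  if (!any(comp)) {
    warning("no comparable sites between ", a, " and ", b)
    return(NA_real_)
  }
  sum(ca[comp] != cb[comp]) / sum(comp)
}

#' Mean ingroup-to-P3 genetic distance of a trio
#'
#' The average of the P1-P3 and P2-P3 pairwise distances, the per-trio
#' divergence measure used in the distance regressions.
#'
#' @param x a [SiteMatrix-class].
#' @param trio character(>=3): P1, P2, P3 sample identifiers (an outgroup
#'   entry, if present, is ignored).
#' @return mean of the two heterospecific pairwise distances.
#' @export
trioGeneticDistance <- function(x, trio) {
  mean(c(pairwiseGeneticDistance(x, trio[1], trio[3]),
         pairwiseGeneticDistance(x, trio[2], trio[3])))
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b coordinates as `c(lat, lon)` in decimal degrees, or two-column
#'   (lat, lon) matrices of equal row count.
#' @return distance(s) in km.
#' @examples
#' haversineKm(c(0, 0), c(0, 180))  # half the equator
#' @export
haversineKm <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (any(abs(a[, 1]) > 90 | abs(b[, 1]) > 90 |
          abs(a[, 2]) > 180 | abs(b[, 2]) > 180))
    stop("coordinates must be (lat in [-90,90], lon in [-180,180])")
  # geosphere expects (lon, lat)
  d <- geosphere::distHaversine(a[, c(2, 1), drop = FALSE],
                                b[, c(2, 1), drop = FALSE], r = 6371000)
  d / 1000
}

#' Relative proximity of P1 versus P2 to the nearest P3 population
#'
#' `min over P3 accessions of dist(P1, .) - min over P3 of dist(P2, .)`,
#' in km. Positive values mean P2 sits closer to the P3 species than P1
#' does, i.e. the trio is structured as predicted for the geographic
#' hypothesis.
#'
#' @param p1,p2 `c(lat, lon)` of the P1 and P2 accessions.
#' @param p3Coords two-column (lat, lon) matrix of P3 accession coordinates
#'   (one row per known P3 population).
#' @return difference of the two minimum distances, km.
#' @export
relativeProximity <- function(p1, p2, p3Coords) {
  p3Coords <- rbind(p3Coords)
  if (!nrow(p3Coords)) stop("at least one P3 coordinate is required")
  if (anyNA(p1) || anyNA(p2) || anyNA(p3Coords))
    stop("missing coordinates")
  d1 <- min(haversineKm(matrix(p1, nrow(p3Coords), 2, byrow = TRUE),
                        p3Coords))
  d2 <- min(haversineKm(matrix(p2, nrow(p3Coords), 2, byrow = TRUE),
                        p3Coords))
  d1 - d2
}

#' Exact two-sided sign test
#'
#' Exact binomial test of `k` successes in `n` trials against p = 0.5,
#' two-sided (the doubled smaller tail, capped at 1).
#'
#' @param k number of successes (e.g. trios with D of the predicted sign).
#' @param n number of trials.
#' @return the two-sided p-value.
#' @examples
#' signTest(10, 13)
#' @export
signTest <- function(k, n) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
}

#' Ordinary least-squares regression of Dp on a predictor
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, R-squared and the
#' t-test p-value on the slope; used for the Dp-versus-genetic-distance and
#' Dp-versus-relative-proximity association tests.
#'
#' @param x predictor values (e.g. trio genetic distance, or relative
#'   proximity in km).
#' @param y responses (Dp per trio).
#' @return a list with `slope`, `intercept`, `rSquared`, `pSlope`, `n`.
#' @export
regressDp <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("at least 3 complete observations are required")
  if (stats::sd(x) == 0) stop("degenerate design: predictor is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = sm$r.squared,
       pSlope = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Maximum accession-disjoint trio sets
#'
#' Enumerates all maximum-cardinality sets of trios whose (P1, P2, P3)
#' accession triples are pairwise disjoint (the shared outgroup is ignored).
#' Exact search; intended for battery sizes of up to a few dozen trios.
#'
#' @param trios a `data.frame` with columns `p1`, `p2`, `p3` (and optionally
#'   `name`, used to label results).
#' @return a list of integer vectors (row indices into `trios`), each a
#'   maximum disjoint set; all returned sets have equal size.
#' @export
disjointTrioSets <- function(trios) {
  n <- nrow(trios)
  if (n < 1) stop("at least one trio is required")
  acc <- lapply(seq_len(n), function(i)
    unique(as.character(unlist(trios[i, c("p1", "p2", "p3")]))))
  compat <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    compat[i, j] <- !length(intersect(acc[[i]], acc[[j]])) || i == j
  best <- list(size = 0L, sets = list())
  recurse <- function(i, chosen) {
    if (i > n) {
      k <- length(chosen)
      if (k > best$size) best <<- list(size = k, sets = list(chosen))
      else if (k == best$size && k > 0L)
        best$sets[[length(best$sets) + 1L]] <<- chosen
      return(invisible())
    }
    if (length(chosen) + (n - i + 1L) < best$size) return(invisible())
    if (all(compat[chosen, i])) recurse(i + 1L, c(chosen, i))
    recurse(i + 1L, chosen)
  }
  recurse(1L, integer(0))
  best$sets
}

#' Read a trio configuration file
#'
#' YAML with a `trios` list (fields: `name`, `p1`, `p2`, `p3`, `outgroup`,
#' `hypothesis` in geographic/mating_system/both, `expected_sign` +1/-1,
#' optional `mating_systems` as a 3-vector of SI/SC for P1/P2/P3) and an
#' optional `accessions` list (fields `id`, `lat`, `lon`, `mating_system`,
#' `species`).
#'
#' @param path YAML file path.
#' @return a list with `trios` and `accessions` data.frames.
#' @export
readTrioConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$trios)) stop("trio config must contain a 'trios' list")
  trios <- do.call(rbind, lapply(cfg$trios, function(t) {
    ms <- t$mating_systems
    data.frame(name = t$name %||% paste(t$p1, t$p2, t$p3, sep = "."),
               p1 = t$p1, p2 = t$p2, p3 = t$p3, outgroup = t$outgroup,
               hypothesis = t$hypothesis %||% NA_character_,
               expected_sign = as.numeric(t$expected_sign %||% 1),
               ms1 = if (is.null(ms)) NA_character_ else ms[[1]],
               ms2 = if (is.null(ms)) NA_character_ else ms[[2]],
               ms3 = if (is.null(ms)) NA_character_ else ms[[3]],
               stringsAsFactors = FALSE)
  }))
  accessions <- NULL
  if (!is.null(cfg$accessions)) {
    accessions <- do.call(rbind, lapply(cfg$accessions, function(a)
      data.frame(id = a$id, lat = as.numeric(a$lat %||% NA),
                 lon = as.numeric(a$lon %||% NA),
                 mating_system = a$mating_system %||% NA_character_,
                 species = a$species %||% NA_character_,
                 stringsAsFactors = FALSE)))
  }
  list(trios = trios, accessions = accessions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
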