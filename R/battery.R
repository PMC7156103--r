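#' BatteryReport: results of a clade-wide trio battery
#'
#' @slot trios per-trio results table (counts, D, Dp, bootstrap inference,
#'   significance, direction call, donor/recipient mating systems, status).
#' @slot signTests list of sign-test results (predicted-sign test and, when
#'   direction calls are available, the SC-to-SI versus SI-to-SC test).
#' @slot regressions list of [regressDp()] results (Dp on genetic distance
#'   and, when coordinates are supplied, on relative proximity).
#' @slot disjointSets list: maximum accession-disjoint subsets of the
#'   significant trios with a sign test re-run within each.
#' @exportClass BatteryReport
setClass("BatteryReport",
  representation(trios = "data.frame", signTests = "list",
                 regressions = "list", disjointSets = "list"))

setMethod("show", "BatteryReport", function(object) {
  cat("BatteryReport:", nrow(object@trios), "trios,",
      sum(object@trios$significant, na.rm = TRUE), "significant\n")
  if (!is.null(object@signTests$predictedSign))
    cat(sprintf("  predicted-sign test: %d/%d, p = %.3g\n",
                object@signTests$predictedSign$k,
                object@signTests$predictedSign$n,
                object@signTests$predictedSign$p))
})

#' Per-trio results of a BatteryReport
#' @param x a `BatteryReport`.
#' @return the per-trio results `data.frame`.
#' @export
batteryTrios <- function(x) {
  stopifnot(is(x, "BatteryReport"))
  x@trios
}

#' Battery-level inference of a BatteryReport
#' @param x a `BatteryReport`.
#' @return list with elements `signTests`, `regressions`, `disjointSets`.
#' @export
batteryTests <- function(x) {
  stopifnot(is(x, "BatteryReport"))
  list(signTests = x@signTests, regressions = x@regressions,
       disjointSets = x@disjointSets)
}

#' Run the clade-wide trio battery
#'
#' For every trio: polarizes the alignment, tallies ABBA/BABA/BBAA, computes
#' D and Dp, runs the block bootstrap, and adjusts p-values over the family
#' of trios (Bonferroni). Significant trios (adjusted p below `alpha`)
#' receive a D2-based direction call when `d2Null` scenarios are supplied.
#' Battery-level inference follows: a sign test of observed D signs against
#' each trio's `expected_sign`, a sign test of SC-to-SI versus SI-to-SC
#' direction calls (when mating systems and direction calls are available),
#' a regression of Dp on trio genetic distance (and on relative geographic
#' proximity when accession coordinates are given), and maximum
#' accession-disjoint subsets of the significant trios, each re-tested.
#'
#' Per-trio failures are isolated: a failing trio is reported with
#' `status = "error"` and its message, and the battery continues.
#'
#' @param x a [SiteMatrix-class] with all referenced samples.
#' @param trios trio table (see [readTrioConfig()]) or a YAML path.
#' @param chromLengths named chromosome lengths for window tiling.
#' @param windowSize,minSnps,zThreshold window-scan settings.
#' @param bootWindows,bootReps block-bootstrap settings.
#' @param alpha significance level on the Bonferroni-adjusted bootstrap p.
#' @param nTests family size for the adjustment (default: number of trios).
#' @param accessions optional accession table (id, lat, lon, ...) for the
#'   proximity regression.
#' @param d2Null optional named list of [SimParams-class] null scenarios,
#'   one per trio name, enabling D2 direction calls via [d2NullTest()].
#' @param d2Reps null replicates per D2 test.
#' @param seed integer master seed; per-trio child seeds are derived.
#' @return a [BatteryReport-class].
#' @export
runBattery <- function(x, trios, chromLengths, windowSize = 100000,
                       minSnps = 20, zThreshold = 3, bootWindows = 1000,
                       bootReps = 1000, alpha = 0.05, nTests = NULL,
                       accessions = NULL, d2Null = NULL, d2Reps = 1000,
                       seed = 1) {
  if (is.character(trios)) {
    cfg <- readTrioConfig(trios)
    trios <- cfg$trios
    if (is.null(accessions)) accessions <- cfg$accessions
  }
  if (nrow(trios) == 0L)
    return(new("BatteryReport",
               trios = data.frame(), signTests = list(),
               regressions = list(), disjointSets = list()))
  if (is.null(nTests)) nTests <- nrow(trios)

  rows <- lapply(seq_len(nrow(trios)), function(i) {
    tr <- trios[i, ]
    quartet <- c(tr$p1, tr$p2, tr$p3, tr$outgroup)
    row <- data.frame(name = tr$name, p1 = tr$p1, p2 = tr$p2, p3 = tr$p3,
                      outgroup = tr$outgroup,
                      expected_sign = tr$expected_sign,
                      abba = NA_real_, baba = NA_real_, bbaa = NA_real_,
                      d = NA_real_, dp = NA_real_, sd = NA_real_,
                      se = NA_real_, ci_lwr = NA_real_, ci_upr = NA_real_,
                      p_raw = NA_real_, p_adj = NA_real_,
                      significant = NA, genetic_distance = NA_real_,
                      direction = "not evaluated",
                      donor_ms = NA_character_, recipient_ms = NA_character_,
                      d2 = NA_real_, d2_p = NA_real_,
                      status = "ok", message = "",
                      stringsAsFactors = FALSE)
    tryCatch({
      ps <- polarizeSites(x, quartet)
      win <- partitionWindows(ps, chromLengths, windowSize)
      cnt <- countPatterns(ps)
      boot <- blockBootstrap(ps, win, nWindowsPerRep = bootWindows,
                             nReps = bootReps, seed = .childSeed(seed, i))
      row$abba <- abba(cnt); row$baba <- baba(cnt); row$bbaa <- bbaa(cnt)
      row$d <- computeD(cnt); row$dp <- computeDp(cnt)
      row$sd <- boot@sd; row$se <- boot@se
      row$ci_lwr <- boot@ci95[1]; row$ci_upr <- boot@ci95[2]
      row$p_raw <- boot@pRaw
      row$p_adj <- adjustPvalues(boot@pRaw, nTests)
      row$significant <- row$p_adj < alpha
      row$genetic_distance <- trioGeneticDistance(x, quartet)
      if (isTRUE(row$significant) && !is.null(d2Null) &&
          !is.null(d2Null[[tr$name]])) {
        # orient so the exchanging ingroup accession sits in the P2 slot
        dquartet <- if (row$d >= 0) quartet else quartet[c(2, 1, 3, 4)]
        exch <- if (row$d >= 0) "P2" else "P1"
        exchMs <- if (row$d >= 0) tr$ms2 else tr$ms1
        sub <- SiteMatrix(x@calls[, dquartet, drop = FALSE],
                          as.character(GenomeInfoDb::seqnames(x@positions)),
                          GenomicRanges::start(x@positions))
        colnames(sub@calls) <- c("P1", "P2", "P3", "O")
        wt <- assignTopology(sub, partitionWindows(polarizeSites(
          sub, c("P1", "P2", "P3", "O")), chromLengths, windowSize),
          c("P1", "P2", "P3", "O"))
        obs <- suppressWarnings(computeD2(wt))
        if (!is.na(obs@d2)) {
          res <- d2NullTest(obs, d2Null[[tr$name]], nReps = d2Reps,
                            seed = .childSeed(seed, 1000 + i))
          row$d2 <- res@d2; row$d2_p <- res@pNull
          ingToP3 <- res@pNull < alpha
          row$direction <- if (ingToP3) paste0(exch, " -> P3")
                           else paste0("P3 -> ", exch)
          row$donor_ms <- if (ingToP3) exchMs else tr$ms3
          row$recipient_ms <- if (ingToP3) tr$ms3 else exchMs
        }
      }
      row
    }, error = function(e) {
      row$status <- "error"; row$message <- conditionMessage(e)
      row
    })
  })
  tab <- do.call(rbind, rows)

  signTests <- list()
  sig <- which(tab$significant %in% TRUE)
  if (length(sig)) {
    k <- sum(sign(tab$d[sig]) == tab$expected_sign[sig])
    signTests$predictedSign <- list(k = k, n = length(sig),
                                    p = signTest(k, length(sig)))
  }
  cross <- !is.na(tab$donor_ms) & !is.na(tab$recipient_ms) &
    tab$donor_ms != tab$recipient_ms
  if (any(cross)) {
    kSC <- sum(tab$donor_ms[cross] == "SC")
    signTests$scToSi <- list(k = kSC, n = sum(cross),
                             p = signTest(kSC, sum(cross)))
  }

  regressions <- list()
  okReg <- !is.na(tab$dp) & !is.na(tab$genetic_distance)
  if (sum(okReg) >= 3 && stats::sd(tab$genetic_distance[okReg]) > 0)
    regressions$dpVsGeneticDistance <-
      regressDp(tab$genetic_distance[okReg], tab$dp[okReg])
  if (!is.null(accessions)) {
    prox <- vapply(seq_len(nrow(tab)), function(i) {
      co <- function(id) unlist(accessions[accessions$id == id,
                                           c("lat", "lon")])
      p3sp <- accessions$species[accessions$id == tab$p3[i]]
      p3set <- accessions[!is.na(accessions$species) &
                            accessions$species %in% p3sp,
                          c("lat", "lon"), drop = FALSE]
      if (!nrow(p3set)) p3set <- accessions[accessions$id == tab$p3[i],
                                            c("lat", "lon"), drop = FALSE]
      tryCatch(relativeProximity(co(tab$p1[i]), co(tab$p2[i]),
                                 as.matrix(p3set)),
               error = function(e) NA_real_)
    }, numeric(1))
    tab$relative_proximity <- prox
    okProx <- !is.na(prox) & !is.na(tab$dp)
    if (sum(okProx) >= 3 && stats::sd(prox[okProx]) > 0)
      regressions$dpVsProximity <- regressDp(prox[okProx], tab$dp[okProx])
  }

  disjointSets <- list()
  if (length(sig) >= 1) {
    sets <- disjointTrioSets(tab[sig, , drop = FALSE])
    disjointSets <- lapply(sets, function(s) {
      rows <- sig[s]
      k <- sum(sign(tab$d[rows]) == tab$expected_sign[rows])
      list(trios = tab$name[rows], k = k, n = length(rows),
           p = signTest(k, length(rows)))
    })
  }

  new("BatteryReport", trios = tab, signTests = signTests,
      regressions = regressions, disjointSets = disjointSets)
}

#' Write a BatteryReport to disk
#'
#' Emits `<prefix>_trios.tsv` (the per-trio table) and `<prefix>.json`
#' (the full report including battery-level tests).
#'
#' @param report a [BatteryReport-class].
#' @param prefix output path prefix.
#' @return the JSON path, invisibly.
#' @export
writeBatteryReport <- function(report, prefix) {
  stopifnot(is(report, "BatteryReport"))
  tsv <- paste0(prefix, "_trios.tsv")
  utils::write.table(report@trios, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json <- paste0(prefix, ".json")
  jsonlite::write_json(list(trios = report@trios,
                            signTests = report@signTests,
                            regressions = report@regressions,
                            disjointSets = report@disjointSets),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(json)
}
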