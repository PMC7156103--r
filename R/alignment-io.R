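#' Read a multi-sample alignment into a SiteMatrix
#'
#' Reads multi-sample biallelic variant data from either a VCF (plain or
#' bgzipped) or a concatenated multi-FASTA alignment in reference coordinates
#' (one record per sample, equal lengths). Only variable columns are
#' returned: columns with exactly two distinct non-missing alleles among the
#' selected samples. Indels and multiallelic records are dropped; missing
#' genotypes and ambiguity codes become `N`.
#'
#' Heterozygous diploid VCF genotypes are handled per `hetPolicy`:
#' `"strict"` (default) records them as `N`, so any downstream trio
#' containing the site drops it; `"random"` draws one of the two alleles,
#' reproducibly under `seed`.
#'
#' For FASTA input the alignment column index is the reference coordinate.
#' If `chromLengths` is supplied (a named vector, chromosomes in
#' concatenation order) the single concatenated coordinate system is split
#' back into per-chromosome coordinates; otherwise all sites are placed on
#' one chromosome named `"concat"`.
#'
#' @param path path to the input file.
#' @param format `"auto"` (by extension), `"fasta"`, or `"vcf"`.
#' @param samples sample identifiers to retain, in the desired order;
#'   `NULL` keeps all. Unknown identifiers are an error.
#' @param hetPolicy `"strict"` or `"random"` (VCF only).
#' @param seed RNG seed used when `hetPolicy = "random"`.
#' @param chromLengths named numeric vector of chromosome lengths
#'   (FASTA only; see Details).
#' @return a [SiteMatrix-class].
#' @seealso [writeAlignmentFasta()], [writeAlignmentVcf()], [polarizeSites()]
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "vcf"),
                          samples = NULL,
                          hetPolicy = c("strict", "random"), seed = NULL,
                          chromLengths = NULL) {
  format <- match.arg(format)
  hetPolicy <- match.arg(hetPolicy)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
      "vcf" else "fasta"
  }
  if (format == "fasta") {
    .readAlignmentFasta(path, samples, chromLengths)
  } else {
    .readAlignmentVcf(path, samples, hetPolicy, seed)
  }
}

.selectSamples <- function(mat, samples) {
  if (is.null(samples)) return(mat)
  missing <- setdiff(samples, colnames(mat))
  if (length(missing))
    stop("unknown sample ID(s): ", paste(missing, collapse = ", "))
  mat[, samples, drop = FALSE]
}

# columns with exactly two distinct non-N alleles (vectorised over sites)
.biallelicMask <- function(calls) {
  n <- ncol(calls)
  a1 <- rep(NA_character_, nrow(calls))   # first allele seen
  a2 <- rep(NA_character_, nrow(calls))   # second allele seen
  extra <- logical(nrow(calls))           # a third allele seen
  for (j in seq_len(n)) {
    x <- calls[, j]
    ok <- x != "N"
    new1 <- ok & is.na(a1)
    a1[new1] <- x[new1]
    new2 <- ok & !is.na(a1) & x != a1 & is.na(a2)
    a2[new2] <- x[new2]
    extra <- extra | (ok & !is.na(a1) & !is.na(a2) & x != a1 & x != a2)
  }
  !is.na(a2) & !extra
}

.readAlignmentFasta <- function(path, samples, chromLengths) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("FASTA sequences must all have equal length")
  calls <- t(as.matrix(seqs))           # sites x samples
  colnames(calls) <- names(seqs)
  calls[!(calls %in% c("A", "C", "G", "T"))] <- "N"
  calls <- .selectSamples(calls, samples)
  keep <- .biallelicMask(calls)
  calls <- calls[keep, , drop = FALSE]
  pos <- which(keep)
  if (is.null(chromLengths)) {
    chrom <- rep("concat", length(pos))
  } else {
    ends <- cumsum(chromLengths)
    if (length(pos) && max(pos) > ends[length(ends)])
      stop("alignment longer than the declared chromosome lengths")
    idx <- findInterval(pos - 1L, c(0, ends[-length(ends)]))
    chrom <- names(chromLengths)[idx]
    pos <- pos - c(0, ends[-length(ends)])[idx]
  }
  SiteMatrix(calls, chrom, pos)
}

.readAlignmentVcf <- function(path, samples, hetPolicy, seed) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- .selectSamples(gt, samples)
  gt <- gt[snp, , drop = FALSE]
  chrom <- fix[snp, "CHROM"]
  pos <- as.integer(fix[snp, "POS"])
  ref <- ref[snp]; alt <- alt[snp]
  a1 <- sub("^([^/|]*).*$", "\\1", gt)
  a2 <- ifelse(grepl("[/|]", gt), sub("^[^/|]*[/|]", "", gt), a1)
  valid <- function(x) !is.na(x) & x %in% c("0", "1")
  calls <- matrix("N", nrow(gt), ncol(gt), dimnames = dimnames(gt))
  hom <- valid(a1) & valid(a2) & a1 == a2
  calls[hom] <- ifelse(a1[hom] == "0", ref[row(gt)[hom]], alt[row(gt)[hom]])
  het <- valid(a1) & valid(a2) & a1 != a2
  if (any(het)) {
    if (hetPolicy == "random") {
      if (!is.null(seed)) {
        old <- .saveSeed(); on.exit(.restoreSeed(old))
        set.seed(seed)
      }
      pick <- ifelse(stats::runif(sum(het)) < 0.5, a1[het], a2[het])
      calls[het] <- ifelse(pick == "0", ref[row(gt)[het]], alt[row(gt)[het]])
    } # strict: leave as N
  }
  keep <- .biallelicMask(calls)
  ord <- order(factor(chrom[keep], levels = unique(chrom)), pos[keep])
  idx <- which(keep)[ord]
  calls <- calls[idx, , drop = FALSE]
  rownames(calls) <- NULL
  SiteMatrix(calls, chrom[idx], pos[idx])
}

#' Write a SiteMatrix as a multi-sample FASTA alignment
#'
#' Writes one full-length sequence per sample in reference coordinates,
#' concatenating chromosomes in the order of `chromLengths`. Positions not
#' present in the matrix (invariant in the data) are filled with `A`; they
#' are dropped again on re-reading, so write-then-read round-trips exactly
#' for `N`-free biallelic matrices.
#'
#' @param x a [SiteMatrix-class].
#' @param path output path.
#' @param chromLengths named numeric vector of chromosome lengths; defaults
#'   to the largest observed position per chromosome.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(x, path, chromLengths = NULL) {
  stopifnot(is(x, "SiteMatrix"))
  ch <- as.character(GenomeInfoDb::seqnames(x@positions))
  po <- GenomicRanges::start(x@positions)
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(po, factor(ch, levels = unique(ch))),
                           max, numeric(1))
  }
  offs <- c(0, cumsum(chromLengths)[-length(chromLengths)])
  names(offs) <- names(chromLengths)
  if (!all(ch %in% names(chromLengths)))
    stop("chromLengths missing chromosome(s): ",
         paste(setdiff(ch, names(chromLengths)), collapse = ", "))
  gpos <- offs[ch] + po
  total <- sum(chromLengths)
  seqs <- vapply(seq_len(ncol(x@calls)), function(j) {
    s <- rep("A", total)
    s[gpos] <- x@calls[, j]
    paste(s, collapse = "")
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- colnames(x@calls)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write a SiteMatrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with haploid genotypes (`0`, `1`, `.`). The REF
#' allele of each site is its first non-missing call in sample order.
#'
#' @param x a [SiteMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentVcf <- function(x, path) {
  stopifnot(is(x, "SiteMatrix"))
  calls <- x@calls
  n <- nrow(calls)
  ref <- rep(NA_character_, n)
  alt <- rep(NA_character_, n)
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    ok <- cj != "N"
    ref[is.na(ref) & ok] <- cj[is.na(ref) & ok]
    isalt <- ok & !is.na(ref) & cj != ref & is.na(alt)
    alt[isalt] <- cj[isalt]
  }
  if (anyNA(ref)) stop("cannot write sites with no non-missing call")
  alt[is.na(alt)] <- "."
  gtc <- matrix(".", n, ncol(calls))
  gtc[calls == ref[row(calls)]] <- "0"
  gtc[alt != "." & calls == alt[row(calls)]] <- "1"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=Dtrio",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(calls)), collapse = "\t"))
  body <- paste(as.character(GenomeInfoDb::seqnames(x@positions)),
                GenomicRanges::start(x@positions), ".", ref, alt, ".",
                ".", ".", "GT",
                apply(gtc, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Polarize sites against the outgroup of an ordered trio
#'
#' For an ordered quartet (P1, P2, P3, outgroup), retains sites where the
#' outgroup call is non-missing, no ingroup call is missing, and exactly two
#' alleles segregate among the four samples; the outgroup allele defines the
#' ancestral state "A" (even where the outgroup carries the minor allele)
#' and the other allele the derived state "B". All other sites are dropped
#' with counted reasons.
#'
#' @param x a [SiteMatrix-class] containing all four samples.
#' @param trio character(4): P1, P2, P3, outgroup sample identifiers.
#' @return a [PolarizedSites-class].
#' @examples
#' m <- SiteMatrix(matrix(c("G","T","T","G"), 1,
#'                        dimnames = list(NULL, c("p1","p2","p3","og"))),
#'                 chrom = "1", pos = 5)
#' siteStates(polarizeSites(m, c("p1", "p2", "p3", "og")))
#' @export
polarizeSites <- function(x, trio) {
  stopifnot(is(x, "SiteMatrix"))
  if (length(trio) != 4L)
    stop("'trio' must name exactly 4 samples (P1, P2, P3, outgroup)")
  missing <- setdiff(trio, sampleNames(x))
  if (length(missing))
    stop("unknown sample ID(s): ", paste(missing, collapse = ", "))
  p1 <- x@calls[, trio[1]]; p2 <- x@calls[, trio[2]]
  p3 <- x@calls[, trio[3]]; og <- x@calls[, trio[4]]

  ogMissing <- og == "N"
  ingMissing <- !ogMissing & (p1 == "N" | p2 == "N" | p3 == "N")
  complete <- !ogMissing & !ingMissing
  nd <- 1L + (p2 != p1) + (p3 != p1 & p3 != p2) +
    (og != p1 & og != p2 & og != p3)
  invariant <- complete & nd == 1L
  notBiallelic <- complete & nd > 2L
  keep <- complete & nd == 2L

  okeep <- og[keep]
  states <- matrix("B", sum(keep), 3, dimnames = list(NULL,
                                                      c("p1", "p2", "p3")))
  states[p1[keep] == okeep, 1] <- "A"
  states[p2[keep] == okeep, 2] <- "A"
  states[p3[keep] == okeep, 3] <- "A"
  new("PolarizedSites", trio = trio, positions = x@positions[keep],
      states = states,
      dropped = c(outgroup_missing = sum(ogMissing),
                  ingroup_missing = sum(ingMissing),
                  invariant = sum(invariant),
                  not_biallelic = sum(notBiallelic)))
}

#' Tile chromosomes into fixed windows and assign polarized sites
#'
#' Tiles each chromosome `[1, L]` into non-overlapping windows of
#' `windowSize` bp (the terminal window of a chromosome may be shorter; it
#' is kept and subject to downstream SNP-count filters). Every retained site
#' is assigned to exactly one window; empty windows are kept.
#'
#' @param x a [PolarizedSites-class] (or any `GRanges` of width-1 sites).
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param windowSize window size in bp (default 100000, i.e. 100 kb).
#' @return a `GRanges` of windows with metadata columns `siteIdx`
#'   (an `IntegerList` of indices into the sites of `x`) and `nSites`.
#' @export
partitionWindows <- function(x, chromLengths, windowSize = 100000) {
  if (windowSize <= 0) stop("windowSize must be positive")
  gr <- if (is(x, "PolarizedSites")) x@positions else x
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  if (!all(ch %in% names(chromLengths)))
    stop("sites on chromosome(s) absent from chromLengths: ",
         paste(setdiff(unique(ch), names(chromLengths)), collapse = ", "))
  po <- GenomicRanges::start(gr)
  over <- po > chromLengths[ch]
  if (any(over))
    stop(sprintf("site %s:%d beyond declared chromosome length %d",
                 ch[which(over)[1]], po[which(over)[1]],
                 as.integer(chromLengths[ch[which(over)[1]]])))
  sl <- stats::setNames(as.integer(chromLengths), names(chromLengths))
  windows <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(windowSize),
                                       cut.last.tile.in.chrom = TRUE)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(ch, IRanges::IRanges(po, width = 1L),
                           seqlengths = sl),
    windows)
  idx <- S4Vectors::split(S4Vectors::queryHits(hits),
                          factor(S4Vectors::subjectHits(hits),
                                 levels = seq_along(windows)))
  S4Vectors::mcols(windows)$siteIdx <- IRanges::IntegerList(idx)
  S4Vectors::mcols(windows)$nSites <- unname(lengths(idx))
  windows
}

#' Read a two-column chromosome-length table
#'
#' @param path TSV with chromosome name and length (no header).
#' @return named numeric vector of lengths.
#' @export
readChromLengths <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$length, tab$chrom)
}

#' Dump polarized sites as TSV
#'
#' Writes columns chrom, pos (1-based), p1, p2, p3 ("A"/"B").
#'
#' @param x a [PolarizedSites-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePolarizedTsv <- function(x, path) {
  stopifnot(is(x, "PolarizedSites"))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x@positions)),
                   pos = GenomicRanges::start(x@positions),
                   x@states, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write windows as BED3
#'
#' Converts the 1-based closed `GRanges` windows to the 0-based half-open
#' BED convention.
#'
#' @param windows a `GRanges`, e.g. from [partitionWindows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWindowsBed <- function(windows, path) {
  df <- data.frame(as.character(GenomeInfoDb::seqnames(windows)),
                   GenomicRanges::start(windows) - 1L,
                   GenomicRanges::end(windows))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
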