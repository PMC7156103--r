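# Shared fixture builders. Everything is generated in code at test time.

# SiteMatrix from a character vector of per-sample sequences (equal length);
# all columns are kept (the constructor is permissive).
smFromStrings <- function(seqs, chrom = "1") {
  calls <- do.call(cbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  colnames(calls) <- names(seqs)
  SiteMatrix(calls, chrom = chrom, pos = seq_len(nrow(calls)))
}

# PolarizedSites straight from an A/B state matrix at given positions
psFromStates <- function(states, pos = seq_len(nrow(states)), chrom = "1",
                         trio = c("p1", "p2", "p3", "og")) {
  colnames(states) <- c("p1", "p2", "p3")
  new("PolarizedSites", trio = trio,
      positions = GenomicRanges::GRanges(rep(chrom, length.out = length(pos)),
                                         IRanges::IRanges(pos, width = 1L)),
      states = states,
      dropped = c(outgroup_missing = 0L, ingroup_missing = 0L,
                  invariant = 0L, not_biallelic = 0L))
}

# random A/B state matrix
randomStates <- function(n, pAbba = 0.25, pBaba = 0.25, pBbaa = 0.3) {
  pick <- sample(c("ABBA", "BABA", "BBAA", "OTHER"), n, replace = TRUE,
                 prob = c(pAbba, pBaba, pBbaa, 1 - pAbba - pBaba - pBbaa))
  t(vapply(pick, function(p) switch(p,
    ABBA = c("A", "B", "B"), BABA = c("B", "A", "B"),
    BBAA = c("B", "B", "A"), OTHER = c("B", "B", "B")),
    character(3)))
}

# minimal diploid VCF text: 3 biallelic SNPs, 1 triallelic, 1 indel,
# with one heterozygous and one missing genotype
writeTinyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/0\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t300\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2\t0/0",
    "chr1\t400\t.\tT\tTA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/0\t0/0",
    "chr2\t150\t.\tG\tC\t.\tPASS\t.\tGT\t0/0\t1/1\t./.\t0/0"),
    path)
  path
}

# default 4-sample trio labels used by the simulator
simTrio <- c("P1", "P2", "P3", "O")

# D and Dp for one simulated dataset
simStats <- function(params) {
  sim <- simulateDataset(params)
  cnt <- countPatterns(polarizeSites(sim$sites, simTrio))
  c(d = suppressWarnings(computeD(cnt)),
    dp = suppressWarnings(computeDp(cnt)))
}
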