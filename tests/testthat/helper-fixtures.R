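# small in-code fixtures shared across test files

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a tiny VCF with 5 records: 2 clean SNPs, 1 indel, 1 multiallelic,
# 1 SNP with a missing genotype; two samples with AD
mini_vcf_path <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/0:10,0\t1/1:0,12",
    "chr1\t200\t.\tC\tCAT\t.\tPASS\t.\tGT:AD\t0/0:9,0\t0/1:5,4",
    "chr1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT:AD\t0/0:8,0\t0/1:4,4",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT:AD\t./.:.\t0/1:10,5",
    "chr2\t150\t.\tG\tC\t.\tPASS\t.\tGT:AD\t0/1:6,6\t0/1:7,7"),
    ext = ".vcf")
}

# GFF3 with: plus-strand coding gene (2 CDS segments, 18 bp total),
# minus-strand gene, and a gene whose CDS length is not a multiple of 3
mini_gff_path <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t11\t60\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t11\t60\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t31\t39\t.\t+\t0\tID=g1.c2;Parent=g1.t1",
    "chr1\tsrc\tCDS\t11\t19\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\tsrc\tgene\t101\t160\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t101\t160\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\tsrc\tCDS\t101\t130\t.\t-\t0\tID=g2.c1;Parent=g2.t1",
    "chr2\tsrc\tgene\t11\t50\t.\t+\t.\tID=g3",
    "chr2\tsrc\tmRNA\t11\t50\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chr2\tsrc\tCDS\t11\t20\t.\t+\t0\tID=g3.c1;Parent=g3.t1"),
    ext = ".gff3")
}

# genotype matrix from per-individual strings like "AAAHH"
geno_from_strings <- function(x, markers) {
  m <- do.call(rbind, strsplit(x, ""))
  m[m == "-"] <- NA_character_
  dimnames(m) <- list(sprintf("ind%02d", seq_along(x)), markers)
  m
}

random_freq4 <- function() {
  x <- stats::runif(4)
  x / sum(x)
}

# independent brute-force oracle: per-site windowed median with symmetric
# end shrink (whole-chromosome median when the window does not fit)
oracle_snpnum <- function(ed2, chrom, window) {
  half <- (window - 1) %/% 2
  out <- numeric(length(ed2))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    n <- length(i)
    if (window >= n) {
      out[i] <- median(ed2[i])
    } else {
      for (k in seq_len(n)) {
        h <- min(half, k - 1, n - k)
        out[i[k]] <- median(ed2[i][(k - h):(k + h)])
      }
    }
  }
  out
}

# independent brute-force oracle for interval narrowing: enumerate every
# candidate region (marker point or open inter-marker gap) and keep those
# where every individual's phenotype can be satisfied by some genotype
# compatible with its observed marker data under a single crossover-free
# reading of the gap
oracle_narrow <- function(geno, phenotype, map) {
  m <- nrow(map)
  ok <- rep(TRUE, 2 * m - 1)
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    for (s in seq_len(2 * m - 1)) {
      possible <- c("A", "H", "B")
      if (s %% 2 == 1) {                        # marker point
        j <- (s + 1) / 2
        if (!is.na(g[j])) possible <- g[j]
        else {
          l <- which(!is.na(g[seq_len(j - 1)]))
          r <- which(!is.na(g)) ; r <- r[r > j]
          if (length(l) && length(r) && g[max(l)] == g[min(r)])
            possible <- g[max(l)]
        }
      } else {                                  # gap between j and j+1
        j <- s / 2
        l <- which(!is.na(g[seq_len(j)]))
        r <- which(!is.na(g)); r <- r[r > j]
        if (length(l) && length(r) && g[max(l)] == g[min(r)])
          possible <- g[max(l)]
      }
      fits <- if (phenotype[i] == "round") "B" %in% possible
              else any(possible != "B")
      if (!fits) ok[s] <- FALSE
    }
  }
  ok
}
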