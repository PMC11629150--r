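mk_map <- function(pos, chrom = "chr3")
  data.frame(marker = sprintf("M%d", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos))

test_that("recombinants are individuals whose genotype class changes", {
  map <- mk_map(c(100, 200, 300, 400, 500))
  g <- geno_from_strings(c("AAAHH", "HHHHH", "AHAAA", "--A--"),
                         map$marker)
  r <- find_recombinants(g, map)
  # AAAHH: one breakpoint between markers 3 and 4
  r1 <- r[r$individual == "ind01", ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$left_marker, "M3")
  expect_equal(r1$right_marker, "M4")
  expect_equal(c(r1$left_pos, r1$right_pos), c(300L, 400L))
  # uniform H: not recombinant
  expect_false("ind02" %in% r$individual)
  # AHAAA: double recombinant, flagged
  r3 <- r[r$individual == "ind03", ]
  expect_equal(nrow(r3), 2L)
  expect_true(all(r3$n_breakpoints == 2L))
  # all-missing individuals are skipped with a tally
  g2 <- geno_from_strings(c("AAAHH", "-----"), map$marker)
  r2 <- find_recombinants(g2, map)
  expect_equal(attr(r2, "skipped"), 1L)
})

test_that("interval narrowing recovers the region flanked by recombinants", {
  # 6 markers; causal locus lies between M4 and M5
  map <- mk_map(c(78500000, 79700000, 80900000, 81539936, 82252537, 84400000))
  g <- geno_from_strings(c(
    "AAAAAA",   # oval, non-recombinant: uninformative
    "BBBBBB",   # round, consistent everywhere
    "BBBBHH",   # round recombinant: locus left of M5
    "HBBBBB",   # round recombinant: locus right of M1 (wait, is A) -> see below
    "HHHHBB",   # oval with B from M5 on: locus left of M5
    "BBBHHH"),  # oval, B up to M3: locus right of M3
    map$marker)
  ph <- c("oval", "round", "round", "round", "oval", "oval")
  res <- narrow_interval(g, ph, map)
  # round ind4 is H at M1 only -> excludes M1 region; oval ind6 is B through
  # M3 -> excludes up to M3; round ind3 H at M5,M6 -> excludes them; oval
  # ind5 B at M5,M6 -> excludes them. Consistent zone: gap M3-M4, M4, gap M4-M5
  expect_equal(res$left_marker, "M3")
  expect_equal(res$right_marker, "M5")
  expect_equal(res$start, 80900000L)
  expect_equal(res$end, 82252537L)
  # length arithmetic in bp and kb
  expect_equal(res$length_bp, res$end - res$start + 1L)
  expect_equal(res$length_kb, round(res$length_bp / 1000, 1))
})

test_that("no recombinants yields the full input interval", {
  map <- mk_map(c(100, 5000, 9000))
  g <- geno_from_strings(c("AAA", "BBB", "HHH"), map$marker)
  res <- narrow_interval(g, c("oval", "round", "oval"), map)
  expect_equal(res$start, 100L)
  expect_equal(res$end, 9000L)
})

test_that("contradictory records raise an inconsistency error", {
  map <- mk_map(c(100, 5000, 9000))
  g <- geno_from_strings(c("AAA", "BBB"), map$marker)
  expect_error(narrow_interval(g, c("round", "oval"), map),
               "no region is consistent")
})

test_that("the printed flanking positions give 712.6 kb at one decimal", {
  map <- mk_map(c(81539936, 82252537))
  g <- geno_from_strings(c("AB", "BA", "BB"), map$marker)
  res <- narrow_interval(g, c("round", "round", "round"), map)
  expect_equal(res$start, 81539936L)
  expect_equal(res$end, 82252537L)
  expect_equal(res$length_kb, 712.6)
})

test_that("narrowing agrees with the exhaustive consistency oracle", {
  set.seed(55)
  for (rep in 1:20) {
    m <- sample(4:10, 1)
    pos <- sort(sample(1e6, m))
    map <- mk_map(pos)
    causal <- sample((min(pos) + 1):(max(pos) - 1), 1)
    cross <- make_f2_cross(
      n_individuals = 200, marker_map = map,
      causal = list(chrom = "chr3", pos = causal),
      fsi_model = list(mu_dom = 1.2, mu_rec = 0.9, sigma = 0,
                       threshold = 1.0),
      seed = 1000 + rep)
    ok <- tryCatch(
      narrow_interval(cross$geno, cross$phenotypes$class, map,
                      include_double = TRUE),
      error = function(e) NULL)
    oracle_ok <- oracle_narrow(cross$geno, cross$phenotypes$class, map)
    if (is.null(ok)) {
      expect_false(any(oracle_ok))
      next
    }
    expect_identical(ok$consistent_segments, which(oracle_ok))
    # the reported physical interval always contains the planted locus
    expect_true(ok$start <= causal && ok$end >= causal)
  }
})

test_that("double recombinants are excluded from narrowing by default", {
  map <- mk_map(c(100, 200, 300, 400, 500))
  # ind1 is a double recombinant (A H A) that would exclude everything for a
  # round phenotype; with the default policy it is set aside
  g <- geno_from_strings(c("AHAAA", "BBBBB", "BBBHH"), map$marker)
  ph <- c("round", "round", "round")
  res <- narrow_interval(g, ph, map)
  expect_equal(res$excluded_double, "ind01")
  expect_equal(res$right_marker, "M4")
  # with the override the double recombinant's exclusions apply: only the
  # gaps flanking its isolated H call stay consistent
  res2 <- narrow_interval(g, ph, map, include_double = TRUE)
  expect_equal(res2$left_marker, "M1")
  expect_equal(res2$right_marker, "M3")
})

test_that("gene-interval overlap uses the any-overlap rule", {
  gff <- c("##gff-version 3",
           vapply(1:29, function(i) {
             s <- 1000 * i
             paste0("chr1\tsrc\tgene\t", s, "\t", s + 500, "\t.\t+\t.\tID=G",
                    i)
           }, character(1)))
  gm <- read_gff(write_lines_tmp(gff, ext = ".gff3"))
  # interval covering genes 2..28 plus half of gene 1 (straddles the edge)
  hits <- genes_in_interval(gm, "chr1", 1200, 28600)
  expect_equal(nrow(hits), 28L)
  expect_true("G1" %in% hits$gene_id)       # straddling gene included
  expect_false("G29" %in% hits$gene_id)
  within <- genes_in_interval(gm, "chr1", 1200, 28600, mode = "within")
  expect_false("G1" %in% within$gene_id)
  # 27 genes fully inside a tighter interval
  expect_equal(nrow(genes_in_interval(gm, "chr1", 2000, 28501)), 27L)
  expect_equal(nrow(genes_in_interval(gm, "chr2", 1, 1e6)), 0L)
})

test_that("W-box scanning finds literal, consensus and core on both strands", {
  s <- scan_wbox("AATTGACCAA")
  expect_equal(s$motif_fwd, 3L)
  expect_equal(length(s$motif_rev), 0L)
  expect_equal(s$consensus_fwd, 3L)   # TTGACC matches [CT]TGAC[TC]
  expect_equal(s$core_fwd, 4L)
  # reverse-complement strand hit reported in rc coordinates
  s2 <- scan_wbox("GGTCAA")
  expect_equal(length(s2$motif_fwd), 0L)
  expect_equal(s2$motif_rev, 1L)
  # degenerate consensus: CTGACT matches, TTGACC matches, TTGACG does not
  expect_equal(length(scan_wbox("CTGACT")$consensus_fwd), 1L)
  expect_equal(length(scan_wbox("TTGACG")$consensus_fwd), 0L)
  # forward+reverse hit multiset is invariant under reverse complementing
  set.seed(17)
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    a <- scan_wbox(x); b <- scan_wbox(rc)
    expect_equal(sort(c(a$motif_fwd, a$motif_rev)),
                 sort(c(b$motif_fwd, b$motif_rev)))
    expect_equal(length(a$core_fwd) + length(a$core_rev),
                 length(b$core_fwd) + length(b$core_rev))
  }
})

test_that("a 91-bp promoter deletion removes its only W-box", {
  set.seed(23)
  bases <- sample(c("A", "T"), 800, TRUE)  # AT background: no spurious motif
  bases[400:405] <- c("T", "T", "G", "A", "C", "C")
  ref_allele <- paste(bases, collapse = "")
  # delete 91 bp covering the motif
  del_allele <- paste0(substr(ref_allele, 1, 360),
                       substr(ref_allele, 452, 800))
  expect_gte(length(scan_wbox(ref_allele)$motif_fwd), 1L)
  expect_equal(length(scan_wbox(del_allele)$motif_fwd), 0L)
  expect_equal(length(scan_wbox(del_allele)$motif_rev), 0L)
  d <- diff_alleles(ref_allele, del_allele)
  expect_equal(nrow(d), 1L)
  expect_equal(d$type, "deletion")
  expect_equal(d$length, 91L)
  expect_equal(nchar(d$ref), 91L)
})

test_that("allele comparison reports substitutions and is empty for identity", {
  set.seed(29)
  a <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  expect_equal(nrow(diff_alleles(a, a)), 0L)
  b <- a
  old <- substr(b, 200, 200)
  substr(b, 200, 200) <- setdiff(c("A", "C", "G", "T"), old)[1]
  d <- diff_alleles(a, b)
  expect_equal(nrow(d), 1L)
  expect_equal(d$type, "snp")
  expect_equal(d$pos1, 200L)
  expect_error(diff_alleles("", "ACGT"), "empty")
})

test_that("marker map and genotype tables are read and validated", {
  mp <- write_lines_tmp(c("marker\tchrom\tpos", "M1\tchr3\t100",
                          "M2\tchr3\t900"), ext = ".tsv")
  map <- read_marker_map(mp)
  expect_equal(map$pos, c(100L, 900L))
  bad <- write_lines_tmp(c("marker\tchrom\tpos", "M1\tchr3\t900",
                           "M2\tchr3\t100"), ext = ".tsv")
  expect_error(read_marker_map(bad), "increase")
  gp <- write_lines_tmp(c("id\tM1\tM2", "i1\tA\tH", "i2\tB\t-"), ext = ".tsv")
  g <- read_marker_genotypes(gp)
  expect_equal(unname(g["i1", "M2"]), "H")
  expect_true(is.na(g["i2", "M2"]))
  badg <- write_lines_tmp(c("id\tM1\tM2", "i1\tA\tX"), ext = ".tsv")
  expect_error(read_marker_genotypes(badg), "invalid genotype")
})
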