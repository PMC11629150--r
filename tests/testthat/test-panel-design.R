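test_that("site statistics count alleles over called genotypes only", {
  # 10 samples: 8 ref/ref + 2 ref/alt -> alt freq 0.10
  s <- site_stats(c(rep(0L, 8), 1L, 1L))
  expect_equal(s$maf, 0.10)
  expect_equal(s$missing_rate, 0)
  expect_equal(s$n_called, 10L)
  # 5 missing + 5 het -> maf 0.5, missing 0.5
  s <- site_stats(c(rep(NA_integer_, 5), rep(1L, 5)))
  expect_equal(s$maf, 0.5)
  expect_equal(s$missing_rate, 0.5)
  # monomorphic alt -> maf 0 (minor allele is ref)
  expect_equal(site_stats(rep(2L, 10))$maf, 0)
  # all missing -> undefined maf, missing_rate 1
  s <- site_stats(rep(NA_integer_, 4))
  expect_true(is.na(s$maf))
  expect_equal(s$missing_rate, 1)
})

test_that("MAF filter is inclusive and missingness filter strict at the bound", {
  gt <- rbind(
    c(rep(0L, 107), 1L, 1L, 1L),              # maf 0.014 -> reject: maf
    c(rep(NA_integer_, 55), rep(1L, 55)),     # missing exactly 0.50 -> reject
    c(rep(NA_integer_, 50), rep(0L, 54), rep(1L, 6)))  # maf 0.05, miss 0.45
  vs <- variant_set(rep("c1", 3), c(10L, 20L, 30L), rep("A", 3), rep("G", 3),
                    gt, samples = sprintf("S%d", 1:110))
  fs <- filter_stats(vs)
  expect_equal(fs$keep, c(FALSE, FALSE, TRUE))
  expect_equal(fs$rejections, c(maf = 1L, missing = 1L))
  expect_equal(fs$stats$maf[3], 0.05, tolerance = 1e-12)
  # tallies + survivors = inputs
  expect_equal(sum(fs$rejections) + n_sites(fs$kept), n_sites(vs))
})

test_that("GC fraction excludes N from the denominator", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ANGC"), 2 / 3)
  expect_true(is.na(gc_fraction("NNN")))
  expect_error(gc_fraction(""), "non-empty")
})

test_that("flank extraction windows are anchored on pos-1 and pos+1", {
  g <- Biostrings::DNAStringSet(c(c1 = paste(rep("AT", 150), collapse = "")))
  ctx <- extract_flanks(g, "c1", 101L)
  expect_true(ctx$complete)
  expect_equal(nchar(ctx$up_seq), 100L)
  expect_equal(nchar(ctx$down_seq), 100L)
  expect_equal(ctx$gc_up, 0)      # AT-only flanks
  expect_equal(ctx$gc_down, 0)
  ctx2 <- extract_flanks(g, "c1", 50L)
  expect_false(ctx2$complete)
  expect_equal(nchar(ctx2$up_seq), 49L)
  expect_error(extract_flanks(g, "c1", 500L), "outside")
  expect_error(extract_flanks(g, "nope", 10L), "not in genome")
})

test_that("flank filter applies strict GC bounds and the no-N rule", {
  ctx <- list(up_seq = "", down_seq = "", gc_up = 0.39, gc_down = 0.50,
              has_n = FALSE, complete = TRUE)
  expect_equal(flank_filter(ctx)$reason, "gc")
  ctx$gc_up <- 0.41; ctx$has_n <- TRUE
  expect_equal(flank_filter(ctx)$reason, "N")
  ctx$has_n <- FALSE; ctx$gc_down <- 0.59
  f <- flank_filter(ctx)
  expect_true(f$pass)
  ctx$complete <- FALSE
  expect_equal(flank_filter(ctx)$reason, "incomplete")
  # boundary values are excluded (strictly greater / strictly less)
  ctx$complete <- TRUE; ctx$gc_up <- 0.40
  expect_equal(flank_filter(ctx)$reason, "gc")
  ctx$gc_up <- 0.45; ctx$gc_down <- 0.60
  expect_equal(flank_filter(ctx)$reason, "gc")
})

test_that("copy search finds planted duplicates >= 120 bp and none shorter", {
  fx <- make_genome(
    n_chrom = 2, length = 5e4, seed = 201,
    duplications = data.frame(
      src_chrom = c("chr1", "chr1"), src_start = c(10000L, 25000L),
      length = c(150L, 100L), dest_chrom = c("chr2", "chr2"),
      dest_start = c(20000L, 30000L)))
  s1 <- as.character(fx$genome[["chr1"]])
  # probe centred on the 150-bp duplicate: second locus must be reported
  pos <- 10075L
  probe <- substr(s1, pos - 100L, pos + 100L)
  rep150 <- find_copies(fx$genome, probe, list(chrom = "chr1", start = pos - 100L))
  expect_false(rep150$is_single_copy)
  expect_true(any(rep150$hits$chrom == "chr2" &
                    rep150$hits$aligned_length >= 150L))
  # probe centred on the 100-bp duplicate: copy is below the 120-bp rule
  pos <- 25050L
  probe <- substr(s1, pos - 100L, pos + 100L)
  rep100 <- find_copies(fx$genome, probe, list(chrom = "chr1", start = pos - 100L))
  expect_true(rep100$is_single_copy)
  expect_equal(nrow(rep100$hits), 1L)
  expect_error(find_copies(fx$genome, "ACGT", list(chrom = "chr1", start = 1)),
               "shorter")
})

test_that("copy search agrees with a brute-force shared-120-mer scan", {
  fx <- make_genome(n_chrom = 1, length = 3e4, seed = 77)
  s <- as.character(fx$genome[["chr1"]])
  k <- 120L
  # brute force: a >= 120 bp exact match exists iff probe and genome share a
  # 120-mer (beyond the probe's own locus)
  genome_kmers <- substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  for (pos in c(5000L, 17000L)) {
    probe <- substr(s, pos - 100L, pos + 100L)
    probe_kmers <- substring(probe, 1:(nchar(probe) - k + 1L),
                             k:nchar(probe))
    hits_at <- which(genome_kmers %in% probe_kmers)
    self_only <- all(hits_at >= pos - 100L - k & hits_at <= pos + 100L)
    got <- find_copies(fx$genome, probe, list(chrom = "chr1",
                                              start = pos - 100L))
    expect_equal(got$is_single_copy, self_only)
    expect_true(got$is_single_copy)  # random 30-kb genome: no spurious copy
  }
})

test_that("functional classification is strand-aware and uses the genetic code", {
  # chr1: g1 (+) CDS 11-19 & 31-39 -> protein from ATG GCT ... ; g2 (-) 101-130
  left <- "AAAAAAAAAA"                       # 1-10
  cds1a <- "ATGGCTTGG"                       # 11-19: M A W
  mid <- paste(rep("T", 11), collapse = "")  # 20-30
  cds1b <- "GCCAAATAAC"                      # 31-39 is GCCAAATAA + spacer
  g2revcds <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGCCTCCTCCTCCTCCTCCTCCTCCTTGA")))  # 30 bp
  chr1 <- paste0(left, cds1a, mid, substr(cds1b, 1, 9), "C",
                 paste(rep("A", 60), collapse = ""), g2revcds,
                 paste(rep("G", 40), collapse = ""))
  chr2 <- paste(rep("ACGT", 25), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  genes <- read_gff(mini_gff_path())

  # between genes -> intergenic
  expect_equal(classify_site("chr1", 70, "A", "G", genes, genome), "intergenic")
  # inside gene span but not CDS -> noncoding_genic
  expect_equal(classify_site("chr1", 25, "T", "A", genes, genome),
               "noncoding_genic")
  # GCT -> GCC (Ala -> Ala), third codon base at pos 16
  expect_equal(classify_site("chr1", 16, "T", "C", genes, genome),
               "synonymous")
  # TGG -> TGA at pos 19 (third base of codon 3, spliced pos 9)
  expect_equal(classify_site("chr1", 19, "G", "A", genes, genome),
               "stop_codon_change")
  # ATG start codon disrupted
  expect_equal(classify_site("chr1", 11, "A", "C", genes, genome),
               "start_codon_change")
  # missense in codon 2: GCT -> GTT (Ala -> Val)
  expect_equal(classify_site("chr1", 15, "C", "T", genes, genome),
               "nonsynonymous")
  # minus-strand gene g2 (CDS 101-130): genomic pos 128 carries the G of the
  # start ATG (third CDS base, complemented); genomic C>T is CDS G>A
  expect_equal(classify_site("chr1", 128, "C", "T", genes, genome),
               "start_codon_change")
})

test_that("cascade audit conserves sites and matches constructed truth", {
  gfx <- make_genome(
    n_chrom = 2, length = 5e4, seed = 7,
    duplications = data.frame(src_chrom = "chr1", src_start = 10000L,
                              length = 150L, dest_chrom = "chr2",
                              dest_start = 20000L),
    n_runs = data.frame(chrom = "chr1", start = 30000L, length = 50L),
    gc_regions = data.frame(chrom = "chr2", start = 5000L, length = 400L,
                            gc = 0.75))
  pv <- make_population_vcf(gfx, n_samples = 20, n_sites = 60,
                            violations = c(maf = 5, missing = 5, n_flank = 3,
                                           gc = 3, copy = 2),
                            mode = "construction", seed = 11)
  pan <- select_panel(pv$vcf, gfx$genome)
  truth <- pv$truth
  expect_setequal(paste(pan$panel$chrom, pan$panel$pos),
                  paste(truth$chrom, truth$pos)[truth$violates == "none"])
  tab <- table(truth$violates)
  expect_equal(unname(pan$rejections["maf"]), unname(tab["maf"]))
  expect_equal(unname(pan$rejections["missing"]), unname(tab["missing"]))
  expect_equal(unname(pan$rejections["n_flank"]), unname(tab["n_flank"]))
  expect_equal(unname(pan$rejections["gc"]), unname(tab["gc"]))
  expect_equal(unname(pan$rejections["multi_copy"]), unname(tab["copy"]))
  # every rejected site in exactly one tally; tallies + survivors = inputs
  expect_equal(sum(pan$rejections) + nrow(pan$panel), n_sites(pv$vcf))
  # all-passing fixture: everything survives
  pv2 <- make_population_vcf(gfx, n_samples = 20, n_sites = 50, seed = 12)
  pan2 <- select_panel(pv2$vcf, gfx$genome)
  expect_equal(nrow(pan2$panel), 50L)
})

test_that("cascade filters are order-invariant pure predicates", {
  gfx <- make_genome(n_chrom = 2, length = 5e4, seed = 8,
                     n_runs = data.frame(chrom = "chr1", start = 40000L,
                                         length = 60L))
  pv <- make_population_vcf(gfx, n_samples = 20, n_sites = 40,
                            violations = c(maf = 4, missing = 4, n_flank = 4),
                            mode = "construction", seed = 13)
  vs <- pv$vcf
  st <- site_stats(vs)
  pred_stats <- !is.na(st$maf) & st$maf >= 0.05 & st$missing_rate < 0.5
  pred_flank <- vapply(seq_len(n_sites(vs)), function(i)
    flank_filter(extract_flanks(gfx$genome, vs$chrom[i], vs$pos[i]))$pass,
    logical(1))
  # applying the independent predicates in any order = cascade survivors
  pan <- select_panel(vs, gfx$genome)
  expect_setequal(paste(vs$chrom, vs$pos)[pred_flank & pred_stats],
                  paste(pan$panel$chrom, pan$panel$pos))
})

test_that("density report bins conserve the panel and flag uniformity", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGTT", 2000),
                                               collapse = "")))
  panel <- data.frame(chrom = "chr1", pos = sample(1:1000, 10))
  d <- density_report(panel, g, bin_size = 1000)
  expect_equal(d$count[1], 10L)
  expect_true(all(d$count[-1] == 0L))
  expect_equal(sum(d$count), nrow(panel))
  expect_error(density_report(panel, g, bin_size = 0), "bin_size")
  # approximately uniform fixture passes a chi-square uniformity check
  set.seed(5)
  panel2 <- data.frame(chrom = "chr1", pos = sample(10000L, 2000L, TRUE))
  d2 <- density_report(panel2, g, bin_size = 1000)
  expect_equal(sum(d2$count), 2000L)
  expect_gt(stats::chisq.test(d2$count)$p.value, 0.001)
})

test_that("panel thinning enforces a minimum spacing", {
  panel <- data.frame(chrom = "chr1", pos = c(100L, 150L, 300L, 310L, 600L))
  th <- thin_panel(panel, min_spacing = 200L)
  expect_equal(th$pos, c(100L, 300L, 600L))
})
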