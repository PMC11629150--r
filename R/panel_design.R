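#' Per-site genotype statistics
#'
#' Minor-allele frequency and missing rate for every site of a variant set.
#' Allele frequencies are computed from called diploid genotypes only, so
#' `maf <= 0.5` always; a site with zero called genotypes gets `maf = NA`
#' and `missing_rate = 1`.
#'
#' @param vs A [variant_set], or an integer genotype vector (0/1/2/NA) for a
#'   single site.
#' @param n_samples Sample count; required only for the vector form.
#' @return Data frame with one row per site: `maf`, `missing_rate`, `n_called`.
#' @export
site_stats <- function(vs, n_samples = NULL) {
  if (inherits(vs, "variant_set")) {
    gt <- vs$gt
    n_samples <- length(vs$samples)
  } else {
    gt <- matrix(as.integer(vs), nrow = 1L)
    if (is.null(n_samples)) n_samples <- length(vs)
  }
  n_called <- rowSums(!is.na(gt))
  alt_count <- rowSums(gt, na.rm = TRUE)
  p <- ifelse(n_called > 0L, alt_count / (2 * n_called), NA_real_)
  data.frame(maf = pmin(p, 1 - p),
             missing_rate = 1 - n_called / n_samples,
             n_called = n_called)
}

#' MAF / missingness filter
#'
#' Keeps sites with `maf >= maf_min` and `missing_rate < missing_max`
#' (inclusive on the MAF bound, strict on missingness). Each rejected site is
#' tallied once, under the first failing rule (`maf`, then `missing`); sites
#' with no called genotype count as `missing`.
#'
#' @param vs A [variant_set].
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param missing_max Missing-rate ceiling, exclusive (default 0.5).
#' @return List with `kept` (a [variant_set]), `keep` (logical per site),
#'   `stats` (the [site_stats] frame) and `rejections` (named tally).
#' @export
filter_stats <- function(vs, maf_min = 0.05, missing_max = 0.5) {
  st <- site_stats(vs)
  reason <- rep(NA_character_, n_sites(vs))
  reason[!is.na(st$maf) & st$maf < maf_min] <- "maf"
  reason[is.na(reason) & st$missing_rate >= missing_max] <- "missing"
  reason[is.na(reason) & is.na(st$maf)] <- "missing"
  keep <- is.na(reason)
  list(kept = subset_sites(vs, keep),
       keep = keep,
       stats = st,
       rejections = c(maf = sum(reason == "maf", na.rm = TRUE),
                      missing = sum(reason == "missing", na.rm = TRUE)))
}

#' GC fraction of a nucleotide string
#'
#' `(G + C) / (A + C + G + T)`; N bases are excluded from the denominator.
#' An all-N sequence yields `NA`.
#'
#' @param seq Non-empty nucleotide string over A/C/G/T/N (case-insensitive).
#' @return Fraction in `[0, 1]`, or `NA` if no unambiguous base.
#' @export
gc_fraction <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("gc_fraction expects one non-empty sequence string")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gc <- sum(ch %in% c("G", "C"))
  acgt <- sum(ch %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

#' Extract the probe flanks around a SNP
#'
#' Takes the 100-bp (by default) windows immediately upstream and downstream
#' of a position and derives their GC fractions and N content. `complete` is
#' `FALSE` when either window overruns a chromosome end (the returned flank is
#' then truncated).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param pos 1-based position; must lie on the chromosome.
#' @param flank Flank width in bp (default 100).
#' @return A `flank_context` list: `up_seq`, `down_seq`, `gc_up`, `gc_down`,
#'   `has_n`, `complete`.
#' @export
extract_flanks <- function(genome, chrom, pos, flank = 100L) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (pos < 1L || pos > len)
    stop("position ", pos, " outside chromosome ", chrom, " (1-", len, ")")
  s <- as.character(genome[[chrom]])
  up <- substr(s, max(1L, pos - flank), pos - 1L)
  down <- substr(s, pos + 1L, min(len, pos + flank))
  complete <- (pos - flank >= 1L) && (pos + flank <= len)
  structure(list(
    up_seq = up, down_seq = down,
    gc_up = if (nchar(up)) gc_fraction(up) else NA_real_,
    gc_down = if (nchar(down)) gc_fraction(down) else NA_real_,
    has_n = grepl("N", up, fixed = TRUE) || grepl("N", down, fixed = TRUE),
    complete = complete), class = "flank_context")
}

#' Flank GC / N filter
#'
#' A probe context passes when both flanks are complete, contain no N, and
#' each flank's GC fraction lies strictly inside `(gc_lo, gc_hi)`.
#'
#' @param context A `flank_context` from [extract_flanks()].
#' @param gc_lo,gc_hi GC bounds, strict (defaults 0.40 and 0.60).
#' @return List with `pass` (logical) and `reason` (`NA`, `"incomplete"`,
#'   `"N"` or `"gc"`).
#' @export
flank_filter <- function(context, gc_lo = 0.40, gc_hi = 0.60) {
  reason <- NA_character_
  if (!context$complete) reason <- "incomplete"
  else if (context$has_n) reason <- "N"
  else if (is.na(context$gc_up) || is.na(context$gc_down) ||
           context$gc_up <= gc_lo || context$gc_up >= gc_hi ||
           context$gc_down <= gc_lo || context$gc_down >= gc_hi)
    reason <- "gc"
  list(pass = is.na(reason), reason = reason)
}

## longest exact-match run between probe and the genome window anchored so
## that probe position 1 sits at genome position `anchor`
.aligned_run <- function(probe_ch, chrom_seq, anchor) {
  L <- length(probe_ch)
  lo <- max(1L, anchor)
  hi <- min(nchar(chrom_seq), anchor + L - 1L)
  if (hi < lo) return(0L)
  g <- strsplit(substr(chrom_seq, lo, hi), "", fixed = TRUE)[[1]]
  p <- probe_ch[(lo - anchor + 1L):(hi - anchor + 1L)]
  eq <- p == g
  if (!any(eq)) return(0L)
  r <- rle(eq)
  max(r$lengths[r$values])
}

#' Find genomic copies of a probe context
#'
#' Searches a genome for loci where the probe sequence (SNP plus flanks, 201
#' bp by default) has an ungapped exact match of at least `min_copy_len` bp,
#' on either strand. The search is seed-and-verify: non-overlapping seeds of
#' length `floor(min_copy_len / 2)` tile the probe, so every exact match of
#' length `>= min_copy_len` is guaranteed to be found; each candidate locus is
#' verified by its longest exact run. Diverged (inexact) copies are found only
#' when they retain a full seed — aligner-grade best effort, not a guarantee.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param probe_seq Probe sequence (character), length `>= min_copy_len`.
#' @param self_locus List or vector with `chrom` and `start`: the 1-based
#'   genome position of the probe's own first base.
#' @param min_copy_len Minimum aligned length to call a copy (default 120).
#' @return A `copy_report` list: `hits` (data frame `chrom`, `start`,
#'   `strand`, `aligned_length`) and `is_single_copy`.
#' @export
find_copies <- function(genome, probe_seq, self_locus, min_copy_len = 120L) {
  probe_seq <- toupper(probe_seq)
  L <- nchar(probe_seq)
  if (L < min_copy_len)
    stop("probe (", L, " bp) shorter than min_copy_len (", min_copy_len, ")")
  self_chrom <- as.character(self_locus[["chrom"]])
  self_start <- as.integer(self_locus[["start"]])
  slen <- max(3L, min_copy_len %/% 2L)
  offs <- unique(c(seq(1L, L - slen + 1L, by = slen), L - slen + 1L))
  chrom_seqs <- as.character(genome)
  strands <- list(`+` = probe_seq,
                  `-` = as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(probe_seq))))
  hits <- list()
  for (std in names(strands)) {
    q <- strands[[std]]
    q_ch <- strsplit(q, "", fixed = TRUE)[[1]]
    anchors <- list()
    for (ci in seq_along(chrom_seqs)) {
      subj <- Biostrings::DNAString(chrom_seqs[[ci]])
      a <- integer(0)
      for (o in offs) {
        m <- Biostrings::matchPattern(substr(q, o, o + slen - 1L), subj)
        if (length(m)) a <- c(a, BiocGenerics::start(m) - o + 1L)
      }
      anchors[[ci]] <- unique(a)
    }
    for (ci in seq_along(chrom_seqs)) {
      for (a in anchors[[ci]]) {
        run <- .aligned_run(q_ch, chrom_seqs[[ci]], a)
        if (run >= min_copy_len)
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = names(genome)[ci], start = a, strand = std,
            aligned_length = run)
      }
    }
  }
  hits <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(chrom = character(0), start = integer(0),
               strand = character(0), aligned_length = integer(0))
  row.names(hits) <- NULL
  is_self <- hits$chrom == self_chrom & hits$strand == "+" &
    hits$start == self_start
  if (sum(is_self) != 1L)
    warning("self locus matched ", sum(is_self),
            " times; probe/genome mismatch?")
  structure(list(hits = hits, is_single_copy = all(is_self)),
            class = "copy_report")
}

## spliced CDS coordinate of a genomic position; NA when pos not in CDS
.cds_coord <- function(gene, pos) {
  cds <- gene$cds
  if (!nrow(cds)) return(NA_integer_)
  hit <- which(pos >= cds$start & pos <= cds$end)
  if (!length(hit)) return(NA_integer_)
  if (gene$strand == "-") {
    after <- if (hit < nrow(cds)) sum(cds$end[(hit + 1L):nrow(cds)] -
                                        cds$start[(hit + 1L):nrow(cds)] + 1L)
             else 0L
    after + (cds$end[hit] - pos) + 1L
  } else {
    before <- if (hit > 1L) sum(cds$end[seq_len(hit - 1L)] -
                                  cds$start[seq_len(hit - 1L)] + 1L)
              else 0L
    before + (pos - cds$start[hit]) + 1L
  }
}

.splice_cds <- function(gene, chrom_seq) {
  segs <- vapply(seq_len(nrow(gene$cds)), function(i)
    substr(chrom_seq, gene$cds$start[i], gene$cds$end[i]), character(1))
  s <- paste(segs, collapse = "")
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

.comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a SNP by functional context
#'
#' Assigns one of `intergenic`, `noncoding_genic`, `synonymous`,
#' `nonsynonymous`, `start_codon_change`, `stop_codon_change` using the gene
#' models' CDS chains and the standard genetic code (strand-aware). A CDS
#' whose phase is inconsistent (reference base disagreeing with the genome,
#' or a truncated codon) falls back to `noncoding_genic` with a warning.
#'
#' @param chrom,pos,ref,alt The SNP.
#' @param genes A `gene_model_set` from [read_gff()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return A single classification string.
#' @export
classify_site <- function(chrom, pos, ref, alt, genes, genome) {
  in_gene <- Filter(function(g) g$chrom == chrom && pos >= g$start &&
                      pos <= g$end, genes)
  if (!length(in_gene)) return("intergenic")
  chrom_seq <- as.character(genome[[chrom]])
  for (g in in_gene) {
    cpos <- .cds_coord(g, pos)
    if (is.na(cpos)) next
    cds_seq <- .splice_cds(g, chrom_seq)
    codon_i <- (cpos - 1L) %/% 3L + 1L
    within <- (cpos - 1L) %% 3L + 1L
    codon <- substr(cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    if (nchar(codon) < 3L) {
      warning("truncated codon in ", g$gene_id, "; classified noncoding_genic")
      return("noncoding_genic")
    }
    ref_cds <- if (g$strand == "-") .comp_base[[ref]] else ref
    alt_cds <- if (g$strand == "-") .comp_base[[alt]] else alt
    if (substr(codon, within, within) != ref_cds) {
      warning("reference allele disagrees with genome at ", chrom, ":", pos,
              "; classified noncoding_genic")
      return("noncoding_genic")
    }
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt_cds
    ref_aa <- Biostrings::GENETIC_CODE[[codon]]
    alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
    if (codon_i == 1L && codon == "ATG" && alt_codon != "ATG")
      return("start_codon_change")
    if (xor(ref_aa == "*", alt_aa == "*")) return("stop_codon_change")
    return(if (ref_aa == alt_aa) "synonymous" else "nonsynonymous")
  }
  "noncoding_genic"
}

#' Run the full panel-selection cascade
#'
#' Applies, in order: the biallelic-SNP restriction (done at VCF parse time),
#' the MAF/missingness filter, flank completeness/N/GC rules, the single-copy
#' probe-context check, and functional classification. Each stage records its
#' survivor count in an audit table; each rejected site is tallied under
#' exactly one reason.
#'
#' @param vs A [variant_set] (biallelic SNPs).
#' @param genome A [Biostrings::DNAStringSet].
#' @param genes A `gene_model_set`, or `NULL` to skip classification
#'   (`func_class` then `NA`).
#' @param maf_min,missing_max,flank,gc_lo,gc_hi,min_copy_len Cascade
#'   parameters; defaults 0.05, 0.5, 100, 0.40, 0.60, 120.
#' @param check_copies Run the built-in copy search (default `TRUE`). Set to
#'   `FALSE` when supplying `external_hits`.
#' @param external_hits Optional adapter for production genomes: a data frame
#'   of alignment hits (`chrom`, `pos`, `n_hits`) from an external aligner;
#'   sites with `n_hits > 1` fail the single-copy stage.
#' @return An object of class `snp_panel`: `panel` (data frame with `chrom`,
#'   `pos`, `ref`, `alt`, `maf`, `missing_rate`, `gc_up`, `gc_down`,
#'   `func_class`), `audit` (stage survivor counts) and `rejections`.
#' @export
select_panel <- function(vs, genome, genes = NULL,
                         maf_min = 0.05, missing_max = 0.5, flank = 100L,
                         gc_lo = 0.40, gc_hi = 0.60, min_copy_len = 120L,
                         check_copies = TRUE, external_hits = NULL) {
  n_in <- n_sites(vs)
  fs <- filter_stats(vs, maf_min = maf_min, missing_max = missing_max)
  vs2 <- fs$kept
  st2 <- fs$stats[fs$keep, , drop = FALSE]

  ctx <- lapply(seq_len(n_sites(vs2)), function(i)
    extract_flanks(genome, vs2$chrom[i], vs2$pos[i], flank = flank))
  ff <- lapply(ctx, flank_filter, gc_lo = gc_lo, gc_hi = gc_hi)
  pass_flank <- vapply(ff, `[[`, logical(1), "pass")
  flank_reasons <- vapply(ff, `[[`, character(1), "reason")
  vs3 <- subset_sites(vs2, pass_flank)
  st3 <- st2[pass_flank, , drop = FALSE]
  ctx3 <- ctx[pass_flank]

  if (!is.null(external_hits)) {
    key <- paste(vs3$chrom, vs3$pos)
    ek <- paste(external_hits$chrom, external_hits$pos)
    nh <- external_hits$n_hits[match(key, ek)]
    single <- is.na(nh) | nh <= 1L
  } else if (check_copies) {
    chrom_seqs <- as.character(genome)
    single <- vapply(seq_len(n_sites(vs3)), function(i) {
      s <- chrom_seqs[[vs3$chrom[i]]]
      probe <- substr(s, vs3$pos[i] - flank, vs3$pos[i] + flank)
      find_copies(genome, probe,
                  list(chrom = vs3$chrom[i], start = vs3$pos[i] - flank),
                  min_copy_len = min_copy_len)$is_single_copy
    }, logical(1))
  } else single <- rep(TRUE, n_sites(vs3))
  vs4 <- subset_sites(vs3, single)
  st4 <- st3[single, , drop = FALSE]
  ctx4 <- ctx3[single]

  func <- if (is.null(genes)) rep(NA_character_, n_sites(vs4)) else
    vapply(seq_len(n_sites(vs4)), function(i)
      classify_site(vs4$chrom[i], vs4$pos[i], vs4$ref[i], vs4$alt[i],
                    genes, genome), character(1))

  panel <- data.frame(
    chrom = vs4$chrom, pos = vs4$pos, ref = vs4$ref, alt = vs4$alt,
    maf = st4$maf, missing_rate = st4$missing_rate,
    gc_up = vapply(ctx4, `[[`, numeric(1), "gc_up"),
    gc_down = vapply(ctx4, `[[`, numeric(1), "gc_down"),
    func_class = func)
  audit <- data.frame(
    stage = c("input", "maf_missing", "flank", "single_copy"),
    survivors = c(n_in, n_sites(vs2), n_sites(vs3), n_sites(vs4)))
  rejections <- c(fs$rejections,
                  incomplete_flank = sum(flank_reasons == "incomplete",
                                         na.rm = TRUE),
                  n_flank = sum(flank_reasons == "N", na.rm = TRUE),
                  gc = sum(flank_reasons == "gc", na.rm = TRUE),
                  multi_copy = sum(!single))
  if (nrow(panel) == 0L) warning("no site survived the cascade; empty panel")
  structure(list(panel = panel, audit = audit, rejections = rejections),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", nrow(x$panel), "SNPs retained\n")
  print(x$audit, row.names = FALSE)
  cat("rejections:",
      paste(names(x$rejections), x$rejections, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Binned SNP density along chromosomes
#'
#' @param panel An `snp_panel` or its `$panel` data frame.
#' @param genome A [Biostrings::DNAStringSet] (defines chromosome lengths).
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return Data frame `chrom`, `bin_start`, `bin_end`, `count`; counts over
#'   all bins sum to the panel size.
#' @export
density_report <- function(panel, genome, bin_size = 1e6) {
  if (inherits(panel, "snp_panel")) panel <- panel$panel
  if (!is.numeric(bin_size) || bin_size <= 0) stop("bin_size must be > 0")
  if (nrow(panel) == 0L) stop("empty panel")
  out <- lapply(names(genome), function(ch) {
    len <- Biostrings::width(genome)[match(ch, names(genome))]
    nb <- ceiling(len / bin_size)
    pos <- panel$pos[panel$chrom == ch]
    bin <- pmin(nb, (pos - 1) %/% bin_size + 1)
    data.frame(chrom = ch,
               bin_start = as.integer((seq_len(nb) - 1) * bin_size + 1),
               bin_end = as.integer(pmin(seq_len(nb) * bin_size, len)),
               count = tabulate(bin, nbins = nb))
  })
  do.call(rbind, out)
}

#' Thin a panel to a minimum marker spacing
#'
#' Optional greedy down-sampling used when the cascade leaves more markers
#' than an array can carry: walks each chromosome left to right keeping a
#' site only when it lies at least `min_spacing` bp after the last kept one.
#'
#' @param panel An `snp_panel` or its `$panel` data frame.
#' @param min_spacing Minimum distance between kept SNPs, bp.
#' @return The thinned `$panel` data frame.
#' @export
thin_panel <- function(panel, min_spacing) {
  if (inherits(panel, "snp_panel")) panel <- panel$panel
  keep <- logical(nrow(panel))
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    idx <- idx[order(panel$pos[idx])]
    last <- -Inf
    for (i in idx) {
      if (panel$pos[i] - last >= min_spacing) {
        keep[i] <- TRUE
        last <- panel$pos[i]
      }
    }
  }
  panel[keep, , drop = FALSE]
}
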