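#' Simulate a diploid reference genome with planted features
#'
#' Generates random chromosomes (uniform base composition, GC 0.5) and plants,
#' verbatim and non-overlapping: duplicated segments (a source region copied
#' to a destination), N runs, and GC-extreme regions (bases resampled at a
#' target GC). Every planted feature is recorded in the returned truth so
#' downstream filter decisions are predictable.
#'
#' @param n_chrom Number of chromosomes.
#' @param length Chromosome length(s) in bp (recycled); >= 10 kb.
#' @param seed RNG seed; the genome is bit-reproducible given the seed.
#' @param duplications Optional data frame `src_chrom`, `src_start`, `length`,
#'   `dest_chrom`, `dest_start`: the source segment is copied verbatim.
#' @param n_runs Optional data frame `chrom`, `start`, `length` of N runs.
#' @param gc_regions Optional data frame `chrom`, `start`, `length`, `gc`.
#' @return List with `genome` (a [Biostrings::DNAStringSet]) and `truth`
#'   (class `fixture_truth`).
#' @export
make_genome <- function(n_chrom = 2L, length = 1e5, seed = 1L,
                        duplications = NULL, n_runs = NULL,
                        gc_regions = NULL) {
  if (any(length < 1e4)) stop("chromosome lengths must be >= 10 kb")
  set.seed(seed)
  lens <- as.integer(rep_len(length, n_chrom))
  nm <- paste0("chr", seq_len(n_chrom))
  seqs <- lapply(lens, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(seqs) <- nm

  feats <- list()
  add_feat <- function(chrom, start, len, what) {
    feats[[length(feats) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = start + len - 1L, what = what)
  }
  if (!is.null(gc_regions)) {
    for (i in seq_len(nrow(gc_regions))) {
      r <- gc_regions[i, ]
      idx <- r$start:(r$start + r$length - 1L)
      gc <- stats::runif(r$length) < r$gc
      seqs[[r$chrom]][idx] <- ifelse(gc, sample(c("G", "C"), r$length, TRUE),
                                     sample(c("A", "T"), r$length, TRUE))
      add_feat(r$chrom, r$start, r$length, "gc")
    }
  }
  if (!is.null(duplications)) {
    for (i in seq_len(nrow(duplications))) {
      d <- duplications[i, ]
      src <- seqs[[d$src_chrom]][d$src_start:(d$src_start + d$length - 1L)]
      seqs[[d$dest_chrom]][d$dest_start:(d$dest_start + d$length - 1L)] <- src
      add_feat(d$src_chrom, d$src_start, d$length, "dup_src")
      add_feat(d$dest_chrom, d$dest_start, d$length, "dup_dest")
    }
  }
  if (!is.null(n_runs)) {
    for (i in seq_len(nrow(n_runs))) {
      r <- n_runs[i, ]
      seqs[[r$chrom]][r$start:(r$start + r$length - 1L)] <- "N"
      add_feat(r$chrom, r$start, r$length, "n_run")
    }
  }
  if (length(feats) > 1L) {
    f <- do.call(rbind, feats)
    for (i in seq_len(nrow(f) - 1L)) for (j in (i + 1L):nrow(f)) {
      if (f$chrom[i] == f$chrom[j] &&
          f$start[i] <= f$end[j] && f$start[j] <= f$end[i])
        stop("planted features overlap: ", f$what[i], " and ", f$what[j],
             " on ", f$chrom[i])
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- nm
  truth <- structure(list(seed = seed, duplications = duplications,
                          n_runs = n_runs, gc_regions = gc_regions),
                     class = "fixture_truth")
  list(genome = genome, truth = truth)
}

.flank_ok <- function(chrom_seq, pos, flank, gc_lo, gc_hi) {
  up <- substr(chrom_seq, pos - flank, pos - 1L)
  down <- substr(chrom_seq, pos + 1L, pos + flank)
  if (grepl("N", up, fixed = TRUE) || grepl("N", down, fixed = TRUE))
    return(FALSE)
  gu <- gc_fraction(up); gd <- gc_fraction(down)
  !is.na(gu) && !is.na(gd) && gu > gc_lo && gu < gc_hi &&
    gd > gc_lo && gd < gc_hi
}

#' Simulate a population VCF with controlled filter violations
#'
#' Places biallelic SNPs on a simulated genome and assigns genotypes either
#' by Hardy-Weinberg sampling (`mode = "sampling"`) or deterministically so
#' that each site's MAF and missingness are hit exactly
#' (`mode = "construction"`). A requested number of sites is constructed to
#' violate exactly one panel rule each (low MAF, high missingness, flank N,
#' flank GC outside bounds, multi-copy context); all remaining sites are
#' verified at generation time to pass every rule, so the truth table
#' predicts [select_panel()]'s decision for every site.
#'
#' @param genome_fx A genome fixture from [make_genome()] (list with `genome`
#'   and `truth`); GC/N/duplicate violations are placed inside the planted
#'   regions recorded there.
#' @param n_samples Number of samples.
#' @param n_sites Total number of sites.
#' @param maf_range True MAF range for clean sites (default `c(0.1, 0.5)`).
#' @param missing_rate Missingness for clean sites (default 0).
#' @param violations Named counts among `maf`, `missing`, `n_flank`, `gc`,
#'   `copy` (default none). GC/N/copy violations require matching planted
#'   regions in the genome fixture.
#' @param mode `"construction"` (exact genotype counts) or `"sampling"` (HWE
#'   draws).
#' @param seed RNG seed.
#' @param path Optional path; when given the VCF is also written there.
#' @return List with `vcf` (a [variant_set]) and `truth` (data frame `chrom`,
#'   `pos`, `true_maf`, `true_missing`, `violates`).
#' @export
make_population_vcf <- function(genome_fx, n_samples = 20L, n_sites = 100L,
                                maf_range = c(0.1, 0.5), missing_rate = 0,
                                violations = c(), mode = c("construction",
                                                           "sampling"),
                                seed = 1L, path = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  genome <- genome_fx$genome
  truth <- genome_fx$truth
  chrom_seqs <- as.character(genome)
  lens <- Biostrings::width(genome)
  flank <- 100L
  viol <- c(maf = 0L, missing = 0L, n_flank = 0L, gc = 0L, copy = 0L)
  if (length(violations)) viol[names(violations)] <- violations
  n_clean <- n_sites - sum(viol)
  if (n_clean < 0L) stop("more violations than sites")

  used <- new.env(); assign("keys", character(0), envir = used)
  take_pos <- function(chrom, pos) {
    key <- paste(chrom, pos)
    if (key %in% get("keys", envir = used)) return(FALSE)
    assign("keys", c(get("keys", envir = used), key), envir = used)
    TRUE
  }
  in_any <- function(chrom, pos, df, pad = 0L) {
    if (is.null(df)) return(FALSE)
    any(df[[1]] == chrom & pos >= df$start - pad &
          pos <= df$start + df$length - 1L + pad)
  }
  clean_pos <- function() {
    repeat {
      ci <- sample(seq_along(chrom_seqs), 1L)
      pos <- sample(seq(flank + 1L, lens[ci] - flank), 1L)
      ch <- names(genome)[ci]
      if (in_any(ch, pos, truth$n_runs, pad = flank)) next
      if (in_any(ch, pos, truth$gc_regions, pad = flank)) next
      dups <- truth$duplications
      if (!is.null(dups)) {
        near_src <- any(dups$src_chrom == ch &
                          pos >= dups$src_start - flank &
                          pos <= dups$src_start + dups$length - 1L + flank)
        near_dst <- any(dups$dest_chrom == ch &
                          pos >= dups$dest_start - flank &
                          pos <= dups$dest_start + dups$length - 1L + flank)
        if (near_src || near_dst) next
      }
      if (!.flank_ok(chrom_seqs[[ci]], pos, flank, 0.40, 0.60)) next
      if (take_pos(ch, pos)) return(list(chrom = ch, pos = pos))
    }
  }
  sites <- list()
  add_site <- function(chrom, pos, violates, true_maf, true_missing) {
    sites[[length(sites) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, violates = violates,
      true_maf = true_maf, true_missing = true_missing)
  }
  draw_maf <- function() stats::runif(1L, maf_range[1], maf_range[2])

  for (k in seq_len(viol[["n_flank"]])) {
    nr <- truth$n_runs
    if (is.null(nr)) stop("n_flank violations need planted N runs")
    r <- nr[sample(nrow(nr), 1L), ]
    repeat {
      pos <- r$start - sample(2:(flank - 1L), 1L)   # N run inside the up flank
      ci <- match(r$chrom, names(genome))
      if (pos - flank >= 1L && take_pos(r$chrom, pos)) break
    }
    add_site(r$chrom, pos, "n_flank", draw_maf(), missing_rate)
  }
  for (k in seq_len(viol[["gc"]])) {
    gr <- truth$gc_regions
    if (is.null(gr)) stop("gc violations need planted GC-extreme regions")
    repeat {
      r <- gr[sample(nrow(gr), 1L), ]
      pos <- r$start + flank + sample(r$length - 2L * flank, 1L) - 1L
      ci <- match(r$chrom, names(genome))
      ctx <- extract_flanks(genome, r$chrom, pos, flank)
      off <- ctx$gc_up <= 0.40 || ctx$gc_up >= 0.60 ||
        ctx$gc_down <= 0.40 || ctx$gc_down >= 0.60
      if (off && !ctx$has_n && take_pos(r$chrom, pos)) break
    }
    add_site(r$chrom, pos, "gc", draw_maf(), missing_rate)
  }
  for (k in seq_len(viol[["copy"]])) {
    dups <- truth$duplications
    if (is.null(dups)) stop("copy violations need planted duplications")
    repeat {
      d <- dups[sample(nrow(dups), 1L), ]
      if (d$length < 140L) stop("planted duplications must be >= 140 bp for ",
                                "copy-violation sites")
      pos <- d$src_start + d$length %/% 2L   # probe overlap with copy >= len/2
      ci <- match(d$src_chrom, names(genome))
      if (.flank_ok(chrom_seqs[[ci]], pos, flank, 0.40, 0.60) &&
          take_pos(d$src_chrom, pos)) break
      pos <- pos + sample(-20:20, 1L)
      if (pos > d$src_start + 60L && pos < d$src_start + d$length - 60L &&
          .flank_ok(chrom_seqs[[ci]], pos, flank, 0.40, 0.60) &&
          take_pos(d$src_chrom, pos)) break
    }
    add_site(d$src_chrom, pos, "copy", draw_maf(), missing_rate)
  }
  for (k in seq_len(viol[["maf"]])) {
    p <- clean_pos()
    low <- if (mode == "construction") 0.03 else stats::runif(1L, 0.005, 0.04)
    add_site(p$chrom, p$pos, "maf", low, missing_rate)
  }
  for (k in seq_len(viol[["missing"]])) {
    p <- clean_pos()
    add_site(p$chrom, p$pos, "missing", draw_maf(), 0.6)
  }
  for (k in seq_len(n_clean)) {
    p <- clean_pos()
    add_site(p$chrom, p$pos, "none", draw_maf(), missing_rate)
  }
  tr <- do.call(rbind, sites)
  o <- order(tr$chrom, tr$pos)
  tr <- tr[o, , drop = FALSE]
  row.names(tr) <- NULL

  n <- nrow(tr)
  ref <- vapply(seq_len(n), function(i)
    substr(chrom_seqs[[tr$chrom[i]]], tr$pos[i], tr$pos[i]), character(1))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

  gt <- matrix(NA_integer_, n, n_samples)
  for (i in seq_len(n)) {
    maf <- tr$true_maf[i]; miss <- tr$true_missing[i]
    if (mode == "construction") {
      n_miss <- round(miss * n_samples)
      n_called <- n_samples - n_miss
      alt_alleles <- round(2 * n_called * maf)
      n_hom <- alt_alleles %/% 2L
      n_het <- alt_alleles %% 2L
      g <- c(rep(2L, n_hom), rep(1L, n_het),
             rep(0L, n_called - n_hom - n_het), rep(NA_integer_, n_miss))
      gt[i, ] <- sample(g)
      ac <- sum(gt[i, ], na.rm = TRUE)
      tr$true_maf[i] <- min(ac, 2 * n_called - ac) / (2 * n_called)
      tr$true_missing[i] <- n_miss / n_samples
    } else {
      g <- stats::rbinom(n_samples, 2L, maf)
      g[stats::runif(n_samples) < miss] <- NA_integer_
      gt[i, ] <- g
    }
  }
  vcf <- variant_set(tr$chrom, tr$pos, ref, alt, gt,
                     samples = sprintf("S%03d", seq_len(n_samples)))
  if (!is.null(path)) write_vcf(vcf, path, contigs = stats::setNames(
    Biostrings::width(genome), names(genome)))
  list(vcf = vcf, truth = tr)
}

#' Default evenly spaced marker map for BSA simulations
#'
#' @param n_chrom Number of chromosomes (default 4).
#' @param chrom_len Chromosome length in bp (default 90 Mb).
#' @param markers_per_chrom Markers per chromosome, evenly spaced
#'   (default 500).
#' @return Data frame `marker`, `chrom`, `pos`.
#' @export
default_marker_map <- function(n_chrom = 4L, chrom_len = 9e7,
                               markers_per_chrom = 500L) {
  do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    pos <- as.integer(round(seq(chrom_len / (markers_per_chrom + 1),
                                chrom_len, length.out = markers_per_chrom)))
    data.frame(marker = sprintf("m%d_%04d", ci, seq_len(markers_per_chrom)),
               chrom = paste0("chr", ci), pos = pos)
  }))
}

## simulate one gamete per individual over ordered loci (Haldane, no
## interference): allele 1 = maternal. `r` = recombination fractions between
## consecutive loci (0.5 across chromosome boundaries).
.gametes <- function(n, r) {
  L <- length(r) + 1L
  al <- matrix(0L, n, L)
  al[, 1L] <- stats::rbinom(n, 1L, 0.5)
  cur <- al[, 1L]
  for (j in seq_along(r)) {
    sw <- stats::rbinom(n, 1L, r[j])
    cur <- (cur + sw) %% 2L
    al[, j + 1L] <- cur
  }
  al
}

#' Simulate an F2 cross segregating a single dominant locus
#'
#' Builds `n_individuals` F2 genotypes over a marker map by simulating two
#' recombination-aware gametes each (Haldane map function, no interference,
#' `cm_per_mb` centimorgan per megabase; chromosomes assort independently).
#' The phenotype is driven by the genotype at the causal locus: individuals
#' carrying at least one maternal (dominant) allele draw
#' `FSI ~ N(mu_dom, sigma)`, the rest `N(mu_rec, sigma)`; shape classes come
#' from [classify_shape()].
#'
#' @param n_individuals Cross size (default 1435).
#' @param marker_map Data frame `marker`, `chrom`, `pos`
#'   (see [default_marker_map()]).
#' @param causal Causal locus: `list(chrom =, pos =)` inside the map span.
#' @param fsi_model List: `mu_dom` (1.2), `mu_rec` (0.9), `sigma` (0.04),
#'   `threshold` (1.0).
#' @param cm_per_mb Map density (default 1 cM/Mb).
#' @param seed RNG seed.
#' @return An `f2_cross` list: `dosage` (integer matrix individuals x markers,
#'   maternal-allele count 0/1/2), `geno` (same as `A`/`H`/`B` letters),
#'   `phenotypes` (`individual`, `fsi`, `class`), `causal_dosage`,
#'   `marker_map`, `truth`.
#' @export
make_f2_cross <- function(n_individuals = 1435L,
                          marker_map = default_marker_map(),
                          causal = list(chrom = "chr3", pos = 81900000L),
                          fsi_model = list(mu_dom = 1.2, mu_rec = 0.9,
                                           sigma = 0.04, threshold = 1.0),
                          cm_per_mb = 1, seed = 1L) {
  set.seed(seed)
  map <- marker_map[order(marker_map$chrom, marker_map$pos), , drop = FALSE]
  span <- map$pos[map$chrom == causal$chrom]
  if (!length(span) || causal$pos < min(span) || causal$pos > max(span))
    stop("causal position must lie inside the marker map span")
  loci <- rbind(map[, c("chrom", "pos")],
                data.frame(chrom = causal$chrom, pos = causal$pos))
  o <- order(loci$chrom, loci$pos)
  loci <- loci[o, , drop = FALSE]
  causal_i <- which(loci$chrom == causal$chrom & loci$pos == causal$pos)[1]
  d_bp <- diff(loci$pos)
  same_chr <- loci$chrom[-1] == loci$chrom[-nrow(loci)]
  d_morgan <- d_bp * cm_per_mb / 1e6 / 100
  r <- ifelse(same_chr, 0.5 * (1 - exp(-2 * d_morgan)), 0.5)
  dosage_all <- .gametes(n_individuals, r) + .gametes(n_individuals, r)

  causal_dosage <- dosage_all[, causal_i]
  marker_cols <- setdiff(seq_len(nrow(loci)), causal_i)
  # map back to the input marker order
  key_loci <- paste(loci$chrom, loci$pos)[marker_cols]
  key_map <- paste(map$chrom, map$pos)
  dosage <- dosage_all[, marker_cols, drop = FALSE][, match(key_map, key_loci),
                                                    drop = FALSE]
  colnames(dosage) <- map$marker
  ids <- sprintf("F2_%04d", seq_len(n_individuals))
  rownames(dosage) <- ids

  fsi <- ifelse(causal_dosage >= 1L,
                stats::rnorm(n_individuals, fsi_model$mu_dom, fsi_model$sigma),
                stats::rnorm(n_individuals, fsi_model$mu_rec, fsi_model$sigma))
  pheno <- data.frame(individual = ids, fsi = fsi,
                      class = classify_shape(fsi, fsi_model$threshold))
  geno <- matrix(c("B", "H", "A")[dosage + 1L], nrow = n_individuals,
                 dimnames = dimnames(dosage))
  structure(list(dosage = dosage, geno = geno, phenotypes = pheno,
                 causal_dosage = causal_dosage, marker_map = map,
                 truth = structure(list(seed = seed, causal = causal,
                                        fsi_model = fsi_model,
                                        cm_per_mb = cm_per_mb),
                                   class = "fixture_truth")),
            class = "f2_cross")
}

#' @export
print.f2_cross <- function(x, ...) {
  tab <- table(x$phenotypes$class)
  cat("f2_cross:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "markers; classes:", paste(names(tab), tab, collapse = ", "),
      "| causal", x$truth$causal$chrom, x$truth$causal$pos, "\n")
  invisible(x)
}

#' Simulate extreme-phenotype pooled sequencing depths
#'
#' Selects the `n_extreme` lowest-FSI and `n_extreme` highest-FSI individuals
#' of an F2 cross (or, with `use_thresholds`, individuals beyond fixed FSI
#' cutoffs), then draws per-marker pooled read counts: total depth is Poisson
#' with mean `depth_mean` per pool, and maternal-allele reads are binomial at
#' the pool's maternal allele frequency. Ref/alt bases are assigned per
#' marker so depths live on the four-base (A, C, G, T) axes.
#'
#' @param cross An `f2_cross` from [make_f2_cross()].
#' @param n_extreme Individuals per tail (default 30).
#' @param depth_mean Mean pool depth per site (> 0; default 30).
#' @param use_thresholds If `TRUE`, select FSI `<= thresholds[1]` (pool 1) and
#'   `> thresholds[2]` (pool 2) instead of rank tails.
#' @param thresholds FSI cutoffs used with `use_thresholds`
#'   (default `c(0.9, 1.2)`).
#' @param seed RNG seed.
#' @return List with `pools` (a [pool_depths]; pool 1 = low FSI/round,
#'   pool 2 = high FSI/oval) and `truth` (selected ids, causal locus, marker
#'   alleles).
#' @export
make_pools <- function(cross, n_extreme = 30L, depth_mean = 30,
                       use_thresholds = FALSE, thresholds = c(0.9, 1.2),
                       seed = 1L) {
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  set.seed(seed)
  fsi <- cross$phenotypes$fsi
  if (use_thresholds) {
    low <- which(fsi <= thresholds[1]); high <- which(fsi > thresholds[2])
    if (length(low) < n_extreme || length(high) < n_extreme)
      stop("fewer than n_extreme individuals beyond a threshold; ",
           "use a larger cross")
    low <- low[order(fsi[low])][seq_len(n_extreme)]
    high <- high[order(-fsi[high])][seq_len(n_extreme)]
  } else {
    if (nrow(cross$dosage) < 2L * n_extreme)
      stop("cross smaller than 2 * n_extreme; use a larger cross")
    o <- order(fsi)
    low <- o[seq_len(n_extreme)]
    high <- rev(o)[seq_len(n_extreme)]
  }
  m <- ncol(cross$dosage)
  freq1 <- colSums(cross$dosage[low, , drop = FALSE]) / (2 * n_extreme)
  freq2 <- colSums(cross$dosage[high, , drop = FALSE]) / (2 * n_extreme)
  dep1 <- stats::rpois(m, depth_mean)
  dep2 <- stats::rpois(m, depth_mean)
  mat1 <- stats::rbinom(m, dep1, freq1)
  mat2 <- stats::rbinom(m, dep2, freq2)
  bases <- c("A", "C", "G", "T")
  mat_base <- sample(bases, m, replace = TRUE)
  pat_base <- vapply(mat_base, function(b) sample(setdiff(bases, b), 1L),
                     character(1))
  d1 <- matrix(0L, m, 4L, dimnames = list(NULL, bases))
  d2 <- matrix(0L, m, 4L, dimnames = list(NULL, bases))
  rows <- seq_len(m)
  d1[cbind(rows, match(mat_base, bases))] <- mat1
  d1[cbind(rows, match(pat_base, bases))] <- dep1 - mat1
  d2[cbind(rows, match(mat_base, bases))] <- mat2
  d2[cbind(rows, match(pat_base, bases))] <- dep2 - mat2
  pd <- pool_depths(cross$marker_map$chrom, cross$marker_map$pos, d1, d2)
  truth <- structure(list(
    seed = seed, pool1_ids = cross$phenotypes$individual[low],
    pool2_ids = cross$phenotypes$individual[high],
    causal = cross$truth$causal,
    marker_alleles = data.frame(marker = cross$marker_map$marker,
                                maternal = mat_base, paternal = pat_base)),
    class = "fixture_truth")
  list(pools = pd, truth = truth)
}
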