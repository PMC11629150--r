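#' Construct per-pool base depths
#'
#' Holds, for every site, the (A, C, G, T) read depth observed in each of two
#' phenotype bulks. Input to the Euclidean-distance statistic.
#'
#' @param chrom,pos Site coordinates (1-based bp).
#' @param d1,d2 Integer matrices, sites x 4, columns A/C/G/T: depths in pool 1
#'   and pool 2.
#' @return An object of class `pool_depths`.
#' @export
pool_depths <- function(chrom, pos, d1, d2) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(ncol(d1) == 4L, ncol(d2) == 4L,
            nrow(d1) == length(pos), nrow(d2) == length(pos))
  if (any(d1 < 0) || any(d2 < 0)) stop("depths must be non-negative")
  colnames(d1) <- colnames(d2) <- c("A", "C", "G", "T")
  o <- order(chrom, pos)
  structure(list(chrom = as.character(chrom)[o], pos = as.integer(pos)[o],
                 d1 = d1[o, , drop = FALSE], d2 = d2[o, , drop = FALSE]),
            class = "pool_depths")
}

#' @export
print.pool_depths <- function(x, ...) {
  cat("pool_depths:", length(x$pos), "sites on",
      length(unique(x$chrom)), "chromosome(s); mean depths ",
      round(mean(rowSums(x$d1)), 1), "/", round(mean(rowSums(x$d2)), 1), "\n")
  invisible(x)
}

#' Base frequencies from depths
#'
#' @param depths Numeric 4-vector (A, C, G, T) of read depths.
#' @return Frequency 4-vector summing to 1, or all-`NA` when total depth is 0
#'   (the site is unusable).
#' @export
base_frequencies <- function(depths) {
  stopifnot(length(depths) == 4L)
  tot <- sum(depths)
  if (tot < 1) return(rep(NA_real_, 4L))
  depths / tot
}

#' Per-site Euclidean distance between two pools
#'
#' `ED = sqrt(sum_b (p1_b - p2_b)^2)` over the four bases. For biallelic
#' frequencies `0 <= ED <= sqrt(2)`.
#'
#' @param p1,p2 Base-frequency 4-vectors (each summing to 1).
#' @return The distance, a non-negative scalar.
#' @export
ed_site <- function(p1, p2) {
  stopifnot(length(p1) == 4L, length(p2) == 4L)
  sqrt(sum((p1 - p2)^2))
}

#' Select informative sites from a two-pool variant set
#'
#' Keeps sites where the two bulks' genotype calls differ, and projects the
#' ref/alt allele depths onto the four-base axes (other bases get depth 0).
#' Sites with a missing call or missing AD in either pool are skipped and
#' tallied.
#'
#' @param vs A [variant_set] with exactly the two pool samples (with AD).
#' @param pool1,pool2 Sample names of the two bulks (default: the two samples
#'   in order).
#' @return A [pool_depths] object; attribute `skipped` tallies exclusions
#'   (`same_genotype`, `missing_gt`, `missing_ad`).
#' @export
informative_sites <- function(vs, pool1 = vs$samples[1], pool2 = vs$samples[2]) {
  i1 <- match(pool1, vs$samples); i2 <- match(pool2, vs$samples)
  if (is.na(i1) || is.na(i2)) stop("pool sample not found in VCF")
  if (is.null(vs$ad_ref)) stop("VCF has no AD field; depths unavailable")
  g1 <- vs$gt[, i1]; g2 <- vs$gt[, i2]
  miss_gt <- is.na(g1) | is.na(g2)
  miss_ad <- is.na(vs$ad_ref[, i1]) | is.na(vs$ad_alt[, i1]) |
    is.na(vs$ad_ref[, i2]) | is.na(vs$ad_alt[, i2])
  same <- !miss_gt & g1 == g2
  keep <- !miss_gt & !miss_ad & !same
  skipped <- c(same_genotype = sum(same & !miss_gt),
               missing_gt = sum(miss_gt),
               missing_ad = sum(miss_ad & !miss_gt & !same))
  base_i <- function(b) match(b, c("A", "C", "G", "T"))
  n <- sum(keep)
  d1 <- matrix(0L, n, 4L); d2 <- matrix(0L, n, 4L)
  ri <- base_i(vs$ref[keep]); ai <- base_i(vs$alt[keep])
  rows <- seq_len(n)
  d1[cbind(rows, ri)] <- vs$ad_ref[keep, i1]
  d1[cbind(rows, ai)] <- vs$ad_alt[keep, i1]
  d2[cbind(rows, ri)] <- vs$ad_ref[keep, i2]
  d2[cbind(rows, ai)] <- vs$ad_alt[keep, i2]
  pd <- pool_depths(vs$chrom[keep], vs$pos[keep], d1, d2)
  attr(pd, "skipped") <- skipped
  pd
}

#' Euclidean-distance profile along the genome
#'
#' Computes per-site ED between the two bulks' base-frequency vectors and the
#' powered value used as the association signal (the square by default, which
#' suppresses background noise). Sites where either pool's total depth is
#' below `min_depth` are excluded and tallied.
#'
#' @param pd A [pool_depths] object.
#' @param power Exponent applied to ED (default 2).
#' @param min_depth Minimum per-pool total depth for a usable site
#'   (default 10).
#' @return An `ed_profile`: data frame `chrom`, `pos`, `ed`, `ed2`, `fitted`
#'   (NA until [fit_snpnum()]), ordered by chromosome and position, with
#'   attributes `power` and `excluded`.
#' @export
ed_profile <- function(pd, power = 2, min_depth = 10) {
  t1 <- rowSums(pd$d1); t2 <- rowSums(pd$d2)
  usable <- t1 >= max(1, min_depth) & t2 >= max(1, min_depth)
  f1 <- pd$d1[usable, , drop = FALSE] / t1[usable]
  f2 <- pd$d2[usable, , drop = FALSE] / t2[usable]
  ed <- sqrt(rowSums((f1 - f2)^2))
  prof <- data.frame(chrom = pd$chrom[usable], pos = pd$pos[usable],
                     ed = ed, ed2 = ed^power, fitted = NA_real_)
  attr(prof, "power") <- power
  attr(prof, "excluded") <- sum(!usable)
  class(prof) <- c("ed_profile", "data.frame")
  prof
}

#' Fit the ED signal over SNP-count windows
#'
#' SNPNUM-style fitting: the fitted value at each site is the median of the
#' powered ED over a window of `window_snps` consecutive SNPs centred on it.
#' Windows shrink symmetrically at chromosome ends and never span
#' chromosomes; when a chromosome holds fewer sites than `window_snps`, the
#' whole-chromosome median is used for all its sites.
#'
#' @param profile An [ed_profile()].
#' @param window_snps Window size in SNPs (odd recommended; default 101).
#' @param step_snps Fit every `step_snps`-th site and assign intermediate
#'   sites the nearest fitted value (default 1 = every site).
#' @return The profile with its `fitted` column filled.
#' @export
fit_snpnum <- function(profile, window_snps = 101L, step_snps = 1L) {
  if (window_snps < 3L) stop("window_snps must be >= 3")
  half <- (window_snps - 1L) %/% 2L
  fitted <- rep(NA_real_, nrow(profile))
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch)
    x <- profile$ed2[idx]
    n <- length(x)
    at <- unique(c(seq(1L, n, by = step_snps), n))
    fv <- rep(NA_real_, n)
    if (window_snps >= n) {
      fv[] <- stats::median(x)
    } else {
      for (i in at) {
        h <- min(half, i - 1L, n - i)
        fv[i] <- stats::median(x[(i - h):(i + h)])
      }
      if (step_snps > 1L) {
        # carry each computed value to the intermediate sites nearest to it
        for (i in seq_len(n)) {
          if (is.na(fv[i])) {
            j <- at[which.min(abs(at - i))]
            fv[i] <- fv[j]
          }
        }
      }
    }
    fitted[idx] <- fv
  }
  profile$fitted <- fitted
  profile
}

#' Genome-wide signal threshold
#'
#' Default rule: `median(fitted) + 3 * sd(fitted)`. Alternatively an
#' empirical quantile of the fitted values.
#'
#' @param fitted Numeric vector of fitted values (an [ed_profile()]'s
#'   `fitted` column); at least 30 values recommended.
#' @param quantile If non-`NULL`, use `quantile(fitted, quantile)` instead of
#'   the median + 3 SD rule.
#' @return The threshold scalar.
#' @export
call_threshold <- function(fitted, quantile = NULL) {
  fitted <- fitted[!is.na(fitted)]
  if (length(fitted) < 30L)
    warning("fewer than 30 fitted values; threshold is unstable")
  if (!is.null(quantile))
    return(unname(stats::quantile(fitted, quantile)))
  stats::median(fitted) + 3 * stats::sd(fitted)
}

#' Call candidate intervals from a fitted profile
#'
#' Maximal runs of at least `min_sites` consecutive sites with
#' `fitted > threshold` (strict). Runs on the same chromosome separated by
#' fewer than `gap_sites` below-threshold sites are merged first. The
#' interval spans the first to the last site of the run.
#'
#' @param profile A fitted [ed_profile()].
#' @param threshold Signal threshold (see [call_threshold()]).
#' @param min_sites Minimum run length in sites (default 10).
#' @param gap_sites Merge runs separated by fewer than this many
#'   below-threshold sites (default 1 = never merge).
#' @return A `candidate_intervals` data frame: `chrom`, `start`, `end`,
#'   `length_bp`, `length_mb`, `n_sites`, `peak_pos`, `peak_fitted`, ordered
#'   by decreasing `peak_fitted`.
#' @export
call_intervals <- function(profile, threshold, min_sites = 10L,
                           gap_sites = 1L) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch)
    above <- profile$fitted[idx] > threshold
    above[is.na(above)] <- FALSE
    r <- rle(above)
    # merge short below-threshold gaps between above-threshold runs
    if (length(r$lengths) > 2L) {
      inner <- 2:(length(r$lengths) - 1L)
      gap <- !r$values[inner] & r$lengths[inner] < gap_sites &
        r$values[inner - 1L] & r$values[inner + 1L]
      r$values[inner][gap] <- TRUE
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_sites)
    for (k in runs) {
      sites <- idx[starts[k]:ends[k]]
      pk <- sites[which.max(profile$fitted[sites])]
      s <- profile$pos[sites[1]]; e <- profile$pos[sites[length(sites)]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        length_bp = e - s + 1L, length_mb = (e - s + 1L) / 1e6,
        n_sites = length(sites),
        peak_pos = profile$pos[pk], peak_fitted = profile$fitted[pk])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               length_bp = integer(0), length_mb = numeric(0),
               n_sites = integer(0), peak_pos = integer(0),
               peak_fitted = numeric(0))
  res <- res[order(-res$peak_fitted), , drop = FALSE]
  row.names(res) <- NULL
  class(res) <- c("candidate_intervals", "data.frame")
  res
}

#' Plot an ED profile
#'
#' Base-graphics Manhattan-style plot of the powered ED values with the
#' fitted curve and an optional threshold line.
#'
#' @param x A fitted [ed_profile()].
#' @param threshold Optional threshold to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ed_profile <- function(x, threshold = NULL, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(x$pos[x$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  gx <- x$pos + offs[x$chrom]
  graphics::plot(gx, x$ed2, pch = 16, cex = 0.3,
                 col = c("grey60", "grey30")[match(x$chrom, chroms) %% 2 + 1],
                 xlab = "genome position (bp, concatenated)",
                 ylab = paste0("ED^", attr(x, "power")), ...)
  if (any(!is.na(x$fitted)))
    graphics::lines(gx[order(gx)], x$fitted[order(gx)], col = "red", lwd = 1.5)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "blue")
  invisible(x)
}
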