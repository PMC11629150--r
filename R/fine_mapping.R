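#' Read a marker map
#'
#' @param path TSV with columns `marker`, `chrom`, `pos` (1-based bp,
#'   strictly increasing within the chromosome).
#' @return Data frame `marker`, `chrom`, `pos`.
#' @export
read_marker_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(map)[1:3] <- c("marker", "chrom", "pos")
  validate_marker_map(map)
  map
}

validate_marker_map <- function(map) {
  if (nrow(map) < 2L) stop("marker map needs at least 2 markers")
  if (length(unique(map$chrom)) != 1L)
    stop("fine-mapping marker map must be on one chromosome")
  if (any(diff(map$pos) <= 0)) stop("marker positions must strictly increase")
  invisible(map)
}

#' Read a marker genotype table
#'
#' @param path TSV: first column individual ids, remaining columns one per
#'   marker, values `A` (maternal homozygote), `H` (heterozygote), `B`
#'   (paternal homozygote) or `-`/empty for missing.
#' @return Character matrix individuals x markers with `NA` for missing.
#' @export
read_marker_genotypes <- function(path) {
  g <- utils::read.delim(path, row.names = 1L, stringsAsFactors = FALSE,
                         check.names = FALSE)
  m <- as.matrix(g)
  m[m %in% c("-", ".", "")] <- NA_character_
  bad <- !is.na(m) & !(m %in% c("A", "H", "B"))
  if (any(bad)) stop("invalid genotype code: ", m[bad][1])
  m
}

#' Find recombinant individuals and their breakpoints
#'
#' An individual is a recombinant iff its genotype class changes between
#' consecutive non-missing markers; each change yields a breakpoint interval
#' between the two flanking marker positions. Individuals with two or more
#' breakpoints are flagged as double recombinants (likely genotyping error).
#'
#' @param geno Character matrix individuals x markers (`A`/`H`/`B`/`NA`),
#'   columns ordered as in `map`.
#' @param map Marker map data frame (`marker`, `chrom`, `pos`).
#' @return Data frame `individual`, `left_marker`, `right_marker`,
#'   `left_pos`, `right_pos`, `from`, `to`, `n_breakpoints` (per individual);
#'   attribute `skipped` counts all-missing individuals.
#' @export
find_recombinants <- function(geno, map) {
  validate_marker_map(map)
  stopifnot(ncol(geno) == nrow(map))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("F2_%04d", seq_len(nrow(geno)))
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    obs <- which(!is.na(g))
    if (!length(obs)) { skipped <- skipped + 1L; next }
    if (length(obs) < 2L) next
    chg <- which(g[obs[-length(obs)]] != g[obs[-1]])
    if (!length(chg)) next
    for (k in chg) {
      l <- obs[k]; r <- obs[k + 1L]
      out[[length(out) + 1L]] <- data.frame(
        individual = ids[i],
        left_marker = map$marker[l], right_marker = map$marker[r],
        left_pos = map$pos[l], right_pos = map$pos[r],
        from = unname(g[l]), to = unname(g[r]),
        n_breakpoints = length(chg))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(0), left_marker = character(0),
               right_marker = character(0), left_pos = integer(0),
               right_pos = integer(0), from = character(0), to = character(0),
               n_breakpoints = integer(0))
  attr(res, "skipped") <- skipped
  res
}

## implied genotype of each candidate segment for one individual:
## segments are markers (odd index 2j-1) and inter-marker gaps (even 2j).
## A gap's genotype is known only when the nearest non-missing markers on
## both sides agree; a missing marker inherits the same rule.
.segment_genotypes <- function(g, m) {
  seg <- rep(NA_character_, 2L * m - 1L)
  obs <- which(!is.na(g))
  if (!length(obs)) return(seg)
  seg[2L * obs - 1L] <- g[obs]
  for (s in which(is.na(seg))) {
    j <- (s + 1L) %/% 2L   # marker index (odd s) or left marker of gap (even s)
    ol <- if (s %% 2L == 1L) obs[obs < j] else obs[obs <= j]
    or <- obs[obs > j]
    if (length(ol) && length(or) && g[max(ol)] == g[min(or)])
      seg[s] <- g[max(ol)]
  }
  seg
}

#' Narrow a QTL interval with recombinant F2 individuals
#'
#' Under a single-locus model with the maternal allele dominant (oval fruit),
#' every round individual must be paternal-homozygous (`B`) at the causal
#' position, and every oval individual must not be `B` there. Each candidate
#' region (a marker or an inter-marker gap) is excluded when any individual's
#' implied genotype there contradicts its phenotype; dominant (oval)
#' individuals contribute exclusion evidence only where they are `B`. The
#' remaining consistent zone is reported as the physical interval spanned by
#' its flanking markers.
#'
#' @param geno Character matrix individuals x markers (`A`/`H`/`B`/`NA`).
#' @param phenotype Character vector per individual, `"oval"`/`"round"`.
#' @param map Marker map data frame (`marker`, `chrom`, `pos`).
#' @param include_double Keep double recombinants (default `FALSE`: flagged
#'   and excluded as likely genotyping errors).
#' @return An object of class `finemap_result`: `left_marker`,
#'   `right_marker`, `start`, `end`, `length_bp` (end - start + 1),
#'   `length_kb` (1 dp), `recombinants_used` (data frame of ids and sides),
#'   `excluded_double` (ids), `consistent_segments`.
#' @export
narrow_interval <- function(geno, phenotype, map, include_double = FALSE) {
  validate_marker_map(map)
  m <- nrow(map)
  stopifnot(ncol(geno) == m, nrow(geno) == length(phenotype))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("F2_%04d", seq_len(nrow(geno)))
  rec <- find_recombinants(geno, map)
  dbl <- unique(rec$individual[rec$n_breakpoints >= 2L])
  use <- rep(TRUE, nrow(geno))
  if (!include_double) use[ids %in% dbl] <- FALSE

  n_seg <- 2L * m - 1L
  consistent <- rep(TRUE, n_seg)
  conflict_by <- vector("list", n_seg)
  for (i in which(use)) {
    seg <- .segment_genotypes(geno[i, ], m)
    bad <- if (phenotype[i] == "round") !is.na(seg) & seg != "B"
           else !is.na(seg) & seg == "B"
    consistent[bad] <- FALSE
    for (s in which(bad)) conflict_by[[s]] <- c(conflict_by[[s]], ids[i])
  }
  if (!any(consistent)) {
    worst <- which.min(lengths(conflict_by))
    stop("no region is consistent with all records under the ",
         "dominant-oval model; e.g. individuals ",
         paste(utils::head(conflict_by[[worst]], 5), collapse = ", "),
         " conflict everywhere")
  }
  zone <- range(which(consistent))
  # boundary markers: the marker at the zone edge when the edge is a marker,
  # otherwise the marker just outside the open gap at the edge
  left_m <- (zone[1] + 1L) %/% 2L
  right_m <- min(m, zone[2] %/% 2L + 1L)
  # recombinants whose breakpoint straddles a reported boundary
  side <- character(0); rid <- character(0)
  if (nrow(rec)) {
    lb <- map$pos[left_m]; rb <- map$pos[right_m]
    at_left <- rec$left_pos <= lb & rec$right_pos >= lb & rec$right_pos <= rb
    at_right <- rec$right_pos >= rb & rec$left_pos <= rb & rec$left_pos >= lb
    keep <- (at_left | at_right) & (include_double | !(rec$individual %in% dbl))
    rid <- rec$individual[keep]
    side <- ifelse(at_left[keep], "left", "right")
  }
  start <- map$pos[left_m]; end <- map$pos[right_m]
  structure(list(
    chrom = map$chrom[1],
    left_marker = map$marker[left_m], right_marker = map$marker[right_m],
    start = start, end = end,
    length_bp = end - start + 1L,
    length_kb = round((end - start + 1L) / 1000, 1),
    recombinants_used = data.frame(individual = rid, side = side),
    excluded_double = dbl,
    consistent_segments = which(consistent)),
    class = "finemap_result")
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("fine-mapped interval %s:%d-%d (%s kb) between %s and %s\n",
              x$chrom, x$start, x$end, format(x$length_kb),
              x$left_marker, x$right_marker))
  cat(" informative recombinants:", nrow(x$recombinants_used),
      "| double recombinants excluded:", length(x$excluded_double), "\n")
  invisible(x)
}

#' Genes overlapping an interval
#'
#' @param genes A `gene_model_set` from [read_gff()].
#' @param chrom,start,end The interval (1-based inclusive).
#' @param mode `"any"` (default) keeps genes with any overlap; `"within"`
#'   keeps only genes fully contained.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `coding_complete`, sorted by start.
#' @export
genes_in_interval <- function(genes, chrom, start, end, mode = c("any",
                                                                 "within")) {
  mode <- match.arg(mode)
  hit <- Filter(function(g) {
    g$chrom == chrom && if (mode == "any") g$end >= start && g$start <= end
    else g$start >= start && g$end <= end
  }, genes)
  out <- data.frame(
    gene_id = vapply(hit, `[[`, character(1), "gene_id"),
    chrom = vapply(hit, `[[`, character(1), "chrom"),
    start = vapply(hit, `[[`, numeric(1), "start"),
    end = vapply(hit, `[[`, numeric(1), "end"),
    strand = vapply(hit, `[[`, character(1), "strand"),
    coding_complete = vapply(hit, `[[`, logical(1), "coding_complete"))
  out <- out[order(out$start), , drop = FALSE]
  row.names(out) <- NULL
  out
}

.match_positions <- function(seq, pattern, fixed = TRUE) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = fixed)
  BiocGenerics::start(m)
}

#' Scan a promoter for W-box motifs
#'
#' Reports 1-based start positions of the exact W-box literal (`TTGACC` by
#' default), the degenerate consensus `[CT]TGAC[TC]` (IUPAC `YTGACY`), and
#' the conserved core (`TGAC`), on the forward sequence and on its reverse
#' complement (positions in reverse-complement coordinates).
#'
#' @param seq Promoter sequence over A/C/G/T/N.
#' @param motif Exact motif literal (default `"TTGACC"`).
#' @param core Core tetramer (default `"TGAC"`).
#' @return A `wbox_scan` list of position vectors: `motif_fwd`, `motif_rev`,
#'   `consensus_fwd`, `consensus_rev`, `core_fwd`, `core_rev`.
#' @export
scan_wbox <- function(seq, motif = "TTGACC", core = "TGAC") {
  seq <- toupper(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  structure(list(
    motif_fwd = .match_positions(seq, motif),
    motif_rev = .match_positions(rc, motif),
    consensus_fwd = .match_positions(seq, "YTGACY", fixed = FALSE),
    consensus_rev = .match_positions(rc, "YTGACY", fixed = FALSE),
    core_fwd = .match_positions(seq, core),
    core_rev = .match_positions(rc, core)),
    class = "wbox_scan")
}

#' @export
print.wbox_scan <- function(x, ...) {
  cat("W-box scan: motif", length(x$motif_fwd), "fwd /",
      length(x$motif_rev), "rev; consensus", length(x$consensus_fwd),
      "fwd /", length(x$consensus_rev), "rev; core",
      length(x$core_fwd), "fwd /", length(x$core_rev), "rev\n")
  invisible(x)
}

#' Variants between two alleles of a locus
#'
#' Globally aligns the two sequences (unit match/mismatch scores, affine
#' gaps) and reports every substitution and every contiguous indel with its
#' position and length.
#'
#' @param seq1,seq2 The two allele sequences (e.g. the parents' promoter).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 4 and 0.5,
#'   favouring one long gap over scattered short ones).
#' @return Data frame `type` (`snp`/`insertion`/`deletion`, relative to
#'   `seq1`), `pos1`, `pos2` (1-based starts in each sequence), `ref`, `alt`,
#'   `length`.
#' @export
diff_alleles <- function(seq1, seq2, gap_opening = 4, gap_extension = 0.5) {
  if (!nchar(seq1) || !nchar(seq2)) stop("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq1)), Biostrings::DNAString(toupper(seq2)),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  p1 <- cumsum(a1 != "-"); p2 <- cumsum(a2 != "-")
  state <- ifelse(a1 == "-", "insertion",
                  ifelse(a2 == "-", "deletion",
                         ifelse(a1 != a2, "snp", "match")))
  out <- list()
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "match") next
    i <- starts[k]:ends[k]
    if (r$values[k] == "snp") {
      for (j in i)
        out[[length(out) + 1L]] <- data.frame(
          type = "snp", pos1 = p1[j], pos2 = p2[j],
          ref = a1[j], alt = a2[j], length = 1L)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        type = r$values[k],
        pos1 = if (starts[k] > 1L) p1[starts[k] - 1L] + 1L else 1L,
        pos2 = if (starts[k] > 1L) p2[starts[k] - 1L] + 1L else 1L,
        ref = paste(a1[i][a1[i] != "-"], collapse = ""),
        alt = paste(a2[i][a2[i] != "-"], collapse = ""),
        length = r$lengths[k])
    }
  }
  if (!length(out))
    return(data.frame(type = character(0), pos1 = integer(0),
                      pos2 = integer(0), ref = character(0),
                      alt = character(0), length = integer(0)))
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
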