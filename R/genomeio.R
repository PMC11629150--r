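#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file, uppercases the sequences (soft-masking
#' is discarded) and normalises any IUPAC ambiguity code other than A/C/G/T
#' to N, so downstream code only ever sees the five-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet]; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L)
    stop("FASTA format error at line 1: empty file")
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">"))
    stop("FASTA format error at line 1: expected '>' header, got: ",
         substr(first, 1, 30))
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("FASTA format error: duplicated record name '",
         nm[duplicated(nm)][1], "'")
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGTN]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Construct a variant set
#'
#' The in-memory genotype model used throughout the package: a collection of
#' biallelic SNPs with per-sample diploid genotypes coded as the number of
#' alternate alleles (0, 1, 2; `NA` = missing) and optional per-allele read
#' depths.
#'
#' @param chrom,pos,ref,alt Per-site vectors; `pos` is 1-based.
#' @param gt Integer matrix, sites x samples, values 0/1/2/NA.
#' @param samples Sample names (defaults to `colnames(gt)`).
#' @param ad_ref,ad_alt Optional integer matrices of ref/alt read depths,
#'   same shape as `gt`.
#' @param skip_report Named integer vector of records excluded during parsing.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(chrom, pos, ref, alt, gt,
                        samples = colnames(gt),
                        ad_ref = NULL, ad_alt = NULL,
                        skip_report = integer(0)) {
  n <- length(pos)
  if (is.null(samples)) samples <- colnames(gt)
  gt <- matrix(as.integer(gt), nrow = n)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L))
    stop("variant_set holds single-base biallelic SNPs only")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("alleles must be A/C/G/T; offending site index ",
                     which(bad)[1])
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(gt)))
  dimnames(gt) <- list(NULL, samples)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         gt = gt, samples = samples,
         ad_ref = ad_ref, ad_alt = ad_alt,
         skip_report = skip_report),
    class = "variant_set")
}

#' Number of sites in a variant set
#' @param vs A `variant_set`.
#' @return Integer site count.
#' @export
n_sites <- function(vs) length(vs$pos)

#' Subset a variant set by site index
#' @param vs A `variant_set`.
#' @param idx Integer or logical site index.
#' @return A `variant_set` with the selected sites.
#' @export
subset_sites <- function(vs, idx) {
  variant_set(vs$chrom[idx], vs$pos[idx], vs$ref[idx], vs$alt[idx],
              vs$gt[idx, , drop = FALSE], samples = vs$samples,
              ad_ref = if (!is.null(vs$ad_ref)) vs$ad_ref[idx, , drop = FALSE],
              ad_alt = if (!is.null(vs$ad_alt)) vs$ad_alt[idx, , drop = FALSE],
              skip_report = vs$skip_report)
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", n_sites(x), "biallelic SNPs,",
      length(x$samples), "samples\n")
  if (length(x$skip_report))
    cat("  skipped on input:",
        paste(names(x$skip_report), x$skip_report, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

## genotype string -> alt-allele dosage; half-calls and any '.' are missing
.parse_gt <- function(g) {
  g <- sub(":.*$", "", g)
  out <- rep(NA_integer_, length(g))
  out[g %in% c("0/0", "0|0")] <- 0L
  out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[g %in% c("1/1", "1|1")] <- 2L
  out
}

#' Read biallelic SNPs from a VCF
#'
#' Parses a VCF v4.x file with \pkg{vcfR} and returns the biallelic SNPs as a
#' [variant_set]. Multiallelic records and indels are excluded and counted in
#' the skip report; `GT` is required, `AD` is used when present. Missing
#' genotypes (`./.`, `.|.`, `.` and half-calls) map to `NA`.
#'
#' @param path Path to a (plain-text or bgzipped) VCF.
#' @return A [variant_set]; `$skip_report` tallies excluded records by reason
#'   (`indel`, `multiallelic`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  hdr <- readLines(path, n = 1000L)
  if (!any(startsWith(hdr, "#CHROM")))
    stop("VCF format error: missing #CHROM header line")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skip <- c(indel = sum(!multi & !snp), multiallelic = sum(multi))
  fmt <- v@gt[, "FORMAT"]
  no_gt <- !vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))
  if (any(no_gt & snp))
    stop("VCF record without GT field: ", fix[which(no_gt & snp)[1], "CHROM"],
         ":", fix[which(no_gt & snp)[1], "POS"])
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(.parse_gt(gt_chr), nrow = nrow(gt_chr),
               dimnames = dimnames(gt_chr))
  ad_ref <- ad_alt <- NULL
  if (any(grepl("(^|:)AD(:|$)", fmt))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ad_ref <- matrix(suppressWarnings(as.integer(sub(",.*$", "", ad))),
                     nrow = nrow(ad))
    ad_alt <- matrix(suppressWarnings(
      as.integer(sub("^[^,]*,([^,]*).*$", "\\1", ad))), nrow = nrow(ad))
  }
  variant_set(fix[snp, "CHROM"], as.integer(fix[snp, "POS"]),
              ref[snp], alt[snp],
              gt[snp, , drop = FALSE],
              samples = colnames(gt_chr),
              ad_ref = if (!is.null(ad_ref)) ad_ref[snp, , drop = FALSE],
              ad_alt = if (!is.null(ad_alt)) ad_alt[snp, , drop = FALSE],
              skip_report = skip)
}

#' Write a variant set as plain-text VCF v4.2
#'
#' @param vs A [variant_set].
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vs, path, contigs = NULL) {
  has_ad <- !is.null(vs$ad_ref)
  meta <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_ad)
    meta <- c(meta, paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
                           'Description="Allelic depths">'))
  if (!is.null(contigs))
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(contigs), as.integer(contigs)))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$gt + 1L], nrow = n_sites(vs))
  gt_str[is.na(gt_str)] <- "./."
  fmt <- "GT"
  if (has_ad) {
    ad_str <- matrix(paste0(vs$ad_ref, ",", vs$ad_alt), nrow = n_sites(vs))
    ad_str[is.na(vs$ad_ref) | is.na(vs$ad_alt)] <- "."
    gt_str <- matrix(paste(gt_str, ad_str, sep = ":"), nrow = n_sites(vs))
    fmt <- "GT:AD"
  }
  body <- paste(vs$chrom, vs$pos, ".", vs$ref, vs$alt, ".", "PASS", ".",
                fmt, apply(gt_str, 1L, paste, collapse = "\t"),
                sep = "\t")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", vs$samples), collapse = "\t")
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds one gene model per gene, taking the CDS chain of the longest
#' (total CDS length) mRNA. Coordinates stay 1-based inclusive; CDS segments
#' are stored ascending regardless of strand. Genes whose total CDS length is
#' not a multiple of 3 are flagged as not coding-complete. CDS features
#' without a resolvable parent are skipped with a warning.
#'
#' @param path Path to a GFF3 file with gene/mRNA/CDS features.
#' @return An object of class `gene_model_set`: a list of gene records, each
#'   with `gene_id`, `chrom`, `strand`, `start`, `end`, `cds` (data frame of
#'   start/end) and `coding_complete`.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent_of <- function(i) {
    p <- gr$Parent[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }
  genes <- which(type == "gene")
  mrnas <- which(type %in% c("mRNA", "transcript"))
  cdss <- which(type == "CDS")
  mrna_parent <- vapply(mrnas, parent_of, character(1))
  cds_parent <- vapply(cdss, parent_of, character(1))
  orphan <- is.na(cds_parent) | !(cds_parent %in% ids[mrnas])
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a parent mRNA skipped")
    cdss <- cdss[!orphan]; cds_parent <- cds_parent[!orphan]
  }
  out <- lapply(genes, function(gi) {
    gid <- ids[gi]
    my_mrnas <- mrnas[!is.na(mrna_parent) & mrna_parent == gid]
    cds <- data.frame(start = integer(0), end = integer(0))
    if (length(my_mrnas)) {
      chains <- lapply(my_mrnas, function(mi) {
        ci <- cdss[cds_parent == ids[mi]]
        data.frame(start = BiocGenerics::start(gr)[ci],
                   end = BiocGenerics::end(gr)[ci])
      })
      lens <- vapply(chains, function(d) sum(d$end - d$start + 1L), numeric(1))
      cds <- chains[[which.max(lens)]]
      cds <- cds[order(cds$start), , drop = FALSE]
      row.names(cds) <- NULL
    }
    total <- sum(cds$end - cds$start + 1L)
    list(gene_id = gid,
         chrom = as.character(GenomicRanges::seqnames(gr))[gi],
         strand = as.character(BiocGenerics::strand(gr))[gi],
         start = BiocGenerics::start(gr)[gi],
         end = BiocGenerics::end(gr)[gi],
         cds = cds,
         coding_complete = total > 0L && total %% 3L == 0L)
  })
  names(out) <- ids[genes]
  structure(out, class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", length(x), "genes on",
      length(unique(vapply(x, `[[`, character(1), "chrom"))),
      "chromosome(s)\n")
  invisible(x)
}

#' Write intervals as BED
#'
#' Intervals are held 1-based inclusive inside the package; BED output is
#' 0-based half-open, so `start - 1` is written.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  lines <- "#chrom\tstart\tend"
  if (nrow(intervals)) {
    if (any(intervals$end < intervals$start))
      stop("interval end < start at row ",
           which(intervals$end < intervals$start)[1])
    body <- paste(intervals$chrom,
                  format(intervals$start - 1L, scientific = FALSE,
                         trim = TRUE),
                  format(intervals$end, scientific = FALSE, trim = TRUE),
                  sep = "\t")
    if (!is.null(intervals$name))
      body <- paste(body, intervals$name, sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
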