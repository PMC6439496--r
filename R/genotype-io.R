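# VCF / FASTA / TSV ingestion and emission. Reading goes through vcfR and
# ape; writing is plain-text VCF v4.2 so output is byte-stable and diffable.

#' Read a VCF into a genotype matrix
#'
#' Biallelic SNP rows are parsed to ALT-allele dosages; missing GT becomes a
#' missing dosage; GQ is carried when present. Indel and multiallelic rows
#' are retained but flagged (`is_biallelic_snp = FALSE`, dosage missing) so
#' [filter_biallelic_snps()] can drop them. Flanking sequences stored in the
#' INFO keys `FLL`/`FLR` (as written by [write_vcf()]) are recovered.
#'
#' @param path VCF v4.x file, optionally gzipped.
#' @param meta optional sample metadata data.frame or TSV path with columns
#'   `sample_id`, `region`, `source`, `sex`; samples absent from it get
#'   `NA` region, `"tissue"` source, `"unknown"` sex.
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path, meta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_site <- nrow(fix)
  ref <- fix$REF
  alt <- fix$ALT
  is_snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  info <- fix$INFO
  fl <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[ACGTN]+"), info))
    out <- rep(NA_character_, n_site)
    hit <- grepl(paste0(key, "=[ACGTN]+"), info)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  # dosage = number of '1' alleles; any '.' in the call -> missing
  gt_clean <- gsub("\\|", "/", gt)
  dose <- matrix(NA_integer_, nrow = length(ids), ncol = n_site,
                 dimnames = list(ids, NULL))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (j in seq_len(n_site)) {
    calls <- gt_clean[j, ]
    d <- unname(known[calls])
    dose[, j] <- d
  }
  dose[, !is_snp] <- NA_integer_
  qual <- NULL
  if (n_site > 0 && any(grepl("GQ", v@gt[, "FORMAT"], fixed = TRUE))) {
    gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    qual <- t(gq)
  }
  sites <- data.frame(
    scaffold = fix$CHROM,
    position = as.integer(fix$POS),
    ref = ref, alt = alt,
    is_biallelic_snp = is_snp,
    flank_left = fl("FLL"), flank_right = fl("FLR"),
    stringsAsFactors = FALSE
  )
  samples <- resolve_metadata(ids, meta)
  genotype_matrix(dose, sites, samples, quality = qual)
}

resolve_metadata <- function(ids, meta) {
  if (is.null(meta)) {
    return(data.frame(sample_id = ids, region = NA_character_,
                      source = "tissue", sex = "unknown",
                      stringsAsFactors = FALSE))
  }
  if (is.character(meta)) meta <- read_metadata(meta)
  m <- meta[match(ids, meta$sample_id), ]
  data.frame(sample_id = ids,
             region = m$region,
             source = ifelse(is.na(m$source), "tissue", m$source),
             sex = ifelse(is.na(m$sex), "unknown", m$sex),
             stringsAsFactors = FALSE)
}

#' Read / write the sample metadata TSV
#'
#' Columns: `sample_id`, `region`, `source`, `sex`.
#' @param path TSV file (gzip accepted on read)
#' @export
read_metadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname read_metadata
#' @param samples sample metadata data.frame
#' @export
write_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT and (when present) GQ FORMAT fields; sites are sorted by
#' `(scaffold, position)`. Flanking sequences, when attached to the site
#' table, are stored in INFO as `FLL`/`FLR` so a round-trip preserves
#' panel-design context. Output is uncompressed text and byte-stable for a
#' given matrix.
#'
#' @param g a [genotype_matrix()]
#' @param path output file path
#' @export
write_vcf <- function(g, path) {
  s <- g$sites
  key <- paste(s$scaffold, s$position)
  if (anyDuplicated(key)) stop("duplicate (scaffold, position) pairs")
  ord <- order(s$scaffold, s$position)
  g <- subset_genotypes(g, sites = ord)
  s <- g$sites
  has_gq <- !is.null(g$quality)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=goshawkpop",
    "##INFO=<ID=FLL,Number=1,Type=String,Description=\"Left flanking sequence\">",
    "##INFO=<ID=FLR,Number=1,Type=String,Description=\"Right flanking sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_gq)
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  lines <- hdr
  if (n_sites(g) > 0) {
    gt_str <- matrix("./.", nrow = n_samples(g), ncol = n_sites(g))
    gt_str[which(g$dosage == 0L)] <- "0/0"
    gt_str[which(g$dosage == 1L)] <- "0/1"
    gt_str[which(g$dosage == 2L)] <- "1/1"
    if (has_gq) {
      q <- ifelse(is.na(g$quality) | gt_str == "./.", ".",
                  format(g$quality, trim = TRUE, scientific = FALSE))
      gt_str <- paste(gt_str, q, sep = ":")
      dim(gt_str) <- dim(g$dosage)
    }
    info <- rep(".", n_sites(g))
    if (!is.null(s$flank_left)) {
      have <- !is.na(s$flank_left) & !is.na(s$flank_right)
      info[have] <- paste0("FLL=", s$flank_left[have],
                           ";FLR=", s$flank_right[have])
    }
    fmt <- if (has_gq) "GT:GQ" else "GT"
    body <- vapply(seq_len(n_sites(g)), function(j) {
      paste(c(s$scaffold[j], s$position[j], ".", s$ref[j], s$alt[j], ".",
              "PASS", info[j], fmt, gt_str[, j]), collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an aligned FASTA file as a haplotype alignment
#'
#' Sequences are uppercased and checked for equal length.
#'
#' @param path FASTA file (gzip accepted)
#' @param regions optional named character vector mapping sample id to
#'   region code
#' @return a [haplotype_alignment()]
#' @export
read_fasta_alignment <- function(path, regions = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  haplotype_alignment(names(dna), unname(seqs), regions = regions)
}

#' Construct a haplotype alignment
#'
#' Equal-length aligned sequences over `{A,C,G,T,N,-}`, keyed by sample id,
#' with optional region labels.
#'
#' @param sample_ids character vector of sequence names
#' @param sequences character vector of aligned sequences (one string each)
#' @param regions optional region labels, recycled against `sample_ids` or a
#'   named vector keyed by sample id
#' @export
haplotype_alignment <- function(sample_ids, sequences, regions = NULL) {
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(lens) == 0 || lens[1] == 0) stop("empty alignment")
  if (length(unique(lens)) != 1)
    stop("alignment error: sequences differ in length (",
         paste(unique(lens), collapse = ", "), ")")
  if (!is.null(regions) && !is.null(names(regions)))
    regions <- unname(regions[sample_ids])
  structure(list(sample_ids = sample_ids, sequences = sequences,
                 length = lens[1],
                 regions = if (is.null(regions)) rep(NA_character_,
                                                     length(sample_ids))
                           else regions),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment:", length(x$sample_ids), "sequences of",
      x$length, "bp\n")
  invisible(x)
}

#' Write a haplotype alignment as FASTA
#' @param aln a [haplotype_alignment()]
#' @param path output file
#' @export
write_fasta_alignment <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$sample_ids), aln$sequences)),
             path)
  invisible(path)
}

#' Convert a haplotype alignment to ape's DNAbin
#' @param aln a [haplotype_alignment()]
#' @export
as_DNAbin <- function(aln) {
  m <- do.call(rbind, strsplit(tolower(aln$sequences), ""))
  rownames(m) <- aln$sample_ids
  ape::as.DNAbin(m)
}

#' Length of a half-open genomic interval
#'
#' All internal interval logic is half-open `[start, end)` on 1-based
#' coordinates, so the control-region segment 1,169-1,747 spans 578 bp.
#' @param start,end interval bounds
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end < start")
  end - start
}
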