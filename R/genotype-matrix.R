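#' Region codes recognised in sample metadata
#'
#' Sampling-region vocabulary used throughout the pipeline: the island
#' population (HG, Haida Gwaii), seven continental North American regions,
#' Europe and an outgroup bucket.
#' @export
REGION_CODES <- c("HG", "AA", "AK", "BC", "BCc", "East", "VI", "WA",
                  "Eur", "outgroup")

#' Tissue sources recognised in sample metadata
#' @export
SOURCE_CODES <- c("tissue", "feather", "blood", "toepad")

#' Construct a genotype matrix
#'
#' The central container of the pipeline: a samples-by-sites matrix of diploid
#' dosages (count of the VCF ALT allele, `NA` = missing call) with an
#' optional per-genotype quality matrix of identical shape, plus per-site and
#' per-sample metadata.
#'
#' @param dosage integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `scaffold`, `position` (1-based bp),
#'   `ref`, `alt`, and logical `is_biallelic_snp`; optional `flank_left`,
#'   `flank_right` sequences used for marker-panel design.
#' @param samples data.frame with columns `sample_id`, `region`, `source`,
#'   `sex` (`"M"`, `"F"` or `"unknown"`).
#' @param quality numeric matrix of per-genotype qualities (same shape as
#'   `dosage`) or `NULL` when no qualities are available.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, samples, quality = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    storage.mode(quality) <- "double"
  }
  g <- structure(
    list(dosage = dosage, quality = quality,
         sites = as.data.frame(sites, stringsAsFactors = FALSE),
         samples = as.data.frame(samples, stringsAsFactors = FALSE)),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (nrow(d) != nrow(g$samples))
    stop("dosage rows (", nrow(d), ") != sample count (", nrow(g$samples), ")")
  if (ncol(d) != nrow(g$sites))
    stop("dosage columns (", ncol(d), ") != site count (", nrow(g$sites), ")")
  if (!is.null(g$quality) && !identical(dim(g$quality), dim(d)))
    stop("quality and dosage dimensions differ")
  bad <- d[!is.na(d) & !(d %in% 0:2)]
  if (length(bad)) stop("non-missing dosages must be in {0,1,2}")
  req_site <- c("scaffold", "position", "ref", "alt")
  if (!all(req_site %in% names(g$sites)))
    stop("sites must have columns: ", paste(req_site, collapse = ", "))
  if (any(g$sites$position < 1)) stop("positions are 1-based; must be >= 1")
  req_samp <- c("sample_id", "region", "source", "sex")
  if (!all(req_samp %in% names(g$samples)))
    stop("samples must have columns: ", paste(req_samp, collapse = ", "))
  reg <- g$samples$region
  unknown <- setdiff(unique(reg[!is.na(reg)]), REGION_CODES)
  if (length(unknown))
    stop("unknown region code(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(g$samples$sample_id))
    stop("duplicate sample ids")
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "sites;", if (is.null(x$quality)) "no" else "with", "GQ;",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of samples / sites in a genotype matrix
#' @param g a `genotype_matrix`
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_sites <- function(g) ncol(g$dosage)

#' Subset a genotype matrix by site and/or sample index
#'
#' @param g a `genotype_matrix`
#' @param sites,samples logical or integer index vectors (default: keep all)
#' @return the subsetted `genotype_matrix`
#' @export
subset_genotypes <- function(g, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(g)) else sites
  sa <- if (is.null(samples)) seq_len(n_samples(g)) else samples
  genotype_matrix(
    dosage  = g$dosage[sa, si, drop = FALSE],
    quality = if (is.null(g$quality)) NULL else g$quality[sa, si, drop = FALSE],
    sites   = g$sites[si, , drop = FALSE],
    samples = g$samples[sa, , drop = FALSE]
  )
}

#' Row indices of the samples belonging to a group
#'
#' A group may be given as region codes (matched against `samples$region`)
#' or as explicit sample ids; ids take precedence when both match.
#' @param g a `genotype_matrix`
#' @param group character vector of region codes or sample ids
#' @return integer vector of row indices
#' @export
group_indices <- function(g, group) {
  ids <- g$samples$sample_id
  if (all(group %in% ids)) return(match(group, ids))
  if (all(group %in% REGION_CODES)) return(which(g$samples$region %in% group))
  bad <- setdiff(group, c(ids, REGION_CODES))
  stop("group members neither sample ids nor region codes: ",
       paste(utils::head(bad, 5), collapse = ", "))
}

#' Per-site ALT allele frequencies for a set of samples
#'
#' @param g a `genotype_matrix`
#' @param idx sample row indices (default: all samples)
#' @return list with `p` (ALT frequency, `NaN` where no calls), `n`
#'   (non-missing diploid individuals per site), and `nchr` (= 2n).
#' @export
allele_freqs <- function(g, idx = seq_len(n_samples(g))) {
  d <- g$dosage[idx, , drop = FALSE]
  n <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  list(p = alt / (2 * n), n = n, nchr = 2L * n)
}

#' Per-site minor allele frequency over a set of samples
#' @inheritParams allele_freqs
#' @return numeric vector of MAF (`NaN` where no calls)
#' @export
minor_allele_freq <- function(g, idx = seq_len(n_samples(g))) {
  p <- allele_freqs(g, idx)$p
  pmin(p, 1 - p)
}
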