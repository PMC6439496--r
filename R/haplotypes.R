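# mtDNA analyses: uncorrected p-distances with pairwise deletion, a
# Neighbor-Joining tree, collapsing of identical sequences into haplotypes
# with per-region frequencies, and a minimum-spanning-tree haplotype
# network over Hamming distances (a deterministic substitute for
# median-joining network inference, which infers unobserved intermediate
# haplotypes and is out of scope).

#' Uncorrected p-distance matrix
#'
#' Per pair: mismatches over validly compared sites, dropping columns where
#' either sequence has N or a gap (pairwise deletion). A pair with zero
#' comparable sites is an error.
#'
#' @param aln a [haplotype_alignment()]
#' @return symmetric matrix with zero diagonal, dimnames = sample ids
#' @export
p_distance_matrix <- function(aln) {
  M <- aln_matrix(aln)
  n <- nrow(M)
  if (n < 2) stop("need >= 2 sequences")
  valid <- matrix(M %in% c("A", "C", "G", "T"), nrow = n)
  D <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok))
      stop("no comparable sites between ", aln$sample_ids[i], " and ",
           aln$sample_ids[j])
    D[i, j] <- D[j, i] <- mean(M[i, ok] != M[j, ok])
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Classic NJ agglomeration (exact on additive matrices); negative branch
#' lengths are clamped to zero with a message. Returns the tree and its
#' newick string.
#'
#' @param D symmetric distance matrix with finite entries (>= 3 taxa)
#' @return list: `tree` (ape `phylo`), `newick`
#' @export
neighbor_joining <- function(D) {
  if (any(!is.finite(D))) stop("undefined distances in the matrix")
  if (nrow(D) < 3) stop("need >= 3 taxa")
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    message("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Trim an alignment to a half-open column interval
#'
#' Columns `[start, end)` (1-based), e.g. the well-covered core of an
#' amplicon before haplotype collapsing.
#' @param aln a [haplotype_alignment()]
#' @param start,end half-open bounds; `end - start` columns are kept
#' @export
trim_alignment <- function(aln, start, end) {
  if (start < 1 || end > aln$length + 1 || end <= start)
    stop("invalid trim interval")
  haplotype_alignment(aln$sample_ids,
                      substr(aln$sequences, start, end - 1),
                      regions = aln$regions)
}

#' Collapse identical sequences into haplotypes
#'
#' Sequences are grouped by exact identity; sequences differing only at an
#' N are NOT merged (N is treated as incompatible, the conservative
#' choice). Haplotypes are labelled H1, H2, ... in order of decreasing
#' frequency (ties by first occurrence), with per-region counts attached.
#'
#' @param aln a [haplotype_alignment()] (trim first if needed)
#' @param regions optional region labels overriding `aln$regions`
#' @return a `haplotype_table`: data.frame `haplotype`, `sequence`, `n`,
#'   one count column per region, and a `members` attribute (list of
#'   sample ids)
#' @export
collapse_haplotypes <- function(aln, regions = NULL) {
  reg <- if (is.null(regions)) aln$regions else regions
  seqs <- aln$sequences
  uniq <- unique(seqs)
  n <- vapply(uniq, function(s) sum(seqs == s), integer(1))
  ord <- order(-n, match(uniq, seqs))
  uniq <- uniq[ord]; n <- n[ord]
  reg_levels <- unique(reg[!is.na(reg)])
  tab <- data.frame(haplotype = paste0("H", seq_along(uniq)),
                    sequence = uniq, n = n, stringsAsFactors = FALSE)
  for (r in reg_levels)
    tab[[r]] <- vapply(uniq, function(s)
      sum(seqs == s & !is.na(reg) & reg == r), integer(1))
  members <- lapply(uniq, function(s) aln$sample_ids[seqs == s])
  rownames(tab) <- NULL
  attr(tab, "members") <- members
  class(tab) <- c("haplotype_table", class(tab))
  tab
}

#' Hamming distance between two equal-length sequences
#' @param a,b sequences (strings)
#' @export
hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  sum(x != y)
}

#' Minimum-spanning-tree haplotype network
#'
#' Prim's algorithm over pairwise Hamming distances between haplotype
#' sequences, with deterministic tie-breaking by haplotype label order.
#' Edge weights are mutational step counts.
#'
#' @param table a `haplotype_table` from [collapse_haplotypes()]
#' @return data.frame edge list: `from`, `to`, `steps`
#' @export
mst_haplotype_network <- function(table) {
  h <- table$haplotype
  k <- length(h)
  if (k < 2) stop("need >= 2 haplotypes")
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    D[i, j] <- D[j, i] <- hamming(table$sequence[i], table$sequence[j])
  in_tree <- c(TRUE, rep(FALSE, k - 1))
  edges <- list()
  while (!all(in_tree)) {
    best <- NULL
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      cand <- c(i, j, D[i, j])
      if (is.null(best) || cand[3] < best[3] ||
          (cand[3] == best[3] &&
           (cand[1] < best[1] || (cand[1] == best[1] && cand[2] < best[2]))))
        best <- cand
    }
    edges[[length(edges) + 1L]] <- data.frame(
      from = h[best[1]], to = h[best[2]], steps = best[3],
      stringsAsFactors = FALSE)
    in_tree[best[2]] <- TRUE
  }
  do.call(rbind, edges)
}
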