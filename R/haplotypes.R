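#' Phased haplotype matrix
#'
#' Container for phased biallelic haplotypes on a single chromosome: a
#' haplotype-by-site 0/1 matrix (0 = reference/putative-ancestral allele,
#' 1 = alternate/putative-derived), strictly increasing 1-based site
#' positions, a population label per haplotype row, and one sample id per
#' diploid individual (two consecutive haplotype rows per individual).
#'
#' @param alleles integer matrix, haplotypes x sites, entries in \{0, 1\}.
#' @param positions integer vector of 1-based site coordinates, strictly
#'   increasing, one per column of `alleles`.
#' @param chrom chromosome label.
#' @param hap_pop character vector of population labels, one per haplotype
#'   row; the two rows of an individual must share a label.
#' @param sample_ids character vector of individual ids, `nrow(alleles)/2`
#'   of them, in row-pair order.
#' @return an object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, positions, chrom = "chr1", hap_pop, sample_ids) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(positions) != ncol(alleles))
    stop("positions length must equal the number of allele columns")
  if (ncol(alleles) > 0) {
    if (any(is.na(alleles)) || any(alleles != 0L & alleles != 1L))
      stop("allele entries must be 0 or 1 (missing genotypes are not supported)")
    if (any(diff(positions) <= 0))
      stop("positions must be strictly increasing")
    if (any(positions < 1))
      stop("positions must be 1-based (>= 1)")
  }
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype row count must be 2 x individual count")
  if (length(hap_pop) != nrow(alleles))
    stop("hap_pop must have one label per haplotype row")
  if (length(sample_ids) != nrow(alleles) / 2L)
    stop("sample_ids must have one entry per diploid individual")
  odd <- seq_len(length(hap_pop) %/% 2L) * 2L - 1L
  if (length(odd) && any(hap_pop[odd] != hap_pop[odd + 1L]))
    stop("the two haplotypes of an individual must share a population label")
  structure(
    list(chrom = as.character(chrom),
         positions = as.integer(positions),
         alleles = alleles,
         hap_pop = as.character(hap_pop),
         sample_ids = as.character(sample_ids)),
    class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes (%d individuals) x %d sites on %s\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles), x$chrom))
  tab <- table(x$hap_pop[seq(1, length(x$hap_pop), by = 2)])
  cat("individuals per population:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of haplotypes / sites
#' @param h a `hap_matrix`.
#' @return integer count.
#' @export
n_haplotypes <- function(h) nrow(h$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(h) ncol(h$alleles)

#' Minor allele frequency per site
#'
#' The lesser of the two allele frequencies at each biallelic site.
#'
#' @param h a `hap_matrix`.
#' @return numeric vector, one MAF per site.
#' @export
site_maf <- function(h) {
  if (ncol(h$alleles) == 0) return(numeric(0))
  f <- colMeans(h$alleles)
  pmin(f, 1 - f)
}

#' Subset a haplotype matrix by site index
#' @param h a `hap_matrix`.
#' @param idx integer or logical index into the site columns.
#' @return a `hap_matrix` with the selected sites, order preserved.
#' @export
hap_subset_sites <- function(h, idx) {
  hap_matrix(h$alleles[, idx, drop = FALSE], h$positions[idx],
             chrom = h$chrom, hap_pop = h$hap_pop, sample_ids = h$sample_ids)
}

#' Subset a haplotype matrix to the sites of a genomic window
#'
#' Regions are 0-based half-open; a 1-based site position `p` lies in
#' `[start, end)` extended by `flank_bp` iff `start - flank_bp < p <=
#' end + flank_bp`.
#'
#' @param h a `hap_matrix`.
#' @param start,end region bounds, 0-based half-open.
#' @param flank_bp symmetric flank in bp (default 0).
#' @return a `hap_matrix` restricted to the window sites.
#' @export
hap_window <- function(h, start, end, flank_bp = 0) {
  # positions are sorted, so locate the column range by binary search
  lo <- findInterval(start - flank_bp, h$positions) + 1L
  hi <- findInterval(end + flank_bp, h$positions)
  idx <- if (hi >= lo) seq.int(lo, hi) else integer(0)
  hap_subset_sites(h, idx)
}

#' Subset a haplotype matrix to one or more populations
#' @param h a `hap_matrix`.
#' @param pops population labels to keep.
#' @return a `hap_matrix` with only the matching individuals.
#' @export
hap_subset_pops <- function(h, pops) {
  keep <- h$hap_pop %in% pops
  if (!any(keep)) stop("no haplotypes from population(s): ",
                       paste(pops, collapse = ", "))
  ind_keep <- h$hap_pop[seq(1, length(h$hap_pop), by = 2)] %in% pops
  hap_matrix(h$alleles[keep, , drop = FALSE], h$positions, chrom = h$chrom,
             hap_pop = h$hap_pop[keep], sample_ids = h$sample_ids[ind_keep])
}
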