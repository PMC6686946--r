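# Region-level selection statistics.  Each statistic returns a list with a
# `value` (numeric, NA when undefined) and a `reason` code drawn from
# {"no_segregating_sites", "insufficient_haplotypes", "no_valid_focal_sites"}.

metric_value <- function(value, reason = NA_character_) {
  list(value = as.numeric(value), reason = reason)
}

undefined_metric <- function(reason) metric_value(NA_real_, reason)

#' Nucleotide diversity (pi)
#'
#' Sum over sites of the pairwise-difference proportion
#' `2 c (n - c) / (n (n - 1))`, with `c` the alternate-allele count and `n`
#' the haplotype count.
#'
#' @param h a [hap_matrix] restricted to the region of interest.
#' @return numeric pi (>= 0), or `NA` with a `reason` attribute when fewer
#'   than 2 haplotypes are present.
#' @export
nucleotide_diversity <- function(h) {
  n <- n_haplotypes(h)
  if (n < 2) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient_haplotypes"
    return(out)
  }
  if (n_sites(h) == 0) return(0)
  cc <- colSums(h$alleles)
  sum(2 * cc * (n - cc) / (n * (n - 1)))
}

#' Tajima's D constants
#'
#' The eight constants of the Tajima (1989) test for a sample of `n`
#' haplotypes.
#'
#' @param n number of haplotypes (>= 4).
#' @return named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` over the segregating sites
#' of the region.  Negative values indicate an excess of rare variants, as
#' expected after a selective sweep.
#'
#' @param h a [hap_matrix] restricted to the region of interest.
#' @return list with `value` and `reason` (`no_segregating_sites` when S = 0,
#'   `insufficient_haplotypes` when n < 4).
#' @export
tajimas_d <- function(h) {
  n <- n_haplotypes(h)
  if (n < 4) return(undefined_metric("insufficient_haplotypes"))
  cc <- colSums(h$alleles)
  seg <- cc > 0 & cc < n
  S <- sum(seg)
  if (S == 0) return(undefined_metric("no_segregating_sites"))
  cc <- cc[seg]
  pi <- sum(2 * cc * (n - cc) / (n * (n - 1)))
  k <- tajima_constants(n)
  metric_value((pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1)))
}

#' Weighted Weir-Cockerham F_ST
#'
#' Multi-population, multi-site weighted estimator: per biallelic site the
#' Weir & Cockerham (1984) variance components a (among populations),
#' b (among individuals within populations) and c (within individuals) are
#' computed from diploid genotypes (individuals reconstituted from
#' consecutive haplotype rows, observed heterozygosity); the estimate is
#' `sum(a) / sum(a + b + c)` over sites.
#'
#' @param h a [hap_matrix] restricted to the region, carrying >= 2
#'   populations with >= 1 diploid individual each.
#' @param pops populations to use; default all labels present in `h`.
#' @return list with `value` and `reason` (undefined when the denominator
#'   is 0).
#' @export
wc_fst <- function(h, pops = NULL) {
  ind_pop <- h$hap_pop[seq(1, n_haplotypes(h), by = 2)]
  if (is.null(pops)) pops <- sort(unique(ind_pop))
  missing <- setdiff(pops, unique(ind_pop))
  if (length(missing))
    stop("population(s) absent from the sample: ", paste(missing, collapse = ", "))
  r <- length(pops)
  if (r < 2) stop("wc_fst needs at least 2 populations")
  n_i <- as.numeric(table(factor(ind_pop, levels = pops)))
  nbar <- mean(n_i)
  if (nbar <= 1) return(undefined_metric("insufficient_haplotypes"))
  if (n_sites(h) == 0) return(undefined_metric("no_segregating_sites"))

  A <- h$alleles
  odd <- seq(1, nrow(A), by = 2)
  G <- A[odd, , drop = FALSE] + A[odd + 1, , drop = FALSE]   # 0/1/2 genotypes
  HET <- (A[odd, , drop = FALSE] != A[odd + 1, , drop = FALSE]) * 1L
  fpop <- factor(ind_pop, levels = pops)
  # per-population allele frequency and observed heterozygosity per site
  p_i <- rowsum(G, fpop) / (2 * n_i)          # r x S
  h_i <- rowsum(HET, fpop) / n_i

  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- sum(a + b + cc)
  if (denom == 0) return(undefined_metric("no_segregating_sites"))
  metric_value(sum(a) / denom)
}

#' H12 haplotype homozygosity
#'
#' Haplotypes are compared by exact identity over all region sites; with
#' sorted haplotype-class frequencies `p1 >= p2 >= p3 >= ...`,
#' `H12 = (p1 + p2)^2 + sum(p_i^2, i >= 3)`.  Elevated under both hard and
#' soft sweeps.
#'
#' @param h a [hap_matrix] restricted to the region of interest.
#' @return list with `value` in (0, 1] and `reason`
#'   (`no_segregating_sites` when the region contains no sites at all).
#' @export
h12 <- function(h) {
  if (n_haplotypes(h) < 2) return(undefined_metric("insufficient_haplotypes"))
  if (n_sites(h) == 0) return(undefined_metric("no_segregating_sites"))
  key <- apply(h$alleles, 1, paste, collapse = "")
  p <- sort(as.numeric(table(key)) / length(key), decreasing = TRUE)
  if (length(p) == 1) return(metric_value(1))
  metric_value((p[1] + p[2])^2 + sum(p[-(1:2)]^2))
}

#' Unstandardised nS_L at a focal site
#'
#' For every haplotype pair (i, j), `L(i, j)` counts the consecutive
#' segregating sites, in the maximal run containing the focal site, at which
#' i and j carry identical alleles (runs truncated at the window edges).
#' `SL_anc` is the mean of L over pairs both carrying allele 0 at the focal
#' site, `SL_der` over pairs both carrying allele 1; the statistic is
#' `ln(SL_anc / SL_der)`.  Sites are indexed within the (already
#' MAF-filtered) window matrix.
#'
#' @param h a [hap_matrix] of the window sites.
#' @param focal_index 1-based column index of the focal site.
#' @return numeric, or `NA` when either allele class has fewer than
#'   2 carriers.
#' @export
nsl_site <- function(h, focal_index) {
  stopifnot(focal_index >= 1, focal_index <= n_sites(h))
  nsl_site_cpp(h$alleles, as.integer(focal_index) - 1L)
}

#' Region-level nS_L score
#'
#' Subsets to one population and to the window `[start - flank, end + flank)`,
#' drops sites below the MAF cutoff (computed within the population), and
#' returns the maximum of |nS_L| over all valid focal sites in the window.
#'
#' @param h a [hap_matrix] (all populations, full chromosome or wider window).
#' @param start,end region bounds, 0-based half-open.
#' @param population single population label.
#' @param flank_bp window flank in bp (default 50000).
#' @param maf_min minor-allele-frequency cutoff (default 0.01, sites with
#'   MAF >= the cutoff are retained).
#' @return list with `value` and `reason` (`no_valid_focal_sites` when no
#'   focal site qualifies).
#' @export
nsl_region <- function(h, start, end, population, flank_bp = 50000,
                       maf_min = 0.01) {
  hw <- hap_window(h, start, end, flank_bp = flank_bp)
  hp <- hap_subset_pops(hw, population)
  nsl_window_value(hp, maf_min = maf_min)
}

# nS_L over an already-extracted window: MAF filter, per-focal values,
# max |nSL|.  Shared by nsl_region() and the null builder.
nsl_window_value <- function(hw, maf_min = 0.01) {
  if (n_haplotypes(hw) < 4) return(undefined_metric("insufficient_haplotypes"))
  keep <- site_maf(hw) >= maf_min
  if (!any(keep)) return(undefined_metric("no_valid_focal_sites"))
  hw <- hap_subset_sites(hw, keep)
  vals <- nsl_all_sites_cpp(hw$alleles)
  if (all(is.na(vals))) return(undefined_metric("no_valid_focal_sites"))
  metric_value(max(abs(vals), na.rm = TRUE))
}
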