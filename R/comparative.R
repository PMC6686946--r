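# Comparative layer: tissue-breadth classification, pairwise distribution
# tests with Bonferroni correction, rankings, interval-overlap tests and
# complete-LD SNP expansion against a trait catalog.

#' Classify regions by tissue breadth
#'
#' A region active in exactly one tissue is `tissue_specific`; in two or
#' more, `tissue_broad`.  The summary tabulates, among tissue-broad regions,
#' how many organ systems each belongs to, with percentages of the
#' tissue-broad total reported to 2 decimals.
#'
#' @param regions a [region_set].
#' @return list with `labels` (data.frame: region_id, breadth, n_tissues,
#'   n_organ_systems) and `summary` (data.frame: n_organ_systems, count,
#'   percent).
#' @export
classify_breadth <- function(regions) {
  if (nrow(regions) == 0) stop("empty region set")
  n_t <- lengths(regions$tissues)
  n_o <- lengths(regions$organ_systems)
  labels <- data.frame(region_id = regions$region_id,
                       breadth = ifelse(n_t == 1, "tissue_specific",
                                        "tissue_broad"),
                       n_tissues = n_t, n_organ_systems = n_o,
                       stringsAsFactors = FALSE)
  broad <- labels[labels$breadth == "tissue_broad", ]
  if (nrow(broad)) {
    tab <- table(broad$n_organ_systems)
    summary <- data.frame(n_organ_systems = as.integer(names(tab)),
                          count = as.integer(tab),
                          percent = round(100 * as.integer(tab) / nrow(broad), 2))
  } else {
    summary <- data.frame(n_organ_systems = integer(0), count = integer(0),
                          percent = numeric(0))
  }
  list(labels = labels, summary = summary)
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' Statistic: supremum over x of |ECDF_a(x) - ECDF_b(x)|; p-value from the
#' asymptotic two-sample Kolmogorov distribution (effective
#' n = n_a n_b / (n_a + n_b)).  NA values are removed first.
#'
#' @param sample_a,sample_b numeric vectors (non-empty after NA removal).
#' @return list with `statistic`, `p_raw`, `n_a`, `n_b`.
#' @export
ks_two_sided <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0 || length(b) == 0)
    stop("KS test needs non-empty samples after NA removal")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_raw = unname(kt$p.value),
       n_a = length(a), n_b = length(b))
}

#' Pairwise distribution tests across groups
#'
#' With `grouping = "tissue"`, one two-sided KS test per unordered pair of
#' tissues on the metric's region values (a tissue-broad region contributes
#' to every tissue it is active in).  With `grouping = "breadth"` (needs
#' `regions`) or `grouping = "label"` (needs `label_map`), one two-group KS
#' test per tissue, splitting that tissue's regions into tissue-specific vs
#' tissue-broad (or by the supplied two-level label).  The Bonferroni family
#' is the set of tests actually run in the invocation:
#' `p_adjusted = min(1, p_raw * m)`.
#'
#' @param table a metric-table data.frame (long format).
#' @param metric metric name to test.
#' @param grouping `"tissue"`, `"breadth"` or `"label"`.
#' @param population restrict to one population scope (default: all rows of
#'   the metric).
#' @param regions a [region_set]; required for `grouping = "breadth"`.
#' @param label_map named vector `region_id -> group`; required for
#'   `grouping = "label"`.
#' @return data.frame with tissue (NA for tissue grouping), group_a,
#'   group_b, ks_statistic, p_raw, p_adjusted, n_a, n_b, family `m`.
#' @export
pairwise_tissue_tests <- function(table, metric,
                                  grouping = c("tissue", "breadth", "label"),
                                  population = NULL, regions = NULL,
                                  label_map = NULL) {
  grouping <- match.arg(grouping)
  rows <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(population))
    rows <- rows[rows$population == population, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows for metric ", metric)

  run_tests <- function(specs) {
    out <- lapply(specs, function(sp) {
      a <- sp$a[!is.na(sp$a)]; b <- sp$b[!is.na(sp$b)]
      if (length(a) < 2 || length(b) < 2) {
        warning("skipping ", sp$ga, " vs ", sp$gb,
                ": a group has < 2 defined values")
        return(NULL)
      }
      kt <- ks_two_sided(a, b)
      data.frame(tissue = sp$tissue, group_a = sp$ga, group_b = sp$gb,
                 ks_statistic = kt$statistic, p_raw = kt$p_raw,
                 n_a = kt$n_a, n_b = kt$n_b, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(out)) stop("no testable group pairs")
    m <- nrow(out)
    out$p_adjusted <- pmin(1, out$p_raw * m)
    out$m <- m
    out[, c("tissue", "group_a", "group_b", "ks_statistic", "p_raw",
            "p_adjusted", "n_a", "n_b", "m")]
  }

  if (grouping == "tissue") {
    groups <- split(rows$value, rows$tissue)
    gn <- names(groups)
    if (length(gn) < 2) stop("need >= 2 groups")
    specs <- list()
    for (i in seq_len(length(gn) - 1))
      for (j in seq((i + 1), length(gn)))
        specs[[length(specs) + 1]] <-
          list(tissue = NA_character_, ga = gn[i], gb = gn[j],
               a = groups[[i]], b = groups[[j]])
    return(run_tests(specs))
  }

  if (grouping == "breadth") {
    if (is.null(regions)) stop("grouping = 'breadth' requires regions")
    lb <- classify_breadth(regions)$labels
    label_map <- stats::setNames(lb$breadth, lb$region_id)
    lev <- c("tissue_specific", "tissue_broad")
  } else {
    if (is.null(label_map)) stop("grouping = 'label' requires label_map")
    lev <- sort(unique(unname(label_map)))
    if (length(lev) != 2) stop("label_map must have exactly 2 levels")
  }
  rows$group <- unname(label_map[rows$region_id])
  specs <- lapply(sort(unique(rows$tissue)), function(tis) {
    rt <- rows[rows$tissue == tis, ]
    list(tissue = tis, ga = lev[1], gb = lev[2],
         a = rt$value[rt$group == lev[1]], b = rt$value[rt$group == lev[2]])
  })
  run_tests(specs)
}

#' Rank groups by a summary of a metric
#'
#' Groups (tissues) ranked in descending order of the group median value or
#' of the proportion of significant calls; NA values are excluded before
#' summarising; ties share the smaller rank.
#'
#' @param table a metric-table data.frame.
#' @param metric metric name.
#' @param by `"median"` or `"proportion_significant"`.
#' @param population optional population-scope filter.
#' @return data.frame (group, value, rank), ordered by rank.
#' @export
rank_groups <- function(table, metric,
                        by = c("median", "proportion_significant"),
                        population = NULL) {
  by <- match.arg(by)
  rows <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(population))
    rows <- rows[rows$population == population, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows for metric ", metric)
  f <- function(d) {
    if (by == "median") stats::median(d$value, na.rm = TRUE)
    else mean(d$significant[!is.na(d$value)], na.rm = TRUE)
  }
  val <- vapply(split(rows, rows$tissue), f, numeric(1))
  out <- data.frame(group = names(val), value = unname(val),
                    rank = rank(-val, ties.method = "min"),
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$group), , drop = FALSE]
}

#' Any-overlap flags against an annotation track
#'
#' TRUE for a region iff it intersects at least one annotation interval by
#' >= 1 bp.  Both sides are 0-based half-open.
#'
#' @param regions a [region_set] (or data.frame with chrom/start/end).
#' @param annotation data.frame with columns chrom, start, end (0-based
#'   half-open).
#' @return logical vector, one flag per region in input order.
#' @export
overlap_any <- function(regions, annotation) {
  if (nrow(annotation) == 0) return(rep(FALSE, nrow(regions)))
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1, regions$end))
  s <- GenomicRanges::GRanges(annotation$chrom,
                              IRanges::IRanges(annotation$start + 1,
                                               annotation$end))
  IRanges::overlapsAny(q, s)
}

#' 2x2 chi-squared test with Yates continuity correction
#'
#' `chi2 = N (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`, p from
#' the chi-squared distribution with 1 df.  Undefined (with reason) when a
#' margin is zero.
#'
#' @param a,b,c,d non-negative integer cell counts (rows: significant vs
#'   not; columns: overlapping vs not), or `a` may be a 2x2 matrix.
#' @return list with `statistic`, `p`, and `reason` (NA unless undefined).
#' @export
chi2_yates <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(m < 0) || sum(m) == 0) stop("invalid 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = NA_real_, p = NA_real_, reason = "zero_margin"))
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       reason = NA_character_)
}

#' Haplotype r-squared between two sites
#'
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))` from phased
#' haplotype counts.
#'
#' @param site_a,site_b 0/1 vectors over the same haplotype set.
#' @return numeric in [0, 1]; NA when either site is monomorphic.
#' @export
ld_r2 <- function(site_a, site_b) {
  if (length(site_a) != length(site_b))
    stop("sites must cover the same haplotype set")
  pA <- mean(site_a); pB <- mean(site_b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(site_a == 1 & site_b == 1)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Expand a SNP set by complete LD
#'
#' Returns the union of the input SNP positions and every polymorphic site
#' within `window_bp` of an input SNP whose haplotype r-squared with it is
#' 1.0 (within `tol`).
#'
#' @param snp_positions 1-based positions of the seed SNPs (must be sites of
#'   `h`).
#' @param h a [hap_matrix].
#' @param window_bp search window each side (default 1e6).
#' @param tol tolerance on r2 = 1 (default 1e-12).
#' @return sorted integer vector of positions.
#' @export
expand_complete_ld <- function(snp_positions, h, window_bp = 1e6,
                               tol = 1e-12) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  snp_positions <- intersect(snp_positions, h$positions)
  out <- as.integer(snp_positions)
  f <- colMeans(h$alleles)
  poly <- f > 0 & f < 1
  for (p in snp_positions) {
    i <- match(p, h$positions)
    cand <- which(poly & abs(h$positions - p) <= window_bp)
    cand <- setdiff(cand, i)
    if (!length(cand)) next
    x <- h$alleles[, i]
    r2 <- vapply(cand, function(j) ld_r2(x, h$alleles[, j]), numeric(1))
    out <- c(out, h$positions[cand[!is.na(r2) & r2 >= 1 - tol]])
  }
  sort(unique(out))
}

#' Trait-catalog hits per region
#'
#' Matches catalog SNPs by (chrom, position) against the SNPs inside each
#' region and, optionally, against the complete-LD expansion of those SNPs;
#' hits reachable only through an LD partner are flagged `via_ld`.
#'
#' @param regions a [region_set].
#' @param h a [hap_matrix] on the same chromosome/assembly.
#' @param catalog a `snp_catalog` data.frame (see [read_snp_catalog]).
#' @param expand_ld include complete-LD partners (default TRUE).
#' @param window_bp LD search window (default 1e6).
#' @return list with `hits` (data.frame: region_id, rsid, position, trait,
#'   via_ld) and `overlap` (named logical per region: any hit).
#' @export
catalog_hits <- function(regions, h, catalog, expand_ld = TRUE,
                         window_bp = 1e6) {
  hits <- list()
  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    inside <- h$positions[h$positions > rg$start & h$positions <= rg$end]
    snpset <- inside
    if (expand_ld && length(inside))
      snpset <- expand_complete_ld(inside, h, window_bp = window_bp)
    cat_rows <- catalog[catalog$chrom == rg$chrom &
                          catalog$position %in% snpset, , drop = FALSE]
    if (nrow(cat_rows))
      hits[[length(hits) + 1]] <-
        data.frame(region_id = rg$region_id, rsid = cat_rows$rsid,
                   position = cat_rows$position, trait = cat_rows$trait,
                   via_ld = !(cat_rows$position %in% inside),
                   stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(region_id = character(0), rsid = character(0),
               position = integer(0), trait = character(0),
               via_ld = logical(0))
  overlap <- stats::setNames(regions$region_id %in% hits$region_id,
                             regions$region_id)
  list(hits = hits, overlap = overlap)
}
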