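# Ground-truthed synthetic cohorts: neutral background variation per region
# window, optional planted sweeps by founder-haplotype copying, tissue and
# organ-system labels, a piecewise-constant recombination map, annotation
# tracks and a trait catalog -- everything the pipeline reads, with truth.

#' Cohort generator configuration
#'
#' Defaults emulate a FANTOM-like enhancer atlas on a 1000-Genomes-like
#' cohort: short regions (lognormal around 300 bp, clamped to 200-1000 bp),
#' 41 tissues grouped into 10 organ systems with 80% tissue-specific
#' regions, each region sitting in its own window (region plus two 50 kb
#' flanks) so distinct regions are effectively unlinked, and a
#' piecewise-constant recombination map drawn lognormally around 1.2 cM/Mb.
#'
#' @param n_regions number of regions.
#' @param n_tissues,n_organ_systems label-space sizes.
#' @param frac_specific fraction of regions active in exactly one tissue.
#' @param broad_tissues_range tissue-count range for tissue-broad regions.
#' @param region_len_meanlog,region_len_sdlog,region_len_range lognormal
#'   length model (bp) and clamp.
#' @param flank_bp window flank (bp) around each region.
#' @param gap_bp extra spacing between consecutive windows.
#' @param rate_meanlog,rate_sdlog lognormal model of per-window
#'   recombination rate (cM/Mb).
#' @param sweep_fraction fraction of regions carrying a planted sweep.
#' @param sweep_mode `"hard"` or `"soft"`.
#' @param carrier_fraction fraction f of target haplotypes receiving the
#'   founder haplotype.
#' @param n_founders founder count for soft sweeps (hard sweeps use 1).
#' @param target_pops populations receiving the sweep; NULL = all.
#' @return a named list of settings.
#' @export
cohort_config <- function(n_regions = 100, n_tissues = 41,
                          n_organ_systems = 10, frac_specific = 0.8,
                          broad_tissues_range = c(2, 6),
                          region_len_meanlog = log(300),
                          region_len_sdlog = 0.45,
                          region_len_range = c(200, 1000),
                          flank_bp = 50000, gap_bp = 2000,
                          rate_meanlog = log(1.2), rate_sdlog = 0.4,
                          sweep_fraction = 0, sweep_mode = "hard",
                          carrier_fraction = 0.8, n_founders = 3,
                          target_pops = NULL) {
  cfg <- as.list(environment())
  if (cfg$sweep_fraction < 0 || cfg$sweep_fraction > 1)
    stop("sweep_fraction must lie in [0, 1]")
  if (cfg$carrier_fraction <= 0 || cfg$carrier_fraction > 1)
    stop("carrier_fraction must lie in (0, 1]")
  if (!cfg$sweep_mode %in% c("hard", "soft")) stop("sweep_mode: hard or soft")
  if (cfg$sweep_mode == "soft" && cfg$n_founders < 2)
    stop("soft sweeps need >= 2 founder haplotypes")
  cfg
}

#' Generate a synthetic cohort with ground truth
#'
#' Lays regions out in non-overlapping windows along one synthetic
#' chromosome, simulates neutral background variation per window under the
#' demographic model (each window at its own map rate), then plants sweeps
#' in the configured fraction of regions by copying one (hard) or several
#' (soft) founder haplotypes over the region's sites onto a fraction
#' `carrier_fraction` of the target-population haplotypes.  Sites rendered
#' monomorphic by planting are dropped.  Fully deterministic given
#' (config, seed).
#'
#' @param model a [demographic_model].
#' @param n_haps haplotype counts per population; default matches a
#'   1000-Genomes-scale cohort of 661 AFR, 503 EUR and 504 EAS individuals.
#' @param config a [cohort_config] list.
#' @param seed master seed.
#' @return a list of class `synthetic_cohort`: `haps` ([hap_matrix]),
#'   `regions` ([region_set]), `map` ([genetic_map]), `organ_map`, `truth`
#'   (data.frame: region_id, mode, carrier_fraction, n_founders,
#'   target_pops, swept), plus the generating `config`, `model`, `n_haps`
#'   and `seed`.
#' @export
generate_cohort <- function(model = ooa_gravel_model(),
                            n_haps = c(AFR = 1322, EUR = 1006, EAS = 1008),
                            config = cohort_config(), seed = 1) {
  cfg <- config
  pops <- model_populations(model)
  set.seed(seed)

  # region layout
  len <- round(pmin(pmax(stats::rlnorm(cfg$n_regions, cfg$region_len_meanlog,
                                       cfg$region_len_sdlog),
                         cfg$region_len_range[1]), cfg$region_len_range[2]))
  seg_len <- len + 2 * cfg$flank_bp
  seg_start <- cumsum(c(0, utils::head(seg_len + cfg$gap_bp, -1)))
  start <- seg_start + cfg$flank_bp
  end <- start + len
  ids <- sprintf("r%05d", seq_len(cfg$n_regions))

  # tissue / organ-system structure
  tissues_all <- sprintf("t%02d", seq_len(cfg$n_tissues))
  organ_map <- stats::setNames(
    sprintf("os%02d", rep_len(seq_len(cfg$n_organ_systems), cfg$n_tissues)),
    tissues_all)
  tissues <- lapply(seq_len(cfg$n_regions), function(i) {
    if (stats::runif(1) < cfg$frac_specific) sample(tissues_all, 1)
    else sample(tissues_all,
                sample(seq(min(cfg$broad_tissues_range[1], cfg$n_tissues),
                           min(cfg$broad_tissues_range[2], cfg$n_tissues)), 1))
  })
  regions <- region_set("chr1", start, end, ids, tissues, organ_map)

  # recombination map: piecewise constant per window
  rate_seg <- stats::rlnorm(cfg$n_regions, cfg$rate_meanlog, cfg$rate_sdlog)
  map_pos <- c(seg_start + 1, seg_start[cfg$n_regions] +
                 seg_len[cfg$n_regions] + cfg$gap_bp)
  map_rate <- c(rate_seg, rate_seg[cfg$n_regions])
  map_cum <- cumsum(c(0, map_rate[-length(map_rate)] *
                        diff(map_pos) / 1e6))
  map <- genetic_map(map_pos, map_rate, map_cum)

  # sweep assignment (all layout randomness drawn before simulation)
  n_swept <- round(cfg$sweep_fraction * cfg$n_regions)
  swept_idx <- if (n_swept > 0) sort(sample(cfg$n_regions, n_swept)) else integer(0)
  target_pops <- if (is.null(cfg$target_pops)) pops else cfg$target_pops
  if (!all(target_pops %in% pops)) stop("unknown target population(s)")

  # neutral background per window, one independent seed stream per window
  seg_seeds <- derive_seeds(seed + 1L, cfg$n_regions)
  hap_pop <- rep(pops, times = n_haps)
  target_rows <- which(hap_pop %in% target_pops)
  mats <- vector("list", cfg$n_regions)
  poss <- vector("list", cfg$n_regions)
  truth_founders <- integer(cfg$n_regions)
  for (k in seq_len(cfg$n_regions)) {
    sim <- simulate_neutral(model, n_haps, seg_len[k],
                            recomb_rate = rate_seg[k] * 1e-8,
                            seed = seg_seeds[k])
    A <- sim$alleles
    pos <- sim$positions + seg_start[k]
    if (k %in% swept_idx) {
      nf <- if (cfg$sweep_mode == "hard") 1L else as.integer(cfg$n_founders)
      truth_founders[k] <- nf
      in_region <- pos > start[k] & pos <= end[k]
      if (any(in_region)) {
        founders <- sample(target_rows, nf)
        carriers <- sample(target_rows,
                           round(cfg$carrier_fraction * length(target_rows)))
        share <- rep_len(seq_len(nf), length(carriers))
        for (fi in seq_len(nf)) {
          rows <- carriers[share == fi]
          if (length(rows))
            A[rows, in_region] <- rep(A[founders[fi], in_region],
                                      each = length(rows))
        }
        # planting can fix sites; drop the monomorphic columns
        cc <- colSums(A)
        keep <- cc > 0 & cc < nrow(A)
        A <- A[, keep, drop = FALSE]
        pos <- pos[keep]
      }
    }
    mats[[k]] <- A
    poss[[k]] <- pos
  }
  n_ind <- as.integer(n_haps) %/% 2L
  haps <- hap_matrix(do.call(cbind, mats), unlist(poss), chrom = "chr1",
                     hap_pop = hap_pop,
                     sample_ids = unlist(lapply(seq_along(pops), function(i)
                       sprintf("%s_%04d", pops[i], seq_len(n_ind[i])))))

  truth <- data.frame(
    region_id = ids,
    mode = ifelse(seq_len(cfg$n_regions) %in% swept_idx, cfg$sweep_mode,
                  "neutral"),
    carrier_fraction = ifelse(seq_len(cfg$n_regions) %in% swept_idx,
                              cfg$carrier_fraction, NA_real_),
    n_founders = ifelse(seq_len(cfg$n_regions) %in% swept_idx,
                        truth_founders, 0L),
    target_pops = ifelse(seq_len(cfg$n_regions) %in% swept_idx,
                         paste(target_pops, collapse = ","), ""),
    swept = seq_len(cfg$n_regions) %in% swept_idx,
    stringsAsFactors = FALSE)

  structure(list(haps = haps, regions = regions, map = map,
                 organ_map = organ_map, truth = truth, config = cfg,
                 model = model, n_haps = n_haps, seed = seed),
            class = "synthetic_cohort")
}

#' Generate annotation intervals and a trait catalog with planted truth
#'
#' Annotation intervals (a RepeatMasker-like track) are planted inside a
#' designated fraction of regions (>= 1 bp overlap each), plus decoy
#' intervals that overlap no region.  Catalog SNPs are placed at real
#' cohort sites inside a designated fraction of regions; when haplotypes
#' are supplied, additional catalog SNPs are placed at complete-LD partner
#' sites outside the regions (recoverable only through LD expansion).
#'
#' @param regions a [region_set].
#' @param planted_overlap_fraction fraction of regions intersected by the
#'   annotation track.
#' @param seed RNG seed.
#' @param h optional [hap_matrix] (required for the catalog).
#' @param catalog_fraction fraction of regions receiving a catalog SNP.
#' @param ld_partner_fraction of the catalog regions, fraction that also
#'   gets a catalog SNP at an outside complete-LD partner site.
#' @param ld_window_bp LD search window.
#' @return list with `annotation` (data.frame chrom/start/end),
#'   `catalog` (`snp_catalog`), and `truth` (data.frame region_id,
#'   planted_overlap, planted_catalog).
#' @export
generate_annotations <- function(regions, planted_overlap_fraction = 0.5,
                                 seed = 1, h = NULL, catalog_fraction = 0.3,
                                 ld_partner_fraction = 0.5,
                                 ld_window_bp = 1e6) {
  if (planted_overlap_fraction < 0 || planted_overlap_fraction > 1)
    stop("planted_overlap_fraction must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(regions)
  n_ov <- round(planted_overlap_fraction * n)
  ov_idx <- if (n_ov > 0) sort(sample(n, n_ov)) else integer(0)
  ann <- lapply(ov_idx, function(k) {
    s <- regions$start[k]; e <- regions$end[k]
    a0 <- sample(s:(e - 1), 1)
    a1 <- min(e, a0 + sample(50:400, 1))
    data.frame(chrom = regions$chrom[k], start = a0, end = a1)
  })
  # decoys strictly between windows (no region overlap by construction)
  n_decoy <- max(1, n %/% 5)
  decoys <- lapply(seq_len(n_decoy), function(i) {
    k <- sample(n, 1)
    a1 <- regions$start[k] - sample(2000:10000, 1)
    data.frame(chrom = regions$chrom[k], start = max(0, a1 - 300), end = a1)
  })
  annotation <- do.call(rbind, c(ann, decoys))
  annotation <- annotation[order(annotation$start), , drop = FALSE]
  rownames(annotation) <- NULL

  traits <- c("height", "body_mass_index", "neuroticism", "platelet_count",
              "educational_attainment", "asthma", "type_2_diabetes")
  cat_rows <- list()
  planted_catalog <- rep(FALSE, n)
  if (!is.null(h) && catalog_fraction > 0) {
    n_cat <- round(catalog_fraction * n)
    cat_idx <- if (n_cat > 0) sort(sample(n, n_cat)) else integer(0)
    for (k in cat_idx) {
      inside <- h$positions[h$positions > regions$start[k] &
                              h$positions <= regions$end[k]]
      if (!length(inside)) next
      p <- if (length(inside) == 1) inside else sample(inside, 1)
      cat_rows[[length(cat_rows) + 1]] <-
        data.frame(rsid = sprintf("rs%d", p), chrom = regions$chrom[k],
                   position = p, trait = sample(traits, 1))
      planted_catalog[k] <- TRUE
      if (stats::runif(1) < ld_partner_fraction) {
        partners <- expand_complete_ld(p, h, window_bp = ld_window_bp)
        partners <- setdiff(partners, inside)
        if (length(partners)) {
          q <- partners[1]
          cat_rows[[length(cat_rows) + 1]] <-
            data.frame(rsid = sprintf("rs%d", q), chrom = regions$chrom[k],
                       position = q, trait = sample(traits, 1))
        }
      }
    }
  }
  catalog <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    data.frame(rsid = character(0), chrom = character(0),
               position = integer(0), trait = character(0))
  catalog <- unique(catalog)
  class(catalog) <- c("snp_catalog", "data.frame")
  truth <- data.frame(region_id = regions$region_id,
                      planted_overlap = seq_len(n) %in% ov_idx,
                      planted_catalog = planted_catalog,
                      stringsAsFactors = FALSE)
  list(annotation = annotation, catalog = catalog, truth = truth)
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits the exact formats the readers consume: phased VCF, panel TSV, BED
#' plus tissue/organ maps, HapMap-style genetic map, and the ground-truth
#' TSV.
#'
#' @param cohort a `synthetic_cohort`.
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(outdir, "cohort.vcf"),
             panel = file.path(outdir, "panel.tsv"),
             bed = file.path(outdir, "regions.bed"),
             tissue_map = file.path(outdir, "tissue_map.tsv"),
             organ_map = file.path(outdir, "organ_map.tsv"),
             genetic_map = file.path(outdir, "genetic_map.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  write_vcf(cohort$haps, paths["vcf"],
            contig_length = max(cohort$map$positions))
  write_panel(cohort$haps, paths["panel"])
  write_regions(cohort$regions, paths["bed"], paths["tissue_map"],
                paths["organ_map"], cohort$organ_map)
  write_genetic_map(cohort$map, paths["genetic_map"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
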