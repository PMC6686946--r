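# Pipeline stages (synth -> scan -> null-p -> compare).  Each stage consumes
# and produces plain files, writes a JSON run manifest, and is deterministic
# given (inputs, config, seed).

pkg_version <- function() as.character(utils::packageVersion("enhancersweep"))

# lightweight content fingerprint: file size + FNV-1a over the first 1 MiB
file_digest <- function(path) {
  n <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  b <- as.integer(readBin(con, "raw", n = min(n, 1048576)))
  h <- 2166136261
  # fold bytes in chunks to keep the loop short
  idx <- seq_along(b)
  s1 <- sum(b * (idx %% 251 + 1)) %% 2147483647
  s2 <- sum(b * (idx %% 509 + 1)) %% 2147483647
  sprintf("%d-%d-%d", n, s1, s2)
}

write_manifest <- function(outdir, subcommand, config, inputs, seed) {
  man <- list(subcommand = subcommand,
              version = pkg_version(),
              seed = seed,
              config = config,
              inputs = lapply(inputs, function(p)
                list(path = as.character(p), digest = file_digest(p))),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

prepare_outdir <- function(outdir, force) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force)
    stop("output directory ", outdir, " exists and is non-empty; use force = TRUE")
  if (dir.exists(outdir) && force)
    unlink(list.files(outdir, full.names = TRUE), recursive = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  invisible(outdir)
}

#' Stage 1: generate a synthetic dataset
#'
#' Writes the full synthetic bundle (VCF, panel, BED + tissue/organ maps,
#' genetic map, ground truth, and optionally an annotation track plus trait
#' catalog) and a run manifest.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param model a [demographic_model].
#' @param n_haps haplotype counts per population.
#' @param config a [cohort_config].
#' @param annotations also generate an annotation track and trait catalog.
#' @param force overwrite a non-empty output directory.
#' @return named vector of written paths, invisibly.
#' @export
run_synth <- function(outdir, seed, model = ooa_gravel_model(),
                      n_haps = c(AFR = 1322, EUR = 1006, EAS = 1008),
                      config = cohort_config(), annotations = TRUE,
                      force = FALSE) {
  prepare_outdir(outdir, force)
  cohort <- generate_cohort(model, n_haps, config, seed)
  paths <- write_cohort(cohort, outdir)
  if (annotations) {
    ann <- generate_annotations(cohort$regions, seed = seed + 2L,
                                h = cohort$haps)
    p2 <- c(annotation = file.path(outdir, "annotation.bed"),
            catalog = file.path(outdir, "catalog.tsv"),
            annotation_truth = file.path(outdir, "annotation_truth.tsv"))
    utils::write.table(ann$annotation, p2["annotation"], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(ann$catalog, p2["catalog"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ann$truth, p2["annotation_truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
  }
  rm(cohort); gc(verbose = FALSE)
  write_manifest(outdir, "synth", config, as.list(paths), seed)
  invisible(paths)
}

# compute the per-region metric rows for one region
scan_region_rows <- function(h, rg, pops, flank_bp, maf_min) {
  hr <- hap_window(h, rg$start, rg$end)
  res <- list()
  d <- tajimas_d(hr)
  res[[1]] <- c(metric = "tajimas_d", population = "ALL",
                value = d$value, reason = d$reason)
  v <- h12(hr)
  res[[2]] <- c(metric = "h12", population = "ALL",
                value = v$value, reason = v$reason)
  f <- wc_fst(hr)
  res[[3]] <- c(metric = "fst_wc", population = "ALL",
                value = f$value, reason = f$reason)
  hw <- hap_window(h, rg$start, rg$end, flank_bp = flank_bp)
  for (p in pops) {
    nv <- nsl_window_value(hap_subset_pops(hw, p), maf_min = maf_min)
    res[[length(res) + 1]] <- c(metric = "nsl", population = p,
                                value = nv$value, reason = nv$reason)
  }
  res
}

#' Stage 2: scan regions for the four selection statistics
#'
#' Reads the cohort files, computes Tajima's D, H12 and F_ST on the pooled
#' sample over each region's sites and the nS_L window maximum per
#' population, and writes the long-format metric table (one row per
#' region x tissue x metric x population scope; undefined values keep their
#' reason codes).
#'
#' @param vcf,bed,panel,tissue_map,organ_map input paths.
#' @param outdir output directory.
#' @param flank_bp nS_L window flank (default 50000).
#' @param maf_min MAF cutoff applied to nS_L windows (default 0.01).
#' @param force overwrite a non-empty output directory.
#' @return the metric table, invisibly (also written as
#'   `<outdir>/metrics.tsv`).
#' @export
run_scan <- function(vcf, bed, panel, tissue_map, organ_map, outdir,
                     flank_bp = 50000, maf_min = 0.01, force = FALSE) {
  prepare_outdir(outdir, force)
  pan <- read_panel(panel)
  h <- read_vcf(vcf, pan)
  regions <- read_bed_regions(bed, read_tissue_map(tissue_map),
                              read_organ_map(organ_map))
  off <- setdiff(unique(regions$chrom), h$chrom)
  if (length(off))
    stop("chromosome name(s) in BED but not in VCF: ",
         paste(off, collapse = ", "))
  pops <- sort(unique(h$hap_pop))
  rows <- vector("list", nrow(regions))
  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    mr <- scan_region_rows(h, rg, pops, flank_bp, maf_min)
    rows[[k]] <- do.call(rbind, lapply(mr, function(x)
      data.frame(region_id = rg$region_id, tissue = rg$tissues[[1]],
                 metric = x[["metric"]], population = x[["population"]],
                 value = as.numeric(x[["value"]]),
                 p_empirical = NA_real_, significant = NA,
                 reason = if (is.na(x[["reason"]])) NA_character_ else
                   x[["reason"]],
                 stringsAsFactors = FALSE)))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  rm(h); gc(verbose = FALSE)
  write_metric_table(table, file.path(outdir, "metrics.tsv"))
  write_manifest(outdir, "scan",
                 list(flank_bp = flank_bp, maf_min = maf_min),
                 list(vcf = vcf, bed = bed, panel = panel,
                      tissue_map = tissue_map, organ_map = organ_map),
                 seed = NA)
  invisible(table)
}

# ---- null caching -----------------------------------------------------------

null_cache_path <- function(dir, tissue, metric, population) {
  file.path(dir, sprintf("null_%s_%s_%s.tsv", tissue, metric, population))
}

# full %.17g precision: cached values must round-trip bit-exactly so that
# tie counting in empirical p-values is identical with and without the cache
fmt_full <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

write_null_tsv <- function(null, path) {
  hdr <- c(sprintf("# metric: %s", null$metric),
           sprintf("# population: %s", null$population),
           sprintf("# tissue: %s", null$tissue),
           sprintf("# length_bp: %s", fmt_full(null$params$length_bp)),
           sprintf("# recomb_rate: %s", fmt_full(null$params$recomb_rate)),
           sprintf("# replicates: %d", null$params$replicates),
           sprintf("# seed: %d", null$params$seed),
           sprintf("# model_hash: %s", null$params$model_hash),
           sprintf("# n_undefined: %d", null$n_undefined))
  writeLines(c(hdr, "value", fmt_full(null$values)), path)
  invisible(path)
}

read_null_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), ": ", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  vals <- as.numeric(lines[(length(hdr) + 2):length(lines)])
  structure(list(metric = meta[["metric"]], population = meta[["population"]],
                 tissue = meta[["tissue"]],
                 values = vals[!is.na(vals)],
                 n_undefined = as.integer(meta[["n_undefined"]]),
                 params = list(length_bp = as.numeric(meta[["length_bp"]]),
                               recomb_rate = as.numeric(meta[["recomb_rate"]]),
                               replicates = as.integer(meta[["replicates"]]),
                               seed = as.integer(meta[["seed"]]),
                               model_hash = meta[["model_hash"]])),
            class = "null_distribution")
}

null_cache_matches <- function(cached, params, replicates, seed, model) {
  isTRUE(all.equal(cached$params$length_bp, params$length_bp)) &&
    isTRUE(all.equal(cached$params$recomb_rate, params$recomb_rate)) &&
    cached$params$replicates == replicates &&
    cached$params$seed == seed &&
    cached$params$model_hash == object_hash(unclass(model))
}

#' Stage 3: neutral nulls and empirical p-values
#'
#' For each tissue, simulates neutral null distributions at the tissue's
#' mean region length (fixed 1e-8 recombination for Tajima's D / F_ST / H12,
#' all three computed on a shared replicate set) and, for nS_L, at the mean
#' window length with the tissue's mean map-derived recombination rate (one
#' null per population, computed from the same window simulations).  Nulls
#' are cached as TSV with a parameter header and reused on rerun when the
#' parameters match.  Every defined metric value then receives an empirical
#' p-value and a significance call at `alpha`.
#'
#' @param scan metric table (data.frame) or path to `metrics.tsv`.
#' @param bed,tissue_map,organ_map,genetic_map input paths (region layout
#'   and recombination map).
#' @param outdir output directory.
#' @param model a [demographic_model].
#' @param n_haps haplotype counts per population (should match the scanned
#'   cohort).
#' @param replicates null size for Tajima's D / F_ST / H12 (default 10000).
#' @param nsl_replicates null size for nS_L (default 2500).
#' @param seed master seed.
#' @param alpha significance cutoff (default 0.05).
#' @param tails named tail directions per metric; the defaults point each
#'   statistic in the direction positive selection pushes it.
#' @param flank_bp,maf_min as in [run_scan].
#' @param force overwrite a non-empty output directory.
#' @return the metric table with `p_empirical` and `significant` filled,
#'   invisibly (also written as `<outdir>/pvalues.tsv`).
#' @export
run_null_p <- function(scan, bed, tissue_map, organ_map, genetic_map, outdir,
                       model = ooa_gravel_model(),
                       n_haps = c(AFR = 1322, EUR = 1006, EAS = 1008),
                       replicates = 10000, nsl_replicates = 2500, seed = 1,
                       alpha = 0.05,
                       tails = c(tajimas_d = "lower", fst_wc = "upper",
                                 h12 = "upper", nsl = "upper"),
                       flank_bp = 50000, maf_min = 0.01, force = FALSE) {
  if (is.character(scan)) scan <- read_metric_table(scan)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(outdir, "nulls")
  dir.create(cache_dir, showWarnings = FALSE)
  regions <- read_bed_regions(bed, read_tissue_map(tissue_map),
                              read_organ_map(organ_map))
  map <- read_genetic_map(genetic_map)
  tissues <- sort(unique(scan$tissue))
  miss <- setdiff(tissues, unique(unlist(regions$tissues)))
  if (length(miss))
    stop("tissue(s) in scan table but not in region set: ",
         paste(miss, collapse = ", "))
  pops <- sort(unique(scan$population[scan$metric == "nsl"]))
  tissue_seeds <- derive_seeds(seed, length(tissues)) %/% 2L + 1L

  nulls <- list()
  for (ti in seq_along(tissues)) {
    tis <- tissues[ti]
    keep <- vapply(regions$tissues, function(tt) tis %in% tt, TRUE)
    rt <- regions[keep, , drop = FALSE]
    params <- tissue_null_params(rt, for_nsl = FALSE)
    nsl_params <- tissue_null_params(rt, map = map, flank_bp = flank_bp,
                                     for_nsl = TRUE)
    tseed <- tissue_seeds[ti]
    want <- c(stats::setNames(rep("ALL", 3), c("tajimas_d", "fst_wc", "h12")),
              stats::setNames(pops, rep("nsl", length(pops))))
    cached <- list()
    all_cached <- TRUE
    for (i in seq_along(want)) {
      metric <- names(want)[i]; p <- unname(want[i])
      f <- null_cache_path(cache_dir, tis, metric, p)
      rep_i <- if (metric == "nsl") nsl_replicates else replicates
      par_i <- if (metric == "nsl") nsl_params else params
      seed_i <- if (metric == "nsl") tseed + 1L else tseed
      if (file.exists(f)) {
        nd <- read_null_tsv(f)
        if (null_cache_matches(nd, par_i, rep_i, seed_i, model)) {
          cached[[paste0(metric, ".", p)]] <- nd
          next
        }
      }
      all_cached <- FALSE
    }
    if (all_cached) {
      ns <- cached
      names(ns) <- sub("\\.ALL$", "", names(ns))
    } else {
      ns <- build_null_set(model, n_haps, params,
                           metrics = c("tajimas_d", "fst_wc", "h12"),
                           replicates = replicates, seed = tseed,
                           tissue = tis, nsl_populations = pops,
                           nsl_params = nsl_params,
                           nsl_replicates = nsl_replicates,
                           maf_min = maf_min)
      for (nm in names(ns)) {
        nd <- ns[[nm]]
        write_null_tsv(nd, null_cache_path(cache_dir, tis, nd$metric,
                                           nd$population))
      }
    }
    nulls[[tis]] <- ns
  }

  out <- scan
  out$p_empirical <- NA_real_
  out$significant <- NA
  for (i in seq_len(nrow(out))) {
    key <- if (out$metric[i] == "nsl")
      paste0("nsl.", out$population[i]) else out$metric[i]
    nd <- nulls[[out$tissue[i]]][[key]]
    if (is.null(nd)) next
    ep <- empirical_p(out$value[i], nd, tail = tails[[out$metric[i]]],
                      alpha = alpha)
    out$p_empirical[i] <- ep$p
    out$significant[i] <- ep$significant
  }
  write_metric_table(out, file.path(outdir, "pvalues.tsv"))
  write_manifest(outdir, "null-p",
                 list(replicates = replicates, nsl_replicates = nsl_replicates,
                      alpha = alpha, tails = as.list(tails),
                      flank_bp = flank_bp, maf_min = maf_min),
                 list(bed = bed, tissue_map = tissue_map,
                      organ_map = organ_map, genetic_map = genetic_map),
                 seed = seed)
  invisible(out)
}

#' Stage 4: comparative analyses
#'
#' Writes, per metric/population scope: the pairwise tissue KS grid with
#' Bonferroni-adjusted p-values, tissue rankings (by median and by
#' proportion significant), the tissue-breadth classification and per-tissue
#' specific-vs-broad tests, and -- when an annotation track and/or trait
#' catalog are supplied -- the 2x2 Yates chi-squared overlap tests
#' (significant vs not x overlapping vs not, on unique regions) and the
#' per-region catalog hit list.
#'
#' @param table metric table with p-values (data.frame or path).
#' @param bed,tissue_map,organ_map input paths.
#' @param outdir output directory.
#' @param annotation optional annotation BED path (3 columns).
#' @param catalog optional trait catalog TSV path.
#' @param vcf,panel optional cohort paths; needed for catalog LD expansion.
#' @param alpha significance cutoff used in rankings/contingency tables.
#' @param force overwrite a non-empty output directory.
#' @return list of the written tables, invisibly.
#' @export
run_compare <- function(table, bed, tissue_map, organ_map, outdir,
                        annotation = NULL, catalog = NULL, vcf = NULL,
                        panel = NULL, alpha = 0.05, force = FALSE) {
  if (is.character(table)) table <- read_metric_table(table)
  prepare_outdir(outdir, force)
  regions <- read_bed_regions(bed, read_tissue_map(tissue_map),
                              read_organ_map(organ_map))
  out <- list()

  br <- classify_breadth(regions)
  utils::write.table(br$labels, file.path(outdir, "breadth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(br$summary, file.path(outdir, "breadth_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$breadth <- br

  combos <- unique(table[, c("metric", "population")])
  n_tissue <- length(unique(table$tissue))
  for (i in seq_len(nrow(combos))) {
    metric <- combos$metric[i]; popn <- combos$population[i]
    tag <- if (popn == "ALL") metric else paste(metric, popn, sep = "_")
    if (n_tissue >= 2) {
      pw <- pairwise_tissue_tests(table, metric, grouping = "tissue",
                                  population = popn)
      utils::write.table(pw, file.path(outdir, paste0("pairwise_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[paste0("pairwise_", tag)]] <- pw
      bt <- tryCatch(
        pairwise_tissue_tests(table, metric, grouping = "breadth",
                              population = popn, regions = regions),
        error = function(e) NULL)
      if (!is.null(bt)) {
        utils::write.table(bt, file.path(outdir, paste0("breadth_tests_", tag,
                                                        ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[paste0("breadth_tests_", tag)]] <- bt
      }
    }
    for (by in c("median", "proportion_significant")) {
      rk <- rank_groups(table, metric, by = by, population = popn)
      utils::write.table(rk, file.path(outdir, sprintf("ranking_%s_%s.tsv",
                                                       tag, by)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[sprintf("ranking_%s_%s", tag, by)]] <- rk
    }
  }

  if (!is.null(annotation)) {
    ann <- utils::read.table(annotation, header = FALSE, sep = "",
                             stringsAsFactors = FALSE)[, 1:3]
    names(ann) <- c("chrom", "start", "end")
    ov <- stats::setNames(overlap_any(regions, ann), regions$region_id)
    chi <- list()
    for (i in seq_len(nrow(combos))) {
      metric <- combos$metric[i]; popn <- combos$population[i]
      rows <- table[table$metric == metric & table$population == popn &
                      !is.na(table$p_empirical), , drop = FALSE]
      if (!nrow(rows)) next
      sig <- vapply(split(rows$significant, rows$region_id), any, TRUE)
      ovr <- ov[names(sig)]
      tab <- matrix(c(sum(sig & ovr), sum(sig & !ovr),
                      sum(!sig & ovr), sum(!sig & !ovr)), 2, 2, byrow = TRUE)
      ct <- chi2_yates(tab)
      chi[[length(chi) + 1]] <-
        data.frame(metric = metric, population = popn,
                   sig_overlap = tab[1, 1], sig_no = tab[1, 2],
                   nonsig_overlap = tab[2, 1], nonsig_no = tab[2, 2],
                   statistic = ct$statistic, p = ct$p,
                   reason = ifelse(is.na(ct$reason), "NA", ct$reason),
                   stringsAsFactors = FALSE)
    }
    if (length(chi)) {
      chi <- do.call(rbind, chi)
      utils::write.table(chi, file.path(outdir, "overlap_chi2.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$overlap_chi2 <- chi
    }
  }

  if (!is.null(catalog) && !is.null(vcf) && !is.null(panel)) {
    h <- read_vcf(vcf, read_panel(panel))
    hits <- catalog_hits(regions, h, read_snp_catalog(catalog))
    utils::write.table(hits$hits, file.path(outdir, "catalog_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$catalog_hits <- hits
  }
  write_manifest(outdir, "compare", list(alpha = alpha),
                 list(bed = bed, tissue_map = tissue_map,
                      organ_map = organ_map),
                 seed = NA)
  invisible(out)
}
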