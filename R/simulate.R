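#' Deterministic per-replicate seed streams
#'
#' Derives one RNG seed per replicate from a master seed by integer mixing,
#' so that replicate `k` of a run is reproducible in isolation (the first
#' `k` seeds do not depend on the total replicate count).
#'
#' @param seed master seed (integer).
#' @param n number of replicate seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  k <- seq_len(n)
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + k * 1103515245 + 12345
  as.integer(s %% 2147483646 + 1)
}

#' Simulate a neutral coalescent sample
#'
#' Draws phased haplotypes for one chromosome segment under the given
#' demographic model using the package's structured coalescent with
#' recombination, migration, exponential growth and population merges.
#' Output is infinite-sites-style biallelic variation with strictly
#' increasing integer positions in `[1, length_bp]` (allele 1 = derived).
#'
#' @param model a [demographic_model].
#' @param n_haps named integer vector of haplotype counts per population, in
#'   `model_populations(model)` order; each count must be even (two
#'   haplotypes per diploid individual).
#' @param length_bp segment length in bp.
#' @param recomb_rate recombination rate per bp per generation.
#' @param seed optional RNG seed (`set.seed` is called when non-NULL).
#' @return a [hap_matrix] (possibly with zero sites).
#' @export
simulate_neutral <- function(model, n_haps, length_bp, recomb_rate = 1e-8,
                             seed = NULL) {
  if (!inherits(model, "demographic_model")) stop("invalid demographic model")
  pops <- model_populations(model)
  if (length(n_haps) != length(pops))
    stop("n_haps must have one count per population (",
         paste(pops, collapse = ", "), ")")
  n_haps <- as.integer(n_haps)
  if (any(n_haps <= 0)) stop("haplotype counts must be positive")
  if (any(n_haps %% 2L != 0L))
    stop("haplotype counts must be even (two per diploid individual)")
  if (length_bp < 1) stop("length_bp must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a <- sim_args(model)
  res <- sim_coalescent_cpp(n_haps, as.numeric(length_bp),
                            as.numeric(recomb_rate), a$mu,
                            a$pop_sizes, a$pop_growth, a$mig, a$events)
  hap_pop <- rep(pops, times = n_haps)
  n_ind <- n_haps %/% 2L
  sample_ids <- unlist(lapply(seq_along(pops), function(i)
    sprintf("%s_%04d", pops[i], seq_len(n_ind[i]))))
  hap_matrix(res$genotypes, res$positions, chrom = "chr1",
             hap_pop = hap_pop, sample_ids = sample_ids)
}

#' Null-simulation parameters for a tissue
#'
#' For the non-nS_L statistics the simulated segment is the rounded mean
#' length of the tissue's regions with a fixed recombination rate of 1e-8
#' per bp per generation.  For nS_L the segment is the mean length plus two
#' window flanks, and the rate is the tissue mean of the per-region mean
#' window recombination rate, converted from cM/Mb to a per-bp crossover
#' probability (1 cM/Mb = 1e-8 per bp per generation).
#'
#' @param regions a [region_set] restricted to one tissue.
#' @param map a [genetic_map]; required when `for_nsl = TRUE`.
#' @param flank_bp window flank in bp (default 50000).
#' @param for_nsl logical.
#' @return list with `length_bp` and `recomb_rate`.
#' @export
tissue_null_params <- function(regions, map = NULL, flank_bp = 50000,
                               for_nsl = FALSE) {
  if (nrow(regions) == 0) stop("empty region list")
  len <- round(mean(regions$end - regions$start))
  if (!for_nsl) return(list(length_bp = len, recomb_rate = 1e-8))
  if (is.null(map)) stop("for_nsl = TRUE requires a genetic map")
  rates <- mapply(function(s, e) mean_window_rate(map, s, e, flank_bp),
                  regions$start, regions$end)
  list(length_bp = len + 2 * flank_bp, recomb_rate = mean(rates) * 1e-8)
}

# compute one metric on one simulated replicate
null_metric_value <- function(sim, metric, population, maf_min = 0.01) {
  if (metric == "nsl") {
    hw <- hap_subset_pops(sim, population)
    return(nsl_window_value(hw, maf_min = maf_min))
  }
  hh <- if (identical(population, "ALL")) sim else hap_subset_pops(sim, population)
  switch(metric,
         tajimas_d = tajimas_d(hh),
         h12 = h12(hh),
         fst_wc = wc_fst(sim),
         stop("unknown metric: ", metric))
}

#' Build a neutral null distribution for one metric
#'
#' Simulates `replicates` independent neutral segments (per-replicate seed
#' streams derived from `seed`, see [derive_seeds]) and computes the metric
#' on each exactly as the scan does (for nS_L: the maximum |unstandardised
#' nS_L| over the simulated window after the MAF filter, within the given
#' population).  Undefined replicates are counted and excluded.
#'
#' @param model a [demographic_model].
#' @param n_haps haplotype counts per population (see [simulate_neutral]).
#' @param params list with `length_bp` and `recomb_rate`
#'   (see [tissue_null_params]).
#' @param metric one of `"tajimas_d"`, `"fst_wc"`, `"h12"`, `"nsl"`.
#' @param population `"ALL"` for pooled statistics, a single population
#'   label for nS_L.
#' @param replicates number of simulations.
#' @param seed master seed.
#' @param tissue optional tissue tag stored with the distribution.
#' @param maf_min MAF cutoff used for nS_L.
#' @return an object of class `null_distribution`: `values`,
#'   `n_undefined`, `metric`, `population`, `tissue` and a `params` record
#'   (length, rate, replicates, seed, model hash) that reproduces the
#'   distribution.
#' @export
build_null <- function(model, n_haps, params, metric,
                       population = "ALL", replicates, seed, tissue = NA,
                       maf_min = 0.01) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (metric == "fst_wc" && !identical(population, "ALL"))
    stop("fst_wc is defined only for population = 'ALL'")
  if (metric == "nsl" && identical(population, "ALL"))
    stop("nsl requires a single population")
  seeds <- derive_seeds(seed, replicates)
  vals <- numeric(0)
  n_undef <- 0L
  for (k in seq_len(replicates)) {
    sim <- simulate_neutral(model, n_haps, params$length_bp,
                            params$recomb_rate, seed = seeds[k])
    v <- null_metric_value(sim, metric, population, maf_min)$value
    if (is.na(v)) n_undef <- n_undef + 1L else vals <- c(vals, v)
  }
  new_null_distribution(vals, n_undef, metric, population, tissue,
                        params, replicates, seed, model)
}

new_null_distribution <- function(values, n_undefined, metric, population,
                                  tissue, params, replicates, seed, model) {
  structure(list(metric = metric, population = population, tissue = tissue,
                 values = values, n_undefined = n_undefined,
                 params = list(length_bp = params$length_bp,
                               recomb_rate = params$recomb_rate,
                               replicates = replicates, seed = seed,
                               model_hash = object_hash(unclass(model)))),
            class = "null_distribution")
}

#' Build null distributions for several metrics from shared simulations
#'
#' The pooled statistics (Tajima's D, F_ST, H12) are computed on the same
#' simulated replicate set, mirroring the usual practice of reusing one
#' batch of neutral sequences for all frequency-spectrum statistics; nS_L
#' (per population) gets its own simulations because it uses a different
#' segment length and recombination rate.
#'
#' @inheritParams build_null
#' @param metrics character vector of metric names; `"nsl"` entries must be
#'   given as `list(metric = "nsl", population = <pop>)` via the
#'   `nsl_populations` argument instead.
#' @param nsl_populations populations for which per-population nS_L nulls
#'   are built (with `nsl_params`); NULL to skip.
#' @param nsl_params params for the nS_L simulations.
#' @param nsl_replicates replicate count for nS_L.
#' @return named list of `null_distribution` objects (`tajimas_d`,
#'   `fst_wc`, `h12`, `nsl.<pop>`, ...).
#' @export
build_null_set <- function(model, n_haps, params,
                           metrics = c("tajimas_d", "fst_wc", "h12"),
                           replicates, seed, tissue = NA,
                           nsl_populations = NULL, nsl_params = NULL,
                           nsl_replicates = replicates, maf_min = 0.01) {
  out <- list()
  if (length(metrics)) {
    seeds <- derive_seeds(seed, replicates)
    acc <- lapply(metrics, function(m) numeric(0))
    names(acc) <- metrics
    undef <- stats::setNames(integer(length(metrics)), metrics)
    for (k in seq_len(replicates)) {
      sim <- simulate_neutral(model, n_haps, params$length_bp,
                              params$recomb_rate, seed = seeds[k])
      for (m in metrics) {
        v <- null_metric_value(sim, m, "ALL", maf_min)$value
        if (is.na(v)) undef[m] <- undef[m] + 1L else acc[[m]] <- c(acc[[m]], v)
      }
    }
    for (m in metrics)
      out[[m]] <- new_null_distribution(acc[[m]], undef[[m]], m, "ALL",
                                        tissue, params, replicates, seed, model)
  }
  if (length(nsl_populations)) {
    if (is.null(nsl_params)) stop("nsl_params required for nS_L nulls")
    seeds <- derive_seeds(seed + 1L, nsl_replicates)
    acc <- lapply(nsl_populations, function(p) numeric(0))
    names(acc) <- nsl_populations
    undef <- stats::setNames(integer(length(nsl_populations)), nsl_populations)
    for (k in seq_len(nsl_replicates)) {
      sim <- simulate_neutral(model, n_haps, nsl_params$length_bp,
                              nsl_params$recomb_rate, seed = seeds[k])
      for (p in nsl_populations) {
        v <- null_metric_value(sim, "nsl", p, maf_min)$value
        if (is.na(v)) undef[p] <- undef[p] + 1L else acc[[p]] <- c(acc[[p]], v)
      }
    }
    for (p in nsl_populations)
      out[[paste0("nsl.", p)]] <-
        new_null_distribution(acc[[p]], undef[[p]], "nsl", p, tissue,
                              nsl_params, nsl_replicates, seed + 1L, model)
  }
  out
}

#' Empirical p-value against a neutral null
#'
#' `p` is the proportion of defined simulated values equal to or more
#' extreme than the observed value (upper tail: `sim >= obs`; lower tail:
#' `sim <= obs`).  A p-value of 0 is reported together with a
#' below-resolution flag (the null can only resolve down to `1/N`).
#'
#' @param observed observed metric value (numeric, or a metric result list
#'   with a `value` field).
#' @param null a `null_distribution` (or bare numeric vector of null
#'   values).
#' @param tail `"upper"` or `"lower"`.
#' @param alpha significance cutoff (default 0.05); significant iff
#'   `p < alpha`.
#' @return list with `p`, `significant`, `tail`, `n_null`, `resolution`
#'   (`1/N`) and `below_resolution`.
#' @export
empirical_p <- function(observed, null, tail = c("upper", "lower"),
                        alpha = 0.05) {
  tail <- match.arg(tail)
  if (is.list(observed)) observed <- observed$value
  vals <- if (inherits(null, "null_distribution")) null$values else null
  if (length(vals) == 0) stop("null distribution is empty")
  if (is.na(observed))
    return(list(p = NA_real_, significant = FALSE, tail = tail,
                n_null = length(vals), resolution = 1 / length(vals),
                below_resolution = FALSE))
  p <- if (tail == "upper") mean(vals >= observed) else mean(vals <= observed)
  list(p = p, significant = p < alpha, tail = tail, n_null = length(vals),
       resolution = 1 / length(vals), below_resolution = p == 0)
}
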