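small_nh <- c(AFR = 24, EUR = 20, EAS = 20)
small_cfg <- function(...) cohort_config(n_regions = 8, n_tissues = 3,
                                         n_organ_systems = 2, ...)

test_that("cohort generation is deterministic and internally consistent", {
  c1 <- generate_cohort(n_haps = small_nh, config = small_cfg(), seed = 7)
  c2 <- generate_cohort(n_haps = small_nh, config = small_cfg(), seed = 7)
  expect_identical(c1$haps$alleles, c2$haps$alleles)
  expect_identical(c1$haps$positions, c2$haps$positions)
  expect_identical(c1$regions$start, c2$regions$start)
  expect_identical(c1$map$cumulative_cM, c2$map$cumulative_cM)
  c3 <- generate_cohort(n_haps = small_nh, config = small_cfg(), seed = 8)
  expect_false(identical(c1$haps$positions, c3$haps$positions))

  # all-neutral config has an all-neutral truth table
  expect_true(all(c1$truth$mode == "neutral"))
  expect_true(all(!c1$truth$swept))
  expect_equal(nrow(c1$truth), 8L)
  # region lengths live in the configured clamp
  len <- c1$regions$end - c1$regions$start
  expect_true(all(len >= 200 & len <= 1000))
})

test_that("written cohort files re-read to the in-memory objects", {
  co <- generate_cohort(n_haps = small_nh, config = small_cfg(), seed = 19)
  od <- file.path(tempdir(), "cohort_roundtrip")
  unlink(od, recursive = TRUE)
  paths <- write_cohort(co, od)
  h <- read_vcf(paths["vcf"], read_panel(paths["panel"]))
  expect_identical(h$alleles, co$haps$alleles)
  expect_identical(h$positions, co$haps$positions)
  expect_identical(h$hap_pop, co$haps$hap_pop)
  rs <- read_bed_regions(paths["bed"], read_tissue_map(paths["tissue_map"]),
                         read_organ_map(paths["organ_map"]))
  expect_identical(rs$start, co$regions$start)
  expect_identical(rs$end, co$regions$end)
  expect_identical(rs$tissues, co$regions$tissues)
  gm <- read_genetic_map(paths["genetic_map"])
  expect_equal(gm$positions, co$map$positions)
  expect_equal(gm$rate, co$map$rate, tolerance = 1e-10)

  # byte determinism of the emitted files
  od2 <- file.path(tempdir(), "cohort_roundtrip2")
  unlink(od2, recursive = TRUE)
  co2 <- generate_cohort(n_haps = small_nh, config = small_cfg(), seed = 19)
  paths2 <- write_cohort(co2, od2)
  for (k in names(paths))
    expect_identical(readLines(paths[[k]]), readLines(paths2[[k]]))
})

test_that("a fixed hard sweep forces per-population haplotype identity", {
  cfg <- small_cfg(sweep_fraction = 0.5, sweep_mode = "hard",
                   carrier_fraction = 1.0, target_pops = "EUR")
  co <- generate_cohort(n_haps = small_nh, config = cfg, seed = 23)
  swept <- co$truth$region_id[co$truth$swept]
  expect_gt(length(swept), 0)
  for (rid in swept) {
    rg <- co$regions[co$regions$region_id == rid, ]
    hr <- hap_window(co$haps, rg$start, rg$end)
    if (n_sites(hr) == 0) next
    v <- h12(hap_subset_pops(hr, "EUR"))$value
    expect_equal(v, 1.0)
    # untargeted populations keep their diversity
    expect_gt(nucleotide_diversity(hap_subset_pops(hr, "AFR")), 0)
  }
})

test_that("planted sweeps skew Tajima's D down and H12 up", {
  nh <- c(AFR = 40, EUR = 30, EAS = 30)
  cfg <- cohort_config(n_regions = 40, n_tissues = 2, n_organ_systems = 1,
                       sweep_fraction = 0.5, sweep_mode = "hard",
                       carrier_fraction = 0.8)
  co <- generate_cohort(n_haps = nh, config = cfg, seed = 29)
  vals <- lapply(seq_len(nrow(co$regions)), function(k) {
    rg <- co$regions[k, ]
    hr <- hap_window(co$haps, rg$start, rg$end)
    c(d = tajimas_d(hr)$value, h = h12(hr)$value)
  })
  d <- vapply(vals, `[[`, numeric(1), "d")
  h <- vapply(vals, `[[`, numeric(1), "h")
  sw <- co$truth$swept
  expect_lt(mean(d[sw], na.rm = TRUE), mean(d[!sw], na.rm = TRUE))
  expect_gt(mean(h[sw], na.rm = TRUE), mean(h[!sw], na.rm = TRUE))
})

test_that("soft sweeps plant the configured number of founder classes", {
  cfg <- small_cfg(sweep_fraction = 1, sweep_mode = "soft", n_founders = 3,
                   carrier_fraction = 1.0)
  co <- generate_cohort(n_haps = small_nh, config = cfg, seed = 31)
  expect_true(all(co$truth$n_founders[co$truth$swept] == 3L))
  rid <- co$truth$region_id[co$truth$swept][1]
  rg <- co$regions[co$regions$region_id == rid, ]
  hr <- hap_window(co$haps, rg$start, rg$end)
  if (n_sites(hr) > 0) {
    key <- apply(hr$alleles, 1, paste, collapse = "")
    expect_lte(length(unique(key)), 3L)
  }
})

test_that("annotation planting hits exactly the designated regions", {
  co <- generate_cohort(n_haps = small_nh, config = small_cfg(), seed = 37)
  a0 <- generate_annotations(co$regions, planted_overlap_fraction = 0,
                             seed = 41)
  expect_false(any(overlap_any(co$regions, a0$annotation)))
  a1 <- generate_annotations(co$regions, planted_overlap_fraction = 1,
                             seed = 41)
  expect_true(all(overlap_any(co$regions, a1$annotation)))
  amid <- generate_annotations(co$regions, planted_overlap_fraction = 0.5,
                               seed = 43)
  expect_equal(overlap_any(co$regions, amid$annotation),
               amid$truth$planted_overlap)

  # catalog SNPs land on real sites inside their regions
  ac <- generate_annotations(co$regions, planted_overlap_fraction = 0,
                             seed = 47, h = co$haps, catalog_fraction = 1)
  expect_gt(nrow(ac$catalog), 0)
  expect_true(all(ac$catalog$position %in% co$haps$positions))
})
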