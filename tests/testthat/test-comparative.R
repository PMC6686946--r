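test_that("tissue-breadth classification reproduces printed organ-system shares", {
  omap <- toy_organ_map(c("t1", "t2", "t3"), c("os1", "os1", "os2"))
  rs <- region_set("chr1", c(0, 100, 200), c(50, 180, 260), c("a", "b", "c"),
                   list("t1", c("t1", "t2"), c("t1", "t3")), omap)
  cb <- classify_breadth(rs)
  expect_equal(cb$labels$breadth,
               c("tissue_specific", "tissue_broad", "tissue_broad"))
  expect_equal(cb$labels$n_organ_systems, c(1L, 1L, 2L))
  expect_true(all(cb$labels$n_organ_systems <= cb$labels$n_tissues))

  # multiplicity shares from the printed FANTOM-scale counts
  counts <- c(833, 2659, 1224, 685, 416, 305, 193, 187, 118, 137)
  omap10 <- toy_organ_map(c(paste0("t", 1:10), "t1b"),
                          c(paste0("os", 1:10), "os1"))
  tiss <- unlist(lapply(seq_along(counts), function(k)
    rep(list(if (k == 1) c("t1", "t1b") else paste0("t", seq_len(k))),
        counts[k])), recursive = FALSE)
  n <- sum(counts)
  rs10 <- region_set("chr1", seq_len(n) * 100, seq_len(n) * 100 + 50,
                     sprintf("e%04d", seq_len(n)), tiss, omap10)
  sm <- classify_breadth(rs10)$summary
  expect_equal(sm$percent[sm$n_organ_systems == 1], 12.33)
  expect_equal(sm$percent[sm$n_organ_systems == 2], 39.35)
  expect_error(classify_breadth(rs10[0, ]), "empty")
})

test_that("KS statistic equals the brute-force ECDF gap", {
  expect_equal(ks_two_sided(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sided(1:5, 11:15)$statistic, 1)
  expect_equal(ks_two_sided(c(1, 2, 3, 4), c(2, 3, 4, 5))$statistic, 0.25)
  set.seed(9)
  for (rep in 1:50) {
    a <- sample(1:20, sample(3:30, 1), replace = TRUE)
    b <- rnorm(sample(3:30, 1))
    k1 <- ks_two_sided(a, b)
    expect_equal(k1$statistic, oracle_ks_stat(a, b), tolerance = 1e-12)
    # symmetry and invariance under a strictly monotone transform
    expect_equal(ks_two_sided(b, a)$statistic, k1$statistic)
    f <- function(x) exp(x / 10)
    expect_equal(ks_two_sided(f(a), f(b))$statistic, k1$statistic)
  }
  expect_error(ks_two_sided(numeric(0), 1:3), "non-empty")
})

test_that("pairwise tests cover all group pairs with a Bonferroni family", {
  set.seed(41)
  tab <- data.frame(region_id = sprintf("r%03d", 1:120),
                    tissue = rep(c("a", "b", "c"), each = 40),
                    metric = "tajimas_d", population = "ALL",
                    value = rep(rnorm(40), 3),   # identical distributions
                    p_empirical = NA_real_, significant = NA,
                    reason = NA_character_, stringsAsFactors = FALSE)
  pw <- pairwise_tissue_tests(tab, "tajimas_d", grouping = "tissue")
  expect_equal(nrow(pw), 3L)
  expect_equal(unique(pw$m), 3L)
  expect_true(all(pw$p_adjusted == 1))           # identical groups
  expect_true(all(pw$p_adjusted >= pw$p_raw))
  expect_true(sum(pw$p_adjusted < 0.05) <= sum(pw$p_raw < 0.05))

  two <- tab[tab$tissue != "c", ]
  pw2 <- pairwise_tissue_tests(two, "tajimas_d", grouping = "tissue")
  expect_equal(pw2$p_adjusted, pw2$p_raw)        # m = 1

  # 41 groups give choose(41, 2) = 820 tests
  set.seed(42)
  big <- data.frame(region_id = sprintf("r%04d", 1:(41 * 10)),
                    tissue = rep(sprintf("t%02d", 1:41), each = 10),
                    metric = "h12", population = "ALL",
                    value = runif(410), p_empirical = NA_real_,
                    significant = NA, reason = NA_character_,
                    stringsAsFactors = FALSE)
  pw3 <- pairwise_tissue_tests(big, "h12", grouping = "tissue")
  expect_equal(nrow(pw3), 820L)
  expect_equal(unique(pw3$m), 820L)
})

test_that("breadth grouping tests specific vs broad within each tissue", {
  omap <- toy_organ_map(c("t1", "t2"))
  n <- 40
  rs <- region_set("chr1", seq_len(n) * 100, seq_len(n) * 100 + 50,
                   sprintf("r%02d", 1:n),
                   c(rep(list("t1"), 10), rep(list(c("t1", "t2")), 10),
                     rep(list("t2"), 10), rep(list(c("t2", "t1")), 10)),
                   omap)
  set.seed(5)
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(region_id = rs$region_id[i], tissue = unlist(rs$tissues[i]),
               metric = "h12", population = "ALL", value = runif(1),
               p_empirical = NA_real_, significant = NA,
               reason = NA_character_, stringsAsFactors = FALSE)))
  bt <- pairwise_tissue_tests(rows, "h12", grouping = "breadth", regions = rs)
  expect_equal(sort(bt$tissue), c("t1", "t2"))
  expect_equal(unique(bt$m), 2L)
  expect_true(all(bt$n_a == 10 & bt$n_b == 20))  # broad counted in both tissues
})

test_that("group ranking orders by the chosen summary with min-ties", {
  tab <- data.frame(region_id = sprintf("r%02d", 1:6),
                    tissue = rep(c("A", "B"), each = 3),
                    metric = "fst_wc", population = "ALL",
                    value = c(1, 2, 3, 4, 5, 6),
                    p_empirical = 0.5, significant = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  rk <- rank_groups(tab, "fst_wc", by = "median")
  expect_equal(rk$group, c("B", "A"))
  expect_equal(rk$value, c(5, 2))
  expect_equal(rk$rank, c(1L, 2L))

  tab$significant <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  rk2 <- rank_groups(tab, "fst_wc", by = "proportion_significant")
  expect_equal(rk2$rank, c(1L, 1L))              # tie shares the smaller rank
  single <- rank_groups(tab[tab$tissue == "A", ], "fst_wc")
  expect_equal(single$rank, 1L)
})

test_that("interval overlap respects half-open adjacency", {
  omap <- toy_organ_map("t")
  rs <- region_set("chr1", 100, 200, "r1", list("t"), omap)
  ov <- function(s, e) overlap_any(rs, data.frame(chrom = "chr1",
                                                  start = s, end = e))
  expect_true(ov(150, 160))
  expect_false(ov(200, 300))   # adjacent half-open intervals do not touch
  expect_true(ov(199, 500))
  expect_false(ov(0, 100))

  set.seed(13)
  rs2 <- region_set("chr1", (1:30) * 100, (1:30) * 100 + sample(10:90, 30, TRUE),
                    sprintf("q%02d", 1:30), rep(list("t"), 30), omap)
  ann <- data.frame(chrom = "chr1",
                    start = sample(0:3200, 40, TRUE))
  ann$end <- ann$start + sample(5:200, 40, TRUE)
  expect_equal(overlap_any(rs2, ann), oracle_overlap(rs2, ann))
})

test_that("Yates chi-squared matches its expected-counts form", {
  r1 <- chi2_yates(10, 20, 30, 40)
  expect_equal(r1$statistic, 100 * (abs(10 * 40 - 20 * 30) - 50)^2 /
                 (30 * 70 * 40 * 60), tolerance = 1e-9)
  expect_equal(chi2_yates(10, 20, 20, 40)$statistic, 0)  # ad = bc clamps to 0
  expect_equal(chi2_yates(0, 10, 0, 20)$reason, "zero_margin")
  set.seed(17)
  for (rep in 1:50) {
    m <- matrix(sample(1:50, 4, TRUE), 2, 2)
    r <- chi2_yates(m)
    expect_equal(r$statistic, oracle_chi2(m), tolerance = 1e-9)
    expect_equal(chi2_yates(t(m))$statistic, r$statistic, tolerance = 1e-12)
    expect_equal(r$p, stats::pchisq(r$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("haplotype r2 and complete-LD expansion use the strict threshold", {
  x <- c(0, 0, 1, 1, 0, 1)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 1 - x), 1)
  # independence: p_AB = p_A p_B
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  expect_equal(ld_r2(a, b), 0)
  expect_true(is.na(ld_r2(x, rep(0, 6))))
  set.seed(23)
  for (rep in 1:50) {
    u <- rbinom(20, 1, 0.5); v <- rbinom(20, 1, 0.5)
    if (var(u) == 0 || var(v) == 0) next
    expect_equal(ld_r2(u, v), oracle_r2(u, v), tolerance = 1e-9)
  }

  # duplicate column 10 kb away is pulled in; an r2 < 1 partner is not
  A <- cbind(x, x, c(0, 1, 1, 1, 0, 1), rbinom(6, 1, 0.5))
  repeat { A[, 4] <- rbinom(6, 1, 0.5); if (var(A[, 4]) > 0) break }
  h <- hap_matrix(A, c(500L, 10500L, 11000L, 2000000L),
                  hap_pop = rep("P1", 6), sample_ids = c("a", "b", "c"))
  got <- expand_complete_ld(500, h, window_bp = 1e6)
  expect_true(10500 %in% got)
  expect_false(11000 %in% got)                   # r2 < 1 partner stays out
  expect_false(2000000 %in% got)                 # outside the window
  expect_equal(expand_complete_ld(11000, h, window_bp = 100), 11000L)
})

test_that("catalog hits match by position and flag LD-only matches", {
  omap <- toy_organ_map("t")
  rs <- region_set("chr1", 1000, 1400, "r1", list("t"), omap)
  x <- c(0, 1, 1, 0, 1, 0)
  A <- cbind(x, rbinom(6, 1, 0.5), x)
  h <- hap_matrix(A, c(1200L, 1300L, 5000L), hap_pop = rep("P1", 6),
                  sample_ids = c("a", "b", "c"))
  catalog <- data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = "chr1",
                        position = c(1200L, 5000L, 99999L),
                        trait = c("height", "asthma", "bmi"),
                        stringsAsFactors = FALSE)
  class(catalog) <- c("snp_catalog", "data.frame")
  res <- catalog_hits(rs, h, catalog, expand_ld = TRUE)
  expect_equal(sort(res$hits$rsid), c("rs1", "rs2"))
  expect_equal(res$hits$via_ld[res$hits$rsid == "rs1"], FALSE)
  expect_equal(res$hits$via_ld[res$hits$rsid == "rs2"], TRUE)
  expect_true(res$overlap[["r1"]])
  res0 <- catalog_hits(rs, h, catalog[0, ], expand_ld = FALSE)
  expect_equal(nrow(res0$hits), 0L)
  expect_false(res0$overlap[["r1"]])
})
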