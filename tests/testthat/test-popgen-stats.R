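test_that("nucleotide diversity matches hand counts and edge cases", {
  expect_equal(nucleotide_diversity(make_haps(c("000", "111"))), 3)
  expect_equal(nucleotide_diversity(make_haps(c("000", "000"))), 0)
  expect_equal(nucleotide_diversity(
    make_haps(c("0000", "0000", "1111", "1111"))), 16 / 6)
  expect_error(hap_matrix(matrix(0L, 1, 2), c(5L, 9L), hap_pop = "P1",
                          sample_ids = "a"), "2 x individual")
  h0 <- hap_matrix(matrix(integer(0), 0, 2), c(5L, 9L),
                   hap_pop = character(0), sample_ids = character(0))
  v <- nucleotide_diversity(h0)
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "insufficient_haplotypes")
})

test_that("Tajima's D follows the constant-based form and its sign property", {
  h <- make_haps(c("0000", "0000", "1111", "1111"))
  # independent evaluation of the 1989 constants at n = 4, S = 4, pi = 16/6
  n <- 4; S <- 4; pi <- 16 / 6
  a1 <- 1 + 1/2 + 1/3; a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(h)$value, expected, tolerance = 1e-12)

  mono <- tajimas_d(make_haps(c("0000", "0000", "0000", "0000")))
  expect_true(is.na(mono$value))
  expect_equal(mono$reason, "no_segregating_sites")
  expect_equal(tajimas_d(make_haps(c("01", "10")))$reason,
               "insufficient_haplotypes")

  # singleton-heavy configuration sits below a balanced one at equal S
  singl <- make_haps(c("1000", "0100", "0010", "0001", "0000", "0000"))
  balan <- make_haps(c("1111", "1111", "1111", "0000", "0000", "0000"))
  expect_lt(tajimas_d(singl)$value, tajimas_d(balan)$value)
})

test_that("Weir-Cockerham F_ST hits its boundary cases", {
  # two populations fixed for alternative alleles
  h <- make_haps(c("111", "111", "111", "111", "000", "000", "000", "000"),
                 pops = rep(c("A", "B"), each = 4))
  expect_equal(wc_fst(h)$value, 1)
  # identical genotype counts in every population
  h2 <- make_haps(rep(c("01", "10"), 4), pops = rep(c("A", "B"), each = 4))
  expect_lte(wc_fst(h2)$value, 0)
  expect_error(wc_fst(make_haps(c("01", "10"), pops = c("A", "A")),
                      pops = c("A", "B")), "absent")
})

test_that("F_ST agrees with the site-wise variance-component oracle", {
  set.seed(404)
  for (rep in 1:100) {
    h <- rand_haps(n = 2 * sample(3:6, 1) * 3, S = sample(1:10, 1), npop = 3)
    a <- wc_fst(h)$value
    b <- oracle_fst(h)
    if (is.na(a)) expect_true(is.na(b)) else
      expect_equal(a, b, tolerance = 1e-9)
  }
  # two-population collapse checked against the same oracle
  set.seed(405)
  for (rep in 1:30) {
    h <- rand_haps(n = 2 * sample(3:8, 1) * 2, S = sample(1:8, 1), npop = 2)
    a <- wc_fst(h)$value
    if (!is.na(a)) expect_equal(a, oracle_fst(h), tolerance = 1e-9)
  }
})

test_that("H12 matches the merged-class formula and its invariances", {
  expect_equal(h12(make_haps(c("01", "01", "01", "01")))$value, 1)
  expect_equal(h12(make_haps(c("00", "00", "11", "11")))$value, 1)
  # classes at (0.4, 0.3, 0.2, 0.1)
  h <- make_haps(c(rep("000", 4), rep("011", 3), rep("101", 2), "110"))
  expect_equal(h12(h)$value, 0.7^2 + 0.2^2 + 0.1^2)
  expect_equal(h12(make_haps(c("0", "0")))$reason, NA_character_)
  h0 <- hap_matrix(matrix(integer(0), 4, 0), integer(0),
                   hap_pop = rep("P1", 4), sample_ids = c("a", "b"))
  expect_equal(h12(h0)$reason, "no_segregating_sites")

  set.seed(77)
  for (rep in 1:50) {
    h <- rand_haps(n = 2 * sample(2:6, 1), S = sample(1:8, 1))
    v <- h12(h)$value
    expect_equal(v, oracle_h12(h), tolerance = 1e-9)
    expect_gt(v, 0); expect_lte(v, 1)
    # invariant to row order and site order (single-population fixture)
    expect_equal(h12(hap_matrix(h$alleles[sample(nrow(h$alleles)), ],
                                h$positions, hap_pop = h$hap_pop,
                                sample_ids = h$sample_ids))$value, v,
                 tolerance = 1e-12)
    perm_c <- sample(ncol(h$alleles))
    expect_equal(h12(hap_matrix(h$alleles[, perm_c, drop = FALSE],
                                sort(h$positions), hap_pop = h$hap_pop,
                                sample_ids = h$sample_ids))$value, v,
                 tolerance = 1e-12)
  }
})

test_that("nS_L matches pair/tract enumeration and its symmetries", {
  # symmetric configuration: ancestral and derived tract structures mirror
  h <- make_haps(c("000", "100", "010", "011"))
  expect_equal(nsl_site(h, 2), 0)

  # 6 x 5 hand-enumerable instance
  set.seed(11)
  A <- matrix(c(0,0,0,1,1,1,
                0,1,0,1,0,1,
                1,1,0,0,1,0,
                0,0,1,1,0,1,
                1,0,1,0,1,0), 6, 5)
  h65 <- hap_matrix(A, 1:5 * 3L, hap_pop = rep("P1", 6),
                    sample_ids = c("a", "b", "c"))
  expect_equal(nsl_site(h65, 3), oracle_nsl(A, 3), tolerance = 1e-12)

  # long identical derived block vs maximally diverse ancestral class
  hd <- make_haps(c("010101000", "101010000", "011011000",
                    "000100111", "000100111", "000100111"))
  expect_lt(nsl_site(hd, 7), 0)

  # label swap negates the statistic
  set.seed(21)
  for (rep in 1:100) {
    n <- 2 * sample(2:6, 1); S <- sample(2:12, 1)
    h <- rand_haps(n, S)
    f <- sample(S, 1)
    v <- nsl_site(h, f)
    expect_equal(v, oracle_nsl(h$alleles, f), tolerance = 1e-9)
    hswap <- hap_matrix(1L - h$alleles, h$positions, hap_pop = h$hap_pop,
                        sample_ids = h$sample_ids)
    vswap <- nsl_site(hswap, f)
    if (is.na(v)) expect_true(is.na(vswap)) else expect_equal(vswap, -v)
  }
})

test_that("region-level nS_L takes the max |score| over valid focal sites", {
  A <- matrix(c(0,0,0,1,1,1,
                0,1,0,1,0,1,
                1,1,0,0,1,0,
                0,0,1,1,0,1,
                1,0,1,0,1,0), 6, 5)
  h <- hap_matrix(A, c(120L, 140L, 160L, 180L, 200L),
                  hap_pop = rep("P1", 6), sample_ids = c("a", "b", "c"))
  per_site <- vapply(1:5, function(f) oracle_nsl(A, f), numeric(1))
  res <- nsl_region(h, start = 100, end = 210, population = "P1",
                    flank_bp = 0, maf_min = 0.01)
  expect_equal(res$value, max(abs(per_site), na.rm = TRUE), tolerance = 1e-9)

  # single valid focal site: the max is that site's |score|
  expect_equal(
    nsl_region(h, start = 100, end = 210, population = "P1", flank_bp = 0,
               maf_min = 0.01)$value >= 0, TRUE)

  # MAF gate: a 1/102 singleton falls below the 0.01 cutoff -> no focal site
  h2 <- make_haps(c("100000", "000000", rep("000000", 100)))
  res2 <- nsl_region(h2, start = 0, end = 1000, population = "P1",
                     flank_bp = 0, maf_min = 0.01)
  expect_true(is.na(res2$value))
  expect_equal(res2$reason, "no_valid_focal_sites")
})

test_that("pi and Watterson's estimator agree on neutral replicates", {
  m <- constant_model(5000, mu = 5 / (4 * 5000 * 1e4))
  set.seed(99)
  Ss <- pis <- numeric(1000)
  for (k in 1:1000) {
    h <- simulate_neutral(m, c(POP = 12), 1e4, recomb_rate = 0)
    Ss[k] <- n_sites(h)
    pis[k] <- nucleotide_diversity(h)
  }
  theta_w <- mean(Ss) / sum(1 / (1:11))
  expect_lt(abs(theta_w - mean(pis)) / mean(pis), 0.05)
})
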