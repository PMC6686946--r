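test_that("demographic model validation enforces the event-time ordering", {
  expect_s3_class(ooa_gravel_model(), "demographic_model")
  expect_error(demographic_model(T_AF = 100), "T_AF > T_B")
  expect_error(demographic_model(N_AF = -1), "positive")
  expect_error(demographic_model(m_AF_B = 1.5), "migration")
  f <- tempfile(fileext = ".json")
  write_model_config(ooa_gravel_model(), f)
  m2 <- read_model_config(f)
  expect_equal(unclass(m2), unclass(ooa_gravel_model()))
})

test_that("simulated segregating sites and diversity match Watterson theory", {
  # theta = 4 N mu L = 10, n = 20 haplotypes, constant size
  N <- 10000; L <- 1e5
  m <- constant_model(N, mu = 10 / (4 * N * L))
  set.seed(11)
  S <- pis <- numeric(1000)
  for (k in 1:1000) {
    h <- simulate_neutral(m, c(POP = 20), L, recomb_rate = 0)
    S[k] <- n_sites(h); pis[k] <- nucleotide_diversity(h)
  }
  expect_lt(abs(mean(S) / (10 * sum(1 / (1:19))) - 1), 0.05)
  expect_lt(abs(mean(pis) / 10 - 1), 0.05)
})

test_that("deeper splits raise F_ST in paired simulation runs", {
  deep <- demographic_model(T_AF = 8000, T_B = 4000, T_EU_AS = 3000,
                            m_AF_B = 0, m_AF_EU = 0, m_AF_AS = 0,
                            m_EU_AS = 0)
  shallow <- demographic_model(T_AF = 8000, T_B = 600, T_EU_AS = 300,
                               m_AF_B = 0, m_AF_EU = 0, m_AF_AS = 0,
                               m_EU_AS = 0)
  nh <- c(AFR = 20, EUR = 20, EAS = 20)
  fst_of <- function(model, seeds) {
    v <- vapply(seeds, function(s)
      wc_fst(simulate_neutral(model, nh, 5000, 1e-8, seed = s))$value,
      numeric(1))
    mean(v, na.rm = TRUE)
  }
  seeds <- derive_seeds(271, 500)
  expect_gt(fst_of(deep, seeds), fst_of(shallow, seeds))
})

test_that("null distributions are reproducible and respect metric ranges", {
  m <- constant_model(8000, mu = 2e-7)
  params <- list(length_bp = 400, recomb_rate = 1e-8)
  n1 <- build_null(m, c(POP = 20), params, "h12", "ALL",
                   replicates = 10, seed = 5)
  n2 <- build_null(m, c(POP = 20), params, "h12", "ALL",
                   replicates = 10, seed = 5)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values > 0 & n1$values <= 1))
  expect_equal(length(n1$values) + n1$n_undefined, 10L)
  expect_error(build_null(m, c(POP = 20), params, "fst_wc", "POP",
                          replicates = 2, seed = 1), "ALL")
  expect_error(build_null(m, c(POP = 20), params, "nsl", "ALL",
                          replicates = 2, seed = 1), "single population")
})

test_that("neutral Tajima's D is centred near zero", {
  N <- 10000; L <- 1e5
  m <- constant_model(N, mu = 10 / (4 * N * L))
  nd <- build_null(m, c(POP = 20), list(length_bp = L, recomb_rate = 0),
                   "tajimas_d", "ALL", replicates = 1000, seed = 33)
  expect_lt(abs(mean(nd$values)), 0.15)
})

test_that("per-replicate seed streams are prefix-stable", {
  expect_identical(derive_seeds(42, 5), derive_seeds(42, 10)[1:5])
  expect_false(any(derive_seeds(42, 100) == derive_seeds(43, 100)))
  expect_true(all(derive_seeds(2^31 - 5, 1000) > 0))
})

test_that("empirical p-values count ties and respect the alpha cutoff", {
  nullv <- 1:10
  e1 <- empirical_p(10, nullv, tail = "upper", alpha = 0.05)
  expect_equal(e1$p, 0.1)
  expect_false(e1$significant)
  e2 <- empirical_p(11, nullv, tail = "upper")
  expect_equal(e2$p, 0)
  expect_true(e2$below_resolution)
  expect_equal(e2$resolution, 0.1)
  e3 <- empirical_p(5, nullv, tail = "lower")
  expect_equal(e3$p, 0.5)
  eNA <- empirical_p(NA_real_, nullv, tail = "upper")
  expect_true(is.na(eNA$p)); expect_false(eNA$significant)
  # p is non-increasing in the observed value for the upper tail
  obs <- sort(runif(50, 0, 12))
  ps <- vapply(obs, function(o) empirical_p(o, nullv, "upper")$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("feeding neutral draws back through empirical_p is calibrated", {
  m <- constant_model(8000, mu = 8 / (4 * 8000 * 2e4))
  params <- list(length_bp = 2e4, recomb_rate = 0)
  nd <- build_null(m, c(POP = 20), params, "tajimas_d", "ALL",
                   replicates = 400, seed = 61)
  obs <- build_null(m, c(POP = 20), params, "tajimas_d", "ALL",
                    replicates = 1000, seed = 62)
  calls <- vapply(obs$values, function(o)
    empirical_p(o, nd, tail = "lower", alpha = 0.05)$significant, logical(1))
  expect_gt(mean(calls), 0.03)
  expect_lt(mean(calls), 0.07)
})

test_that("the default cohort is 1000-Genomes sized", {
  nh <- eval(formals(run_synth)$n_haps)
  expect_equal(nh, c(AFR = 2 * 661, EUR = 2 * 503, EAS = 2 * 504))
})
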