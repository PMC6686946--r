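# Fixture builders and independent brute-force oracles.  The oracles are
# deliberately naive (scalar loops, direct textbook formulas) so they share
# no code path with the package implementations they check.

make_haps <- function(strings, pops = NULL, positions = NULL, chrom = "chr1") {
  A <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  if (is.null(pops)) pops <- rep("P1", nrow(A))
  if (is.null(positions)) positions <- seq_len(ncol(A)) * 10L
  hap_matrix(A, positions, chrom = chrom, hap_pop = pops,
             sample_ids = sprintf("s%02d", seq_len(nrow(A) / 2)))
}

rand_haps <- function(n, S, npop = 1) {
  repeat {
    A <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    if (all(colSums(A) > 0 & colSums(A) < n)) break
  }
  pops <- rep(paste0("P", seq_len(npop)), length.out = n / 2)[
    rep(seq_len(n / 2), each = 2)]
  pops <- sort(pops)  # keep row pairs contiguous per population
  hap_matrix(A, seq_len(S) * 7L, hap_pop = pops,
             sample_ids = sprintf("s%02d", seq_len(n / 2)))
}

oracle_pi <- function(h) {
  A <- h$alleles
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n))
    tot <- tot + sum(A[i, ] != A[j, ])
  tot / (n * (n - 1) / 2)
}

oracle_tajd <- function(h) {
  A <- h$alleles
  n <- nrow(A)
  seg <- apply(A, 2, function(x) length(unique(x)) == 2)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (oracle_pi(h) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# site-by-site Weir & Cockerham (1984) components, scalar arithmetic
oracle_fst <- function(h) {
  A <- h$alleles
  ind_pop <- h$hap_pop[seq(1, nrow(A), by = 2)]
  pops <- sort(unique(ind_pop))
  r <- length(pops)
  num <- den <- 0
  for (s in seq_len(ncol(A))) {
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      rows <- which(h$hap_pop == pops[k])
      g1 <- A[rows[seq(1, length(rows), 2)], s]
      g2 <- A[rows[seq(2, length(rows), 2)], s]
      n_i[k] <- length(g1)
      p_i[k] <- mean(g1 + g2) / 2
      h_i[k] <- mean(g1 != g2)
    }
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

oracle_h12 <- function(h) {
  key <- apply(h$alleles, 1, paste, collapse = "")
  cnt <- sort(table(key), decreasing = TRUE)
  n <- length(key)
  top <- sum(cnt[seq_len(min(2, length(cnt)))]) / n
  rest <- 0
  if (length(cnt) > 2) for (i in 3:length(cnt)) rest <- rest + (cnt[[i]] / n)^2
  top^2 + rest
}

# pair/tract enumeration for nS_L at a 1-based focal column
oracle_nsl <- function(A, f) {
  n <- nrow(A); S <- ncol(A)
  L <- function(i, j) {
    lo <- f; while (lo > 1 && A[i, lo - 1] == A[j, lo - 1]) lo <- lo - 1
    hi <- f; while (hi < S && A[i, hi + 1] == A[j, hi + 1]) hi <- hi + 1
    hi - lo + 1
  }
  cls <- list(which(A[, f] == 0), which(A[, f] == 1))
  if (length(cls[[1]]) < 2 || length(cls[[2]]) < 2) return(NA_real_)
  sl <- vapply(cls, function(rows) {
    tot <- 0; np <- 0
    for (a in seq_along(rows)) for (b in seq_along(rows)) if (a < b) {
      tot <- tot + L(rows[a], rows[b]); np <- np + 1
    }
    tot / np
  }, numeric(1))
  log(sl[1] / sl[2])
}

oracle_ks_stat <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# expected-counts form with continuity correction
oracle_chi2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum(pmax(0, abs(m - E) - 0.5)^2 / E)
}

oracle_overlap <- function(regions, ann) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(ann$chrom == regions$chrom[i] &
          ann$start < regions$end[i] & ann$end > regions$start[i])
  }, logical(1))
}

oracle_r2 <- function(x, y) {
  suppressWarnings(stats::cor(x, y))^2
}

# minimal organ map over k tissues
toy_organ_map <- function(tissues, systems = NULL) {
  if (is.null(systems)) systems <- paste0("os_", tissues)
  stats::setNames(systems, tissues)
}

# in-memory VCF text for IO tests
vcf_text <- function(records, samples) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}
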