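#' Three-population out-of-Africa demographic model
#'
#' Parameterises the standard three-population model of recent human
#' demographic history: a single ancestral population of diploid size `N_A`
#' until `T_AF` generations ago, an African population of size `N_AF`, an
#' out-of-Africa bottleneck branch of size `N_B` between `T_AF` and `T_B`
#' exchanging migrants with Africa, and a European/East-Asian split at
#' `T_EU_AS` with exponential growth to the present and pairwise migration.
#' All sizes are diploid, times are in generations, migration rates are
#' per generation, and the mutation rate is per bp per generation.
#'
#' @param N_A ancestral size. @param N_AF African size.
#' @param N_B out-of-Africa bottleneck size.
#' @param N_EU0,N_AS0 European / East-Asian founding sizes at the split.
#' @param g_EU,g_AS per-generation exponential growth rates.
#' @param T_AF,T_B,T_EU_AS event times in generations
#'   (`T_AF > T_B > T_EU_AS > 0`).
#' @param m_AF_B,m_AF_EU,m_AF_AS,m_EU_AS symmetric migration rates.
#' @param mu mutation rate per bp per generation.
#' @param generation_years generation time in years (bookkeeping only).
#' @return an object of class `c("ooa_model", "demographic_model")`.
#' @export
demographic_model <- function(N_A = 7310, N_AF = 14474, N_B = 1861,
                              N_EU0 = 1032, g_EU = 0.0038,
                              N_AS0 = 554, g_AS = 0.0048,
                              T_AF = 5920, T_B = 2040, T_EU_AS = 920,
                              m_AF_B = 1.5e-4, m_AF_EU = 2.5e-5,
                              m_AF_AS = 7.8e-6, m_EU_AS = 3.11e-5,
                              mu = 2.36e-8, generation_years = 25) {
  m <- list(N_A = N_A, N_AF = N_AF, N_B = N_B, N_EU0 = N_EU0, g_EU = g_EU,
            N_AS0 = N_AS0, g_AS = g_AS, T_AF = T_AF, T_B = T_B,
            T_EU_AS = T_EU_AS, m_AF_B = m_AF_B, m_AF_EU = m_AF_EU,
            m_AF_AS = m_AF_AS, m_EU_AS = m_EU_AS, mu = mu,
            generation_years = generation_years)
  sizes <- c(N_A, N_AF, N_B, N_EU0, N_AS0, mu, generation_years)
  if (any(!is.finite(unlist(m))) || any(sizes <= 0))
    stop("all sizes and rates must be positive and finite")
  if (!(T_AF > T_B && T_B > T_EU_AS && T_EU_AS > 0))
    stop("event times must satisfy T_AF > T_B > T_EU_AS > 0")
  migs <- c(m_AF_B, m_AF_EU, m_AF_AS, m_EU_AS)
  if (any(migs < 0) || any(migs >= 1))
    stop("migration rates must lie in [0, 1)")
  if (g_EU < 0 || g_AS < 0) stop("growth rates must be >= 0")
  structure(m, class = c("ooa_model", "demographic_model"))
}

#' Default out-of-Africa model
#'
#' The Gravel et al. (2011) low-coverage-plus-exome parameter set for the
#' African / European / East-Asian model, shipped as an editable default.
#'
#' @return a [demographic_model].
#' @export
ooa_gravel_model <- function() demographic_model()

#' Single-population constant-size (or exponentially growing) model
#'
#' Mainly for calibration checks: a panmictic population of diploid size `N`.
#'
#' @param N diploid population size.
#' @param mu mutation rate per bp per generation.
#' @param growth forward per-generation exponential growth rate.
#' @return an object of class `c("constant_model", "demographic_model")`.
#' @export
constant_model <- function(N, mu = 2.36e-8, growth = 0) {
  if (N <= 0 || mu <= 0) stop("N and mu must be positive")
  structure(list(N = N, mu = mu, growth = growth),
            class = c("constant_model", "demographic_model"))
}

#' Population labels of a demographic model
#' @param model a `demographic_model`.
#' @return character vector of population labels in simulation order.
#' @export
model_populations <- function(model) UseMethod("model_populations")

#' @export
model_populations.ooa_model <- function(model) c("AFR", "EUR", "EAS")

#' @export
model_populations.constant_model <- function(model) "POP"

# Translate a demographic model into the event table the coalescent engine
# consumes (backward in time; kind 0 = size change, 1 = merge i -> j,
# 2 = symmetric migration reset; populations are 0-indexed).
sim_args <- function(model) UseMethod("sim_args")

#' @export
sim_args.ooa_model <- function(model) {
  m <- model
  pop_sizes <- c(m$N_AF,
                 m$N_EU0 * exp(m$g_EU * m$T_EU_AS),
                 m$N_AS0 * exp(m$g_AS * m$T_EU_AS))
  pop_growth <- c(0, m$g_EU, m$g_AS)
  mig <- matrix(0, 3, 3)
  mig[1, 2] <- mig[2, 1] <- m$m_AF_EU
  mig[1, 3] <- mig[3, 1] <- m$m_AF_AS
  mig[2, 3] <- mig[3, 2] <- m$m_EU_AS
  ev <- data.frame(
    time   = c(m$T_EU_AS, m$T_EU_AS, m$T_EU_AS, m$T_B, m$T_AF),
    kind   = c(1L, 0L, 2L, 1L, 0L),
    pop_i  = c(2L, 1L, 0L, 1L, 0L),
    pop_j  = c(1L, 0L, 1L, 0L, 0L),
    size   = c(0, m$N_B, 0, 0, m$N_A),
    growth = c(0, 0, 0, 0, 0),
    rate   = c(0, 0, m$m_AF_B, 0, 0))
  list(pop_sizes = pop_sizes, pop_growth = pop_growth, mig = mig,
       events = ev, mu = m$mu)
}

#' @export
sim_args.constant_model <- function(model) {
  list(pop_sizes = model$N, pop_growth = model$growth,
       mig = matrix(0, 1, 1),
       events = data.frame(time = numeric(0), kind = integer(0),
                           pop_i = integer(0), pop_j = integer(0),
                           size = numeric(0), growth = numeric(0),
                           rate = numeric(0)),
       mu = model$mu)
}

#' Read / write a demographic model config
#'
#' The config is a flat JSON object whose keys are exactly the
#' [demographic_model] fields.
#'
#' @param path file path.
#' @return `read_model_config()` returns a [demographic_model].
#' @export
read_model_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(demographic_model, x)
}

#' @rdname read_model_config
#' @param model a [demographic_model] to write.
#' @export
write_model_config <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Small deterministic FNV-1a-style fingerprint of an R object (used to tag
# null distributions with the model that produced them).
object_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  b <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (v in b) h <- ((bitwXor(as.integer(h %% 2^31), v)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
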