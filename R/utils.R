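# Internal helpers: seed streams, bounded-scale draws, small numeric utilities.

# Deterministically derive a child seed from a parent seed and a label, so that
# each simulated variable consumes its own RNG stream and changing one
# component does not shift the draws of another.
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647) + 1L
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}

# Truncated-normal draw by inverse-CDF; exact, vectorised, no extra deps.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Moment-matched truncated normal: find the underlying (mean, sd) whose
# truncation to [lo, hi] has the requested mean and sd, so the realized
# moments match the targets rather than shrinking under truncation.
truncnorm_match <- function(target_mean, target_sd, lo, hi) {
  moments <- function(m, s) {
    a <- (lo - m) / s; b <- (hi - m) / s
    Z <- pnorm(b) - pnorm(a)
    d <- (dnorm(a) - dnorm(b)) / Z
    mu <- m + s * d
    v <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - d^2)
    c(mu, sqrt(v))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

# Z-score a numeric vector; error on zero variance.
zscore <- function(x, label = "column") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("cannot standardize '%s': zero or undefined variance", label))
  }
  (x - mean(x)) / s
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stable content hash (FNV-1a over deparsed object) for run manifests.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

write_sidecar <- function(path, seed, spec) {
  meta <- list(seed = seed, spec_hash = config_hash(spec))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
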