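# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derivation from one master seed.
# Exact in double precision (product < 2^53) and always below 2^31 - 1.
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.numeric(master) %% 2147483647 * 48271 + stage) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("'%s' must contain probabilities in [0, 1]", name)
  invisible(x)
}

# Mean of a zero-truncated Poisson with rate lambda.
ztpois_mean <- function(lambda) lambda / (1 - exp(-lambda))

# Invert the zero-truncated Poisson mean; mean must be >= 1.
ztpois_lambda <- function(mean) {
  if (mean < 1) stop_config("zero-truncated Poisson mean must be >= 1 (got %g)", mean)
  if (mean == 1) return(0)
  uniroot(function(l) ztpois_mean(l) - mean, c(1e-10, 1e3), tol = 1e-12)$root
}

# Sample from a zero-truncated Poisson by inverse-CDF conditioning on X >= 1.
rztpois <- function(n, lambda) {
  if (lambda == 0) return(rep(1L, n))
  p0 <- exp(-lambda)
  qpois(runif(n, p0, 1), lambda)
}

# Probability generating function of the zero-truncated Poisson at s.
ztpois_pgf <- function(s, lambda) {
  if (lambda == 0) return(s)
  (exp(lambda * s) - 1) / (exp(lambda) - 1)
}

SESSIONS <- c("MRI", "CAD")
ZONES <- c("PZ", "TZ")
SIDES <- c("left", "right")
LEVELS <- c("apex", "mid", "base")

# The 12-sector prostate grid (zone x side x level) used for lesion placement
# and location matching.
sector_grid <- function() {
  expand.grid(zone = ZONES, side = SIDES, level = LEVELS,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

sector_key <- function(zone, side, level) paste(zone, side, level, sep = "|")
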