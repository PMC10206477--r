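# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("'%s' must be a single number", name))
  }
  if (x < lower || x > upper) {
    stop_input(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

# Normal draw truncated to [lower, upper] by resampling; degenerate sd = 0
# returns the mean (clamped).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop_input("negative standard deviation")
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(mean, lower), upper)
  out
}

#' Normalized mutual information between two labelings
#'
#' Compares two partitions of the same node set, e.g. recovered network
#' modules against the generator's planted modules. Uses the arithmetic-mean
#' normalization NMI = 2 I(a; b) / (H(a) + H(b)); two identical partitions
#' score 1, independent ones score near 0. When both partitions are the
#' trivial single-cluster partition the value is defined as 1.
#'
#' @param a,b vectors of cluster labels (same length; any atomic type).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' module_nmi(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
module_nmi <- function(a, b) {
  if (length(a) != length(b)) stop_input("label vectors must have equal length")
  n <- length(a)
  if (n == 0L) stop_input("empty labelings")
  tab <- table(a, b)
  joint <- tab / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- h(pa)
  hb <- h(pb)
  if (ha + hb == 0) return(1)
  pij <- joint[joint > 0]
  expected <- outer(pa, pb)[joint > 0]
  mi <- sum(pij * log(pij / expected))
  max(0, min(1, 2 * mi / (ha + hb)))
}

# Deterministic child seed derived from a base seed and a stage offset,
# kept well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}
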