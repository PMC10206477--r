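# Connectance-preserving null ensemble for weighted bipartite networks.
#
# Each null matrix keeps the observed number of occupied cells (links) and the
# integer grand total, allocating interactions with cell probabilities
# proportional to the product of the observed marginal totals, but without
# fixing the marginals themselves. Significance of the observed modularity is
# the upper-tail z-score of Q against the null Q distribution.

# Round a weighted matrix to integer interactions, flooring occupied cells at
# one so no observed link disappears.
round_interactions <- function(mat) {
  out <- round(mat)
  out[mat > 0 & out < 1] <- 1
  storage.mode(out) <- "double"
  out
}

#' Generate one connectance-preserving null matrix
#'
#' Cell probabilities are proportional to k_i * d_j (products of the observed
#' row and column totals). Single interactions are placed sequentially: first
#' into cells chosen to guarantee every row and every column gains at least
#' one occupied cell, then among the remaining empty cells, until the occupied
#' cell count equals the observed link count L. The remaining
#' (total - L) interactions are then distributed multinomially among the
#' occupied cells with the same probabilities.
#'
#' @param mat integer interaction matrix (every row and column must have a
#'   positive total).
#' @return an integer matrix of identical dimensions, link count and total.
#' @export
vaznull_matrix <- function(mat) {
  if (any(rowSums(mat) <= 0) || any(colSums(mat) <= 0)) {
    stop_input("every row and column needs at least one interaction")
  }
  nr <- nrow(mat)
  nc <- ncol(mat)
  total <- sum(mat)
  L <- sum(mat > 0)
  p <- outer(rowSums(mat), colSums(mat))
  p <- p / sum(p)
  occupied <- matrix(FALSE, nr, nc)

  # cover phase: draw cells from the uncovered-rows x uncovered-cols block
  # (each draw covers one new row and one new column), then finish whichever
  # side is still uncovered
  row_left <- rep(TRUE, nr)
  col_left <- rep(TRUE, nc)
  while (any(row_left) && any(col_left)) {
    sub <- p * outer(row_left, col_left)
    cell <- sample.int(nr * nc, 1, prob = as.vector(sub))
    occupied[cell] <- TRUE
    row_left[(cell - 1) %% nr + 1] <- FALSE
    col_left[(cell - 1) %/% nr + 1] <- FALSE
  }
  finish_side <- function(left, margin) {
    while (any(left)) {
      mask <- if (margin == 1) outer(left, rep(TRUE, nc)) else outer(rep(TRUE, nr), left)
      sub <- p * mask * !occupied
      cell <- sample.int(nr * nc, 1, prob = as.vector(sub))
      occupied[cell] <<- TRUE
      idx <- if (margin == 1) (cell - 1) %% nr + 1 else (cell - 1) %/% nr + 1
      left[idx] <- FALSE
    }
  }
  finish_side(row_left, 1)
  finish_side(col_left, 2)
  if (sum(occupied) > L) {
    stop_input("observed link count too small to cover all rows and columns")
  }

  # fill phase: open further cells one at a time until L cells are occupied
  n_open <- sum(occupied)
  if (n_open < L) {
    free <- which(!occupied)
    extra <- sample(free, L - n_open, prob = p[free])
    occupied[extra] <- TRUE
  }

  # weight phase: distribute the remaining interactions over occupied cells
  out <- matrix(0, nr, nc, dimnames = dimnames(mat))
  out[occupied] <- 1
  remaining <- total - L
  if (remaining > 0) {
    cells <- which(occupied)
    counts <- stats::rmultinom(1, remaining, prob = p[cells])[, 1]
    out[cells] <- out[cells] + counts
  }
  out
}

#' Null-model significance of the observed modularity
#'
#' Builds `n_null` connectance-preserving null matrices from the observed
#' matrix (rounded to integer interactions, occupied cells floored at one),
#' maximizes Barber modularity on each with [dirt_lpawb_plus()], and reports
#' the z-score of the observed Q against the null distribution together with
#' its upper-tail normal p-value and the empirical rank p-value. Modularity of
#' the observed network itself is computed on the unrounded weights.
#'
#' @param mat observed (possibly non-integer) visit matrix.
#' @param n_null number of null replicates (default 100).
#' @param rng_seed integer seed.
#' @param n_restarts restarts per modularity maximization.
#' @param observed optional precomputed `module_partition` of `mat` (skips one
#'   maximization).
#' @return list of class `null_ensemble`: `Q_obs`, `null_Q`, `mu_null`,
#'   `sd_null`, `z`, `p_normal`, `p_empirical`, `n_null`, `rng_seed`.
#' @export
vaznull_ensemble <- function(mat, n_null = 100, rng_seed = 1L,
                             n_restarts = 5, observed = NULL) {
  check_number(n_null, "n_null", 2)
  rounded <- round_interactions(mat)
  if (any(rowSums(rounded) <= 0) || any(colSums(rounded) <= 0)) {
    stop_input("every row and column needs at least one interaction")
  }
  if (is.null(observed)) {
    observed <- dirt_lpawb_plus(mat, n_restarts = n_restarts, rng_seed = rng_seed)
  }
  null_q <- numeric(n_null)
  for (b in seq_len(n_null)) {
    set.seed(derive_seed(rng_seed, 9000 + b))
    nm <- vaznull_matrix(rounded)
    part <- dirt_lpawb_plus(nm, n_restarts = n_restarts,
                            rng_seed = derive_seed(rng_seed, 9500 + b))
    null_q[b] <- part$Q
  }
  mu <- mean(null_q)
  sdn <- stats::sd(null_q)
  z <- if (sdn > 0) (observed$Q - mu) / sdn else Inf
  structure(list(
    Q_obs = observed$Q,
    partition = observed,
    null_Q = null_q,
    mu_null = mu,
    sd_null = sdn,
    z = z,
    p_normal = stats::pnorm(z, lower.tail = FALSE),
    p_empirical = (1 + sum(null_q >= observed$Q)) / (n_null + 1),
    n_null = n_null,
    rng_seed = rng_seed
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble (%d replicates): Q_obs = %.4f, null %.4f +/- %.4f\n",
              x$n_null, x$Q_obs, x$mu_null, x$sd_null))
  cat(sprintf("  z = %.2f, normal p = %.3g, empirical p = %.3g\n",
              x$z, x$p_normal, x$p_empirical))
  invisible(x)
}
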