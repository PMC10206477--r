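# Weighted bipartite modularity.
#
# Barber's modularity for a plants x species weight matrix A with grand total
# F, row strengths k and column strengths d:
#
#   Q = (1/F) * sum_ij [ A_ij - k_i * d_j / F ] * 1(g_i == g_j)
#
# maximized over joint assignments g of both node sides to modules by
# weighted label propagation (LPAwb+): each node adopts the partner-side
# module that maximizes Q, sides alternating, followed by module-merge moves;
# the multi-restart variant (DIRT) reruns from varied random initial module
# counts and keeps the best partition.

barber_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop_input("need a numeric matrix")
  if (any(mat < 0)) stop_input("weights must be nonnegative")
  f <- sum(mat)
  if (f <= 0) stop_input("matrix has zero total weight")
  k <- rowSums(mat)
  d <- colSums(mat)
  list(B = mat - outer(k, d) / f, F = f)
}

#' Barber's bipartite weighted modularity of a given partition
#'
#' Evaluates Q for a joint module assignment of the row (plant) and column
#' (species) nodes. Any partition with all nodes in one module scores exactly
#' 0; Q is bounded above by 1.
#'
#' @param mat nonnegative weight matrix (plants x species).
#' @param row_labels,col_labels module labels for every row / column node, in
#'   matrix order (or named by the dimnames).
#' @return the modularity Q.
#' @export
#' @examples
#' m <- rbind(c(5, 0), c(0, 5))
#' barber_modularity(m, c(1, 2), c(1, 2)) # 0.5
barber_modularity <- function(mat, row_labels, col_labels) {
  bm <- barber_matrix(mat)
  row_labels <- resolve_labels(row_labels, rownames(mat), nrow(mat), "row")
  col_labels <- resolve_labels(col_labels, colnames(mat), ncol(mat), "column")
  same <- outer(row_labels, col_labels, "==")
  sum(bm$B[same]) / bm$F
}

resolve_labels <- function(labels, ids, n, side) {
  if (length(labels) != n) {
    if (!is.null(names(labels)) && !is.null(ids) && all(ids %in% names(labels))) {
      labels <- labels[ids]
    } else {
      stop_input(sprintf("%s labels missing for some nodes", side))
    }
  } else if (!is.null(names(labels)) && !is.null(ids)) {
    if (!all(ids %in% names(labels))) {
      stop_input(sprintf("%s labels missing for some nodes", side))
    }
    labels <- labels[ids]
  }
  if (anyNA(labels)) stop_input(sprintf("NA %s labels", side))
  as.character(labels)
}

# One-sided optimal relabeling: given the partner side's labels, each node of
# the active side independently adopts the module with the largest summed
# Barber weight toward it, or a fresh singleton module (contribution 0) when
# every existing module has negative score. Ties go to the lowest module
# index. Returns integer labels.
relabel_side <- function(score_mat, module_ids, fresh_from) {
  best <- max.col(score_mat, ties.method = "first")
  best_score <- score_mat[cbind(seq_len(nrow(score_mat)), best)]
  labels <- module_ids[best]
  n_fresh <- sum(best_score < 0)
  if (n_fresh > 0) {
    labels[best_score < 0] <- seq(fresh_from, length.out = n_fresh)
  }
  labels
}

module_scores <- function(B, partner_labels, transpose = FALSE) {
  # returns nodes x modules score matrix and the module ids (sorted)
  ids <- sort(unique(partner_labels))
  ind <- outer(partner_labels, ids, "==") * 1
  S <- if (transpose) crossprod(B, ind) else B %*% ind
  list(S = S, ids = ids)
}

compress_labels <- function(row_labels, col_labels) {
  all_lab <- c(row_labels, col_labels)
  new <- match(all_lab, unique(all_lab))
  list(row = new[seq_along(row_labels)],
       col = new[-seq_along(row_labels)])
}

lpawb_core <- function(mat, init_row_labels, max_steps, tolerance) {
  bm <- barber_matrix(mat)
  B <- bm$B
  lr <- as.integer(init_row_labels)
  # initial column labels: best row-module for each column
  sc <- module_scores(B, lr, transpose = TRUE)
  lc <- relabel_side(sc$S, sc$ids, max(lr) + 1L)
  q <- partition_q(B, bm$F, lr, lc)
  steps <- 0L
  repeat {
    # alternating one-sided sweeps until stalled
    repeat {
      steps <- steps + 1L
      sr <- module_scores(B, lc, transpose = FALSE)
      lr <- relabel_side(sr$S, sr$ids, max(c(lr, lc)) + 1L)
      sc <- module_scores(B, lr, transpose = TRUE)
      lc <- relabel_side(sc$S, sc$ids, max(c(lr, lc)) + 1L)
      qn <- partition_q(B, bm$F, lr, lc)
      if (qn - q < tolerance || steps >= max_steps) {
        q <- max(q, qn)
        break
      }
      q <- qn
    }
    # module-merge moves
    merged <- FALSE
    repeat {
      cl <- compress_labels(lr, lc)
      lr <- cl$row
      lc <- cl$col
      mods <- sort(unique(c(lr, lc)))
      if (length(mods) < 2) break
      # block sums M[a, b] = sum of B over rows in a, cols in b
      ir <- outer(lr, mods, "==") * 1
      ic <- outer(lc, mods, "==") * 1
      Mblock <- t(ir) %*% B %*% ic
      gain <- (Mblock + t(Mblock)) / bm$F
      diag(gain) <- -Inf
      best <- which(gain == max(gain), arr.ind = TRUE)[1, ]
      if (gain[best[1], best[2]] <= tolerance) break
      a <- mods[min(best)]
      b <- mods[max(best)]
      lr[lr == b] <- a
      lc[lc == b] <- a
      q <- q + gain[best[1], best[2]]
      merged <- TRUE
    }
    if (!merged || steps >= max_steps) break
    # merges may open further relabeling improvements; loop back
    qn <- partition_q(B, bm$F, lr, lc)
    q <- qn
  }
  cl <- compress_labels(lr, lc)
  list(row_labels = cl$row, col_labels = cl$col,
       Q = partition_q(B, bm$F, cl$row, cl$col), steps = steps)
}

partition_q <- function(B, f, lr, lc) {
  same <- outer(lr, lc, "==")
  sum(B[same]) / f
}

finish_partition <- function(mat, res) {
  structure(list(
    row_labels = stats::setNames(res$row_labels, rownames(mat)),
    col_labels = stats::setNames(res$col_labels, colnames(mat)),
    Q = res$Q,
    n_modules = length(unique(c(res$row_labels, res$col_labels)))
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Bipartite module partition: %d modules, Q = %.4f\n",
              x$n_modules, x$Q))
  cat(sprintf("  %d row nodes, %d column nodes\n",
              length(x$row_labels), length(x$col_labels)))
  invisible(x)
}

#' Maximize Barber modularity by weighted label propagation (LPAwb+)
#'
#' Starts from every plant node in its own module (or a supplied
#' initialization), alternately relabels each node to the partner-side module
#' maximizing Q, then attempts module-merge moves, iterating until the Q
#' improvement falls below `tolerance` or `max_steps` sweeps are reached. Q is
#' non-decreasing across iterations and the returned partition is a local
#' maximum: no single relabel or pairwise merge improves it.
#'
#' @param mat nonnegative weight matrix with dimnames.
#' @param max_steps maximum number of relabeling sweeps (default 1000).
#' @param tolerance minimum Q improvement to continue (default 1e-10).
#' @param rng_seed seed for the (currently deterministic) sweep; retained so
#'   restart variants can derive child seeds.
#' @param init_row_labels optional integer initialization of the plant-side
#'   modules.
#' @return a `module_partition`: named `row_labels`, `col_labels`, `Q`,
#'   `n_modules`.
#' @export
lpawb_plus <- function(mat, max_steps = 1000, tolerance = 1e-10,
                       rng_seed = 1L, init_row_labels = NULL) {
  if (is.null(init_row_labels)) init_row_labels <- seq_len(nrow(mat))
  if (length(init_row_labels) != nrow(mat)) {
    stop_input("init_row_labels must cover every row node")
  }
  res <- lpawb_core(mat, init_row_labels, max_steps, tolerance)
  finish_partition(mat, res)
}

#' Multi-restart LPAwb+ (DIRT variant)
#'
#' Reruns [lpawb_plus()] from varied initial module counts: the first restart
#' uses the canonical one-module-per-plant start, subsequent restarts draw
#' random plant-side assignments into m modules with m cycling over
#' 2..min(dim). The best-Q partition over all restarts is returned;
#' deterministic given `rng_seed`.
#'
#' @inheritParams lpawb_plus
#' @param n_restarts number of restarts (>= 1).
#' @return a `module_partition`.
#' @export
dirt_lpawb_plus <- function(mat, n_restarts = 10, rng_seed = 1L,
                            max_steps = 1000, tolerance = 1e-10) {
  check_number(n_restarts, "n_restarts", 1)
  best <- lpawb_plus(mat, max_steps, tolerance, rng_seed)
  if (n_restarts > 1) {
    m_options <- seq_len(max(1L, min(dim(mat))))
    for (r in seq_len(n_restarts - 1)) {
      set.seed(derive_seed(rng_seed, 7000 + r))
      m <- m_options[1L + (r - 1L) %% length(m_options)]
      init <- sample.int(m, nrow(mat), replace = TRUE)
      cand <- lpawb_plus(mat, max_steps, tolerance,
                         rng_seed = derive_seed(rng_seed, 7000 + r),
                         init_row_labels = init)
      if (cand$Q > best$Q + 1e-15) best <- cand
    }
  }
  best
}

#' Exact maximum Barber modularity by exhaustive search (small matrices)
#'
#' Independent oracle for the label-propagation heuristic: enumerates all set
#' partitions of the row nodes; given a row partition, Q decomposes over
#' columns, so each column independently joins its best row module (or stays
#' in a singleton contributing 0), making the column side exactly optimizable.
#' Feasible for up to ~8 row nodes.
#'
#' @param mat nonnegative weight matrix.
#' @return list with `Q` (the global optimum) and the optimizing labels.
#' @export
exhaustive_barber_optimum <- function(mat) {
  n <- nrow(mat)
  if (n > 8) stop_input("exhaustive search limited to 8 row nodes")
  bm <- barber_matrix(mat)
  B <- bm$B
  parts <- set_partitions(n)
  best_q <- -Inf
  best <- NULL
  for (p in parts) {
    sc <- module_scores(B, p, transpose = TRUE)
    col_best <- pmax(apply(sc$S, 1, max), 0)
    q <- sum(col_best) / bm$F
    if (q > best_q) {
      best_q <- q
      lc <- relabel_side(sc$S, sc$ids, max(p) + 1L)
      best <- list(row = p, col = lc)
    }
  }
  list(Q = best_q, row_labels = best$row, col_labels = best$col)
}

# All set partitions of n items as integer label vectors (restricted growth
# strings).
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (m in seq_len(k + 1L)) rec(c(labels, m), max(k, m))
  }
  rec(integer(0), 0L)
  out
}

#' Node strength (row and column totals of the visit matrix)
#'
#' The weighted degree of every node: for plants the total estimated visits
#' received, for species the total visits made. Used as the default network
#' centrality in contribution regressions.
#'
#' @param mat visit matrix.
#' @return list with `plants` and `species` named numeric vectors.
#' @export
node_strength <- function(mat) {
  list(plants = rowSums(mat), species = colSums(mat))
}
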