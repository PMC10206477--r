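# Independent oracle for the LMG decomposition: average, over every predictor
# ordering, of the sequential R2 increases when each predictor enters.
lmg_by_orderings <- function(x, y) {
  x <- as.matrix(x)
  p <- ncol(x)
  vars <- colnames(x)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    fit <- stats::lm.fit(cbind(1, x[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))), recursive = FALSE)
  }
  shares <- stats::setNames(numeric(p), vars)
  all_orders <- perms(vars)
  for (ord in all_orders) {
    for (i in seq_along(ord)) {
      shares[ord[i]] <- shares[ord[i]] +
        r2(ord[seq_len(i)]) - r2(ord[seq_len(i - 1)])
    }
  }
  shares / length(all_orders)
}
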