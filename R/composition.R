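# Module composition vs stand provenance: contingency table, Pearson's
# chi-squared test of independence, and Haberman adjusted residuals to locate
# over/under-represented cells.

#' Stand-by-module contingency table of plants
#'
#' Counts the focal plants (species nodes are excluded) in each combination of
#' network module and stand provenance.
#'
#' @param partition a `module_partition`.
#' @param plants plant table with columns plant_id and stand.
#' @return a table with modules as rows and stands as columns.
#' @export
stand_module_table <- function(partition, plants) {
  stopifnot(inherits(partition, "module_partition"))
  if (!all(c("plant_id", "stand") %in% names(plants))) {
    stop_input("plants must have plant_id and stand columns")
  }
  if (anyNA(plants$stand)) stop_input("plant without stand")
  labs <- partition$row_labels
  missing <- setdiff(plants$plant_id, names(labs))
  if (length(missing) > 0) {
    stop_input("plants missing from partition: ", paste(missing, collapse = ", "))
  }
  module <- labs[plants$plant_id]
  table(module = factor(module), stand = factor(plants$stand, levels = unique(plants$stand)))
}

#' Pearson's chi-squared test of independence (no continuity correction)
#'
#' Tests whether module membership is independent of stand identity on a
#' modules x stands count table: expected counts E = row x col / N, statistic
#' X2 = sum (O - E)^2 / E, upper-tail p from the chi-squared distribution with
#' (rows - 1)(cols - 1) degrees of freedom.
#'
#' @param table a matrix or table of nonnegative integer counts.
#' @return list of class `chisq_result`: statistic, df, p_value, expected,
#'   observed, adjusted_residuals.
#' @export
pearson_chi_squared <- function(table) {
  obs <- as.matrix(table)
  if (any(obs < 0)) stop_input("counts must be nonnegative")
  n <- sum(obs)
  if (n <= 0) stop_input("empty table")
  expected <- outer(rowSums(obs), colSums(obs)) / n
  if (any(expected == 0)) {
    stop_input("a module or stand margin is zero; drop it before testing")
  }
  x2 <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  structure(list(
    statistic = x2,
    df = df,
    p_value = stats::pchisq(x2, df, lower.tail = FALSE),
    expected = expected,
    observed = obs,
    adjusted_residuals = adjusted_residuals(obs)
  ), class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson X^2 = %.2f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Haberman adjusted standardized residuals
#'
#' r = (O - E) / sqrt(E (1 - row/N) (1 - col/N)); cells with |r| > 1.96 are
#' the conventionally flagged over- (r > 0) or under-represented (r < 0)
#' combinations.
#'
#' @param table count table.
#' @return matrix of adjusted residuals with a `flagged` attribute (logical
#'   matrix, |r| > 1.96).
#' @export
adjusted_residuals <- function(table) {
  obs <- as.matrix(table)
  n <- sum(obs)
  if (n <= 0) stop_input("empty table")
  rs <- rowSums(obs)
  cs <- colSums(obs)
  expected <- outer(rs, cs) / n
  if (any(expected == 0)) stop_input("zero expected count")
  denom <- sqrt(expected * outer(1 - rs / n, 1 - cs / n))
  r <- (obs - expected) / denom
  attr(r, "flagged") <- abs(r) > 1.96
  r
}
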