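# Which plant traits discriminate module membership: collinearity pruning by
# variance inflation factors, forward variable selection on Wilks' lambda,
# and linear discriminant analysis with resubstitution accuracy.

#' Iterative variance-inflation-factor pruning
#'
#' Computes VIF_j = 1 / (1 - R2_j) for every variable (R2_j from regressing
#' variable j on all the others), drops the variable with the largest VIF,
#' and repeats until all remaining VIFs are below the threshold.
#'
#' @param traits numeric data.frame or matrix (observations x variables),
#'   complete cases only.
#' @param threshold retain variables with VIF strictly below this (default 3).
#' @return list of class `vif_report`: `retained` (variable names), `dropped`
#'   (in drop order), `rounds` (list of named VIF vectors per round),
#'   `threshold`.
#' @export
vif_prune <- function(traits, threshold = 3) {
  x <- as.matrix(traits)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2) stop_input("need at least two variables")
  if (anyNA(x)) stop_input("missing values; supply complete cases")
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop_input("constant column: ",
               paste(colnames(x)[apply(x, 2, stats::sd) == 0], collapse = ", "))
  }
  vif_one <- function(j, cols) {
    fit <- stats::lm.fit(cbind(1, cols[, -j, drop = FALSE]), cols[, j])
    res <- fit$residuals
    tot <- sum((cols[, j] - mean(cols[, j]))^2)
    r2 <- 1 - sum(res^2) / tot
    1 / max(1 - r2, .Machine$double.eps)
  }
  rounds <- list()
  dropped <- character(0)
  repeat {
    if (ncol(x) == 1) break
    vifs <- vapply(seq_len(ncol(x)), vif_one, numeric(1), cols = x)
    names(vifs) <- colnames(x)
    rounds[[length(rounds) + 1]] <- vifs
    if (max(vifs) < threshold) break
    worst <- names(vifs)[which.max(vifs)]
    dropped <- c(dropped, worst)
    x <- x[, setdiff(colnames(x), worst), drop = FALSE]
  }
  structure(list(retained = colnames(x), dropped = dropped,
                 rounds = rounds, threshold = threshold),
            class = "vif_report")
}

# Wilks' lambda of a variable set: det(W) / det(T), W the pooled within-group
# scatter and T the total scatter of the selected columns.
wilks_lambda <- function(x, groups) {
  x <- as.matrix(x)
  g <- as.factor(groups)
  centered_total <- scale(x, center = TRUE, scale = FALSE)
  T_mat <- crossprod(centered_total)
  W <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    ci <- scale(xi, center = TRUE, scale = FALSE)
    W <- W + crossprod(ci)
  }
  detT <- det(T_mat)
  detW <- det(W)
  if (detT <= 0) stop_input("singular total scatter")
  detW / detT
}

#' Forward variable selection by Wilks' lambda
#'
#' At each step the candidate variable minimizing the overall Wilks' lambda of
#' the selected set is entered, provided its partial-F p-value is below
#' `entry_alpha`. The partial F for entering a variable when p variables are
#' already selected (g groups, n observations) is
#' F = ((n - g - p) / (g - 1)) (Lambda_p / Lambda_p+1 - 1) on
#' (g - 1, n - g - p) degrees of freedom.
#'
#' @param traits numeric data.frame/matrix of candidate variables.
#' @param groups group labels (module membership).
#' @param entry_alpha largest partial-F p-value allowed for entry
#'   (default 0.2).
#' @return list of class `wilks_selection`: `selected` (in entry order),
#'   `lambda` (after each entry), `partial_F`, `p_value`, `entry_alpha`.
#' @export
greedy_wilks <- function(traits, groups, entry_alpha = 0.2) {
  x <- as.matrix(traits)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop_input("need at least two groups")
  if (any(table(g) < 2)) stop_input("each group needs at least two members")
  if (anyNA(x)) stop_input("missing values; supply complete cases")
  n <- nrow(x)
  k <- nlevels(g)
  selected <- character(0)
  lambda_seq <- numeric(0)
  f_seq <- numeric(0)
  p_seq <- numeric(0)
  lambda_cur <- 1
  remaining <- colnames(x)
  while (length(remaining) > 0) {
    p <- length(selected)
    df2 <- n - k - p
    if (df2 <= 0) break
    cand_lambda <- vapply(remaining, function(v) {
      tryCatch(wilks_lambda(x[, c(selected, v), drop = FALSE], g),
               error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(cand_lambda))) break
    best <- names(cand_lambda)[which.min(cand_lambda)]
    lam_new <- cand_lambda[best]
    f_stat <- (df2 / (k - 1)) * (lambda_cur / lam_new - 1)
    p_val <- stats::pf(f_stat, k - 1, df2, lower.tail = FALSE)
    if (is.na(p_val) || p_val > entry_alpha) break
    selected <- c(selected, best)
    lambda_seq <- c(lambda_seq, lam_new)
    f_seq <- c(f_seq, f_stat)
    p_seq <- c(p_seq, p_val)
    lambda_cur <- lam_new
    remaining <- setdiff(remaining, best)
  }
  structure(list(selected = selected,
                 lambda = stats::setNames(lambda_seq, selected),
                 partial_F = stats::setNames(f_seq, selected),
                 p_value = stats::setNames(p_seq, selected),
                 entry_alpha = entry_alpha),
            class = "wilks_selection")
}

#' Linear discriminant analysis of module membership
#'
#' Fits Fisher's linear discriminant axes (via [MASS::lda()]) with priors
#' proportional to class sizes by default, classifies every observation by its
#' largest discriminant score, and reports the resubstitution accuracy (the
#' fraction of observations assigned back to their own class). Leave-one-out
#' cross-validated accuracy is available as an option.
#'
#' @param traits numeric data.frame/matrix of predictor variables.
#' @param groups class labels.
#' @param prior "proportional" (default) or "equal".
#' @param cv also compute leave-one-out accuracy.
#' @return list of class `lda_model`: `fit` (the MASS fit), `predicted`,
#'   `accuracy`, `confusion`, `scores`, optionally `accuracy_cv`.
#' @export
lda_fit_classify <- function(traits, groups, prior = c("proportional", "equal"),
                             cv = FALSE) {
  prior <- match.arg(prior)
  x <- as.data.frame(traits)
  g <- as.factor(groups)
  if (anyNA(x)) stop_input("missing values; supply complete cases")
  counts <- table(g)
  if (any(counts < ncol(x) + 1)) {
    warning("some class has fewer observations than variables; covariance is pooled",
            call. = FALSE)
  }
  pr <- if (prior == "proportional") as.numeric(counts) / length(g) else
    rep(1 / nlevels(g), nlevels(g))
  fit <- MASS::lda(x, grouping = g, prior = pr)
  pred <- stats::predict(fit, x)
  acc <- mean(pred$class == g)
  out <- list(
    fit = fit,
    predicted = pred$class,
    scores = pred$x,
    accuracy = acc,
    confusion = table(observed = g, predicted = pred$class),
    prior = pr
  )
  if (cv) {
    fit_cv <- MASS::lda(x, grouping = g, prior = pr, CV = TRUE)
    out$accuracy_cv <- mean(fit_cv$class == g)
  }
  structure(out, class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("LDA: %d classes, resubstitution accuracy %.1f%%\n",
              nlevels(x$predicted), 100 * x$accuracy))
  if (!is.null(x$accuracy_cv)) {
    cat(sprintf("  leave-one-out accuracy %.1f%%\n", 100 * x$accuracy_cv))
  }
  invisible(x)
}

#' Full trait-discrimination pipeline
#'
#' Convenience wrapper running [vif_prune()], [greedy_wilks()] on the retained
#' variables, and [lda_fit_classify()] on the selected set, on complete cases
#' of the requested columns.
#'
#' @param plants plant table.
#' @param modules named module labels for plants (e.g.
#'   `partition$row_labels`).
#' @param columns trait columns to consider.
#' @param vif_threshold,entry_alpha tuning constants of the two screens.
#' @return list with `vif`, `wilks`, `lda`, `used_plants`.
#' @export
discriminate_modules <- function(plants, modules,
                                 columns = c("cover", "height", "crop_size",
                                             "cone_diameter", "cone_length",
                                             "cone_mass", "seeds_per_cone",
                                             "seed_viability", "neigh_density",
                                             "neigh_fecundity"),
                                 vif_threshold = 3, entry_alpha = 0.2) {
  missing_cols <- setdiff(columns, names(plants))
  if (length(missing_cols) > 0) {
    stop_input("plants lack trait columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- plants[, columns, drop = FALSE]
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  ids <- plants$plant_id[complete]
  g <- modules[ids]
  if (anyNA(g)) stop_input("module label missing for some plants")
  sizes <- table(g)
  if (any(sizes < 2)) {
    small <- names(sizes)[sizes < 2]
    warning("module(s) with a single plant excluded from the discriminant analysis: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(as.character(g) %in% small)
    x <- x[keep, , drop = FALSE]
    ids <- ids[keep]
    g <- g[keep]
  }
  vif <- vif_prune(x, threshold = vif_threshold)
  wil <- greedy_wilks(x[, vif$retained, drop = FALSE], g, entry_alpha = entry_alpha)
  if (length(wil$selected) == 0) {
    stop_input("no variable passed the Wilks entry criterion")
  }
  lda <- lda_fit_classify(x[, wil$selected, drop = FALSE], g)
  list(vif = vif, wilks = wil, lda = lda, used_plants = ids)
}
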