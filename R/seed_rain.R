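# Per-plant viable-seed-dispersal estimation and downstream analyses.
#
# The effectiveness estimator is multiplicative: visits are converted to
# viable dispersed seeds through the chain
#   seeds_pf = visits_pf x feeding_rate_f x seeds_per_cone_p
#              x undamaged_fraction_f x seed_viability_p
# i.e. a quantity component (visits x cones per visit x seeds per cone) times
# a quality component (seed survival of gut treatment x seed viability).

#' Estimate viable seeds dispersed per plant and frugivore
#'
#' @param visits visit matrix (plants x species).
#' @param species species table with species_id, feeding_rate,
#'   undamaged_fraction.
#' @param plants plant table with plant_id, seeds_per_cone, seed_viability.
#' @return list of class `seed_rain`: `seeds` (plants x species matrix),
#'   `plant_totals`, `species_totals`.
#' @export
#' @examples
#' v <- matrix(5, 1, 1, dimnames = list("C106", "Vulpes_vulpes"))
#' sp <- data.frame(species_id = "Vulpes_vulpes", feeding_rate = 7.4,
#'                  undamaged_fraction = 0.97)
#' pl <- data.frame(plant_id = "C106", seeds_per_cone = 5.22,
#'                  seed_viability = 0.21)
#' round(estimate_dispersed_seeds(v, sp, pl)$seeds, 1) # 39.3
estimate_dispersed_seeds <- function(visits, species, plants) {
  if (!is.matrix(visits)) stop_input("visits must be a matrix")
  sp_idx <- match(colnames(visits), species$species_id)
  if (anyNA(sp_idx)) {
    stop_input("species parameters missing for: ",
               paste(colnames(visits)[is.na(sp_idx)], collapse = ", "))
  }
  pl_idx <- match(rownames(visits), plants$plant_id)
  if (anyNA(pl_idx)) {
    stop_input("plant parameters missing for: ",
               paste(rownames(visits)[is.na(pl_idx)], collapse = ", "))
  }
  fr <- species$feeding_rate[sp_idx]
  und <- species$undamaged_fraction[sp_idx]
  spc <- plants$seeds_per_cone[pl_idx]
  via <- plants$seed_viability[pl_idx]
  if (anyNA(fr) || anyNA(und)) stop_input("NA species parameter")
  if (anyNA(spc) || anyNA(via)) stop_input("NA plant parameter")
  seeds <- visits * rep(fr, each = nrow(visits)) * rep(und, each = nrow(visits)) *
    spc * via
  structure(list(
    seeds = seeds,
    plant_totals = rowSums(seeds),
    species_totals = colSums(seeds)
  ), class = "seed_rain")
}

#' Per-species shares of the pooled seed rain
#'
#' @param seed_rain a `seed_rain` object (or a seeds matrix).
#' @return named numeric vector of shares summing to 1.
#' @export
species_shares <- function(seed_rain) {
  totals <- if (inherits(seed_rain, "seed_rain")) seed_rain$species_totals
            else colSums(seed_rain)
  pooled <- sum(totals)
  if (pooled <= 0) stop_input("pooled seed rain is zero")
  totals / pooled
}

#' Bootstrap standard errors of per-species seed totals
#'
#' Nonparametric bootstrap over plants: rows of the seeds matrix are resampled
#' with replacement and the per-species totals recomputed.
#'
#' @param seed_rain a `seed_rain` object.
#' @param n_boot resamples (default 1000).
#' @param rng_seed seed.
#' @return data.frame with species, total, se.
#' @export
species_totals_bootstrap <- function(seed_rain, n_boot = 1000, rng_seed = 1L) {
  stopifnot(inherits(seed_rain, "seed_rain"))
  seeds <- seed_rain$seeds
  set.seed(derive_seed(rng_seed, 606))
  boots <- replicate(n_boot, colSums(seeds[sample(nrow(seeds), replace = TRUE), ,
                                           drop = FALSE]))
  data.frame(
    species = colnames(seeds),
    total = colSums(seeds),
    se = apply(boots, 1, stats::sd),
    row.names = NULL
  )
}

# Build the predictor table of the contribution regression: visits by the
# focal species enter alone, the remaining species are aggregated by
# functional group (birds by size class, mammals pooled), plus the plant
# reproductive traits.
contribution_predictors <- function(visits, species, plants,
                                    focal_species = "Turdus_philomelos") {
  sp_idx <- match(colnames(visits), species$species_id)
  if (anyNA(sp_idx)) stop_input("species metadata missing for some columns")
  group <- species$functional_group[sp_idx]
  is_focal <- colnames(visits) == focal_species
  agg_group <- ifelse(grepl("mammal", group), "mammals",
                      ifelse(group == "small-sized bird", "small_birds",
                             "medium_birds"))
  agg_group[is_focal] <- "focal"
  groups <- unique(agg_group)
  pred <- sapply(groups, function(gr) {
    rowSums(visits[, agg_group == gr, drop = FALSE])
  })
  pred <- as.matrix(pred)
  colnames(pred) <- ifelse(groups == "focal", focal_species, groups)
  pl_idx <- match(rownames(visits), plants$plant_id)
  data.frame(pred,
             seeds_per_cone = plants$seeds_per_cone[pl_idx],
             seed_viability = plants$seed_viability[pl_idx],
             check.names = FALSE)
}

#' Regression of individual seed contributions on assemblage and traits
#'
#' Ordinary least squares of log(plant seed total + 1) on the visit predictors
#' (focal dominant species alone, remaining species aggregated by functional
#' group) and the plant reproductive traits (seeds per cone, seed viability).
#' Reports coefficients with standard errors, t and p values, the model R2,
#' its AICc, and the LMG relative-importance decomposition of R2.
#'
#' @param seed_rain a `seed_rain` object.
#' @param visits the visit matrix the seed rain was derived from.
#' @param species species table (needs functional_group).
#' @param plants plant table.
#' @param focal_species species entering as its own predictor (default the
#'   dominant disperser).
#' @param log_offset offset inside the log response (default 1).
#' @return list of class `contribution_regression`: `fit`, `coefficients`
#'   (data.frame), `r_squared`, `aicc`, `lmg` (named shares summing to R2),
#'   `data`.
#' @export
contribution_regression <- function(seed_rain, visits, species, plants,
                                    focal_species = "Turdus_philomelos",
                                    log_offset = 1) {
  stopifnot(inherits(seed_rain, "seed_rain"))
  pred <- contribution_predictors(visits, species, plants, focal_species)
  if (anyNA(pred)) stop_input("missing predictor values")
  y <- log(seed_rain$plant_totals + log_offset)
  dat <- data.frame(.response = y, pred, check.names = FALSE)
  x <- as.matrix(pred)
  dec <- qr(cbind(`(Intercept)` = 1, x))
  if (dec$rank < ncol(x) + 1) {
    kept <- dec$pivot[seq_len(dec$rank)]
    aliased <- setdiff(colnames(x), colnames(cbind(`(Intercept)` = 1, x))[kept])
    stop_input("aliased (degenerate) predictors: ", paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(.response ~ ., data = dat)
  sm <- summary(fit)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2],
    t = sm$coefficients[, 3],
    p = sm$coefficients[, 4],
    row.names = NULL
  )
  structure(list(
    fit = fit,
    coefficients = coefs,
    r_squared = sm$r.squared,
    aicc = aicc_value(fit),
    lmg = lmg_importance(pred, y),
    data = dat
  ), class = "contribution_regression")
}

#' @export
print.contribution_regression <- function(x, ...) {
  cat(sprintf("Contribution regression: R2 = %.3f, AICc = %.2f\n",
              x$r_squared, x$aicc))
  print(x$coefficients, digits = 3)
  cat("LMG shares of R2 (%):\n")
  print(round(100 * x$lmg, 2))
  invisible(x)
}

# Gaussian AICc of a fitted lm: n log(RSS/n) + 2k + 2k(k+1)/(n-k-1), where k
# counts the regression coefficients (including intercept) plus the error
# variance.
aicc_value <- function(fit) {
  rss <- sum(stats::residuals(fit)^2)
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit)) + 1
  if (n - k - 1 <= 0) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets model selection by AICc
#'
#' Fits OLS models for candidate predictor subsets of a response and returns
#' the subset minimizing the small-sample-corrected AIC,
#' AICc = n log(RSS/n) + 2k + 2k(k+1)/(n - k - 1) with k = number of
#' coefficients (including the intercept) plus one for the error variance.
#' When `subsets` is NULL, all subsets of the predictors (including the
#' intercept-only model) are enumerated, which requires at most 12 predictors.
#'
#' @param predictors data.frame/matrix of candidate predictors.
#' @param response numeric response.
#' @param subsets optional list of character vectors naming candidate subsets.
#' @return list of class `aicc_selection`: `best` (names of the winning
#'   subset), `table` (subset, k, aicc, r_squared, sorted by AICc), `fit`.
#' @export
aicc_select <- function(predictors, response, subsets = NULL) {
  x <- as.data.frame(predictors)
  n <- length(response)
  if (nrow(x) != n) stop_input("predictor/response length mismatch")
  vars <- colnames(x)
  if (is.null(subsets)) {
    if (length(vars) > 12) stop_input("all-subsets enumeration limited to 12 predictors")
    subsets <- unlist(lapply(0:length(vars), function(k) {
      if (k == 0) list(character(0)) else
        utils::combn(vars, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  rows <- lapply(subsets, function(s) {
    k <- length(s) + 2 # coefficients incl. intercept, plus variance
    if (n <= k + 1) {
      warning(sprintf("subset {%s} skipped: too few observations",
                      paste(s, collapse = ", ")), call. = FALSE)
      return(NULL)
    }
    dat <- data.frame(.response = response, x[, s, drop = FALSE], check.names = FALSE)
    fit <- stats::lm(.response ~ ., data = dat)
    data.frame(subset = paste(s, collapse = "+"),
               k = k,
               aicc = aicc_value(fit),
               r_squared = summary(fit)$r.squared,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) stop_input("no admissible candidate subset")
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  best_vars <- if (nzchar(tab$subset[1])) strsplit(tab$subset[1], "+", fixed = TRUE)[[1]]
               else character(0)
  dat <- data.frame(.response = response, x[, best_vars, drop = FALSE],
                    check.names = FALSE)
  structure(list(best = best_vars, table = tab,
                 fit = stats::lm(.response ~ ., data = dat)),
            class = "aicc_selection")
}

#' LMG relative-importance decomposition of R2
#'
#' Decomposes the R2 of an OLS model into nonnegative per-predictor shares by
#' averaging, over all orderings of the predictors, the increase in R2 when a
#' predictor enters after its predecessors. Computed exactly through subset
#' enumeration with combinatorial weights |S|! (p - |S| - 1)! / p!, which
#' equals the direct average over the p! orderings.
#'
#' @param predictors data.frame/matrix (at most 10 predictors).
#' @param response numeric response.
#' @return named numeric shares; they sum to the full model's R2.
#' @export
lmg_importance <- function(predictors, response) {
  x <- as.matrix(predictors)
  p <- ncol(x)
  if (p < 1) stop_input("need at least one predictor")
  if (p > 10) stop_input("exact LMG enumeration limited to 10 predictors")
  if (qr(cbind(1, x))$rank < p + 1) {
    stop_input("collinear predictors; prune before decomposing R2")
  }
  n <- nrow(x)
  vars <- colnames(x) %||% paste0("V", seq_len(p))
  colnames(x) <- vars
  # R2 of every subset, keyed by bitmask
  r2 <- numeric(2^p)
  tss <- sum((response - mean(response))^2)
  for (mask in 1:(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    fit <- stats::lm.fit(cbind(1, x[, cols, drop = FALSE]), response)
    r2[mask + 1] <- 1 - sum(fit$residuals^2) / tss
  }
  shares <- stats::setNames(numeric(p), vars)
  lf <- lfactorial
  for (j in seq_len(p)) {
    bit_j <- 2^(j - 1)
    others <- setdiff(seq_len(p), j)
    other_masks <- 0
    if (length(others) > 0) {
      other_masks <- unlist(lapply(0:length(others), function(k) {
        if (k == 0) 0 else
          vapply(utils::combn(others, k, simplify = FALSE),
                 function(s) sum(2^(s - 1)), numeric(1))
      }))
    }
    for (m in other_masks) {
      size <- sum(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
      w <- exp(lf(size) + lf(p - size - 1) - lf(p))
      shares[j] <- shares[j] + w * (r2[bitwOr(m, bit_j) + 1] - r2[m + 1])
    }
  }
  shares
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Fits a one-way ANOVA of log-transformed contributions on a grouping factor
#' (module or stand) and computes all pairwise Tukey honest significant
#' difference comparisons with studentized-range p-values on N - k degrees of
#' freedom. Singleton groups are excluded with a warning.
#'
#' @param contributions named numeric vector of per-plant seed totals.
#' @param grouping named factor/character of the same plants.
#' @param log_offset offset inside the log (default 1).
#' @return list of class `anova_tukey`: `anova` (F, df, p, r_squared),
#'   `tukey` (data.frame of pairwise comparisons), `fit`.
#' @export
group_anova_tukey <- function(contributions, grouping, log_offset = 1) {
  ids <- names(contributions)
  if (!is.null(ids) && !is.null(names(grouping))) grouping <- grouping[ids]
  g <- as.factor(as.character(grouping))
  sizes <- table(g)
  if (any(sizes < 2)) {
    drop_groups <- names(sizes)[sizes < 2]
    warning("singleton group(s) excluded: ", paste(drop_groups, collapse = ", "),
            call. = FALSE)
    keep <- !(as.character(g) %in% drop_groups)
    contributions <- contributions[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop_input("need at least two groups with two members")
  y <- log(contributions + log_offset)
  dat <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = dat)
  sm <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$g
  structure(list(
    anova = list(
      F = sm[1, "F value"],
      df = c(sm[1, "Df"], sm[2, "Df"]),
      p = sm[1, "Pr(>F)"],
      r_squared = sm[1, "Sum Sq"] / sum(sm[, "Sum Sq"])
    ),
    tukey = data.frame(comparison = rownames(tuk), tuk, row.names = NULL),
    fit = fit
  ), class = "anova_tukey")
}

#' Within-stand contribution z-scores and inequality ranking
#'
#' For every plant, how many (sample) standard deviations its seed
#' contribution lies above or below its stand mean; plants are ranked by
#' contribution within stand and the cumulative share curve recorded, from
#' which the number of plants needed to reach a given share of the stand seed
#' rain (default 50%) is derived.
#'
#' @param seed_rain a `seed_rain` object (or named vector of plant totals).
#' @param plants plant table with plant_id and stand.
#' @param share threshold share of the stand seed rain (default 0.5).
#' @return list of class `contribution_ranking`: `table` (plant, stand,
#'   contribution, z, rank, cumulative_share) and `plants_to_share` (named
#'   count per stand).
#' @export
stand_zscores <- function(seed_rain, plants, share = 0.5) {
  totals <- if (inherits(seed_rain, "seed_rain")) seed_rain$plant_totals else seed_rain
  idx <- match(names(totals), plants$plant_id)
  if (anyNA(idx)) stop_input("plants table lacks some plants")
  stand <- plants$stand[idx]
  out <- NULL
  plants_to_share <- c()
  for (s in unique(stand)) {
    v <- totals[stand == s]
    if (length(v) < 2) stop_input("stand with fewer than two plants: ", s)
    if (sum(v) <= 0) stop_input("stand with zero total seed rain: ", s)
    sdv <- stats::sd(v)
    if (sdv == 0) {
      warning("zero contribution spread within stand ", s, "; z set to 0",
              call. = FALSE)
      z <- rep(0, length(v))
      names(z) <- names(v)
    } else {
      z <- (v - mean(v)) / sdv
    }
    ord <- order(v, decreasing = TRUE)
    cum <- cumsum(v[ord]) / sum(v)
    tab <- data.frame(
      plant_id = names(v)[ord],
      stand = s,
      contribution = unname(v[ord]),
      z = unname(z[ord]),
      rank = seq_along(v),
      cumulative_share = unname(cum),
      stringsAsFactors = FALSE
    )
    out <- rbind(out, tab)
    plants_to_share[s] <- which(cum >= share)[1]
  }
  structure(list(table = out, plants_to_share = plants_to_share, share = share),
            class = "contribution_ranking")
}

#' Log-log regression of contributions on a covariate
#'
#' Simple OLS of log(contribution + offset) on log(covariate), e.g. plant
#' cover (a proxy of plant age) or network-node strength.
#'
#' @param contributions named numeric vector of per-plant seed totals.
#' @param covariate named positive covariate for the same plants.
#' @param log_offset offset added to the response before the log (default 1);
#'   the covariate must be strictly positive.
#' @return list with slope, intercept, r_squared, F, df, p, fit.
#' @export
loglog_regression <- function(contributions, covariate, log_offset = 1) {
  if (!is.null(names(contributions)) && !is.null(names(covariate))) {
    covariate <- covariate[names(contributions)]
  }
  if (any(covariate <= 0) || anyNA(covariate)) {
    stop_input("covariate must be strictly positive for the log transform")
  }
  y <- log(contributions + log_offset)
  x <- log(covariate)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    F = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2:3]),
    p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE),
    fit = fit
  )
}
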