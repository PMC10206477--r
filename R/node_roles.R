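# Topological roles of nodes given a module partition: standardized
# within-module degree z and among-module connectivity (participation) c.

#' Node roles: within-module degree z and among-module connectivity c
#'
#' For node i with total strength k_i and strength kappa_it into module t,
#' the among-module connectivity is c_i = 1 - sum_t (kappa_it / k_i)^2
#' (0 when all interactions stay in one module, approaching 1 - 1/T for
#' weight spread evenly over T modules), and the within-module degree
#' z_i = (kappa_i,g(i) - mean) / sd, standardized over the same-side nodes of
#' node i's own module. Strengths are used when `weighted = TRUE`, binary link
#' counts otherwise.
#'
#' Nodes with zero degree are excluded with a warning; a module whose
#' same-side members have zero spread in within-module degree yields z = 0
#' for those nodes (with a warning).
#'
#' @param mat visit matrix.
#' @param partition a `module_partition` from [lpawb_plus()] or
#'   [dirt_lpawb_plus()].
#' @param weighted use interaction weights (default) or binary links.
#' @return data.frame with columns node, side ("plant"/"species"), module,
#'   c, z.
#' @export
node_roles <- function(mat, partition, weighted = TRUE) {
  stopifnot(inherits(partition, "module_partition"))
  lr <- resolve_labels(partition$row_labels, rownames(mat), nrow(mat), "row")
  lc <- resolve_labels(partition$col_labels, colnames(mat), ncol(mat), "column")
  w <- if (weighted) mat else (mat > 0) * 1

  roles_side <- function(w_side, own_labels, partner_labels, side_name, ids) {
    mods <- sort(unique(c(own_labels, partner_labels)))
    ind <- outer(partner_labels, mods, "==") * 1
    kappa <- w_side %*% ind # node x module strengths
    k <- rowSums(kappa)
    zero <- k == 0
    if (any(zero)) {
      warning(sprintf("%d %s node(s) with zero degree excluded", sum(zero),
                      side_name), call. = FALSE)
    }
    c_val <- ifelse(zero, NA_real_, 1 - rowSums((kappa / pmax(k, .Machine$double.eps))^2))
    own_kappa <- kappa[cbind(seq_along(own_labels), match(own_labels, mods))]
    z_val <- rep(NA_real_, length(own_labels))
    warned <- FALSE
    for (m in unique(own_labels)) {
      in_m <- which(own_labels == m & !zero)
      if (length(in_m) == 0) next
      mu <- mean(own_kappa[in_m])
      sdv <- stats::sd(own_kappa[in_m])
      if (is.na(sdv) || sdv == 0) {
        z_val[in_m] <- 0
        warned <- TRUE
      } else {
        z_val[in_m] <- (own_kappa[in_m] - mu) / sdv
      }
    }
    if (warned) {
      warning(sprintf("degenerate within-module spread on the %s side; z set to 0",
                      side_name), call. = FALSE)
    }
    keep <- !zero
    data.frame(node = ids[keep], side = side_name, module = own_labels[keep],
               c = c_val[keep], z = z_val[keep], stringsAsFactors = FALSE)
  }

  out <- rbind(
    roles_side(w, lr, lc, "plant", rownames(mat)),
    roles_side(t(w), lc, lr, "species", colnames(mat))
  )
  rownames(out) <- NULL
  out
}
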