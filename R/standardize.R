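# Sampling-effort standardization of the two survey channels and their
# fusion into a single weighted adjacency matrix (plants x frugivore species).
#
# Both channels observe a fraction of each plant (camera frame or trap area)
# for a fraction of the study, so raw detection counts are scaled by
# 1 / (area fraction x time fraction) to whole-plant, whole-study visit
# estimates. Expressed in the same units, the two estimates can be fused
# cellwise.

#' Camera coverage fraction for a plant of given cover
#'
#' Maps plant canopy cover (m2) to the fraction of the plant surface recorded
#' by a camera: 60% for small plants (cover < 20 m2), 40% for medium plants
#' (20-40 m2) and 20% for large plants (> 40 m2). The middle class is closed
#' on both boundaries.
#'
#' @param cover plant canopy cover in m2 (positive).
#' @param breaks class boundaries.
#' @param fractions recorded surface fraction per class.
#' @return a single fraction in (0, 1].
#' @export
#' @examples
#' coverage_fraction_for_cover(15) # 0.6
#' coverage_fraction_for_cover(25) # 0.4
#' coverage_fraction_for_cover(45) # 0.2
coverage_fraction_for_cover <- function(cover, breaks = c(20, 40),
                                        fractions = c(0.60, 0.40, 0.20)) {
  check_number(cover, "cover")
  if (cover <= 0) stop_input("cover must be positive")
  if (length(fractions) != length(breaks) + 1) {
    stop_input("need one fraction per class")
  }
  # middle classes closed on both boundaries: cover < 20 -> 0.60,
  # 20 <= cover <= 40 -> 0.40, cover > 40 -> 0.20
  if (length(breaks) == 0) return(fractions[1])
  last <- breaks[length(breaks)]
  idx <- 1L + sum(cover >= breaks[-length(breaks)]) + (cover > last)
  fractions[idx]
}

# Build an empty plants x species matrix and add whole-plant whole-study
# estimates cell by cell.
accumulate_matrix <- function(plant_ids, species_ids, plants, species, values) {
  mat <- matrix(0, nrow = length(plant_ids), ncol = length(species_ids),
                dimnames = list(plant_ids, species_ids))
  if (length(values) > 0) {
    idx <- cbind(match(plants, plant_ids), match(species, species_ids))
    for (k in seq_along(values)) {
      mat[idx[k, 1], idx[k, 2]] <- mat[idx[k, 1], idx[k, 2]] + values[k]
    }
  }
  mat
}

#' Standardize camera-trap records to whole-plant, whole-study visits
#'
#' Discards non-foraging records (behaviour filter), then scales each cell's
#' foraging-record count by 1 / coverage_fraction (area standardization) and
#' by study_days / recorded_days (time standardization):
#' estimate = n / coverage / (recorded_days / study_days). For the motivating
#' worked case, 4 recorded visits on a small plant (coverage 0.6) filmed for
#' 20% of the study give 4 / 0.6 = 6.7 whole-plant visits and 33.3 whole-study
#' visits.
#'
#' @param records data.frame with columns plant_id, species_id, n_records (or
#'   n_foraging_visits), recorded_days, coverage_fraction and optionally
#'   behaviour (rows with behaviour != "foraging" are dropped).
#' @param study_days total study duration in days.
#' @param plant_ids,species_ids optional orderings for the output matrix; by
#'   default the sorted ids present in the records.
#' @return numeric matrix (plants x species) of estimated visits.
#' @export
standardize_camera <- function(records, study_days, plant_ids = NULL,
                               species_ids = NULL) {
  check_number(study_days, "study_days", 1)
  if ("behaviour" %in% names(records)) {
    records <- records[records$behaviour == "foraging", , drop = FALSE]
  }
  count_col <- if ("n_records" %in% names(records)) "n_records" else "n_foraging_visits"
  needed <- c("plant_id", "species_id", count_col, "recorded_days", "coverage_fraction")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop_input("camera records lack columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(records) > 0) {
    if (any(records$recorded_days <= 0)) stop_input("recorded_days must be positive")
    if (any(records$recorded_days > study_days)) {
      stop_input("recorded_days exceed study_days")
    }
    if (any(records$coverage_fraction <= 0 | records$coverage_fraction > 1)) {
      stop_input("coverage_fraction must be in (0, 1]")
    }
    if (any(records[[count_col]] < 0)) stop_input("negative record counts")
  }
  plant_ids <- plant_ids %||% sort(unique(records$plant_id))
  species_ids <- species_ids %||% sort(unique(records$species_id))
  est <- records[[count_col]] / records$coverage_fraction /
    (records$recorded_days / study_days)
  accumulate_matrix(plant_ids, species_ids, records$plant_id,
                    records$species_id, est)
}

#' Standardize seed-trap / barcoding records to whole-plant, whole-study visits
#'
#' Drops UNIDENTIFIED samples (no reweighting by default), then scales each
#' identified count by the inverse sampled canopy fraction (capped at 1) and
#' the inverse active-time fraction:
#' estimate = n / min(1, sampled_area / canopy_area) / (active_days / study_days).
#'
#' @param records data.frame with columns plant_id, species_id, n_samples,
#'   sampled_area, canopy_area, active_days.
#' @param study_days total study duration in days.
#' @param inflate_unidentified if TRUE, identified counts are inflated by
#'   1 / id_success_observed (the fraction of samples identified) to account
#'   for dropped UNIDENTIFIED samples. Off by default.
#' @inheritParams standardize_camera
#' @return numeric matrix (plants x species) of estimated visits.
#' @export
standardize_scats <- function(records, study_days, plant_ids = NULL,
                              species_ids = NULL, inflate_unidentified = FALSE) {
  check_number(study_days, "study_days", 1)
  needed <- c("plant_id", "species_id", "n_samples", "sampled_area",
              "canopy_area", "active_days")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop_input("scat records lack columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(records) > 0) {
    if (any(records$canopy_area <= 0)) stop_input("canopy_area must be positive")
    if (any(records$sampled_area <= 0)) stop_input("sampled_area must be positive")
    if (any(records$active_days <= 0 | records$active_days > study_days)) {
      stop_input("active_days must be in (0, study_days]")
    }
  }
  inflation <- 1
  if (inflate_unidentified && nrow(records) > 0) {
    n_total <- sum(records$n_samples)
    n_id <- sum(records$n_samples[records$species_id != "UNIDENTIFIED"])
    if (n_id > 0) inflation <- n_total / n_id
  }
  records <- records[records$species_id != "UNIDENTIFIED", , drop = FALSE]
  plant_ids <- plant_ids %||% sort(unique(records$plant_id))
  species_ids <- species_ids %||% sort(unique(records$species_id))
  area_frac <- pmin(1, records$sampled_area / records$canopy_area)
  est <- inflation * records$n_samples / area_frac /
    (records$active_days / study_days)
  accumulate_matrix(plant_ids, species_ids, records$plant_id,
                    records$species_id, est)
}

#' Merge two standardized visit matrices
#'
#' Combines two whole-plant, whole-study visit matrices over the union of
#' their plant and species ids. The default rule is the cellwise sum, which
#' conserves totals (F_merged = F_a + F_b) since the two survey channels are
#' disjoint detection processes; the cellwise mean of the channels observing a
#' given cell is available as an option.
#'
#' @param a,b numeric matrices with plant rownames and species colnames.
#' @param rule "sum" (default) or "mean".
#' @return merged matrix over the union of ids.
#' @export
merge_visit_matrices <- function(a, b, rule = c("sum", "mean")) {
  rule <- match.arg(rule)
  for (m in list(a, b)) {
    if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
      stop_input("inputs must be matrices with plant rownames and species colnames")
    }
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
      stop_input("duplicate plant or species ids")
    }
    if (any(m < 0)) stop_input("visit estimates must be nonnegative")
  }
  plant_ids <- sort(union(rownames(a), rownames(b)))
  species_ids <- sort(union(colnames(a), colnames(b)))
  expand <- function(m) {
    out <- matrix(0, length(plant_ids), length(species_ids),
                  dimnames = list(plant_ids, species_ids))
    out[rownames(m), colnames(m)] <- m
    out
  }
  ea <- expand(a)
  eb <- expand(b)
  if (rule == "sum") {
    ea + eb
  } else {
    seen <- expand(matrix(1, nrow(a), ncol(a), dimnames = dimnames(a))) +
      expand(matrix(1, nrow(b), ncol(b), dimnames = dimnames(b)))
    out <- (ea + eb) / pmax(seen, 1)
    out
  }
}

#' Write / read a visit matrix as CSV
#'
#' Plain CSV with plant ids in the first column and species ids as headers.
#'
#' @param mat visit matrix.
#' @param path file path.
#' @export
write_visit_matrix <- function(mat, path) {
  df <- data.frame(plant_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' @rdname write_visit_matrix
#' @export
read_visit_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}
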