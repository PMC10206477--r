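# Shared fixtures built in code.

# small random interaction matrix with positive margins
random_matrix <- function(nr, nc, seed, lambda = 3) {
  set.seed(seed)
  repeat {
    m <- matrix(stats::rpois(nr * nc, lambda), nr, nc,
                dimnames = list(paste0("p", seq_len(nr)),
                                paste0("s", seq_len(nc))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# a perfectly block-diagonal matrix with `k` equal blocks of weight `w`
block_matrix <- function(k, w = 6) {
  m <- matrix(0, k, k, dimnames = list(paste0("p", seq_len(k)),
                                       paste0("s", seq_len(k))))
  diag(m) <- w
  m
}

# minimal single-cell camera record
one_camera_record <- function(n, coverage, recorded_days,
                              plant = "p1", species = "s1") {
  data.frame(plant_id = plant, species_id = species, behaviour = "foraging",
             n_records = n, recorded_days = recorded_days,
             coverage_fraction = coverage, stringsAsFactors = FALSE)
}

# a cached strong-signal pipeline run shared by several test files
strong_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- pipeline_config(synthesis = strong_signal_config(rng_seed = 11L),
                             n_null = 0, rng_seed = 11L)
      cache <<- suppressWarnings(run_all(cfg))
    }
    cache
  }
})
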