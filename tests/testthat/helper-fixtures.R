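# shared fixtures built in code

fix_scheme <- function() size_class_scheme()

# small 3-class structure with one fertility arc, for oracle comparisons
fix_structure3 <- function() {
  life_cycle_structure(data.frame(
    target = c(1L, 2L, 3L, 2L, 3L, 1L),
    source = c(1L, 2L, 3L, 1L, 2L, 3L),
    role = c("stasis", "stasis", "stasis", "growth", "growth", "fertility")),
    n_classes = 3L)
}

# noise-free series projected from a known matrix (no recruitment)
fix_series <- function(M, n0, steps) {
  gt <- ground_truth(M, n0)
  simulate_series(gt, steps)
}

# survey table used by the io/pipeline tests: synthetic truth observed at
# full effort with perfect detection so the pipeline is deterministic
fix_survey <- function(years = 2010:2014, stratum = "2m", seed = 11) {
  M <- example_porites_matrix()
  gt <- ground_truth(M, c(120, 80, 60, 30, 10),
                     recruitment = recruitment_spec(c(5, 0, 0, 3, 0), 0, 0))
  ser <- simulate_series(gt, max(years) - years[1])
  tr <- stats::setNames(rep(6L, length(years)), years)
  obs <- observation_model(tr, sc1_detection_prob = 1,
                           deterministic_detection = TRUE)
  emulate_survey(ser, obs, start_year = years[1], stratum = stratum, seed = seed)
}
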