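# shared fixtures: reference constants and small synthetic designs

ref_params <- egfr_reference_params()

truth_vector <- function() {
  c(K1_untreated = 104, K1_erlotinib = 25, K1_lapatinib = 162, K2 = 2.9,
    K3 = 1.3, K4 = 36900, K5 = 95, K6 = 0.45, K7 = 480, K8 = 0.1, K9 = 2.96)
}

# random positive parameter set, log-uniform around the reference magnitudes
random_params <- function(decades = 3) {
  r <- unclass(ref_params)
  do.call(egfr_params, as.list(r * 10^stats::runif(9, -decades, decades)))
}

noiseless_cells <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_binding_experiment(binding_sim_design(cv = 0, seed = 3))
    cache
  }
})

noisy_cells <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_binding_experiment(binding_sim_design(seed = 3))
    cache
  }
})

gauge_fix <- c(K2 = 2.9, K5 = 95)

conservation_error <- function(st) {
  abs(sum(st$species[1:6]) + 2 * sum(st$species[7:12]) - st$Rtot) /
    max(st$Rtot, 1)
}
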