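# shared fixtures for the test suite

paper_theta_grid <- function() 2 * pi * c(1, 2, 3, 4, 5, 7, 9) / 9
paper_alpha_grid <- function() pi * (1:11) / 11

# a fast desk-scale configuration used by several simulator tests
quick_config <- function(theta = 2 * pi, alpha = 2 * pi, seed = 1, ...) {
  sim_config(theta = theta, alpha = alpha, arena = 1.5, seed = seed, ...)
}

pbar_closed <- function(theta, alpha, r = 1) {
  mean_profile_closed(sensor_spec(theta, r), signal_spec(alpha))$p_bar
}

pbar_numeric <- function(theta, alpha, r = 1, tol = 1e-6) {
  mean_profile_numeric(sensor_spec(theta, r), signal_spec(alpha), tol = tol)$p_bar
}
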