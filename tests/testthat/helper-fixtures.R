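# shared fixtures: everything is generated in code at test time

default_scene <- scene_config()

# samples whose targets are an exact affine function of the four features:
# the generating map is recoverable by any degree >= 1 polynomial fit
affine_samples <- function(n = 50, seed = 1,
                           beta_x = c(0.5, 0.8, -0.2, 0.3, 0.1),
                           beta_y = c(0.4, -0.1, 0.7, 0.05, -0.3)) {
  set.seed(seed)
  X <- matrix(runif(n * 4, -0.5, 0.5), n, 4)
  data.frame(frame = seq_len(n),
             target_x = beta_x[1] + X %*% beta_x[-1],
             target_y = beta_y[1] + X %*% beta_y[-1],
             phi_l = X[, 1], theta_l = X[, 2],
             phi_r = X[, 3], theta_r = X[, 4])
}

noise_off <- function(seed = NULL)
  noise_config(p_error = 0, r_error = 0, sigma_prec = 0, p_fd = 0, seed = seed)

# clean binocular simulation of a pattern with optional kappa (radians)
clean_samples <- function(pattern, kh = 0, kv = 0, scene = default_scene) {
  simulate_pattern(pattern, scene, kappa_pair(kh, kv), kappa_pair(kh, kv))
}
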