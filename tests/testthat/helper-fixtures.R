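# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; no binary data.

.fx <- new.env(parent = emptyenv())

# Small block-program simulation: 400 cells x 40 genes, 2 factors.
small_sim <- function() {
  if (is.null(.fx$sim)) {
    .fx$sim <- simulate_scenario(
      sim_scenario(n_cells = 400, n_genes = 40, n_factors = 2,
                   theta_range = c(5, 5), depth_log_mean = log(500), seed = 42)
    )
  }
  .fx$sim
}

# A short fit of the small simulation (normal latent, linear decoder).
small_fit <- function() {
  if (is.null(.fx$fit)) {
    .fx$fit <- fit_ldvae(
      small_sim()$counts,
      model_config(n_factors = 2),
      train_config(n_epochs = 30, seed = 7, holdout_fraction = 0.1)
    )
  }
  .fx$fit
}

# Random but valid posterior for sampling tests.
random_posterior <- function(n = 50, d = 3, seed = 1) {
  set.seed(seed)
  structure(list(
    z_loc = matrix(rnorm(n * d), n, d),
    z_scale = matrix(exp(rnorm(n * d, -1, 0.3)), n, d),
    s_loc = rnorm(n, log(500), 0.3),
    s_scale = exp(rnorm(n, -1, 0.2))
  ), class = "latent_posterior")
}

# Tiny untrained model for engine-level tests.
tiny_model <- function(cfg, seed = 3, G = 7) {
  init_ldvae(G, cfg, seed = seed, s_mu = log(30), s_sigma = 0.5)
}
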