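# Shared fixtures: everything is generated in code at test time.

# A small simulated source/target pair, cached per (intensity, seed) within
# the test session.
small_pair <- local({
  cache <- list()
  function(intensity = 0.2, seed = 101L, n_genes = 300L, n_source = 120L,
           n_target = 80L) {
    key <- paste(intensity, seed, n_genes, n_source, n_target, sep = "_")
    if (is.null(cache[[key]])) {
      p <- simulation_params(n_genes = n_genes, n_source_cells = n_source,
                             n_target_cells = n_target, n_groups = 4L,
                             batch_fac_loc = intensity, seed = seed)
      cache[[key]] <<- simulate_pair(p)
    }
    cache[[key]]
  }
})

# Preprocess a pair down to an HVG-layer pair ready for train().
prep_pair <- function(pair, n_hvg = 60L) {
  cfg <- preprocess_config(n_hvg = n_hvg)
  select_hvg(lognorm(pair$source, cfg), lognorm(pair$target, cfg), cfg)
}

# A tiny model for shape/gradient tests.
tiny_model <- function(input_dim = 7L, n_classes = 3L, seed = 7L,
                       batchnorm = TRUE, grl_lambda = 2.0) {
  init_model(model_spec(input_dim = input_dim, n_classes = n_classes,
                        encoder_dims = c(6L, 4L), discriminator_dims = 5L,
                        batchnorm = batchnorm, grl_lambda = grl_lambda,
                        seed = seed))
}

# Random probability-simplex rows.
random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# Analytic + finite-difference gradients of the domain-BCE of Do(E(X)) with
# respect to the encoder parameters (used by the GRL gradient checks).
domain_head_grads <- function(model, X, y01, grl_lambda = NULL, h = 1e-5) {
  enc <- model$encoder
  dis <- model$discriminator
  lossfun <- function(theta) {
    e2 <- scrdan:::mlp_set_params(enc, theta)
    fe <- scrdan:::mlp_forward(e2, X, training = TRUE)
    fl <- scrdan:::mlp_forward(dis, fe$out, training = TRUE)
    o <- 1 / (1 + exp(-fl$out))
    -mean(y01 * log(o) + (1 - y01) * log(1 - o))
  }
  theta <- scrdan:::mlp_get_params(enc)
  fe <- scrdan:::mlp_forward(enc, X, training = TRUE)
  fl <- scrdan:::mlp_forward(dis, fe$out, training = TRUE)
  o <- 1 / (1 + exp(-fl$out))
  bd <- scrdan:::mlp_backward(dis, fl$caches, (o - y01) / length(y01))
  dZ <- if (is.null(grl_lambda)) bd$dX else grl_backward(bd$dX, grl_lambda)
  be <- scrdan:::mlp_backward(enc, fe$caches, dZ)
  analytic <- scrdan:::mlp_flatten_grads(enc, be$grads)
  fd <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (lossfun(tp) - lossfun(tm)) / (2 * h)
  }, numeric(1))
  list(analytic = analytic, fd = fd)
}
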