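#' Parameters for the two-batch count simulator
#'
#' The simulator draws a reduced Splat-style Gamma-Poisson model: baseline
#' gene means from a Gamma, multiplicative per-group differential-expression
#' (DE) factors, multiplicative per-batch factors, log-normal library sizes,
#' and Poisson counts. The single batch-effect "intensity" knob of the study
#' design sets `batch_fac_loc = batch_fac_scale`, so larger values push the
#' two batches further apart on the log scale.
#'
#' @param n_genes number of genes (default 10000).
#' @param n_source_cells cells in the labeled source batch (default 2000).
#' @param n_target_cells cells in the unlabeled target batch (default 1000).
#' @param n_groups number of cell types shared by the two batches (default 4).
#' @param batch_fac_loc log-normal location of per-batch gene factors (>= 0).
#' @param batch_fac_scale log-normal scale of per-batch gene factors (>= 0).
#' @param de_prob fraction of genes DE in each group, in (0, 1] (default 0.1).
#' @param de_fac_scale log-normal scale of DE factors (default 0.2, the weak
#'   signal regime).
#' @param lib_loc log-scale mean library size (default 11, i.e. ~60k counts).
#' @param lib_scale log-scale sd of library size (default 0.2).
#' @param mean_shape,mean_rate Gamma shape/rate for baseline gene means
#'   (defaults 0.6, 0.3).
#' @param group_probs per-group proportions summing to 1 (default uniform).
#' @param seed RNG seed (default 1).
#' @return A `SimulationParams` list.
#' @export
simulation_params <- function(n_genes = 10000,
                              n_source_cells = 2000,
                              n_target_cells = 1000,
                              n_groups = 4,
                              batch_fac_loc = 0.2,
                              batch_fac_scale = batch_fac_loc,
                              de_prob = 0.1,
                              de_fac_scale = 0.2,
                              lib_loc = 11.0,
                              lib_scale = 0.2,
                              mean_shape = 0.6,
                              mean_rate = 0.3,
                              group_probs = rep(1 / n_groups, n_groups),
                              seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            n_source_cells = as.integer(n_source_cells),
            n_target_cells = as.integer(n_target_cells),
            n_groups = as.integer(n_groups),
            batch_fac_loc = batch_fac_loc, batch_fac_scale = batch_fac_scale,
            de_prob = de_prob, de_fac_scale = de_fac_scale,
            lib_loc = lib_loc, lib_scale = lib_scale,
            mean_shape = mean_shape, mean_rate = mean_rate,
            group_probs = group_probs, seed = as.integer(seed))
  with(p, {
    if (n_genes < 1 || n_source_cells < 1 || n_target_cells < 1 || n_groups < 1)
      stop("all counts must be positive", call. = FALSE)
    if (n_groups > n_source_cells)
      stop("n_groups (", n_groups, ") exceeds n_source_cells (", n_source_cells,
           ")", call. = FALSE)
    if (batch_fac_loc < 0 || batch_fac_scale < 0)
      stop("batch factor location/scale must be non-negative", call. = FALSE)
    if (de_fac_scale < 0 || lib_scale < 0)
      stop("scales must be non-negative", call. = FALSE)
    if (de_prob <= 0 || de_prob > 1)
      stop("de_prob must lie in (0, 1]", call. = FALSE)
    if (length(group_probs) != n_groups)
      stop("group_probs must have length n_groups", call. = FALSE)
    if (abs(sum(group_probs) - 1) > 1e-9)
      stop("group_probs must sum to 1", call. = FALSE)
    if (mean_shape <= 0 || mean_rate <= 0)
      stop("gamma parameters must be positive", call. = FALSE)
  })
  structure(p, class = "SimulationParams")
}

# Draws one batch of cells given shared gene-level parameters.
simulate_batch <- function(params, n_cells, base_mean, de_factors, batch_factors,
                           domain, id_prefix) {
  groups <- sample.int(params$n_groups, n_cells, replace = TRUE,
                       prob = params$group_probs)
  lib_sizes <- stats::rlnorm(n_cells, meanlog = params$lib_loc,
                             sdlog = params$lib_scale)
  # per-group expected gene profile, normalized to proportions
  profiles <- base_mean * de_factors * batch_factors       # genes x groups
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  lambda <- t(profiles[, groups, drop = FALSE]) * lib_sizes # cells x genes
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = n_cells)
  expression_dataset(
    counts,
    gene_names = sprintf("Gene%05d", seq_len(params$n_genes)),
    cell_ids = sprintf("%s%05d", id_prefix, seq_len(n_cells)),
    labels = sprintf("Group%d", groups),
    domain = domain, layer = "counts"
  )
}

#' Simulate a paired source/target dataset with a batch effect
#'
#' Both batches share the baseline gene means and the per-group DE factors
#' (the biology), but each batch receives its own log-normal per-gene batch
#' factor (the technical effect). Group labels are generated for both batches;
#' the target labels serve only as ground truth for evaluation and are never
#' read by the trainer.
#'
#' Generative recipe, per gene g and cell c in batch b with group k:
#' lambda_g ~ Gamma(mean_shape, rate = mean_rate); DE factor f_kg = 1 except
#' for a `de_prob` fraction per group where f_kg = exp(s |N(0, de_fac_scale)|)
#' with sign s = +/-1 equiprobable; batch factor B_bg = exp(N(s_bg *
#' batch_fac_loc, batch_fac_scale)) with s_bg = +/-1 per gene per batch;
#' expected expression = L_c * normalized(lambda * f * B); counts ~ Poisson;
#' L_c ~ LogNormal(lib_loc, lib_scale).
#'
#' @param params a [simulation_params()] object.
#' @return A list with elements `source` and `target`, both count-layer
#'   [expression_dataset()]s sharing the same genes.
#' @export
simulate_pair <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  G <- params$n_genes
  K <- params$n_groups
  base_mean <- stats::rgamma(G, shape = params$mean_shape, rate = params$mean_rate)
  base_mean <- pmax(base_mean, 1e-8)

  de_factors <- matrix(1, nrow = G, ncol = K)
  for (k in seq_len(K)) {
    is_de <- stats::runif(G) < params$de_prob
    n_de <- sum(is_de)
    if (n_de > 0) {
      mag <- abs(stats::rnorm(n_de, 0, params$de_fac_scale))
      sign <- ifelse(stats::runif(n_de) < 0.5, -1, 1)
      de_factors[is_de, k] <- exp(sign * mag)
    }
  }

  batch_factor <- function() {
    s <- ifelse(stats::runif(G) < 0.5, -1, 1)
    exp(stats::rnorm(G, mean = s * params$batch_fac_loc,
                     sd = params$batch_fac_scale))
  }
  b_source <- batch_factor()
  b_target <- batch_factor()

  source <- simulate_batch(params, params$n_source_cells, base_mean, de_factors,
                           b_source, "source", "SRC")
  target <- simulate_batch(params, params$n_target_cells, base_mean, de_factors,
                           b_target, "target", "TGT")
  list(source = source, target = target)
}

#' Simulate a grid of batch-effect intensities with replicates
#'
#' For each intensity v the batch factor location and scale are both set to v
#' (the single-knob convention) and `replicates` independent pairs are drawn.
#' Replicate seeds are `base$seed + 1000 * (intensity index - 1) + (replicate
#' index - 1)`, so the sweep is reproducible and replicate streams do not
#' collide.
#'
#' @param base a [simulation_params()] used as template.
#' @param intensities non-empty numeric vector of batch-effect intensities.
#' @param replicates number of replicate simulations per intensity (>= 1).
#' @return A list of `length(intensities) * replicates` entries, each a list
#'   with `intensity`, `replicate`, `source`, `target`.
#' @export
sweep_intensities <- function(base, intensities, replicates = 5L) {
  stopifnot(inherits(base, "SimulationParams"))
  if (length(intensities) == 0) stop("intensities must be non-empty", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  out <- vector("list", length(intensities) * replicates)
  n <- 0L
  for (i in seq_along(intensities)) {
    for (r in seq_len(replicates)) {
      p <- base
      p$batch_fac_loc <- intensities[i]
      p$batch_fac_scale <- intensities[i]
      p$seed <- as.integer(base$seed + 1000L * (i - 1L) + (r - 1L))
      pair <- simulate_pair(p)
      n <- n + 1L
      out[[n]] <- list(intensity = intensities[i], replicate = r,
                       source = pair$source, target = pair$target)
    }
  }
  out
}

# Save/restore the global RNG state so simulation calls do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
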