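#' Loss term weights and regularization knobs
#'
#' @param lambda_da weight of the adversarial domain loss (default 2).
#' @param lambda_mse weight of the reconstruction loss (default 1).
#' @param lambda_vat weight of the virtual adversarial loss (default 1).
#' @param margin_alpha triplet margin alpha > 0 (default 1).
#' @param consistency_dropout_p feature-dropout fraction for the consistency
#'   views, in (0, 1) (default 0.2).
#' @param vat_epsilon L2 radius of the adversarial perturbation (default 1).
#' @param vat_candidates number of random directions scored per batch; the one
#'   with maximal KL divergence is the adversarial perturbation (default 10).
#' @return A `LossWeights` list.
#' @export
loss_weights <- function(lambda_da = 2.0, lambda_mse = 1.0, lambda_vat = 1.0,
                         margin_alpha = 1.0, consistency_dropout_p = 0.2,
                         vat_epsilon = 1.0, vat_candidates = 10L) {
  if (lambda_da < 0 || lambda_mse < 0 || lambda_vat < 0)
    stop("loss weights must be >= 0", call. = FALSE)
  if (margin_alpha <= 0) stop("margin_alpha must be > 0", call. = FALSE)
  if (consistency_dropout_p <= 0 || consistency_dropout_p >= 1)
    stop("consistency_dropout_p must lie in (0, 1)", call. = FALSE)
  if (vat_epsilon < 0) stop("vat_epsilon must be >= 0", call. = FALSE)
  if (vat_candidates < 1) stop("vat_candidates must be >= 1", call. = FALSE)
  structure(list(lambda_da = lambda_da, lambda_mse = lambda_mse,
                 lambda_vat = lambda_vat, margin_alpha = margin_alpha,
                 consistency_dropout_p = consistency_dropout_p,
                 vat_epsilon = vat_epsilon,
                 vat_candidates = as.integer(vat_candidates)),
            class = "LossWeights")
}

LOG_CLAMP <- 1e-12

#' Denoising reconstruction loss
#'
#' Mean (over cells, per domain) of the squared reconstruction residual summed
#' over genes, added across the two domains.
#'
#' @param Xs,Xs_rec source input and reconstruction (cells x genes).
#' @param Xt,Xt_rec target input and reconstruction.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(Xs, Xs_rec, Xt, Xt_rec) {
  if (!identical(dim(Xs), dim(Xs_rec)))
    stop("source reconstruction shape mismatch", call. = FALSE)
  if (!identical(dim(Xt), dim(Xt_rec)))
    stop("target reconstruction shape mismatch", call. = FALSE)
  sum((Xs - Xs_rec)^2) / nrow(Xs) + sum((Xt - Xt_rec)^2) / nrow(Xt)
}

#' Label prediction (cross-entropy) loss
#'
#' Mean negative log probability of the true class over source cells.
#' Probabilities are clamped at 1e-12 before the log for numerical safety.
#'
#' @param probs matrix of class probabilities, cells x K (rows sum to 1).
#' @param labels integer class indices in 1..K, or a character/factor vector
#'   matching `colnames(probs)`.
#' @return Non-negative scalar.
#' @export
label_loss <- function(probs, labels) {
  idx <- label_indices(labels, probs)
  p_true <- pmax(probs[cbind(seq_len(nrow(probs)), idx)], LOG_CLAMP)
  -mean(log(p_true))
}

label_indices <- function(labels, probs) {
  if (is.numeric(labels)) {
    idx <- as.integer(labels)
  } else {
    if (is.null(colnames(probs)))
      stop("character labels need colnames(probs)", call. = FALSE)
    idx <- match(as.character(labels), colnames(probs))
    if (anyNA(idx)) stop("labels not found among classes", call. = FALSE)
  }
  if (length(idx) != nrow(probs))
    stop("labels length must match rows of probs", call. = FALSE)
  if (any(idx < 1 | idx > ncol(probs)))
    stop("label index out of range", call. = FALSE)
  idx
}

#' Domain discrimination loss
#'
#' Binary cross-entropy with the source domain labeled 1 and the target
#' domain 0: `-mean(log d_source) - mean(log(1 - d_target))`.
#'
#' @param d_source discriminator probabilities for source cells.
#' @param d_target discriminator probabilities for target cells.
#' @return Non-negative scalar.
#' @export
domain_loss <- function(d_source, d_target) {
  ds <- pmin(pmax(d_source, LOG_CLAMP), 1 - LOG_CLAMP)
  dt <- pmin(pmax(d_target, LOG_CLAMP), 1 - LOG_CLAMP)
  -mean(log(ds)) - mean(log(1 - dt))
}

squared_dist_matrix <- function(Z) {
  sq <- rowSums(Z^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  pmax(D, 0)
}

#' Batch-hard triplet mining
#'
#' For every anchor cell that has at least one same-type peer and one
#' different-type cell in the batch, selects the farthest positive (same type,
#' maximal squared Euclidean distance in the embedding) and the closest
#' negative (different type, minimal distance). Ties are broken by the lowest
#' cell index. Anchors lacking a valid positive or negative are skipped.
#'
#' @param Z embedding matrix, cells x d.
#' @param labels per-cell type labels.
#' @return A `TripletIndices` list of parallel integer vectors `anchor`,
#'   `positive`, `negative` (possibly empty).
#' @export
mine_triplets <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.character(labels)
  if (length(labels) != nrow(Z))
    stop("labels length must match rows of Z", call. = FALSE)
  n <- nrow(Z)
  D <- squared_dist_matrix(Z)
  anchor <- integer(0); positive <- integer(0); negative <- integer(0)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- same[same != i]
    diff <- which(labels != labels[i])
    if (length(same) == 0 || length(diff) == 0) next
    pos <- same[which.max(D[i, same])]
    neg <- diff[which.min(D[i, diff])]
    anchor <- c(anchor, i); positive <- c(positive, pos); negative <- c(negative, neg)
  }
  structure(list(anchor = anchor, positive = positive, negative = negative),
            class = "TripletIndices")
}

#' Triplet margin loss
#'
#' Sum over anchors of the hinge `max(0, ||z_a - z_p||^2 - ||z_a - z_n||^2 +
#' alpha)` with squared Euclidean distances.
#'
#' @param Z embedding matrix, cells x d.
#' @param triplets a [mine_triplets()] result.
#' @param alpha margin > 0.
#' @return Non-negative scalar (0 when there are no triplets).
#' @export
triplet_loss <- function(Z, triplets, alpha) {
  if (length(triplets$anchor) == 0) return(0)
  Z <- as.matrix(Z)
  d_ap <- rowSums((Z[triplets$anchor, , drop = FALSE] -
                   Z[triplets$positive, , drop = FALSE])^2)
  d_an <- rowSums((Z[triplets$anchor, , drop = FALSE] -
                   Z[triplets$negative, , drop = FALSE])^2)
  sum(pmax(d_ap - d_an + alpha, 0))
}

draw_masks <- function(n, d, p) {
  matrix(stats::runif(n * d) >= p, n, d) * 1
}

#' Consistency loss over feature-dropout views
#'
#' Two independent Bernoulli(1 - p) feature masks per cell produce two
#' augmented views; the loss is the mean over cells of the summed squared
#' distances between the clean embedding and each view's embedding.
#' Fresh masks are drawn from the current RNG stream unless `masks` injects
#' them (a list of two 0/1 matrices), which makes the value reproducible for
#' testing.
#'
#' @param model a `DANModel`.
#' @param X source batch, cells x input_dim.
#' @param p feature-dropout fraction in (0, 1).
#' @param masks optional list of two 0/1 matrices shaped like `X`.
#' @param training batch-norm mode for the encoder passes.
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(model, X, p, masks = NULL, training = FALSE) {
  X <- check_input_dim(X, model$spec$input_dim, "consistency_loss")
  if (is.null(masks)) {
    if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
    masks <- list(draw_masks(nrow(X), ncol(X), p),
                  draw_masks(nrow(X), ncol(X), p))
  }
  Z <- encode(model, X, training = training)
  Z1 <- encode(model, X * masks[[1]], training = training)
  Z2 <- encode(model, X * masks[[2]], training = training)
  (sum((Z - Z1)^2) + sum((Z - Z2)^2)) / nrow(X)
}

kl_rows <- function(p, q) {
  p <- pmax(p, LOG_CLAMP)
  q <- pmax(q, LOG_CLAMP)
  rowSums(p * (log(p) - log(q)))
}

# Draw a perturbation matrix with unit L2 norm per cell, scaled by epsilon.
vat_direction <- function(n, d, epsilon) {
  r <- matrix(stats::rnorm(n * d), n, d)
  norms <- sqrt(rowSums(r^2))
  r / pmax(norms, 1e-12) * epsilon
}

#' Virtual adversarial training loss
#'
#' Draws `n_candidates` random unit directions per batch, scales each to L2
#' radius `epsilon`, and computes the KL divergence from the clean predictive
#' distribution (treated as constant) to the perturbed one. The candidate
#' with the maximal mean KL is the adversarial perturbation and its KL is the
#' loss.
#'
#' @param model a `DANModel`.
#' @param X target batch, cells x input_dim.
#' @param epsilon perturbation radius >= 0.
#' @param n_candidates number of random directions (>= 1).
#' @param training batch-norm mode for the encoder passes.
#' @return A list: `value` (the max-candidate mean KL), `candidate_kls` (mean
#'   KL per candidate), `r` (the selected perturbation matrix).
#' @export
vat_loss <- function(model, X, epsilon, n_candidates = 10L, training = FALSE) {
  X <- check_input_dim(X, model$spec$input_dim, "vat_loss")
  if (n_candidates < 1) stop("n_candidates must be >= 1", call. = FALSE)
  p_clean <- classify(model, encode(model, X, training = training))
  kls <- numeric(n_candidates)
  best <- NULL
  for (k in seq_len(n_candidates)) {
    r <- vat_direction(nrow(X), ncol(X), epsilon)
    p_pert <- classify(model, encode(model, X + r, training = training))
    kls[k] <- mean(kl_rows(p_clean, p_pert))
    if (is.null(best) || kls[k] > kls[best]) best <- k
    if (k == best) best_r <- r
  }
  list(value = kls[best], candidate_kls = kls, r = best_r)
}

#' Assemble the total training loss
#'
#' `L_DDANN = L_CE + lambda_da * L_DA + lambda_mse * L_mse`;
#' `L_CV = L_con + lambda_vat * L_vat`;
#' `L_total = L_DDANN + L_tri + L_CV`.
#'
#' @param components named list or vector with elements `ce`, `da`, `mse`,
#'   `tri`, `con`, `vat` (missing terms default to 0).
#' @param weights a [loss_weights()].
#' @return A list with `total` and the weighted `breakdown` (named numeric:
#'   ce, da, mse, tri, con, vat, ddann, cv, total).
#' @export
total_loss <- function(components, weights = loss_weights()) {
  comp <- c(ce = 0, da = 0, mse = 0, tri = 0, con = 0, vat = 0)
  comp[names(components)] <- unlist(components)
  bad <- names(comp)[!is.finite(comp)]
  if (length(bad) > 0) {
    stop("non-finite loss component: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ddann <- comp[["ce"]] + weights$lambda_da * comp[["da"]] +
    weights$lambda_mse * comp[["mse"]]
  cv <- comp[["con"]] + weights$lambda_vat * comp[["vat"]]
  total <- ddann + comp[["tri"]] + cv
  list(total = total,
       breakdown = c(comp, ddann = ddann, cv = cv, total = total))
}
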