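#' Network architecture specification
#'
#' The model has four parts sharing a latent space: an encoder E mapping the
#' HVG expression vector to the latent embedding, a mirrored decoder D
#' reconstructing the input (the denoising path), a linear label classifier F,
#' and a domain discriminator Do reached through a gradient reversal layer.
#'
#' @param input_dim number of input features (the HVG count).
#' @param n_classes number of cell types K (>= 2).
#' @param encoder_dims hidden widths of the encoder; the last entry is the
#'   latent dimension (default `c(512, 256)`).
#' @param classifier_dims hidden widths of the classifier; empty means a single
#'   linear layer latent -> K (default).
#' @param discriminator_dims hidden widths of the discriminator (default 128).
#' @param grl_lambda gradient reversal coefficient lambda >= 0 (default 2).
#' @param batchnorm use batch normalization in encoder/decoder hidden layers
#'   (default TRUE).
#' @param seed RNG seed for parameter initialization.
#' @return A `ModelSpec` list.
#' @export
model_spec <- function(input_dim, n_classes,
                       encoder_dims = c(512L, 256L),
                       classifier_dims = integer(0),
                       discriminator_dims = 128L,
                       grl_lambda = 2.0,
                       batchnorm = TRUE,
                       seed = 1L) {
  if (input_dim < 1) stop("input_dim must be positive", call. = FALSE)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (grl_lambda < 0) stop("grl_lambda must be >= 0", call. = FALSE)
  if (length(encoder_dims) < 1) stop("encoder_dims must be non-empty", call. = FALSE)
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 encoder_dims = as.integer(encoder_dims),
                 latent_dim = as.integer(encoder_dims[length(encoder_dims)]),
                 classifier_dims = as.integer(classifier_dims),
                 discriminator_dims = as.integer(discriminator_dims),
                 grl_lambda = grl_lambda,
                 batchnorm = isTRUE(batchnorm),
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

#' Initialize the four network components
#'
#' Encoder: input -> encoder_dims, every layer BN (optional) + ReLU, so the
#' latent embedding is the encoder's last activation. Decoder mirrors the
#' encoder back to the input with a linear output. Classifier and
#' discriminator are small ReLU MLPs with linear resp. sigmoid outputs; the
#' classifier's softmax lives in [classify()].
#'
#' @param spec a [model_spec()].
#' @param class_names character vector of length `n_classes`; maps class index
#'   to cell-type label.
#' @return A `DANModel` list with components `encoder`, `decoder`,
#'   `classifier`, `discriminator`, plus `spec` and `class_names`.
#' @export
init_model <- function(spec, class_names = NULL) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (is.null(class_names)) {
    class_names <- sprintf("class%d", seq_len(spec$n_classes))
  }
  if (length(class_names) != spec$n_classes) {
    stop("class_names must have length n_classes", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  enc_dims <- c(spec$input_dim, spec$encoder_dims)
  dec_dims <- rev(enc_dims)
  model <- list(
    encoder = mlp_init(enc_dims, batchnorm = spec$batchnorm,
                       hidden_act = "relu", out_act = "relu",
                       bn_out = spec$batchnorm),
    decoder = mlp_init(dec_dims, batchnorm = spec$batchnorm,
                       hidden_act = "relu", out_act = "linear"),
    classifier = mlp_init(c(spec$latent_dim, spec$classifier_dims,
                            spec$n_classes),
                          batchnorm = FALSE, hidden_act = "relu",
                          out_act = "linear"),
    # linear output; the sigmoid lives in discriminate() so the training
    # loop can use the numerically stable logit form of the BCE gradient
    discriminator = mlp_init(c(spec$latent_dim, spec$discriminator_dims, 1L),
                             batchnorm = FALSE, hidden_act = "relu",
                             out_act = "linear"),
    spec = spec,
    class_names = as.character(class_names)
  )
  structure(model, class = "DANModel")
}

check_input_dim <- function(X, dim, what) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != dim) {
    stop(what, " expects ", dim, " columns, got ", ncol(X), call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' Encode expression profiles into the latent space
#'
#' @param model a `DANModel` (from [init_model()] or [train()]).
#' @param X numeric matrix, cells x input_dim.
#' @param training use batch statistics for batch normalization (TRUE) or the
#'   stored running statistics (FALSE, deterministic; the default).
#' @return Matrix of latent embeddings, cells x latent_dim.
#' @export
encode <- function(model, X, training = FALSE) {
  X <- check_input_dim(X, model$spec$input_dim, "encode")
  if (training) mlp_forward(model$encoder, X, training = TRUE)$out
  else mlp_infer(model$encoder, X)
}

#' Reconstruct expression profiles from latent embeddings
#'
#' @param model a `DANModel`.
#' @param Z latent matrix, cells x latent_dim.
#' @inheritParams encode
#' @return Reconstructed matrix, cells x input_dim.
#' @export
decode <- function(model, Z, training = FALSE) {
  Z <- check_input_dim(Z, model$spec$latent_dim, "decode")
  if (training) mlp_forward(model$decoder, Z, training = TRUE)$out
  else mlp_infer(model$decoder, Z)
}

#' Class probabilities from latent embeddings
#'
#' @param model a `DANModel`.
#' @param Z latent matrix, cells x latent_dim.
#' @return Matrix of class probabilities, cells x K; rows sum to 1.
#' @export
classify <- function(model, Z) {
  Z <- check_input_dim(Z, model$spec$latent_dim, "classify")
  p <- softmax_rows(mlp_infer(model$classifier, Z))
  colnames(p) <- model$class_names
  p
}

#' Domain probability from latent embeddings
#'
#' Returns the discriminator's probability that each cell comes from the
#' source domain (source is labeled 1, target 0).
#'
#' @param model a `DANModel`.
#' @param Z latent matrix, cells x latent_dim (typically [grl_apply()] output).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
discriminate <- function(model, Z) {
  Z <- check_input_dim(Z, model$spec$latent_dim, "discriminate")
  logits <- mlp_infer(model$discriminator, Z)
  as.numeric(1 / (1 + exp(-logits)))
}

#' Gradient reversal layer
#'
#' Forward pass: the identity (the returned matrix equals `Z` elementwise).
#' Backward pass: the gradient flowing back to `Z` is `-lambda` times the
#' gradient arriving from the discriminator, which is what turns the
#' discriminator's minimization into the encoder's maximization. In this
#' package gradients are propagated by explicit backward routines, so the
#' reversal is realized by [grl_backward()]; the training loop applies it to
#' the discriminator's input gradient before it reaches the encoder.
#'
#' @param Z latent matrix.
#' @param lambda reversal coefficient >= 0.
#' @return `Z`, unchanged.
#' @export
grl_apply <- function(Z, lambda) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  Z
}

#' @rdname grl_apply
#' @param dZ gradient arriving at the GRL output.
#' @return For `grl_backward`: `-lambda * dZ`, the gradient passed on to the
#'   encoder.
#' @export
grl_backward <- function(dZ, lambda) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  -lambda * dZ
}

#' Save / load a trained model
#'
#' Checkpoints are written with [saveRDS()] and round-trip exactly: the loaded
#' object is identical to the saved one, including architecture spec, weights,
#' running statistics, class name mapping, and training provenance.
#'
#' @param model a `DANModel` or `TrainedModel`.
#' @param path file path for the checkpoint.
#' @return `save_model`: `path` invisibly. `load_model`: the model object.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
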