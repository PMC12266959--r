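#' Optimization configuration
#'
#' SGD with momentum, L2 weight decay, and an inverse-decay learning rate
#' schedule `lr0 * (1 + lr_decay * step)^(-lr_power)` evaluated per optimizer
#' step.
#'
#' @param lr0 initial learning rate (default 0.001).
#' @param lr_decay decay factor of the schedule (default 0.001).
#' @param lr_power power exponent of the schedule (default 0.9).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty on linear weights (default 5e-4).
#' @param epochs maximum number of epochs (default 200).
#' @param batch_size mini-batch size per domain (default 256, >= 2).
#' @param seed RNG seed governing shuffling, masks, and perturbations.
#' @param ablation character vector among `no_mse`, `no_da`, `no_tri`,
#'   `no_con`, `no_vat`; each removes the corresponding loss term entirely.
#' @param patience early-stopping patience in epochs (default 20).
#' @param min_delta minimal epoch-loss improvement counted as progress
#'   (default 1e-4).
#' @param verbose print an epoch summary line every 10 epochs.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(lr0 = 0.001, lr_decay = 0.001, lr_power = 0.9,
                         momentum = 0.9, weight_decay = 5e-4,
                         epochs = 200L, batch_size = 256L, seed = 1L,
                         ablation = character(0),
                         patience = 20L, min_delta = 1e-4,
                         verbose = FALSE) {
  if (lr0 <= 0) stop("lr0 must be positive", call. = FALSE)
  if (batch_size < 2) stop("batch_size must be >= 2", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  valid <- c("no_mse", "no_da", "no_tri", "no_con", "no_vat")
  bad <- setdiff(ablation, valid)
  if (length(bad) > 0) {
    stop("unknown ablation flag(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  structure(list(lr0 = lr0, lr_decay = lr_decay, lr_power = lr_power,
                 momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), ablation = ablation,
                 patience = as.integer(patience), min_delta = min_delta,
                 verbose = isTRUE(verbose)),
            class = "TrainConfig")
}

#' Learning rate at a given optimizer step
#'
#' @param step optimizer step, 0-based.
#' @param cfg a [train_config()].
#' @return `lr0 * (1 + lr_decay * step)^(-lr_power)`, strictly decreasing.
#' @export
lr_at <- function(step, cfg = train_config()) {
  if (any(step < 0)) stop("step must be >= 0", call. = FALSE)
  cfg$lr0 * (1 + cfg$lr_decay * step)^(-cfg$lr_power)
}

# Shuffled index stream over n items that reshuffles when exhausted, so the
# smaller domain cycles while the larger one defines the epoch.
batch_stream <- function(n) {
  pool <- sample.int(n)
  pos <- 0L
  function(size) {
    size <- min(size, n)
    if (pos + size > length(pool)) {
      pool <<- sample.int(n)
      pos <<- 0L
    }
    out <- pool[(pos + 1L):(pos + size)]
    pos <<- pos + size
    out
  }
}

#' Train the domain-adversarial annotation model
#'
#' Runs the full optimization: per step a source and a target mini-batch are
#' drawn (independent shuffles, the smaller domain cycling); the encoder
#' embeds both; the decoder reconstructs both (reconstruction loss); the
#' classifier predicts source labels (cross-entropy); the discriminator
#' classifies domains through the gradient reversal layer (adversarial
#' alignment); batch-hard triplets shape the source embedding; feature-dropout
#' consistency and virtual adversarial perturbations regularize source resp.
#' target; one SGD step is taken on the weighted total. Ablation flags remove
#' a term and skip its computation; a component that receives no gradient
#' (decoder under `no_mse`, discriminator under `no_da`) is left untouched.
#'
#' The run is deterministic given `config$seed` (and `spec$seed` for the
#' initialization).
#'
#' @param source labeled [expression_dataset()] (layer `hvg` or `lognorm`).
#' @param target unlabeled [expression_dataset()] with the same genes in the
#'   same order; labels, if present, are ignored.
#' @param spec a [model_spec()]; defaults to one derived from the data
#'   (input_dim = gene count, n_classes = number of source label values,
#'   seed = `config$seed`).
#' @param weights a [loss_weights()].
#' @param config a [train_config()].
#' @return A `TrainedModel` (also a `DANModel`): the model components plus
#'   `weights`, `config`, `genes`, `log` (per-epoch loss breakdown data frame)
#'   and `best_epoch`. Parameters are those of the best (lowest total loss)
#'   epoch.
#' @export
train <- function(source, target, spec = NULL, weights = loss_weights(),
                  config = train_config()) {
  stopifnot(inherits(source, "ExpressionDataset"),
            inherits(target, "ExpressionDataset"))
  if (!identical(source$gene_names, target$gene_names)) {
    div <- which(source$gene_names != target$gene_names)[1]
    stop("source and target gene order differ (first divergence at column ",
         div, ")", call. = FALSE)
  }
  if (is.null(source$labels)) stop("source must carry labels", call. = FALSE)

  class_names <- sort(unique(source$labels))
  if (is.null(spec)) {
    spec <- model_spec(input_dim = ncol(source$matrix),
                       n_classes = max(length(class_names), 2L),
                       seed = config$seed)
  }
  if (length(class_names) == 1 && !("no_tri" %in% config$ablation)) {
    warning("single source class: triplet loss disabled", call. = FALSE)
    config$ablation <- c(config$ablation, "no_tri")
  }

  model <- init_model(spec, class_names = if (length(class_names) >= 2)
    class_names else c(class_names, ".unused"))
  ys <- match(source$labels, model$class_names)
  Xs_all <- source$matrix
  Xt_all <- target$matrix
  ns <- nrow(Xs_all); nt <- nrow(Xt_all)
  K <- spec$n_classes

  off <- function(flag) flag %in% config$ablation
  use_mse <- !off("no_mse"); use_da <- !off("no_da"); use_tri <- !off("no_tri")
  use_con <- !off("no_con"); use_vat <- !off("no_vat")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  enc <- model$encoder; dec <- model$decoder
  cls <- model$classifier; dis <- model$discriminator
  st_enc <- sgd_state_init(enc); st_dec <- sgd_state_init(dec)
  st_cls <- sgd_state_init(cls); st_dis <- sgd_state_init(dis)

  next_s <- batch_stream(ns)
  next_t <- batch_stream(nt)
  bs <- config$batch_size
  steps_per_epoch <- max(ceiling(ns / bs), ceiling(nt / bs))

  log_rows <- vector("list", config$epochs)
  step <- 0L
  best_loss <- Inf; best_epoch <- 0L; best_params <- NULL; stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    acc <- c(ce = 0, da = 0, mse = 0, tri = 0, con = 0, vat = 0, total = 0)
    for (s in seq_len(steps_per_epoch)) {
      is <- next_s(bs); it <- next_t(bs)
      # feature-major (genes x cells) throughout the step: per-feature
      # broadcasts are then native column recycling
      Xs <- t(Xs_all[is, , drop = FALSE]); Xt <- t(Xt_all[it, , drop = FALSE])
      yb <- ys[is]
      mbs <- ncol(Xs); mbt <- ncol(Xt)

      g_enc <- NULL; g_dec <- NULL; g_cls <- NULL; g_dis <- NULL

      fs <- mlp_forward_fm(enc, Xs, training = TRUE); enc <- fs$net; Zs <- fs$out
      ft <- mlp_forward_fm(enc, Xt, training = TRUE); enc <- ft$net; Zt <- ft$out
      dZs <- matrix(0, nrow(Zs), mbs); dZt <- matrix(0, nrow(Zt), mbt)

      # -- cross-entropy on source (Y one-hot; softmax grad (p - y)/m) ------
      fc <- mlp_forward_fm(cls, Zs, training = TRUE)
      probs <- softmax_cols(fc$out)                  # K x mbs
      true_idx <- cbind(yb, seq_len(mbs))
      l_ce <- -mean(log(pmax(probs[true_idx], LOG_CLAMP)))
      dlogit <- probs
      dlogit[true_idx] <- dlogit[true_idx] - 1
      bc <- mlp_backward_fm(cls, fc$caches, dlogit / mbs)
      g_cls <- grads_add(g_cls, bc$grads)
      dZs <- dZs + bc$dX

      # -- reconstruction on both domains -----------------------------------
      l_mse <- 0
      if (use_mse) {
        fds <- mlp_forward_fm(dec, Zs, training = TRUE); dec <- fds$net
        fdt <- mlp_forward_fm(dec, Zt, training = TRUE); dec <- fdt$net
        rs <- fds$out - Xs; rt <- fdt$out - Xt
        l_mse <- sum(rs^2) / mbs + sum(rt^2) / mbt
        bds <- mlp_backward_fm(dec, fds$caches, weights$lambda_mse * 2 * rs / mbs)
        bdt <- mlp_backward_fm(dec, fdt$caches, weights$lambda_mse * 2 * rt / mbt)
        g_dec <- grads_add(grads_add(g_dec, bds$grads), bdt$grads)
        dZs <- dZs + bds$dX
        dZt <- dZt + bdt$dX
      }

      # -- adversarial domain alignment through the GRL ---------------------
      l_da <- 0
      if (use_da) {
        fdis_s <- mlp_forward_fm(dis, grl_apply(Zs, spec$grl_lambda), training = TRUE)
        fdis_t <- mlp_forward_fm(dis, grl_apply(Zt, spec$grl_lambda), training = TRUE)
        os <- 1 / (1 + exp(-fdis_s$out)); ot <- 1 / (1 + exp(-fdis_t$out))
        l_da <- domain_loss(as.numeric(os), as.numeric(ot))
        # BCE-with-logits gradient; source labeled 1, target 0
        bdis_s <- mlp_backward_fm(dis, fdis_s$caches,
                                  weights$lambda_da * (os - 1) / mbs)
        bdis_t <- mlp_backward_fm(dis, fdis_t$caches,
                                  weights$lambda_da * ot / mbt)
        g_dis <- grads_add(grads_add(g_dis, bdis_s$grads), bdis_t$grads)
        dZs <- dZs + grl_backward(bdis_s$dX, spec$grl_lambda)
        dZt <- dZt + grl_backward(bdis_t$dX, spec$grl_lambda)
      }

      # -- batch-hard triplet loss on the source embedding ------------------
      l_tri <- 0
      if (use_tri) {
        tri <- mine_triplets(t(Zs), yb)
        if (length(tri$anchor) > 0) {
          za <- Zs[, tri$anchor, drop = FALSE]
          zp <- Zs[, tri$positive, drop = FALSE]
          zn <- Zs[, tri$negative, drop = FALSE]
          d_ap <- colSums((za - zp)^2); d_an <- colSums((za - zn)^2)
          hinge <- d_ap - d_an + weights$margin_alpha
          active <- hinge > 0
          # averaged over mined anchors in the objective: the raw sum scales
          # with batch size and destabilizes the batchnorm scale parameters
          ntri <- length(hinge)
          l_tri <- sum(pmax(hinge, 0)) / ntri
          if (any(active)) {
            dtri <- matrix(0, nrow(Zs), mbs)
            ga <- 2 * (zn - zp)[, active, drop = FALSE] / ntri
            gp <- 2 * (zp - za)[, active, drop = FALSE] / ntri
            gn <- 2 * (za - zn)[, active, drop = FALSE] / ntri
            aa <- tri$anchor[active]; pp_i <- tri$positive[active]
            nn_i <- tri$negative[active]
            for (r in seq_along(aa)) {
              dtri[, aa[r]] <- dtri[, aa[r]] + ga[, r]
              dtri[, pp_i[r]] <- dtri[, pp_i[r]] + gp[, r]
              dtri[, nn_i[r]] <- dtri[, nn_i[r]] + gn[, r]
            }
            dZs <- dZs + dtri
          }
        }
      }

      # -- consistency over feature-dropout views of the source -------------
      l_con <- 0
      if (use_con) {
        p_drop <- weights$consistency_dropout_p
        m1 <- matrix(stats::runif(length(Xs)) >= p_drop, nrow(Xs), mbs) * 1
        m2 <- matrix(stats::runif(length(Xs)) >= p_drop, nrow(Xs), mbs) * 1
        f1 <- mlp_forward_fm(enc, Xs * m1, training = TRUE); enc <- f1$net
        f2 <- mlp_forward_fm(enc, Xs * m2, training = TRUE); enc <- f2$net
        r1 <- Zs - f1$out; r2 <- Zs - f2$out
        l_con <- (sum(r1^2) + sum(r2^2)) / mbs
        b1 <- mlp_backward_fm(enc, f1$caches, -2 * r1 / mbs)
        b2 <- mlp_backward_fm(enc, f2$caches, -2 * r2 / mbs)
        g_enc <- grads_add(grads_add(g_enc, b1$grads), b2$grads)
        dZs <- dZs + (2 * r1 + 2 * r2) / mbs
      }

      # -- virtual adversarial training on the target ------------------------
      l_vat <- 0
      if (use_vat) {
        p_clean <- softmax_cols(mlp_forward_fm(cls, Zt, training = TRUE)$out)
        # score all candidate directions in one stacked inference pass
        nc <- weights$vat_candidates
        d <- nrow(Xt)
        R_all <- cpp_vat_directions(d, mbt * nc, weights$vat_epsilon,
                                    floor(stats::runif(1) * 2^31))
        rep_cells <- rep(seq_len(mbt), nc)
        X_rep <- Xt[, rep_cells, drop = FALSE] + R_all
        pp <- softmax_cols(mlp_infer_fm(cls, mlp_infer_fm(enc, X_rep)))
        kl_all <- kl_cols(p_clean[, rep_cells, drop = FALSE], pp)
        kl_by_cand <- rowsum(kl_all, rep(seq_len(nc), each = mbt)) / mbt
        best <- which.max(kl_by_cand)
        best_r <- R_all[, ((best - 1) * mbt + 1):(best * mbt), drop = FALSE]
        fe_ad <- mlp_forward_fm(enc, Xt + best_r, training = TRUE); enc <- fe_ad$net
        fc_ad <- mlp_forward_fm(cls, fe_ad$out, training = TRUE)
        p_ad <- softmax_cols(fc_ad$out)
        l_vat <- mean(kl_cols(p_clean, p_ad))
        # d KL / d perturbed logits = (q - p_clean)/m; clean side constant
        bca <- mlp_backward_fm(cls, fc_ad$caches,
                               weights$lambda_vat * (p_ad - p_clean) / mbt)
        g_cls <- grads_add(g_cls, bca$grads)
        bea <- mlp_backward_fm(enc, fe_ad$caches, bca$dX)
        g_enc <- grads_add(g_enc, bea$grads)
      }

      tl <- total_loss(list(ce = l_ce, da = l_da, mse = l_mse, tri = l_tri,
                            con = l_con, vat = l_vat), weights)

      # -- backprop the pooled latent gradients through the encoder ---------
      bs_enc <- mlp_backward_fm(enc, fs$caches, dZs)
      bt_enc <- mlp_backward_fm(enc, ft$caches, dZt)
      g_enc <- grads_add(grads_add(g_enc, bs_enc$grads), bt_enc$grads)

      lr <- lr_at(step, config)
      up <- sgd_step(enc, g_enc, st_enc, lr, config$momentum, config$weight_decay)
      enc <- up$net; st_enc <- up$state
      up <- sgd_step(cls, g_cls, st_cls, lr, config$momentum, config$weight_decay)
      cls <- up$net; st_cls <- up$state
      if (use_mse) {
        up <- sgd_step(dec, g_dec, st_dec, lr, config$momentum, config$weight_decay)
        dec <- up$net; st_dec <- up$state
      }
      if (use_da) {
        up <- sgd_step(dis, g_dis, st_dis, lr, config$momentum, config$weight_decay)
        dis <- up$net; st_dis <- up$state
      }
      step <- step + 1L

      acc <- acc + c(ce = l_ce, da = l_da, mse = l_mse, tri = l_tri,
                     con = l_con, vat = l_vat, total = tl$total)
    }
    mean_loss <- acc / steps_per_epoch
    log_rows[[epoch]] <- data.frame(epoch = epoch, t(mean_loss),
                                    lr = lr_at(step - 1L, config))
    if (config$verbose && epoch %% 10 == 0) {
      message(sprintf("epoch %3d  total %.4f  ce %.4f  da %.4f", epoch,
                      mean_loss[["total"]], mean_loss[["ce"]], mean_loss[["da"]]))
    }
    if (mean_loss[["total"]] < best_loss - config$min_delta) {
      best_loss <- mean_loss[["total"]]; best_epoch <- epoch; stall <- 0L
      best_params <- list(enc = enc, dec = dec, cls = cls, dis = dis)
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  if (is.null(best_params)) {
    best_params <- list(enc = enc, dec = dec, cls = cls, dis = dis)
    best_epoch <- epoch
  }

  model$encoder <- best_params$enc
  model$decoder <- best_params$dec
  model$classifier <- best_params$cls
  model$discriminator <- best_params$dis
  model$weights <- weights
  model$config <- config
  model$genes <- source$gene_names
  model$log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  model$best_epoch <- best_epoch
  class(model) <- c("TrainedModel", "DANModel")
  model
}

#' Annotate target cells with a trained model
#'
#' @param model a `TrainedModel` from [train()].
#' @param target an [expression_dataset()] whose genes match the model's
#'   training gene list in the same order.
#' @return An `Annotation` list: `predictions` (data.frame with `cell_id`,
#'   `predicted_type`), `probabilities` (cells x K, rows sum to 1), and
#'   `embedding` (cells x latent_dim latent coordinates). Class ties are
#'   broken by the lowest class index.
#' @export
annotate <- function(model, target) {
  stopifnot(inherits(model, "TrainedModel"),
            inherits(target, "ExpressionDataset"))
  if (!identical(model$genes, target$gene_names)) {
    n <- min(length(model$genes), length(target$gene_names))
    div <- which(model$genes[seq_len(n)] != target$gene_names[seq_len(n)])
    where <- if (length(div) > 0) div[1] else n + 1L
    stop("target gene order does not match the training gene list ",
         "(first divergence at column ", where, ": expected '",
         model$genes[min(where, length(model$genes))], "')", call. = FALSE)
  }
  Z <- encode(model, target$matrix, training = FALSE)
  probs <- classify(model, Z)
  pred_idx <- max.col(probs, ties.method = "first")
  structure(
    list(predictions = data.frame(cell_id = target$cell_ids,
                                  predicted_type = model$class_names[pred_idx],
                                  stringsAsFactors = FALSE),
         probabilities = probs,
         embedding = Z),
    class = "Annotation")
}
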