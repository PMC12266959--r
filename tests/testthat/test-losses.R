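# Each loss is checked against a naive element-loop oracle on random
# instances, plus closed-form spot values.

oracle_reconstruction <- function(Xs, Xs_rec, Xt, Xt_rec) {
  tot_s <- 0
  for (i in seq_len(nrow(Xs))) {
    for (j in seq_len(ncol(Xs))) tot_s <- tot_s + (Xs[i, j] - Xs_rec[i, j])^2
  }
  tot_t <- 0
  for (i in seq_len(nrow(Xt))) {
    for (j in seq_len(ncol(Xt))) tot_t <- tot_t + (Xt[i, j] - Xt_rec[i, j])^2
  }
  tot_s / nrow(Xs) + tot_t / nrow(Xt)
}

oracle_label <- function(probs, idx) {
  tot <- 0
  for (i in seq_len(nrow(probs))) {
    for (c in seq_len(ncol(probs))) {
      y <- as.numeric(idx[i] == c)
      tot <- tot - y * log(max(probs[i, c], 1e-12))
    }
  }
  tot / nrow(probs)
}

oracle_domain <- function(ds, dt) {
  a <- 0
  for (i in seq_along(ds)) a <- a - log(ds[i]) / length(ds)
  for (j in seq_along(dt)) a <- a - log(1 - dt[j]) / length(dt)
  a
}

oracle_mine <- function(Z, labels) {
  n <- nrow(Z)
  an <- integer(0); po <- integer(0); ne <- integer(0)
  for (i in seq_len(n)) {
    best_p <- 0L; best_pd <- -Inf; best_n <- 0L; best_nd <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sum((Z[i, ] - Z[j, ])^2)
      if (labels[j] == labels[i]) {
        if (d > best_pd) { best_pd <- d; best_p <- j }
      } else {
        if (d < best_nd) { best_nd <- d; best_n <- j }
      }
    }
    if (best_p > 0 && best_n > 0) {
      an <- c(an, i); po <- c(po, best_p); ne <- c(ne, best_n)
    }
  }
  list(anchor = an, positive = po, negative = ne)
}

oracle_triplet <- function(Z, tri, alpha) {
  tot <- 0
  for (k in seq_along(tri$anchor)) {
    d_ap <- sum((Z[tri$anchor[k], ] - Z[tri$positive[k], ])^2)
    d_an <- sum((Z[tri$anchor[k], ] - Z[tri$negative[k], ])^2)
    tot <- tot + max(d_ap - d_an + alpha, 0)
  }
  tot
}

test_that("reconstruction loss matches its loop oracle and hand values", {
  expect_equal(reconstruction_loss(diag(3), diag(3), diag(2), diag(2)), 0)
  # one cell per domain with residuals (1,1) and (2,0)
  expect_equal(reconstruction_loss(matrix(c(1, 1), 1), matrix(c(0, 0), 1),
                                   matrix(c(2, 0), 1), matrix(c(0, 0), 1)), 6)
  set.seed(1)
  for (k in 1:20) {
    Xs <- matrix(rnorm(50), 10); Xs_rec <- matrix(rnorm(50), 10)
    Xt <- matrix(rnorm(35), 7); Xt_rec <- matrix(rnorm(35), 7)
    expect_equal(reconstruction_loss(Xs, Xs_rec, Xt, Xt_rec),
                 oracle_reconstruction(Xs, Xs_rec, Xt, Xt_rec),
                 tolerance = 1e-6)
  }
  expect_error(reconstruction_loss(diag(3), diag(2), diag(2), diag(2)),
               "mismatch")
})

test_that("label loss matches ln K on uniform input and the loop oracle", {
  p <- matrix(0.25, 6, 4)
  expect_equal(label_loss(p, rep(1:4, length.out = 6)), log(4),
               tolerance = 1e-12)
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(label_loss(onehot, c(1, 2, 3, 1)), 0, tolerance = 1e-10)
  set.seed(2)
  for (k in 1:20) {
    probs <- random_simplex(20, 3)
    idx <- sample(1:3, 20, replace = TRUE)
    expect_equal(label_loss(probs, idx), oracle_label(probs, idx),
                 tolerance = 1e-6)
  }
})

test_that("domain loss matches 2 ln 2 at 0.5 and the loop oracle", {
  expect_equal(domain_loss(rep(0.5, 8), rep(0.5, 5)), 2 * log(2),
               tolerance = 1e-12)
  eps <- 1e-9
  expect_lt(domain_loss(rep(1 - eps, 4), rep(eps, 4)), 1e-6)
  set.seed(3)
  for (k in 1:20) {
    ds <- runif(15, 0.01, 0.99); dt <- runif(12, 0.01, 0.99)
    expect_equal(domain_loss(ds, dt), oracle_domain(ds, dt), tolerance = 1e-6)
  }
})

test_that("batch-hard mining agrees with exhaustive search on 50 random batches", {
  # hand geometry: 1-D [0, 1, 5] labels (a, a, b)
  Z0 <- matrix(c(0, 1, 5), 3, 1)
  t0 <- mine_triplets(Z0, c("a", "a", "b"))
  expect_equal(t0$anchor[1], 1)
  expect_equal(t0$positive[1], 2)
  expect_equal(t0$negative[1], 3)
  set.seed(4)
  for (k in 1:50) {
    Z <- matrix(rnorm(30 * 8), 30)
    labels <- sample(letters[1:5], 30, replace = TRUE)
    got <- mine_triplets(Z, labels)
    want <- oracle_mine(Z, labels)
    expect_identical(got$anchor, want$anchor)
    expect_identical(got$positive, want$positive)
    expect_identical(got$negative, want$negative)
  }
  # degenerate single-class batch: no triplets, zero loss
  none <- mine_triplets(matrix(rnorm(10), 5, 2), rep("a", 5))
  expect_length(none$anchor, 0)
  expect_equal(triplet_loss(matrix(rnorm(10), 5, 2), none, 1), 0)
})

test_that("triplet loss matches hand values, hinge and the oracle", {
  # 1-D: z_a=0, z_p=2, z_n=1, alpha=1 -> [4 - 1 + 1]+ = 4
  Z <- matrix(c(0, 2, 1), 3, 1)
  tri <- list(anchor = 1L, positive = 2L, negative = 3L)
  expect_equal(triplet_loss(Z, tri, 1), 4)
  # satisfied margin: z_a = z_p, far negative
  Z2 <- matrix(c(0, 0, 10), 3, 1)
  expect_equal(triplet_loss(Z2, tri, 1), 0)
  set.seed(5)
  for (k in 1:20) {
    Zr <- matrix(rnorm(20 * 4), 20)
    lab <- sample(letters[1:3], 20, replace = TRUE)
    tr <- mine_triplets(Zr, lab)
    val <- triplet_loss(Zr, tr, 0.5)
    expect_gte(val, 0)
    expect_equal(val, oracle_triplet(Zr, tr, 0.5), tolerance = 1e-6)
  }
})

test_that("consistency loss matches a per-cell oracle with injected masks", {
  m <- tiny_model()
  set.seed(6)
  X <- matrix(rnorm(8 * 7), 8)
  masks <- list(matrix(rbinom(56, 1, 0.8), 8, 7),
                matrix(rbinom(56, 1, 0.8), 8, 7))
  got <- consistency_loss(m, X, p = 0.2, masks = masks)
  # per-cell loop oracle (eval-mode encoder is row-independent)
  tot <- 0
  for (i in 1:8) {
    z <- encode(m, X[i, , drop = FALSE])
    z1 <- encode(m, matrix(X[i, ] * masks[[1]][i, ], 1, 7))
    z2 <- encode(m, matrix(X[i, ] * masks[[2]][i, ], 1, 7))
    tot <- tot + sum((z - z1)^2) + sum((z - z2)^2)
  }
  expect_equal(got, tot / 8, tolerance = 1e-6)
  # all-keep masks give identical views and zero loss
  keep <- list(matrix(1, 8, 7), matrix(1, 8, 7))
  expect_equal(consistency_loss(m, X, p = 0.2, masks = keep), 0)
  expect_gte(consistency_loss(m, X, p = 0.5), 0)
})

test_that("VAT loss is a non-negative max over candidates; zero at zero radius", {
  m <- tiny_model()
  set.seed(7)
  X <- matrix(rnorm(9 * 7), 9)
  z0 <- vat_loss(m, X, epsilon = 0, n_candidates = 3)
  expect_equal(z0$value, 0, tolerance = 1e-12)
  v <- vat_loss(m, X, epsilon = 1, n_candidates = 5)
  expect_true(all(v$candidate_kls >= 0))
  expect_equal(v$value, max(v$candidate_kls))
  expect_gte(v$value, mean(v$candidate_kls))
  # selected perturbation has per-cell norm epsilon
  expect_equal(unname(sqrt(rowSums(v$r^2))), rep(1, 9), tolerance = 1e-9)
})

test_that("total loss composes the three module losses with their weights", {
  w <- loss_weights(lambda_da = 2, lambda_mse = 1, lambda_vat = 1)
  ones <- list(ce = 1, da = 1, mse = 1, tri = 1, con = 1, vat = 1)
  tl <- total_loss(ones, w)
  expect_equal(tl$total, 7)   # (1 + 2 + 1) + 1 + (1 + 1)
  expect_equal(unname(tl$breakdown[["ddann"]]), 4)
  expect_equal(unname(tl$breakdown[["cv"]]), 2)
  # breakdown recombines to the total
  b <- tl$breakdown
  expect_equal(b[["ddann"]] + b[["tri"]] + b[["cv"]], b[["total"]],
               tolerance = 1e-9)
  # zero weights leave the unweighted terms
  w0 <- loss_weights(lambda_da = 0, lambda_mse = 0, lambda_vat = 0)
  expect_equal(total_loss(ones, w0)$total, 1 + 1 + 1)
  expect_error(total_loss(list(ce = NaN), w), "ce")
})
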