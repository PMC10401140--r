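# --- minimal Adam optimizer over a named list of parameter matrices ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Fit the non-negative kernel autoencoder
#'
#' Single-hidden-layer autoencoder whose weights and biases are
#' constrained non-negative (projected to zero after every optimizer
#' step): `e = sigmoid(M W_E + b_E)`, `M_hat = e W_D + b_D`, trained by
#' full-batch Adam on mean-squared reconstruction error with a small
#' decoupled weight decay. The per-gene importance score is the row sum
#' of the encoder weight matrix; genes that never help reconstruction
#' (e.g. all-zero columns) receive no reconstruction gradient and decay
#' toward zero score.
#'
#' @param M a [minmax_normalize()]d matrix (or plain matrix in `[0, 1]`),
#'   cells x genes.
#' @param hidden_dim hidden layer width (default 64).
#' @param epochs full-batch training steps (default 30).
#' @param seed integer seed for the weight initialization.
#' @param lr Adam learning rate.
#' @param weight_decay decoupled decay applied per step.
#' @return list of class `NNKAEModel`: `W_E`, `b_E`, `W_D`, `b_D`,
#'   `gene_scores`, `loss_trace`.
#' @export
fit_nnkae <- function(M, hidden_dim = 64L, epochs = 30L, seed = 1L,
                      lr = 5e-3, weight_decay = 2e-2) {
  X <- if (inherits(M, "ExpressionMatrix")) as.matrix(M$values) else as.matrix(M)
  n <- nrow(X); g <- ncol(X)
  if (hidden_dim < 1) stopf("hidden_dim must be >= 1")
  h <- min(hidden_dim, g)
  params <- with_seed(seed, list(
    W_E = matrix(runif(g * h, 0, sqrt(1 / g)), g, h),
    b_E = matrix(0, 1, h),
    W_D = matrix(runif(h * g, 0, sqrt(1 / h)), h, g),
    b_D = matrix(0, 1, g)
  ))
  st <- adam_init(params)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    E <- sigmoid(sweep(X %*% params$W_E, 2, params$b_E, "+"))
    Xhat <- sweep(E %*% params$W_D, 2, params$b_D, "+")
    R <- Xhat - X
    loss <- mean(R^2)
    if (!is.finite(loss))
      stopf("NNKAE training diverged (non-finite loss); lower the learning rate")
    loss_trace[ep] <- loss
    dXhat <- 2 * R / length(R)
    gW_D <- crossprod(E, dXhat)
    gb_D <- matrix(colSums(dXhat), 1, g)
    dE <- dXhat %*% t(params$W_D) * E * (1 - E)
    gW_E <- crossprod(X, dE)
    gb_E <- matrix(colSums(dE), 1, h)
    res <- adam_step(params,
                     list(W_E = gW_E, b_E = gb_E, W_D = gW_D, b_D = gb_D),
                     st, lr = lr)
    params <- res$params; st <- res$state
    # decoupled weight decay, then projection onto the non-negative orthant
    params$W_E <- pmax(params$W_E * (1 - weight_decay), 0)
    params$W_D <- pmax(params$W_D * (1 - weight_decay), 0)
    params$b_E <- pmax(params$b_E, 0)
    params$b_D <- pmax(params$b_D, 0)
  }
  structure(list(W_E = params$W_E, b_E = params$b_E, W_D = params$W_D,
                 b_D = params$b_D, gene_scores = rowSums(params$W_E),
                 loss_trace = loss_trace),
            class = "NNKAEModel")
}

#' Select the most informative genes by encoder weight
#'
#' Indices (1-based, ascending) of the `n_keep` genes with the largest
#' NNKAE importance scores; ties break toward the lower index.
#'
#' @param model a [fit_nnkae()] model (or a bare numeric score vector).
#' @param n_keep number of genes to keep.
#' @return sorted integer vector of gene indices.
#' @export
select_informative_genes <- function(model, n_keep) {
  scores <- if (inherits(model, "NNKAEModel")) model$gene_scores else model
  g <- length(scores)
  if (n_keep < 1 || n_keep > g) stopf("n_keep must lie in [1, %d]", g)
  ord <- order(-scores, seq_len(g))   # ties -> lower index first
  sort(ord[seq_len(n_keep)])
}

#' Fit the stacked Bayesian autoencoder
#'
#' Variational architecture `e = tanh(A W1 + b1)` (hidden width 128),
#' `mu = e Wm + bm`, `sigma = softplus(mu Ws + bs)` (strictly positive),
#' latent draw `z = mu + sigma * eps` with `eps ~ N(0, 1)` via the
#' reparameterization trick, linear decoder `A_hat = z W2 + b2`. Trained
#' by full-batch Adam on `MSE + beta_kl * KL(N(mu, sigma^2) || N(0, 1))`.
#' Deterministic given the seed.
#'
#' @param A matrix (cells x kept genes), e.g. the normalized matrix
#'   restricted to [select_informative_genes()].
#' @param latent_dim latent dimensionality (default 15); must be smaller
#'   than the gene count.
#' @param epochs full-batch optimizer steps (default 1000; one
#'   gradient step per epoch).
#' @param seed integer seed.
#' @param hidden hidden width (default 128).
#' @param beta_kl KL weight (default 0.005).
#' @param lr Adam learning rate.
#' @return list of class `BayesianEncoder` with the parameter matrices,
#'   `latent_dim` and `loss_trace`.
#' @export
fit_stacked_bayesian_ae <- function(A, latent_dim = 15L, epochs = 1000L,
                                    seed = 1L, hidden = 128L,
                                    beta_kl = 0.005, lr = 1e-3) {
  A <- as.matrix(A)
  n <- nrow(A); g <- ncol(A)
  if (n == 0 || g == 0) stopf("input matrix is empty")
  if (latent_dim >= g)
    stopf("latent_dim (%d) must be smaller than the gene count (%d)",
          latent_dim, g)
  L <- latent_dim
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(g * hidden, 0, sqrt(1 / g)), g, hidden),
    b1 = matrix(0, 1, hidden),
    Wm = matrix(rnorm(hidden * L, 0, sqrt(1 / hidden)), hidden, L),
    bm = matrix(0, 1, L),
    Ws = matrix(rnorm(L * L, 0, sqrt(1 / L)), L, L),
    bs = matrix(-2, 1, L),               # start with small sigma
    W2 = matrix(rnorm(L * g, 0, sqrt(1 / L)), L, g),
    b2 = matrix(0, 1, g)
  ))
  st <- adam_init(params)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    eps_draws <- with_seed(derive_seed(seed, 7L, ep), matrix(rnorm(n * L), n, L))
    H <- tanh(sweep(A %*% params$W1, 2, params$b1, "+"))
    Mu <- sweep(H %*% params$Wm, 2, params$bm, "+")
    Sraw <- sweep(Mu %*% params$Ws, 2, params$bs, "+")
    Sig <- softplus(Sraw) + 1e-6
    Zl <- Mu + Sig * eps_draws
    Ahat <- sweep(Zl %*% params$W2, 2, params$b2, "+")
    R <- Ahat - A
    recon <- sum(R^2) / n              # per-cell sum over genes
    kl <- 0.5 * sum(Mu^2 + Sig^2 - 1 - 2 * log(Sig)) / n
    loss <- recon + beta_kl * kl
    if (!is.finite(loss))
      stopf("Bayesian AE training diverged (non-finite loss); lower the learning rate")
    loss_trace[ep] <- loss
    # backprop
    dAhat <- 2 * R / n
    gW2 <- crossprod(Zl, dAhat)
    gb2 <- matrix(colSums(dAhat), 1, g)
    dZ <- dAhat %*% t(params$W2)
    dMu <- dZ + beta_kl * Mu / n
    dSig <- dZ * eps_draws + beta_kl * (Sig - 1 / Sig) / n
    dSraw <- dSig * sigmoid(Sraw)        # d softplus = sigmoid
    gWs <- crossprod(Mu, dSraw)
    gbs <- matrix(colSums(dSraw), 1, L)
    dMu <- dMu + dSraw %*% t(params$Ws)
    gWm <- crossprod(H, dMu)
    gbm <- matrix(colSums(dMu), 1, L)
    dH <- dMu %*% t(params$Wm) * (1 - H^2)
    gW1 <- crossprod(A, dH)
    gb1 <- matrix(colSums(dH), 1, hidden)
    res <- adam_step(params, list(W1 = gW1, b1 = gb1, Wm = gWm, bm = gbm,
                                  Ws = gWs, bs = gbs, W2 = gW2, b2 = gb2),
                     st, lr = lr)
    params <- res$params; st <- res$state
  }
  structure(c(params, list(latent_dim = L, loss_trace = loss_trace)),
            class = "BayesianEncoder")
}

# Encoder forward pass: returns list(mu, sigma) for the rows of A.
encode_mu_sigma <- function(enc, A) {
  A <- as.matrix(A)
  H <- tanh(sweep(A %*% enc$W1, 2, enc$b1, "+"))
  Mu <- sweep(H %*% enc$Wm, 2, enc$bm, "+")
  Sig <- softplus(sweep(Mu %*% enc$Ws, 2, enc$bs, "+")) + 1e-6
  list(mu = Mu, sigma = Sig)
}

#' Sample stochastic latent spaces from a trained encoder
#'
#' Draws `d` independent latent matrices `z = mu + sigma * eps`,
#' `eps ~ N(0, 1)`, from the encoder's posterior over the rows of `A`.
#' Each draw uses a seed derived from `(seed, draw index)`, recorded in
#' `seed_record`.
#'
#' @param enc a [fit_stacked_bayesian_ae()] encoder.
#' @param A the matrix that was encoded (cells x kept genes).
#' @param d number of latent spaces (default 3).
#' @param seed integer master seed.
#' @param deterministic if TRUE, sigma is treated as 0 and every space
#'   equals the posterior mean.
#' @return list of class `LatentSpaces`: `spaces` (list of d matrices),
#'   `seed_record`, `mode`.
#' @export
sample_latent_spaces <- function(enc, A, d = 3L, seed = 1L,
                                 deterministic = FALSE) {
  if (d < 1) stopf("d must be >= 1")
  ms <- encode_mu_sigma(enc, A)
  n <- nrow(ms$mu); L <- ncol(ms$mu)
  seeds <- vapply(seq_len(d), function(i) derive_seed(seed, 31L, i), integer(1))
  spaces <- lapply(seq_len(d), function(i) {
    if (deterministic) return(ms$mu)
    eps <- with_seed(seeds[i], matrix(rnorm(n * L), n, L))
    ms$mu + ms$sigma * eps
  })
  structure(list(spaces = spaces, seed_record = seeds,
                 mode = "autoencoder"),
            class = "LatentSpaces")
}

#' @export
print.LatentSpaces <- function(x, ...) {
  cat(sprintf("LatentSpaces: %d spaces of %d cells x %d dims (%s)\n",
              length(x$spaces), nrow(x$spaces[[1]]), ncol(x$spaces[[1]]),
              x$mode))
  invisible(x)
}

#' Deterministic truncated-SVD embedding
#'
#' A cheap alternative to the autoencoder pipeline: centers the matrix,
#' projects onto the top `latent_dim` right singular vectors, and
#' returns `d` copies perturbed by seeded Gaussian noise of relative
#' scale `1e-3` (so the spaces are distinct but essentially identical).
#' Useful for unit tests and low-resource runs; flagged in `mode`.
#'
#' @param A matrix (cells x genes).
#' @param latent_dim embedding dimensionality.
#' @param d number of (perturbed) copies.
#' @param seed integer seed.
#' @return A `LatentSpaces` object with `mode = "svd"`.
#' @export
svd_embedding <- function(A, latent_dim = 15L, d = 3L, seed = 1L) {
  A <- as.matrix(A)
  L <- min(latent_dim, ncol(A), nrow(A))
  Ac <- sweep(A, 2, colMeans(A))
  sv <- svd(Ac, nu = 0, nv = L)
  Zb <- Ac %*% sv$v
  scale_n <- mean(abs(Zb)) * 1e-3
  seeds <- vapply(seq_len(d), function(i) derive_seed(seed, 31L, i), integer(1))
  spaces <- lapply(seq_len(d), function(i) {
    Zb + with_seed(seeds[i], matrix(rnorm(length(Zb), 0, scale_n + 1e-12),
                                    nrow(Zb), ncol(Zb)))
  })
  structure(list(spaces = spaces, seed_record = seeds, mode = "svd"),
            class = "LatentSpaces")
}

#' Hierarchical-autoencoder latent spaces from a normalized matrix
#'
#' Convenience wrapper chaining gene filtering (NNKAE), the stacked
#' Bayesian autoencoder and latent sampling; or the SVD embedding when
#' `mode = "svd_fallback"`.
#'
#' @param M a [minmax_normalize()]d matrix.
#' @param n_keep informative genes to retain (default 5000, capped at
#'   the gene count).
#' @param latent_dim latent dimensionality (default 15).
#' @param d number of latent spaces (default 3).
#' @param epochs_nnkae,epochs_vae training lengths.
#' @param mode `"autoencoder"` or `"svd_fallback"`.
#' @param seed integer master seed.
#' @return A `LatentSpaces` object; attribute `"kept_genes"` holds the
#'   selected gene indices.
#' @export
compute_latent_spaces <- function(M, n_keep = 5000L, latent_dim = 15L,
                                  d = 3L, epochs_nnkae = 30L,
                                  epochs_vae = 1000L,
                                  mode = c("autoencoder", "svd_fallback"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  X <- if (inherits(M, "ExpressionMatrix")) as.matrix(M$values) else as.matrix(M)
  n_keep <- min(n_keep, ncol(X))
  if (mode == "svd_fallback") {
    Z <- svd_embedding(X, latent_dim, d, seed)
    attr(Z, "kept_genes") <- seq_len(ncol(X))
    return(Z)
  }
  nnkae <- fit_nnkae(X, epochs = epochs_nnkae, seed = derive_seed(seed, 1L))
  kept <- select_informative_genes(nnkae, n_keep)
  A <- X[, kept, drop = FALSE]
  latent_dim <- min(latent_dim, ncol(A) - 1L)
  enc <- fit_stacked_bayesian_ae(A, latent_dim, epochs = epochs_vae,
                                 seed = derive_seed(seed, 2L))
  Z <- sample_latent_spaces(enc, A, d, seed = derive_seed(seed, 3L))
  attr(Z, "kept_genes") <- kept
  Z
}
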