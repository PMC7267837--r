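# Mini-batch stochastic training of the variational objective, held-out
# splitting, convergence history, and the epoch rule of thumb.

#' Training configuration
#'
#' @param n_epochs number of passes over the training cells, or \code{"auto"}
#'   to use \code{\link{recommended_epochs}} (1 million divided by the number
#'   of cells, at least 1).
#' @param batch_size cells per mini-batch (default 128).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param holdout_fraction fraction of cells held out for monitoring, in
#'   \[0, 1) (default 0.1).
#' @param seed integer seed controlling initialization, the held-out split,
#'   shuffling and Monte Carlo noise; identical seed and configuration give
#'   identical fits.
#' @param kl_warmup_epochs linearly anneal the KL weight from 0 to 1 over
#'   this many epochs (0 = disabled, the plain objective).
#' @param patience optional early stopping: stop when the held-out objective
#'   has not improved for this many epochs (\code{NULL} = train all epochs).
#' @param verbose print per-epoch objectives.
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(n_epochs = "auto", batch_size = 128L,
                         learning_rate = 1e-3, holdout_fraction = 0.1,
                         seed = 1L, kl_warmup_epochs = 0L, patience = NULL,
                         verbose = FALSE) {
  if (!identical(n_epochs, "auto")) n_epochs <- .check_scalar_count(n_epochs, "n_epochs")
  batch_size <- .check_scalar_count(batch_size, "batch_size")
  if (!is.numeric(holdout_fraction) || holdout_fraction < 0 || holdout_fraction >= 1) {
    .stopf("holdout_fraction must be in [0, 1)")
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) .stopf("learning_rate must be positive")
  structure(list(n_epochs = n_epochs, batch_size = batch_size,
                 learning_rate = learning_rate,
                 holdout_fraction = holdout_fraction, seed = as.integer(seed),
                 kl_warmup_epochs = as.integer(kl_warmup_epochs),
                 patience = patience, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Epoch rule of thumb
#'
#' For a first-pass analysis, train for about one million cell-visits:
#' \code{max(1, ceiling(1e6 / n_cells))} epochs. Large atlases converge in a
#' handful of epochs, so a 1,000,000-cell dataset gets 1 epoch and a
#' 100,000-cell dataset gets 10.
#'
#' @param n_cells number of cells in the dataset (>= 1).
#' @return integer epoch count.
#' @examples
#' recommended_epochs(1e6)   # 1
#' recommended_epochs(1e5)   # 10
#' @export
recommended_epochs <- function(n_cells) {
  n_cells <- .check_scalar_count(n_cells, "n_cells")
  max(1L, as.integer(ceiling(1e6 / n_cells)))
}

# Deterministic evaluation objective: per-cell mean ELBO with the posterior
# locations substituted for the Monte Carlo draw (no sampling noise).
#' @noRd
.eval_objective <- function(par, buf, cfg, s_prior, X) {
  draws <- list(eps_z = matrix(0, nrow(X), cfg$n_factors), eps_s = rep(0, nrow(X)))
  f <- .forward_batch(par, buf, cfg, s_prior, X, draws = draws, training = FALSE)
  (f$reconstruction - f$kl) / nrow(X)
}

#' Fit an LDVAE model by stochastic gradient ascent on the ELBO
#'
#' Splits off a held-out monitoring set, sets the lognormal exposure prior
#' from the training cells (mean and standard deviation of per-cell log total
#' counts), then runs seeded, shuffled mini-batch Adam on the negative ELBO.
#' One reparameterized draw of (z, s) is used per cell per step. The history
#' records the per-epoch mean training objective (running mean over batches)
#' and, when a holdout is present, the deterministic held-out objective.
#'
#' @param data a \code{\link{count_matrix}} (or plain count matrix).
#' @param config a \code{\link{model_config}}.
#' @param train a \code{\link{train_config}}.
#' @return An object of class \code{ldvae_fit}: \code{model} (trained
#'   \code{ldvae_model}), \code{history} (data frame with columns
#'   \code{epoch}, \code{train_objective}, \code{heldout_objective}),
#'   \code{holdout_idx}, and the configuration snapshots.
#' @examples
#' \donttest{
#' sim <- simulate_scenario(sim_scenario(n_cells = 300, n_genes = 40, n_factors = 2))
#' fit <- fit_ldvae(sim$counts, model_config(n_factors = 2),
#'                  train_config(n_epochs = 5, seed = 1))
#' tail(fit$history, 1)
#' }
#' @export
fit_ldvae <- function(data, config = model_config(), train = train_config()) {
  if (!inherits(data, "count_matrix")) data <- count_matrix(data)
  X <- .as_dense(data$counts)
  N <- nrow(X)
  G <- ncol(X)

  n_hold <- floor(train$holdout_fraction * N)
  hold_idx <- if (n_hold > 0) {
    sort(.with_seed(train$seed + 101L, sample.int(N, n_hold)))
  } else {
    integer(0)
  }
  train_idx <- setdiff(seq_len(N), hold_idx)
  if (length(train_idx) < 2L) .stopf("too few training cells after holdout")
  Xtr <- X[train_idx, , drop = FALSE]
  Xho <- if (n_hold > 0) X[hold_idx, , drop = FALSE] else NULL

  totals <- pmax(rowSums(Xtr), 1)
  s_prior <- list(s_mu = mean(log(totals)), s_sigma = max(stats::sd(log(totals)), 1e-3))

  # PCA warm start for the linear decoder: the negative-ELBO landscape is
  # multi-modal and random inits can settle into modes that drop a factor
  # entirely; starting the loadings at the leading principal components of
  # log1p depth-normalized counts (columns scaled by component sd so unit-
  # variance latents reproduce the observed logit spread) avoids this.
  W_init <- NULL
  if (config$decoder == "linear") {
    W_init <- tryCatch({
      sub <- if (length(train_idx) > 5000L) {
        .with_seed(train$seed + 202L, sample(seq_len(nrow(Xtr)), 5000L))
      } else {
        seq_len(nrow(Xtr))
      }
      L <- log1p(Xtr[sub, , drop = FALSE] / totals[sub] * 1e4)
      D <- config$n_factors
      pc <- stats::prcomp(L, rank. = min(D, ncol(L), length(sub) - 1L), center = TRUE)
      k <- ncol(pc$rotation)
      W0 <- pc$rotation %*% diag(pc$sdev[seq_len(k)], k, k)
      if (k < D) {  # pad with small noise if data rank is below D
        W0 <- cbind(W0, matrix(.with_seed(train$seed + 203L,
                                          stats::rnorm(G * (D - k), sd = 0.1)), G))
      }
      W0
    }, error = function(e) NULL)
  }

  model <- init_ldvae(data$gene_ids, config, seed = train$seed,
                      s_mu = s_prior$s_mu, s_sigma = s_prior$s_sigma,
                      W_init = W_init)
  par <- model$par
  buf <- model$buf
  n_epochs <- if (identical(train$n_epochs, "auto")) {
    recommended_epochs(N)  # rule of thumb applies to the dataset size
  } else {
    train$n_epochs
  }

  opt <- .adam_init(par)
  hist_train <- numeric(0)
  hist_hold <- numeric(0)
  best_hold <- -Inf
  stall <- 0L

  .with_seed(train$seed, {
    ntr <- length(train_idx)
    for (epoch in seq_len(n_epochs)) {
      klw <- if (train$kl_warmup_epochs > 0) min(1, epoch / train$kl_warmup_epochs) else 1
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = train$batch_size)
      elbo_sum <- 0
      n_seen <- 0L
      for (st in starts) {
        idx <- ord[st:min(st + train$batch_size - 1L, ntr)]
        if (config$batch_norm && length(idx) < 2L) next  # BN needs >= 2 cells
        res <- .loss_and_grads(par, buf, config, s_prior, Xtr[idx, , drop = FALSE], klw = klw)
        upd <- .adam_step(par, res$grads, opt, lr = train$learning_rate)
        par <- upd$par
        opt <- upd$opt
        buf <- res$buf
        elbo_sum <- elbo_sum + res$elbo
        n_seen <- n_seen + length(idx)
      }
      hist_train[epoch] <- elbo_sum / n_seen
      if (!is.null(Xho)) {
        hist_hold[epoch] <- .eval_objective(par, buf, config, s_prior, Xho)
        if (train$verbose) {
          message(sprintf("epoch %d: train %.3f heldout %.3f",
                          epoch, hist_train[epoch], hist_hold[epoch]))
        }
        if (!is.null(train$patience)) {
          if (hist_hold[epoch] > best_hold + 1e-8) {
            best_hold <- hist_hold[epoch]
            stall <- 0L
          } else {
            stall <- stall + 1L
            if (stall >= train$patience) break
          }
        }
      } else if (train$verbose) {
        message(sprintf("epoch %d: train %.3f", epoch, hist_train[epoch]))
      }
    }
  })

  model$par <- par
  model$buf <- buf
  model$s_prior <- s_prior
  history <- data.frame(
    epoch = seq_along(hist_train),
    train_objective = hist_train,
    heldout_objective = if (length(hist_hold)) hist_hold else NA_real_
  )
  structure(list(model = model, history = history, config = config,
                 train_config = train, holdout_idx = hold_idx,
                 gene_ids = data$gene_ids, seed = train$seed),
            class = "ldvae_fit")
}

#' @export
print.ldvae_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "ldvae_fit: %d genes, %d factors, latent=%s, decoder=%s%s, %d epochs\n",
    x$model$G, x$model$D, cfg$latent, cfg$decoder,
    if (cfg$batch_norm) "+batchnorm" else "", nrow(x$history)
  ))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final objective: train %.3f, heldout %.3f\n",
                last$train_objective, last$heldout_objective))
  }
  invisible(x)
}

#' Held-out reconstruction error
#'
#' Mean over cells of the negative NB log-likelihood of the counts under the
#' variational mean embedding: z is set to its posterior location (softmaxed
#' for the logistic-normal family), s to \code{exp(s_loc)}, and no sampling
#' noise is used, so repeated evaluation gives identical values. Lower is
#' better.
#'
#' @param fit an \code{\link{fit_ldvae}} result.
#' @param heldout a \code{\link{count_matrix}} with the same genes.
#' @return non-negative scalar.
#' @export
heldout_reconstruction_error <- function(fit, heldout) {
  model <- .get_model(fit)
  X <- .counts_dense(heldout, model$gene_ids)
  cfg <- model$config
  draws <- list(eps_z = matrix(0, nrow(X), cfg$n_factors), eps_s = rep(0, nrow(X)))
  f <- .forward_batch(model$par, model$buf, cfg, model$s_prior, X,
                      draws = draws, training = FALSE)
  -f$reconstruction / nrow(X)
}

#' Embed cells in the latent factor space
#'
#' Returns the posterior location of each cell: the Gaussian mean for the
#' normal family, or its row-wise softmax (simplex coordinates) for the
#' logistic-normal family.
#'
#' @param fit an \code{ldvae_fit} or \code{ldvae_model}.
#' @param counts cells to embed.
#' @return N x D matrix with columns \code{Z1..ZD}.
#' @export
embed_cells <- function(fit, counts) {
  model <- .get_model(fit)
  post <- encode(model, counts)
  Z <- post$z_loc
  if (model$config$latent == "ln") Z <- .softmax_rows(Z)
  colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  if (inherits(counts, "count_matrix")) rownames(Z) <- counts$cell_ids
  Z
}

#' Subset cells of a count matrix
#'
#' @param x a \code{count_matrix}.
#' @param i cell (row) index.
#' @param ... ignored.
#' @return a \code{count_matrix} with the selected cells.
#' @export
`[.count_matrix` <- function(x, i, ...) {
  count_matrix(x$counts[i, , drop = FALSE], gene_ids = x$gene_ids,
               cell_ids = x$cell_ids[i])
}
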