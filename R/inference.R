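# Amortized variational inference: encoder configuration, model
# initialization, posterior encoding, reparameterized sampling, and the ELBO.

#' Encoder architecture configuration
#'
#' The encoder is a small multilayer perceptron mapping each cell's
#' (transformed) count vector to the parameters of its variational posterior.
#' The architecture is shared across all decoder variants so that accuracy
#' comparisons isolate the decoder.
#'
#' @param n_hidden units per hidden layer (default 128).
#' @param n_layers number of hidden layers (default 1).
#' @param activation hidden activation; only \code{"relu"} is implemented.
#' @param input_transform \code{"log1p"} (default) or \code{"identity"}
#'   transform applied to counts before the encoder.
#' @return A list of class \code{encoder_config}.
#' @export
encoder_config <- function(n_hidden = 128L, n_layers = 1L,
                           activation = "relu",
                           input_transform = c("log1p", "identity")) {
  n_hidden <- .check_scalar_count(n_hidden, "n_hidden")
  n_layers <- .check_scalar_count(n_layers, "n_layers")
  if (!identical(activation, "relu")) .stopf("only 'relu' activation is implemented")
  input_transform <- match.arg(input_transform)
  structure(list(n_hidden = n_hidden, n_layers = n_layers,
                 activation = activation, input_transform = input_transform),
            class = "encoder_config")
}

#' Model configuration
#'
#' @param n_factors latent dimension D.
#' @param latent latent family: \code{"normal"} (factors are unconstrained) or
#'   \code{"ln"} (logistic-normal: factors are non-negative and sum to one per
#'   cell, embedding cells in a simplex).
#' @param decoder \code{"linear"} for the interpretable linear decoder or
#'   \code{"nn"} for the reference one-hidden-layer nonlinear decoder.
#' @param batch_norm logical; apply batch normalization to the linearly
#'   decoded logits before the softmax (linear decoder only).
#' @param encoder an \code{\link{encoder_config}}.
#' @param decoder_hidden hidden units of the nonlinear decoder.
#' @return A list of class \code{model_config}.
#' @examples
#' model_config(n_factors = 5, latent = "ln")
#' @export
model_config <- function(n_factors = 10L, latent = c("normal", "ln"),
                         decoder = c("linear", "nn"), batch_norm = FALSE,
                         encoder = encoder_config(), decoder_hidden = 128L) {
  latent <- match.arg(latent)
  decoder <- match.arg(decoder)
  n_factors <- .check_scalar_count(n_factors, "n_factors")
  if (batch_norm && decoder == "nn") {
    .stopf("batch_norm applies to the linearly decoded logits; use decoder = 'linear'")
  }
  structure(list(n_factors = n_factors, latent = latent, decoder = decoder,
                 batch_norm = isTRUE(batch_norm), encoder = encoder,
                 decoder_hidden = .check_scalar_count(decoder_hidden, "decoder_hidden")),
            class = "model_config")
}

#' Initialize an untrained model
#'
#' Allocates encoder and decoder weights for a dataset with the given genes.
#' Mostly useful for testing; \code{\link{fit_ldvae}} calls this internally.
#'
#' @param gene_ids character vector of gene identifiers (or a single integer,
#'   the number of genes).
#' @param config a \code{\link{model_config}}.
#' @param seed integer seed for weight initialization.
#' @param s_mu,s_sigma lognormal exposure prior; \code{fit_ldvae} sets these
#'   from the data (mean and sd of per-cell log total counts).
#' @param W_init optional G x D warm start for the linear decoder loadings
#'   (\code{fit_ldvae} passes a PCA-based warm start; see the package
#'   vignette). Ignored for the nonlinear decoder.
#' @return An object of class \code{ldvae_model}.
#' @export
init_ldvae <- function(gene_ids, config = model_config(), seed = 1L,
                       s_mu = log(1000), s_sigma = 0.4, W_init = NULL) {
  if (is.numeric(gene_ids) && length(gene_ids) == 1L) {
    gene_ids <- sprintf("gene_%04d", seq_len(gene_ids))
  }
  G <- length(gene_ids)
  if (G < 2L) .stopf("need at least 2 genes")
  D <- config$n_factors
  ec <- config$encoder
  H <- ec$n_hidden
  par <- .with_seed(seed, {
    p <- list()
    fan <- G
    for (l in seq_len(ec$n_layers)) {
      p[[paste0("enc_W", l)]] <- matrix(stats::rnorm(fan * H, sd = sqrt(2 / fan)), fan, H)
      p[[paste0("enc_b", l)]] <- rep(0, H)
      fan <- H
    }
    p$enc_Wz <- matrix(stats::rnorm(H * D, sd = 0.01), H, D)
    p$enc_bz <- rep(0, D)
    p$enc_Wzs <- matrix(stats::rnorm(H * D, sd = 0.01), H, D)
    p$enc_bzs <- rep(-1, D)          # initial posterior sd ~ exp(-1)
    p$enc_Wl <- matrix(stats::rnorm(H, sd = 0.01), H, 1L)
    p$enc_bl <- s_mu                 # start log-exposure near the prior mean
    p$enc_Wls <- matrix(stats::rnorm(H, sd = 0.01), H, 1L)
    p$enc_bls <- -1
    if (config$decoder == "linear") {
      p$dec_W <- if (is.null(W_init)) {
        matrix(stats::rnorm(G * D, sd = 0.1), G, D)
      } else {
        if (!all(dim(W_init) == c(G, D))) .stopf("W_init must be %d x %d", G, D)
        unname(as.matrix(W_init))
      }
      if (config$batch_norm) {
        p$bn_gamma <- rep(1, G)
        p$bn_beta <- rep(0, G)
      }
    } else {
      Hd <- config$decoder_hidden
      p$dec_V1 <- matrix(stats::rnorm(D * Hd, sd = sqrt(2 / D)), D, Hd)
      p$dec_c1 <- rep(0, Hd)
      p$dec_V2 <- matrix(stats::rnorm(Hd * G, sd = sqrt(2 / Hd)), Hd, G)
      p$dec_c2 <- rep(0, G)
    }
    p$log_theta <- rep(0, G)
    p
  })
  buf <- if (config$batch_norm) list(r_mean = rep(0, G), r_var = rep(1, G)) else list()
  structure(list(par = par, buf = buf, config = config,
                 gene_ids = as.character(gene_ids), G = G, D = D,
                 s_prior = list(s_mu = s_mu, s_sigma = s_sigma)),
            class = "ldvae_model")
}

#' @noRd
.get_model <- function(x) {
  if (inherits(x, "ldvae_fit")) x$model
  else if (inherits(x, "ldvae_model")) x
  else .stopf("expected an ldvae_model or ldvae_fit")
}

#' @noRd
.counts_dense <- function(counts, gene_ids = NULL) {
  X <- if (inherits(counts, "count_matrix")) .as_dense(counts$counts) else .as_dense(counts)
  if (!is.null(gene_ids) && ncol(X) != length(gene_ids)) {
    .stopf("counts have %d genes but the model was built for %d", ncol(X), length(gene_ids))
  }
  X
}

#' Encode cells into their variational posterior
#'
#' Runs the encoder network on each cell's count vector and returns the
#' per-cell Gaussian posterior parameters for z and for log s. For the
#' logistic-normal family these parameterize the pre-softmax Gaussian, not the
#' simplex coordinates. Deterministic given the model state and input.
#'
#' @param model an \code{ldvae_model} or \code{\link{fit_ldvae}} result.
#' @param counts a \code{\link{count_matrix}} (or plain matrix) with the same
#'   genes the model was trained on.
#' @return A list of class \code{latent_posterior} with \code{z_loc},
#'   \code{z_scale} (N x D), \code{s_loc}, \code{s_scale} (length N).
#' @export
encode <- function(model, counts) {
  model <- .get_model(model)
  X <- .counts_dense(counts, model$gene_ids)
  f <- .encoder_forward(model$par, model$config, X)
  structure(list(z_loc = f$z_loc, z_scale = exp(f$z_logs),
                 s_loc = drop(f$s_loc), s_scale = drop(exp(f$s_logs))),
            class = "latent_posterior")
}

#' Draw latent states from a variational posterior
#'
#' Reparameterized sampling: \code{z = z_loc + z_scale * eps} with standard
#' normal noise (followed by a row-wise softmax for the logistic-normal
#' family) and \code{s = exp(s_loc + s_scale * eps')}.
#'
#' @param post a \code{latent_posterior} from \code{\link{encode}}.
#' @param latent_family \code{"normal"} or \code{"ln"}.
#' @param seed integer seed; identical seeds give identical draws.
#' @return A list with \code{z} (N x D; rows on the simplex for \code{"ln"})
#'   and \code{s} (positive exposures).
#' @export
sample_latent <- function(post, latent_family = c("normal", "ln"), seed = 1L) {
  latent_family <- match.arg(latent_family)
  if (any(post$z_scale <= 0) || any(post$s_scale <= 0)) {
    .stopf("posterior scales must be strictly positive")
  }
  n <- nrow(post$z_loc)
  d <- ncol(post$z_loc)
  .with_seed(seed, {
    z <- post$z_loc + post$z_scale * matrix(stats::rnorm(n * d), n, d)
    if (latent_family == "ln") z <- .softmax_rows(z)
    s <- exp(post$s_loc + post$s_scale * stats::rnorm(n))
    list(z = z, s = s)
  })
}

#' KL divergence between two univariate normal distributions
#'
#' Elementwise \eqn{KL(q \| p)} for \eqn{q = N(q\_loc, q\_scale^2)} and
#' \eqn{p = N(p\_loc, p\_scale^2)}:
#' \deqn{\log(p_s/q_s) + \frac{q_s^2 + (q_l - p_l)^2}{2 p_s^2} - \frac12.}
#'
#' @param q_loc,q_scale posterior location and scale (scale > 0).
#' @param p_loc,p_scale prior location and scale (scale > 0); default standard
#'   normal.
#' @return per-dimension KL divergences (non-negative).
#' @examples
#' kl_normal(1, 1)  # 0.5
#' @export
kl_normal <- function(q_loc, q_scale, p_loc = 0, p_scale = 1) {
  if (any(q_scale <= 0) || any(p_scale <= 0)) .stopf("scales must be strictly positive")
  log(p_scale / q_scale) + (q_scale^2 + (q_loc - p_loc)^2) / (2 * p_scale^2) - 0.5
}

#' Evidence lower bound of a batch of cells
#'
#' Assembles the variational objective: the reconstruction term is the
#' negative binomial log-likelihood of the counts under one reparameterized
#' draw of (z, s) per cell, and the KL term penalizes the posterior's
#' divergence from the priors (standard normal for z -- on the pre-softmax
#' Gaussian for the logistic-normal family -- and the lognormal exposure
#' prior for s). Terms are sums over the batch, so duplicating cells scales
#' the objective accordingly.
#'
#' @param model an \code{ldvae_model} or fit result.
#' @param counts cells to evaluate (same genes as the model).
#' @param seed seed for the single Monte Carlo draw.
#' @param kl_weight KL annealing weight in \[0, 1\] (1 = plain ELBO).
#' @param draws optional fixed noise, a list with \code{eps_z} (N x D) and
#'   \code{eps_s} (length N); overrides \code{seed}. Zero noise evaluates the
#'   objective at the posterior locations.
#' @return A list with \code{objective}, \code{reconstruction}, \code{kl},
#'   the posterior, and the latent \code{draws} used.
#' @export
elbo <- function(model, counts, seed = 1L, kl_weight = 1, draws = NULL) {
  model <- .get_model(model)
  X <- .counts_dense(counts, model$gene_ids)
  if (nrow(X) < 1L) .stopf("batch must be non-empty")
  f <- .forward_batch(model$par, model$buf, model$config, model$s_prior, X,
                      seed = seed, draws = draws, training = FALSE)
  list(objective = f$reconstruction - kl_weight * f$kl,
       reconstruction = f$reconstruction, kl = f$kl,
       posterior = structure(list(z_loc = f$z_loc, z_scale = exp(f$z_logs),
                                  s_loc = drop(f$s_loc), s_scale = drop(exp(f$s_logs))),
                             class = "latent_posterior"),
       draws = list(z = f$Zin, s = f$s))
}
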