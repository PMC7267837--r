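# Generative model: standard-normal (or logistic-normal) latent factors,
# lognormal per-cell exposure, linear decoder onto the gene simplex, and a
# Gamma-Poisson emission whose analytic marginal is the negative binomial.

#' Construct a cell-by-gene count matrix container
#'
#' Validates and wraps a non-negative integer matrix of molecule counts with
#' cell and gene identifiers. Internally counts are stored as a sparse
#' \code{\link[Matrix]{dgCMatrix}} with cells as rows and genes as columns.
#'
#' @param counts numeric or sparse matrix of non-negative integers, cells in
#'   rows and genes in columns.
#' @param gene_ids character vector of gene identifiers, one per column.
#'   Defaults to \code{gene_0001 ...}.
#' @param cell_ids character vector of cell identifiers, one per row.
#'   Defaults to \code{cell_0001 ...}.
#' @return An object of class \code{count_matrix} with elements
#'   \code{counts}, \code{gene_ids} and \code{cell_ids}.
#' @examples
#' y <- matrix(rpois(20, 3), nrow = 4)
#' cm <- count_matrix(y)
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL) {
  if (is.null(dim(counts))) .stopf("'counts' must be a matrix")
  n <- nrow(counts)
  g <- ncol(counts)
  if (n < 1L || g < 2L) .stopf("need at least 1 cell and 2 genes, got %d x %d", n, g)
  dense_chunk <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  if (length(dense_chunk) && (any(dense_chunk < 0) || any(dense_chunk != floor(dense_chunk)))) {
    .stopf("counts must be non-negative integers")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(g))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(n))
  if (length(gene_ids) != g) .stopf("gene_ids length %d != %d genes", length(gene_ids), g)
  if (length(cell_ids) != n) .stopf("cell_ids length %d != %d cells", length(cell_ids), n)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(cell_ids, gene_ids)
  structure(
    list(counts = m, gene_ids = as.character(gene_ids), cell_ids = as.character(cell_ids)),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  nz <- length(x$counts@x)
  cat(sprintf(
    "count_matrix: %d cells x %d genes, %.1f%% non-zero\n",
    nrow(x$counts), ncol(x$counts), 100 * nz / prod(dim(x$counts))
  ))
  invisible(x)
}

#' Batch-norm state for the decoded logits
#'
#' Running first/second moments plus learnable affine scale and shift, one
#' entry per gene. Used by \code{\link{decode_linear}} in evaluation mode and
#' folded into effective loadings by \code{\link{get_loadings}}.
#'
#' @param r_mean,r_var running mean and variance per gene (variance >= 0).
#' @param gamma,beta affine scale and shift per gene.
#' @return A list of class \code{bn_state}.
#' @export
bn_state <- function(r_mean, r_var, gamma = rep(1, length(r_mean)),
                     beta = rep(0, length(r_mean))) {
  g <- length(r_mean)
  if (length(r_var) != g || length(gamma) != g || length(beta) != g) {
    .stopf("bn_state fields must share one length per gene")
  }
  if (any(r_var < 0)) .stopf("running variances must be >= 0")
  structure(list(r_mean = as.numeric(r_mean), r_var = as.numeric(r_var),
                 gamma = as.numeric(gamma), beta = as.numeric(beta)),
            class = "bn_state")
}

#' Parameters of the generative model
#'
#' Holds the loading matrix W (genes x factors), per-gene inverse dispersions
#' theta (the Gamma shape; larger means closer to Poisson), and the lognormal
#' exposure prior (s_mu, s_sigma). Optionally carries a batch-norm state for
#' the decoded logits.
#'
#' @param W numeric matrix, G genes x D factors, pre-softmax loading weights.
#' @param theta positive numeric vector of length G, per-gene inverse
#'   dispersion.
#' @param s_mu,s_sigma mean and standard deviation (positive) of the
#'   log-exposure prior.
#' @param bn_state optional \code{\link{bn_state}}.
#' @return An object of class \code{generative_params}.
#' @examples
#' p <- generative_params(matrix(rnorm(20), 10, 2), theta = rep(5, 10))
#' @export
generative_params <- function(W, theta, s_mu = log(1000), s_sigma = 0.4,
                              bn_state = NULL) {
  W <- as.matrix(W)
  if (nrow(W) < 2L || ncol(W) < 1L) .stopf("W must be G x D with G >= 2, D >= 1")
  if (length(theta) == 1L) theta <- rep(theta, nrow(W))
  if (length(theta) != nrow(W)) .stopf("theta length %d != %d genes", length(theta), nrow(W))
  if (any(!is.finite(theta)) || any(theta <= 0)) .stopf("theta must be strictly positive")
  if (!is.finite(s_sigma) || s_sigma <= 0) .stopf("s_sigma must be positive")
  if (!is.null(bn_state)) {
    if (!inherits(bn_state, "bn_state")) .stopf("bn_state must be built with bn_state()")
    if (length(bn_state$r_mean) != nrow(W)) .stopf("bn_state length != number of genes")
  }
  structure(list(W = W, theta = as.numeric(theta), s_mu = s_mu,
                 s_sigma = s_sigma, bn_state = bn_state),
            class = "generative_params")
}

# Pre-softmax decoder logits: the linear map z %*% t(W) with the optional
# batch-norm transform. `training` selects batch statistics; eval mode uses
# the stored running statistics.
#' @noRd
.decode_logits <- function(z, params, use_batch_norm = FALSE, training = FALSE) {
  W <- params$W
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != ncol(W)) {
    .stopf("z has %d columns but W has %d factors", ncol(z), ncol(W))
  }
  a <- z %*% t(W)
  if (use_batch_norm) {
    if (training) {
      if (nrow(a) < 2L) .stopf("batch-norm training mode needs >= 2 rows")
      mu <- colMeans(a)
      v <- colMeans(a^2) - mu^2
      a <- sweep(sweep(a, 2L, mu), 2L, sqrt(v + .bn_eps), "/")
      bs <- params$bn_state
      if (!is.null(bs)) {
        a <- sweep(sweep(a, 2L, bs$gamma, "*"), 2L, bs$beta, "+")
      }
    } else {
      bs <- params$bn_state
      if (is.null(bs)) .stopf("batch-norm requested in eval mode but bn_state is empty")
      a <- sweep(sweep(a, 2L, bs$r_mean), 2L, sqrt(bs$r_var + .bn_eps), "/")
      a <- sweep(sweep(a, 2L, bs$gamma, "*"), 2L, bs$beta, "+")
    }
  }
  a
}

#' Linear decoder: latent coordinates to per-gene mean proportions
#'
#' Maps latent coordinates to the gene simplex via
#' \code{mu = softmax(z \%*\% t(W))}, optionally applying a batch-norm
#' transform to the pre-softmax logits. Every output row is strictly positive
#' and sums to one; the expected count for gene g in cell n is then
#' \code{s_n * mu_ng} with \code{s_n} the cell's exposure.
#'
#' @param z numeric vector of length D or N x D matrix of latent coordinates.
#' @param params a \code{\link{generative_params}} object (or any list with a
#'   \code{W} matrix and optional \code{bn_state}).
#' @param use_batch_norm logical; apply the batch-norm transform to the
#'   logits.
#' @param training logical; in training mode batch statistics are used,
#'   otherwise the running statistics stored in \code{params$bn_state}.
#' @return N x G matrix of mean proportions, rows on the simplex.
#' @examples
#' p <- generative_params(matrix(c(1, 0, 0, 1, 0, 0), 3, 2, byrow = TRUE),
#'                        theta = rep(1, 3))
#' decode_linear(c(1, 0), p)  # softmax(1, 0, 0)
#' @export
decode_linear <- function(z, params, use_batch_norm = FALSE, training = FALSE) {
  .softmax_rows(.decode_logits(z, params, use_batch_norm, training))
}

#' Negative binomial (Gamma-Poisson) log probability mass
#'
#' The emission of the generative model is \code{v ~ Gamma(shape = theta,
#' mean = mu)} followed by \code{y ~ Poisson(v * s)}; marginalizing v gives a
#' negative binomial with mean \code{m = s * mu} and inverse dispersion
#' \code{theta}:
#' \deqn{\log NB(y; m, \theta) = \log\Gamma(y+\theta) - \log\Gamma(\theta)
#'   - \log\Gamma(y+1) + \theta \log\frac{\theta}{\theta+m}
#'   + y \log\frac{m}{\theta+m}.}
#' Arguments recycle elementwise following the usual R rules.
#'
#' @param y non-negative integer counts.
#' @param mean positive means (the composite \code{s * mu}).
#' @param theta positive inverse dispersions.
#' @return log probabilities, same shape as the broadcast arguments.
#' @examples
#' nb_log_pmf(0, 1, 1)  # log(1/2)
#' @export
nb_log_pmf <- function(y, mean, theta) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    .stopf("y must contain non-negative integers")
  }
  if (any(!is.finite(mean)) || any(mean <= 0)) .stopf("mean must be strictly positive")
  if (any(!is.finite(theta)) || any(theta <= 0)) .stopf("theta must be strictly positive")
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta / (theta + mean)) + y * log(mean / (theta + mean))
}

# NB log-likelihood of a dense count matrix Y (N x G) given mean matrix M and
# per-gene theta vector; returns per-cell sums. Avoids the elementwise
# recycling trap (R recycles down columns, theta is per column).
#' @noRd
.nb_loglik_rows <- function(Y, M, theta) {
  Th <- matrix(theta, nrow = nrow(Y), ncol = ncol(Y), byrow = TRUE)
  rowSums(lgamma(Y + Th) - lgamma(Th) - lgamma(Y + 1) +
            Th * log(Th / (Th + M)) + Y * log(M / (Th + M)))
}

#' Forward-sample the generative model
#'
#' Draws \code{z_n} (standard normal, or its softmax for the logistic-normal
#' family), exposures \code{s_n ~ lognormal(s_mu, s_sigma^2)}, computes
#' \code{mu = decode_linear(z)}, then \code{v_ng ~ Gamma(shape = theta_g,
#' mean = mu_ng)} and \code{y_ng ~ Poisson(v_ng * s_n)}.
#'
#' @param params a \code{\link{generative_params}} object.
#' @param n_cells number of cells to draw.
#' @param latent_family \code{"normal"} or \code{"ln"} (logistic-normal).
#' @param seed integer seed; identical seeds give identical output.
#' @param use_batch_norm logical; decode through the stored batch-norm state
#'   (evaluation mode).
#' @return A list with \code{counts} (a \code{\link{count_matrix}}) and
#'   \code{latent} (list with \code{z}, \code{s}, \code{v} and \code{mu}).
#' @examples
#' p <- generative_params(matrix(rnorm(40), 20, 2), theta = 5, s_mu = log(200))
#' sim <- sample_generative(p, n_cells = 10, seed = 1)
#' dim(sim$counts)
#' @export
sample_generative <- function(params, n_cells, latent_family = c("normal", "ln"),
                              seed = 1L, use_batch_norm = FALSE) {
  latent_family <- match.arg(latent_family)
  n <- .check_scalar_count(n_cells, "n_cells")
  G <- nrow(params$W)
  D <- ncol(params$W)
  .with_seed(seed, {
    z <- matrix(stats::rnorm(n * D), n, D)
    if (latent_family == "ln") z <- .softmax_rows(z)
    s <- exp(stats::rnorm(n, params$s_mu, params$s_sigma))
    mu <- decode_linear(z, params, use_batch_norm = use_batch_norm, training = FALSE)
    v <- matrix(
      stats::rgamma(n * G, shape = rep(params$theta, each = n),
                    rate = rep(params$theta, each = n) / mu),
      n, G
    )
    y <- matrix(stats::rpois(n * G, v * s), n, G)
    list(
      counts = count_matrix(y),
      latent = list(z = z, s = s, v = v, mu = mu)
    )
  })
}
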