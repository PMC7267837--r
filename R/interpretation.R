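# Factor interpretation: effective loadings, factor covariance of the latent
# representation, eigendecomposition ordering by variance explained, simplex
# rank diagnostics, and ranked gene lists per factor.

#' Effective gene loadings of a fitted linear decoder
#'
#' Returns the G x D matrix of weights linking each factor to each gene's
#' pre-softmax expression logit. Without batch norm this is the stored W.
#' With batch norm, evaluation mode standardizes the logits by the running
#' statistics and applies the affine scale, so the effective linear map from
#' z to logits is \code{W * gamma / sqrt(r_var + eps)} per gene row; that
#' folded matrix is returned, making \code{decode_linear} in evaluation mode
#' affine in z with these loadings as its slope.
#'
#' @param fit an \code{\link{fit_ldvae}} result (or \code{ldvae_model}) with
#'   a linear decoder.
#' @return G x D numeric matrix, rows named by gene, columns \code{Z1..ZD}.
#' @export
get_loadings <- function(fit) {
  model <- .get_model(fit)
  if (model$config$decoder != "linear") {
    .stopf("loadings are only defined for the linear decoder (decoder = 'linear')")
  }
  W <- model$par$dec_W
  if (model$config$batch_norm) {
    scale <- model$par$bn_gamma / sqrt(model$buf$r_var + .bn_eps)
    W <- W * scale
  }
  dimnames(W) <- list(model$gene_ids, paste0("Z", seq_len(ncol(W))))
  W
}

#' Center and scale latent coordinates
#'
#' Columns are centered to mean zero and scaled to unit sample standard
#' deviation (denominator N - 1). Columns with zero spread are centered and
#' left at zero; their indices are recorded in the \code{"degenerate"}
#' attribute.
#'
#' @param Z N x D numeric matrix, N >= 2.
#' @return centered/scaled matrix with attribute \code{degenerate}.
#' @export
center_scale <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) .stopf("need at least 2 rows to center and scale")
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2L, mu)
  sdev <- apply(Zc, 2L, stats::sd)
  degen <- which(sdev <= 0 | !is.finite(sdev))
  sdev[degen] <- 1
  out <- sweep(Zc, 2L, sdev, "/")
  if (length(degen)) out[, degen] <- 0
  attr(out, "degenerate") <- as.integer(degen)
  out
}

#' Factor covariance of a latent representation
#'
#' The correlation-scaled covariance \eqn{\hat Z^T \hat Z / (N-1)} of the
#' centered and scaled coordinates: symmetric, with unit diagonal for
#' non-degenerate columns. Off-diagonals measure how much the learned factors
#' covary; linear decoders are constrained by such covariation while
#' nonlinear decoders are not.
#'
#' @param Z N x D matrix of latent coordinates, N >= 2.
#' @return D x D symmetric matrix.
#' @export
factor_covariance <- function(Z) {
  Zh <- center_scale(Z)
  crossprod(Zh) / (nrow(Zh) - 1)
}

#' Order factors by variance explained
#'
#' Eigendecomposition of a factor covariance matrix: eigenvalues sorted in
#' decreasing order, the proportion of variance explained by each
#' (eigenvalue over trace), and an attribution of eigenvalue ranks to the
#' original factors. Attribution is greedy by dominant eigenvector component:
#' in eigenvalue order, each eigenvector claims the not-yet-claimed factor
#' with the largest absolute weight in it.
#'
#' @param cov D x D symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @return A list with \code{eigenvalues} (decreasing),
#'   \code{variance_explained} (sums to one), \code{factor_order}
#'   (permutation of 1..D: the original factor attributed to each eigenvalue
#'   rank) and \code{vectors} (eigenvectors as columns).
#' @examples
#' order_factors(diag(c(3, 1)))$variance_explained  # 0.75 0.25
#' @export
order_factors <- function(cov) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) .stopf("covariance must be square")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    .stopf("covariance must be symmetric")
  }
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  vals <- e$values
  tr <- sum(vals)
  if (tr <= 0) .stopf("covariance has non-positive trace")
  D <- length(vals)
  claimed <- logical(D)
  ord <- integer(D)
  for (r in seq_len(D)) {
    w <- abs(e$vectors[, r])
    w[claimed] <- -Inf
    ord[r] <- which.max(w)
    claimed[ord[r]] <- TRUE
  }
  list(eigenvalues = vals, variance_explained = vals / tr,
       factor_order = ord, vectors = e$vectors)
}

#' Rank-deficiency diagnostic for simplex-valued latent coordinates
#'
#' Logistic-normal factors live on a simplex: rows are non-negative and sum
#' to one, so the coordinates lie in a (D-1)-dimensional affine subspace and
#' one factor is always linearly dependent on the others. This reports the
#' smallest eigenvalue of the centered (unscaled) covariance and flags rank
#' deficiency when it is at most 1e-8 times the largest eigenvalue.
#'
#' @param Z N x D matrix whose rows lie on the simplex (within 1e-6).
#' @return A list with \code{min_eigenvalue}, \code{max_eigenvalue} and
#'   logical \code{rank_deficient}.
#' @export
simplex_rank_check <- function(Z) {
  Z <- as.matrix(Z)
  if (any(Z < -1e-9) || any(abs(rowSums(Z) - 1) > 1e-6)) {
    .stopf("rows must be non-negative and sum to 1 (simplex invariant)")
  }
  Zc <- sweep(Z, 2L, colMeans(Z))
  C <- crossprod(Zc) / max(1L, nrow(Z) - 1L)
  vals <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(vals)
  mn <- min(vals)
  list(min_eigenvalue = mn, max_eigenvalue = mx,
       rank_deficient = mn <= 1e-8 * max(mx, .Machine$double.eps))
}

#' Top genes of a factor
#'
#' Genes ranked by loading weight on one factor. With \code{direction =
#' "both"} ranking is by absolute weight; \code{"positive"} /
#' \code{"negative"} rank by signed weight (descending / ascending). Ties are
#' broken by gene identifier in lexicographic order.
#'
#' @param loadings G x D loading matrix with gene row names (e.g. from
#'   \code{\link{get_loadings}}).
#' @param factor factor index in 1..D.
#' @param k number of genes to return.
#' @param direction \code{"both"}, \code{"positive"} or \code{"negative"}.
#' @return data frame with columns \code{gene} and \code{weight}.
#' @export
top_genes <- function(loadings, factor, k = 10L,
                      direction = c("both", "positive", "negative")) {
  direction <- match.arg(direction)
  loadings <- as.matrix(loadings)
  D <- ncol(loadings)
  if (length(factor) != 1L || factor < 1L || factor > D || factor != floor(factor)) {
    .stopf("factor must be an index in 1..%d", D)
  }
  k <- .check_scalar_count(k, "k")
  genes <- rownames(loadings)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(nrow(loadings)))
  w <- loadings[, factor]
  key <- switch(direction, both = abs(w), positive = w, negative = -w)
  ord <- order(-key, genes)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(gene = genes[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Full factor report for a fitted model
#'
#' Embeds the cells, computes the factor covariance of the embedding, orders
#' factors by variance explained, and collects ranked top genes per factor
#' from the effective loadings. For logistic-normal fits the simplex
#' rank-deficiency diagnostic is included.
#'
#' @param fit an \code{\link{fit_ldvae}} result with a linear decoder.
#' @param counts cells used to form the latent representation.
#' @param k top genes per factor.
#' @return A list of class \code{factor_report}: \code{loadings},
#'   \code{covariance}, \code{eigenvalues}, \code{variance_explained},
#'   \code{factor_order}, \code{top_genes} (one data frame per factor, in
#'   eigenvalue-rank order) and, for \code{"ln"} fits,
#'   \code{simplex_diagnostic}.
#' @export
factor_report <- function(fit, counts, k = 10L) {
  model <- .get_model(fit)
  W <- get_loadings(fit)
  Z <- embed_cells(fit, counts)
  C <- factor_covariance(Z)
  of <- order_factors(C)
  tg <- lapply(of$factor_order, function(d) top_genes(W, d, k = k))
  names(tg) <- paste0("Z", of$factor_order)
  rep <- list(loadings = W, covariance = C, eigenvalues = of$eigenvalues,
              variance_explained = of$variance_explained,
              factor_order = of$factor_order, top_genes = tg)
  if (model$config$latent == "ln") rep$simplex_diagnostic <- simplex_rank_check(Z)
  structure(rep, class = "factor_report")
}

#' @export
print.factor_report <- function(x, ...) {
  cat(sprintf("factor_report: %d factors\n", length(x$eigenvalues)))
  df <- data.frame(rank = seq_along(x$eigenvalues), factor = x$factor_order,
                   eigenvalue = round(x$eigenvalues, 4),
                   var_explained = round(x$variance_explained, 4))
  print(df, row.names = FALSE)
  if (!is.null(x$simplex_diagnostic)) {
    cat(sprintf("simplex rank-deficient: %s\n", x$simplex_diagnostic$rank_deficient))
  }
  invisible(x)
}
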