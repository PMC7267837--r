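# Loadings, factor covariance, eigendecomposition ordering, simplex rank,
# top genes.

test_that("get_loadings folds batch norm into effective weights", {
  fit <- small_fit()
  W <- get_loadings(fit)
  expect_identical(unname(W), unname(fit$model$par$dec_W))  # identity fold
  expect_identical(rownames(W), fit$gene_ids)

  m <- init_ldvae(5, model_config(2, "normal", "linear", batch_norm = TRUE), seed = 2)
  m$buf$r_mean[] <- 0
  m$buf$r_var[] <- 1 - 1e-5  # sqrt(r_var + eps) exactly 1
  W2 <- get_loadings(m)
  expect_equal(unname(W2), unname(m$par$dec_W), tolerance = 1e-12)
  # running variance 4, affine scale 2 on one gene -> row scaled by 2/sqrt(4+eps)
  m$buf$r_var[3] <- 4
  m$par$bn_gamma[3] <- 2
  W3 <- get_loadings(m)
  expect_equal(unname(W3[3, ]), m$par$dec_W[3, ] * 2 / sqrt(4 + 1e-5),
               tolerance = 1e-12)

  nn <- init_ldvae(5, model_config(2, decoder = "nn"), seed = 1)
  expect_error(get_loadings(nn), "linear")
})

test_that("effective loadings reproduce eval-mode decoding on basis vectors", {
  set.seed(3)
  m <- init_ldvae(8, model_config(3, "normal", "linear", batch_norm = TRUE), seed = 4)
  m$buf$r_mean <- rnorm(8)
  m$buf$r_var <- exp(rnorm(8))
  m$par$bn_gamma <- exp(rnorm(8, 0, 0.3))
  m$par$bn_beta <- rnorm(8)
  W <- get_loadings(m)
  params <- list(W = m$par$dec_W,
                 bn_state = bn_state(m$buf$r_mean, m$buf$r_var,
                                     m$par$bn_gamma, m$par$bn_beta))
  base <- ldvae:::.decode_logits(rep(0, 3), params, use_batch_norm = TRUE)
  for (d in 1:3) {
    e_d <- replace(rep(0, 3), d, 1)
    diffd <- ldvae:::.decode_logits(e_d, params, use_batch_norm = TRUE) - base
    expect_equal(drop(diffd), unname(W[, d]), tolerance = 1e-5)
  }
  # and for 10 random z the map stays affine with slope W
  z <- matrix(rnorm(30), 10, 3)
  expect_equal(ldvae:::.decode_logits(z, params, use_batch_norm = TRUE),
               sweep(z %*% t(W), 2, drop(base), "+"), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("center_scale centers, scales, and flags degenerate columns", {
  out <- center_scale(cbind(a = c(1, 2, 3)))
  expect_equal(drop(out), c(-1, 0, 1), ignore_attr = TRUE)  # sample-sd convention
  # under population sd the same column would be (-1.2247, 0, 1.2247)
  expect_equal(drop(out) * sqrt(3 / 2), c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  z <- matrix(rnorm(100), 50, 2)
  once <- center_scale(z)
  expect_equal(center_scale(once), once, tolerance = 1e-12, ignore_attr = TRUE)
  const <- center_scale(cbind(rnorm(10), rep(2, 10)))
  expect_equal(const[, 2], rep(0, 10))
  expect_equal(attr(const, "degenerate"), 2L)
  expect_error(center_scale(matrix(1, 1, 2)), "2 rows")
})

test_that("factor_covariance is a correlation matrix with the expected structure", {
  set.seed(4)
  Z <- matrix(rnorm(10000 * 3), ncol = 3)
  C <- factor_covariance(Z)
  expect_equal(diag(C), rep(1, 3), tolerance = 1e-12)
  expect_true(all(abs(C[upper.tri(C)]) < 3 / sqrt(10000)))
  expect_equal(C, t(C))
  dup <- cbind(Z[, 1], Z[, 1], Z[, 2])
  expect_equal(factor_covariance(dup)[1, 2], 1, tolerance = 1e-12)
  expect_equal(factor_covariance(Z[, 1, drop = FALSE]), matrix(1), tolerance = 1e-12)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))  # PSD
})

test_that("order_factors sorts eigenvalues and attributes factors", {
  of <- order_factors(diag(3))
  expect_equal(of$variance_explained, rep(1 / 3, 3))
  of2 <- order_factors(diag(c(3, 1)))
  expect_equal(of2$variance_explained, c(0.75, 0.25))
  expect_equal(of2$factor_order, c(1L, 2L))
  expect_equal(order_factors(diag(c(1, 3)))$factor_order, c(2L, 1L))
  expect_true(all(diff(of2$eigenvalues) <= 0))
  # rank-2 representation has a zero trailing eigenvalue
  set.seed(5)
  a <- rnorm(100); b <- rnorm(100)
  C3 <- factor_covariance(cbind(a, b, a + b))
  expect_lte(order_factors(C3)$eigenvalues[3], 1e-8)
  expect_error(order_factors(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("simplex_rank_check flags the structural rank deficiency", {
  set.seed(6)
  Z <- ldvae:::.softmax_rows(matrix(rnorm(500 * 4), ncol = 4))
  chk <- simplex_rank_check(Z)
  expect_true(chk$rank_deficient)
  expect_lte(chk$min_eigenvalue, 1e-8 * chk$max_eigenvalue)
  expect_error(simplex_rank_check(matrix(rnorm(100), 50, 2)), "simplex")
  # D = 1: all entries one, degenerate
  expect_true(simplex_rank_check(matrix(1, 20, 1))$rank_deficient)
  # gaussian latents (rescaled onto no simplex) are full rank: check via the
  # same eigen computation on a centered covariance
  G <- matrix(rnorm(2000 * 3), ncol = 3)
  Cc <- crossprod(sweep(G, 2, colMeans(G))) / (nrow(G) - 1)
  ev <- eigen(Cc, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-8 * max(ev))
})

test_that("top_genes ranks by magnitude with lexicographic ties", {
  W <- matrix(c(0.5, -2, 0.1, 1, 1, 0.2), ncol = 2,
              dimnames = list(c("gB", "gA", "gC"), NULL))
  expect_equal(top_genes(W, 1, k = 1)$gene, "gA")      # |-2| wins
  all3 <- top_genes(W, 1, k = 10)                       # k >= G: fully ordered
  expect_equal(all3$gene, c("gA", "gB", "gC"))
  # tie on factor 2 between gB and gA (both 1): lexicographic
  expect_equal(top_genes(W, 2, k = 2)$gene, c("gA", "gB"))
  expect_equal(top_genes(W, 1, k = 1, direction = "positive")$gene, "gB")
  expect_equal(top_genes(W, 1, k = 1, direction = "negative")$gene, "gA")
  expect_error(top_genes(W, 3), "index")
})

test_that("factor_report assembles a coherent summary", {
  fit <- small_fit()
  rep <- factor_report(fit, small_sim()$counts, k = 5)
  expect_equal(sum(rep$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(rep$variance_explained >= 0 & rep$variance_explained <= 1))
  expect_true(all(diff(rep$eigenvalues) <= 0))
  expect_setequal(rep$factor_order, 1:2)
  expect_length(rep$top_genes, 2)
  expect_equal(nrow(rep$top_genes[[1]]), 5)
})
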