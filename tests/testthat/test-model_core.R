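# Generative model: linear decoder, NB emission, forward sampling.

test_that("decode_linear maps to the simplex with the expected values", {
  p <- generative_params(matrix(c(1, 0, 0, 1, 0, 0), 3, 2, byrow = TRUE),
                         theta = rep(1, 3))
  # softmax of zeros is uniform
  expect_equal(drop(decode_linear(c(0, 0), p)), rep(1 / 3, 3), tolerance = 1e-12)
  # constant column: softmax is shift-invariant
  pc <- generative_params(matrix(2.5, 4, 1), theta = rep(1, 4))
  for (z in c(-3, 0, 1.7)) {
    expect_equal(drop(decode_linear(z, pc)), rep(0.25, 4), tolerance = 1e-12)
  }
  # hand-computed softmax(1, 0, 0)
  mu <- drop(decode_linear(c(1, 0), p))
  expect_equal(mu, c(exp(1), 1, 1) / (exp(1) + 2), tolerance = 1e-10)
})

test_that("decode_linear rows are strictly positive and sum to one", {
  set.seed(1)
  p <- generative_params(matrix(rnorm(60 * 4, sd = 2), 60, 4), theta = rep(1, 60))
  z <- matrix(rnorm(25 * 4, sd = 3), 25, 4)
  mu <- decode_linear(z, p)
  expect_true(all(mu > 0))
  expect_equal(rowSums(mu), rep(1, 25), tolerance = 1e-6)
})

test_that("pre-softmax decoder output is linear in z without batch norm", {
  set.seed(2)
  p <- generative_params(matrix(rnorm(20), 10, 2), theta = rep(1, 10))
  z1 <- matrix(rnorm(6), 3, 2)
  z2 <- matrix(rnorm(6), 3, 2)
  a <- 1.7
  b <- -0.4
  lhs <- ldvae:::.decode_logits(a * z1 + b * z2, p)
  rhs <- a * ldvae:::.decode_logits(z1, p) + b * ldvae:::.decode_logits(z2, p)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("decode_linear batch-norm modes behave and error as specified", {
  set.seed(3)
  W <- matrix(rnorm(8), 4, 2)
  p_nobn <- generative_params(W, theta = rep(1, 4))
  expect_error(decode_linear(c(1, 1), p_nobn, use_batch_norm = TRUE),
               "bn_state is empty")
  expect_error(decode_linear(c(1, 1, 1), p_nobn), "factors")
  bs <- bn_state(r_mean = c(0.1, -0.2, 0, 0.3), r_var = c(4, 1, 2, 0.5),
                 gamma = c(2, 1, 1, 1), beta = c(0, 0.5, 0, 0))
  p_bn <- generative_params(W, theta = rep(1, 4), bn_state = bs)
  z <- matrix(rnorm(10), 5, 2)
  # eval mode matches the hand-built affine transform
  a <- z %*% t(W)
  y <- sweep(sweep(a, 2, bs$r_mean), 2, sqrt(bs$r_var + 1e-5), "/")
  y <- sweep(sweep(y, 2, bs$gamma, "*"), 2, bs$beta, "+")
  expect_equal(decode_linear(z, p_bn, use_batch_norm = TRUE),
               ldvae:::.softmax_rows(y), tolerance = 1e-12)
  # training mode standardizes by batch statistics
  logits <- ldvae:::.decode_logits(z, p_nobn, use_batch_norm = TRUE, training = TRUE)
  expect_equal(colMeans(logits), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(logits, 2, function(x) mean(x^2)), rep(1, 4), tolerance = 1e-3)
})

test_that("nb_log_pmf matches its closed form, dnbinom, and the Poisson limit", {
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # dual route: base R's NB density is an independent implementation
  grid <- expand.grid(y = c(0, 1, 3, 10, 40), m = c(0.3, 2, 25), th = c(0.4, 2, 50))
  expect_equal(nb_log_pmf(grid$y, grid$m, grid$th),
               dnbinom(grid$y, size = grid$th, mu = grid$m, log = TRUE),
               tolerance = 1e-12)
  # NB -> Poisson as theta -> Inf; the exact gap at theta = 1e6 peaks at
  # 1.52e-4 (y = 20), so the 1e-4 bound is asserted one decade further out
  y <- 0:20
  expect_true(all(abs(nb_log_pmf(y, 2, 1e7) - dpois(y, 2, log = TRUE)) <= 1e-4))
  expect_true(all(abs(nb_log_pmf(y, 2, 1e6) - dpois(y, 2, log = TRUE)) <= 2e-4))
})

test_that("nb_log_pmf conserves probability mass", {
  for (par in list(c(1, 1), c(5, 2), c(50, 0.5))) {
    m <- par[1]
    th <- par[2]
    ymax <- qnbinom(1e-9, size = th, mu = m, lower.tail = FALSE) + 10
    expect_equal(sum(exp(nb_log_pmf(0:ymax, m, th))), 1, tolerance = 1e-6)
  }
})

test_that("nb_log_pmf validates its domain", {
  expect_error(nb_log_pmf(-1, 1, 1), "non-negative integers")
  expect_error(nb_log_pmf(1.5, 1, 1), "non-negative integers")
  expect_error(nb_log_pmf(1, 0, 1), "mean")
  expect_error(nb_log_pmf(1, 1, -2), "theta")
})

test_that("sample_generative is reproducible and respects invariants", {
  set.seed(9)
  p <- generative_params(matrix(rnorm(30 * 2), 30, 2), theta = 5, s_mu = log(300))
  a <- sample_generative(p, 40, seed = 5)
  b <- sample_generative(p, 40, seed = 5)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$latent$z, b$latent$z)
  y <- as.matrix(a$counts$counts)
  expect_true(all(y >= 0) && all(y == floor(y)))
  expect_true(all(a$latent$s > 0))
  ln <- sample_generative(p, 25, latent_family = "ln", seed = 2)
  expect_true(all(ln$latent$z >= 0))
  expect_equal(rowSums(ln$latent$z), rep(1, 25), tolerance = 1e-6)
  expect_error(sample_generative(p, 10, latent_family = "bogus"), "arg")
})

test_that("sample_generative matches conditional first moments", {
  set.seed(10)
  p <- generative_params(matrix(rnorm(50 * 2), 50, 2), theta = 5, s_mu = log(400))
  sim <- sample_generative(p, 20000, seed = 77)
  Y <- as.matrix(sim$counts$counts)
  target <- colMeans(sim$latent$mu * sim$latent$s)  # E[y | z, s] averaged
  resid_se <- apply(Y - sim$latent$mu * sim$latent$s, 2, sd) / sqrt(nrow(Y))
  expect_true(all(abs(colMeans(Y) - target) <= 4 * resid_se))
})

test_that("sample_generative reaches the Poisson limit", {
  set.seed(11)
  # near-constant mu (tiny loadings) and degenerate s, so the marginal
  # variance is not inflated by latent variation
  p <- generative_params(matrix(rnorm(20 * 2, sd = 0.01), 20, 2), theta = 1e6,
                         s_mu = log(100), s_sigma = 1e-6)
  sim <- sample_generative(p, 20000, seed = 4)
  Y <- as.matrix(sim$counts$counts)
  ratio <- apply(Y, 2, var) / colMeans(Y)
  expect_true(all(ratio > 0.9 & ratio < 1.1))
})

test_that("count_matrix validates and subsets", {
  expect_error(count_matrix(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  expect_error(count_matrix(matrix(c(1, 0.5, 2, 3), 2)), "non-negative")
  expect_error(count_matrix(matrix(1:4, 2), gene_ids = "a"), "gene_ids")
  cm <- count_matrix(matrix(0:5, 2, 3))
  expect_equal(dim(cm), c(2L, 3L))
  sub <- cm[2]
  expect_equal(dim(sub), c(1L, 3L))
  expect_equal(sub$cell_ids, cm$cell_ids[2])
  # zero-count genes are allowed (no silent filtering)
  cm0 <- count_matrix(cbind(0, matrix(1:4, 2)))
  expect_equal(dim(cm0), c(2L, 3L))
})
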