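# Internal compute engine: forward pass, hand-written reverse-mode gradients
# for the negative ELBO, and the Adam optimizer. Everything here operates on
# the flat named parameter list stored in an ldvae_model (`par`) plus the
# batch-norm running-statistic buffers (`buf`).
#
# Shapes: X is B x G (dense batch), hidden activations B x H, z heads B x D,
# s heads B x 1. Per-gene vectors broadcast along columns via sweep();
# per-cell vectors broadcast down rows via R recycling (length B against a
# B x G matrix).

# Clamp bounds for posterior log-scales; gradients are masked where clamped.
.logs_lo <- -8
.logs_hi <- 5

#' @noRd
.encoder_forward <- function(par, cfg, X) {
  ec <- cfg$encoder
  Xin <- if (ec$input_transform == "log1p") log1p(X) else X
  H <- vector("list", ec$n_layers)
  a <- Xin
  for (l in seq_len(ec$n_layers)) {
    a <- .relu(sweep(a %*% par[[paste0("enc_W", l)]], 2L, par[[paste0("enc_b", l)]], "+"))
    H[[l]] <- a
  }
  z_logs_raw <- sweep(a %*% par$enc_Wzs, 2L, par$enc_bzs, "+")
  s_logs_raw <- a %*% par$enc_Wls + par$enc_bls
  list(
    Xin = Xin, H = H,
    z_loc = sweep(a %*% par$enc_Wz, 2L, par$enc_bz, "+"),
    z_logs = .clamp(z_logs_raw, .logs_lo, .logs_hi),
    z_logs_mask = z_logs_raw > .logs_lo & z_logs_raw < .logs_hi,
    s_loc = a %*% par$enc_Wl + par$enc_bl,
    s_logs = .clamp(s_logs_raw, .logs_lo, .logs_hi),
    s_logs_mask = s_logs_raw > .logs_lo & s_logs_raw < .logs_hi
  )
}

# Full forward pass. `draws` may carry fixed noise (eps_z B x D, eps_s length
# B) for gradient checking; otherwise noise is drawn under `seed`. In
# training mode batch-norm uses batch statistics and the batch moments are
# returned so the caller can update the running buffers.
#' @noRd
.forward_batch <- function(par, buf, cfg, s_prior, X, seed = NULL,
                           draws = NULL, training = FALSE) {
  B <- nrow(X)
  G <- ncol(X)
  D <- cfg$n_factors
  enc <- .encoder_forward(par, cfg, X)
  if (is.null(draws)) {
    draws <- .with_seed(seed, list(
      eps_z = matrix(stats::rnorm(B * D), B, D),
      eps_s = stats::rnorm(B)
    ))
  }
  zg <- enc$z_loc + exp(enc$z_logs) * draws$eps_z
  Zin <- if (cfg$latent == "ln") .softmax_rows(zg) else zg
  bn <- NULL
  if (cfg$decoder == "linear") {
    A <- Zin %*% t(par$dec_W)
    if (cfg$batch_norm) {
      if (training) {
        mu_b <- colMeans(A)
        v_b <- colMeans(A^2) - mu_b^2
      } else {
        mu_b <- buf$r_mean
        v_b <- buf$r_var
      }
      xhat <- sweep(sweep(A, 2L, mu_b), 2L, sqrt(v_b + .bn_eps), "/")
      Y <- sweep(sweep(xhat, 2L, par$bn_gamma, "*"), 2L, par$bn_beta, "+")
      bn <- list(mu_b = mu_b, v_b = v_b, xhat = xhat)
    } else {
      Y <- A
    }
    Hd <- NULL
  } else {
    Hd <- .relu(sweep(Zin %*% par$dec_V1, 2L, par$dec_c1, "+"))
    Y <- sweep(Hd %*% par$dec_V2, 2L, par$dec_c2, "+")
    A <- NULL
  }
  P <- .softmax_rows(Y)
  log_s <- drop(enc$s_loc) + drop(exp(enc$s_logs)) * draws$eps_s
  s <- exp(log_s)
  M0 <- P * s
  M <- pmax(M0, .mean_floor)
  theta <- exp(par$log_theta)
  Th <- matrix(theta, B, G, byrow = TRUE)
  LL <- lgamma(X + Th) - lgamma(Th) - lgamma(X + 1) +
    Th * log(Th / (Th + M)) + X * log(M / (Th + M))
  klz <- sum(-enc$z_logs + (exp(2 * enc$z_logs) + enc$z_loc^2) / 2 - 0.5)
  pm <- s_prior$s_mu
  ps <- s_prior$s_sigma
  kls <- sum(log(ps) - enc$s_logs +
               (exp(2 * enc$s_logs) + (enc$s_loc - pm)^2) / (2 * ps^2) - 0.5)
  c(enc, list(
    draws = draws, zg = zg, Zin = Zin, A = A, bn = bn, Hd = Hd, Y = Y, P = P,
    log_s = log_s, s = s, M = M, Mmask = M0 > .mean_floor, Th = Th,
    reconstruction = sum(LL), klz = klz, kls = kls, kl = klz + kls
  ))
}

# Reverse-mode gradients of loss = -(reconstruction - klw * kl) / B with
# respect to every entry of `par`. `f` is the output of .forward_batch with
# training = TRUE.
#' @noRd
.backward_batch <- function(par, cfg, s_prior, X, f, klw) {
  B <- nrow(X)
  G <- ncol(X)
  sc <- 1 / B
  gr <- list()
  M <- f$M
  Th <- f$Th
  P <- f$P
  s <- f$s

  dM <- -sc * (X / M - (X + Th) / (Th + M))
  dM[!f$Mmask] <- 0
  dP <- dM * s
  ds_vec <- rowSums(dM * P)
  dY <- P * (dP - rowSums(dP * P))

  theta <- exp(par$log_theta)
  dtheta <- -sc * colSums(digamma(X + Th) - digamma(Th) +
                            log(Th / (Th + M)) + 1 - (Th + X) / (Th + M))
  gr$log_theta <- dtheta * theta

  if (cfg$decoder == "linear") {
    if (cfg$batch_norm) {
      xhat <- f$bn$xhat
      gr$bn_gamma <- colSums(dY * xhat)
      gr$bn_beta <- colSums(dY)
      dxhat <- sweep(dY, 2L, par$bn_gamma, "*")
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * xhat)
      dA <- sweep(
        dxhat - matrix(m1, B, G, byrow = TRUE) - xhat * matrix(m2, B, G, byrow = TRUE),
        2L, sqrt(f$bn$v_b + .bn_eps), "/"
      )
    } else {
      dA <- dY
    }
    gr$dec_W <- crossprod(dA, f$Zin)      # t(dA) %*% Zin, G x D
    dZin <- dA %*% par$dec_W
  } else {
    gr$dec_V2 <- crossprod(f$Hd, dY)
    gr$dec_c2 <- colSums(dY)
    dHd <- (dY %*% t(par$dec_V2)) * (f$Hd > 0)
    gr$dec_V1 <- crossprod(f$Zin, dHd)
    gr$dec_c1 <- colSums(dHd)
    dZin <- dHd %*% t(par$dec_V1)
  }

  dzg <- if (cfg$latent == "ln") {
    f$Zin * (dZin - rowSums(dZin * f$Zin))
  } else {
    dZin
  }

  dz_loc <- dzg + klw * sc * f$z_loc
  dz_logs <- (dzg * (f$zg - f$z_loc) +
                klw * sc * (exp(2 * f$z_logs) - 1)) * f$z_logs_mask

  pm <- s_prior$s_mu
  ps <- s_prior$s_sigma
  dlog_s <- ds_vec * s
  ds_loc <- matrix(dlog_s, B, 1L) + klw * sc * (f$s_loc - pm) / ps^2
  ds_logs <- (matrix(dlog_s * (f$log_s - drop(f$s_loc)), B, 1L) +
                klw * sc * (exp(2 * f$s_logs) / ps^2 - 1)) * f$s_logs_mask

  gr$enc_Wz <- crossprod(f$H[[length(f$H)]], dz_loc)
  gr$enc_bz <- colSums(dz_loc)
  gr$enc_Wzs <- crossprod(f$H[[length(f$H)]], dz_logs)
  gr$enc_bzs <- colSums(dz_logs)
  gr$enc_Wl <- crossprod(f$H[[length(f$H)]], ds_loc)
  gr$enc_bl <- sum(ds_loc)
  gr$enc_Wls <- crossprod(f$H[[length(f$H)]], ds_logs)
  gr$enc_bls <- sum(ds_logs)

  dH <- dz_loc %*% t(par$enc_Wz) + dz_logs %*% t(par$enc_Wzs) +
    ds_loc %*% t(par$enc_Wl) + ds_logs %*% t(par$enc_Wls)
  for (l in rev(seq_along(f$H))) {
    dpre <- dH * (f$H[[l]] > 0)
    below <- if (l == 1L) f$Xin else f$H[[l - 1L]]
    gr[[paste0("enc_W", l)]] <- crossprod(below, dpre)
    gr[[paste0("enc_b", l)]] <- colSums(dpre)
    if (l > 1L) dH <- dpre %*% t(par[[paste0("enc_W", l)]])
  }
  gr
}

# One objective + gradient evaluation on a batch (training mode). Returns the
# scalar loss, the summed ELBO pieces, gradients, and updated batch-norm
# buffers (momentum 0.1, unbiased running variance).
#' @noRd
.loss_and_grads <- function(par, buf, cfg, s_prior, X, klw = 1,
                            seed = NULL, draws = NULL) {
  B <- nrow(X)
  f <- .forward_batch(par, buf, cfg, s_prior, X, seed = seed, draws = draws,
                      training = TRUE)
  loss <- -(f$reconstruction - klw * f$kl) / B
  gr <- .backward_batch(par, cfg, s_prior, X, f, klw)
  new_buf <- buf
  if (cfg$batch_norm) {
    mom <- 0.1
    vb_unbiased <- if (B > 1L) f$bn$v_b * B / (B - 1L) else f$bn$v_b
    new_buf$r_mean <- (1 - mom) * buf$r_mean + mom * f$bn$mu_b
    new_buf$r_var <- (1 - mom) * buf$r_var + mom * vb_unbiased
  }
  list(loss = loss, reconstruction = f$reconstruction, kl = f$kl,
       elbo = f$reconstruction - f$kl, grads = gr, buf = new_buf)
}

#' @noRd
.adam_init <- function(par) {
  zero <- lapply(par, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

#' @noRd
.adam_step <- function(par, grads, opt, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] - lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(par = par, opt = opt)
}
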