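# Fixture factory: scenarios with known loadings, dispersions and depths,
# sparsity calibration to match real-data non-zero regimes, a nonlinear
# ground truth for decoder comparisons, and recovery metrics.

#' Describe a simulation scenario
#'
#' A scenario fixes everything the generative process needs: dimensions, the
#' latent family, the loading structure, the per-gene dispersion range, and
#' the lognormal count-depth distribution. Defaults give a small but
#' realistic single-cell-like fixture: gene programs of strong loadings
#' (+/- 2) on disjoint gene blocks over a weak background (sd 0.1),
#' dispersions log-uniform in 1..20, and a median depth of 1000 molecules
#' per cell with 0.4 log-sd.
#'
#' @param n_cells,n_genes,n_factors dimensions (G >= 2 * D for block designs).
#' @param latent_family \code{"normal"} or \code{"ln"}.
#' @param program_structure \code{"block"} (disjoint strong gene programs per
#'   factor) or \code{"none"} (dense random loadings).
#' @param program_size genes per program; default \code{floor(G / (2 * D))}
#'   so half the genes stay background.
#' @param loading_sparsity for \code{"none"} structure: fraction of loadings
#'   shrunk to near zero (sd 0.01).
#' @param theta_range range of per-gene inverse dispersions, drawn
#'   log-uniformly.
#' @param depth_log_mean,depth_log_sd lognormal exposure (count depth) prior.
#' @param target_nonzero_fraction optional sparsity target in (0, 1\];
#'   \code{\link{calibrate_sparsity}} adjusts the depth to reach it.
#' @param seed integer seed.
#' @return A list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(n_cells = 1000L, n_genes = 60L, n_factors = 3L,
                         latent_family = c("normal", "ln"),
                         program_structure = c("block", "none"),
                         program_size = NULL, loading_sparsity = 0,
                         theta_range = c(1, 20), depth_log_mean = log(1000),
                         depth_log_sd = 0.4, target_nonzero_fraction = NULL,
                         seed = 1L) {
  latent_family <- match.arg(latent_family)
  program_structure <- match.arg(program_structure)
  n_cells <- .check_scalar_count(n_cells, "n_cells")
  n_genes <- .check_scalar_count(n_genes, "n_genes")
  n_factors <- .check_scalar_count(n_factors, "n_factors")
  if (program_structure == "block") {
    if (is.null(program_size)) program_size <- max(1L, floor(n_genes / (2L * n_factors)))
    program_size <- .check_scalar_count(program_size, "program_size")
    if (n_genes < 2L * n_factors || program_size * n_factors > n_genes) {
      .stopf("block design infeasible: %d factors x %d genes/program > %d genes",
             n_factors, program_size, n_genes)
    }
  }
  if (!is.null(target_nonzero_fraction) &&
      (target_nonzero_fraction <= 0 || target_nonzero_fraction > 1)) {
    .stopf("target_nonzero_fraction must be in (0, 1]")
  }
  if (loading_sparsity < 0 || loading_sparsity > 1) .stopf("loading_sparsity must be in [0, 1]")
  structure(list(n_cells = n_cells, n_genes = n_genes, n_factors = n_factors,
                 latent_family = latent_family,
                 program_structure = program_structure,
                 program_size = program_size,
                 loading_sparsity = loading_sparsity,
                 theta_range = theta_range, depth_log_mean = depth_log_mean,
                 depth_log_sd = depth_log_sd,
                 target_nonzero_fraction = target_nonzero_fraction,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Instantiate generative parameters for a scenario
#'
#' Draws the loading matrix with the requested block/sparsity structure and
#' per-gene dispersions log-uniform in \code{theta_range}; deterministic
#' under the scenario seed. Block designs assign each factor a disjoint set
#' of program genes with strong weights of random sign (+/- 2) over a weak
#' background (sd 0.1); the gene-to-program map is returned as metadata.
#'
#' @param spec a \code{\link{sim_scenario}}.
#' @return A list with \code{params} (a \code{\link{generative_params}}),
#'   \code{programs} (list of gene index vectors per factor, or NULL) and
#'   \code{background} (gene indices outside every program).
#' @export
make_scenario <- function(spec) {
  stopifnot(inherits(spec, "sim_scenario"))
  G <- spec$n_genes
  D <- spec$n_factors
  .with_seed(spec$seed, {
    if (spec$program_structure == "block") {
      W <- matrix(stats::rnorm(G * D, sd = 0.1), G, D)
      programs <- vector("list", D)
      for (d in seq_len(D)) {
        idx <- ((d - 1L) * spec$program_size + 1L):(d * spec$program_size)
        W[idx, d] <- 2 * sample(c(-1, 1), length(idx), replace = TRUE)
        programs[[d]] <- idx
      }
      background <- setdiff(seq_len(G), unlist(programs))
    } else {
      W <- matrix(stats::rnorm(G * D), G, D)
      if (spec$loading_sparsity > 0) {
        off <- matrix(stats::runif(G * D) < spec$loading_sparsity, G, D)
        W[off] <- stats::rnorm(sum(off), sd = 0.01)
      }
      programs <- NULL
      background <- integer(0)
    }
    theta <- exp(stats::runif(G, log(spec$theta_range[1]), log(spec$theta_range[2])))
    list(
      params = generative_params(W, theta, s_mu = spec$depth_log_mean,
                                 s_sigma = spec$depth_log_sd),
      programs = programs, background = background
    )
  })
}

#' Calibrate simulated sparsity via the exposure depth
#'
#' Adjusts the log-depth prior mean by bisection until a seeded 1000-cell
#' pilot sample's non-zero fraction is within +/- 0.02 of
#' \code{spec$target_nonzero_fraction}. Sparsity is dialed through depth
#' (shallower sequencing means more zeros), not through zero-inflation,
#' matching the generative model's assumptions.
#'
#' @param params a \code{\link{generative_params}}.
#' @param spec a \code{\link{sim_scenario}} with
#'   \code{target_nonzero_fraction} set.
#' @return \code{params} with adjusted \code{s_mu}; the achieved pilot
#'   fraction is stored in the \code{"achieved_nonzero"} attribute.
#' @export
calibrate_sparsity <- function(params, spec) {
  target <- spec$target_nonzero_fraction
  if (is.null(target)) .stopf("spec$target_nonzero_fraction is not set")
  pilot_n <- 1000L
  pilot_seed <- spec$seed + 7L
  frac_at <- function(s_mu) {
    p <- params
    p$s_mu <- s_mu
    sim <- sample_generative(p, pilot_n, latent_family = spec$latent_family,
                             seed = pilot_seed)
    length(sim$counts$counts@x) / prod(dim(sim$counts))
  }
  lo <- log(0.5)
  hi <- log(1e8)
  f_lo <- frac_at(lo)
  f_hi <- frac_at(hi)
  if (target > f_hi + 0.02 || target < f_lo - 0.02) {
    .stopf("sparsity target %.3f unreachable within depth bounds (achievable %.3f..%.3f)",
           target, f_lo, f_hi)
  }
  mid <- (lo + hi) / 2
  f_mid <- frac_at(mid)
  for (i in seq_len(50L)) {
    if (abs(f_mid - target) <= 0.02) break
    if (f_mid < target) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    f_mid <- frac_at(mid)
  }
  if (abs(f_mid - target) > 0.02) {
    .stopf("sparsity calibration did not converge: achieved %.3f for target %.3f",
           f_mid, target)
  }
  params$s_mu <- mid
  attr(params, "achieved_nonzero") <- f_mid
  params
}

#' Simulate a full scenario
#'
#' Instantiates the scenario parameters, optionally calibrates sparsity, and
#' forward-samples the generative model. All randomness derives from the
#' scenario seed.
#'
#' @param spec a \code{\link{sim_scenario}}.
#' @return A list with \code{counts} (\code{\link{count_matrix}}),
#'   \code{latent} (true z, s, v, mu), \code{params}, \code{programs},
#'   \code{background} and \code{scenario}.
#' @examples
#' sim <- simulate_scenario(sim_scenario(n_cells = 50, n_genes = 20, n_factors = 2))
#' print(sim$counts)
#' @export
simulate_scenario <- function(spec) {
  sc <- make_scenario(spec)
  params <- sc$params
  if (!is.null(spec$target_nonzero_fraction)) {
    params <- calibrate_sparsity(params, spec)
  }
  sim <- sample_generative(params, spec$n_cells,
                           latent_family = spec$latent_family,
                           seed = spec$seed + 2L)
  list(counts = sim$counts, latent = sim$latent, params = params,
       programs = sc$programs, background = sc$background, scenario = spec)
}

#' Simulate counts from a nonlinear ground truth
#'
#' Counts are generated as in the main model but with the mean proportions
#' produced by a random one-hidden-layer tanh network instead of a linear
#' map: \code{mu = softmax(tanh(z V1) V2)}. Used to probe the accuracy cost
#' of restricting the decoder to be linear -- a nonlinear-decoder VAE should
#' reconstruct such data better than any linear decoder can.
#'
#' The defaults (8 hidden units, input-weight scale 5) make the truth
#' genuinely nonlinear: saturated tanh units act like soft expression-state
#' switches, and the best affine map from z to the true (gene-centered)
#' logits leaves about a quarter of their variance unexplained.
#'
#' @param n_cells,n_genes,n_factors dimensions.
#' @param hidden hidden units of the ground-truth network.
#' @param weight_scale scale of the input weights; larger saturates the tanh
#'   units and makes the map less linearly approximable.
#' @param theta inverse dispersion shared across genes.
#' @param depth_log_mean,depth_log_sd exposure distribution.
#' @param seed integer seed.
#' @return list with \code{counts}, \code{latent} (z, s, mu) and the network
#'   weights in \code{params}.
#' @export
simulate_nonlinear_truth <- function(n_cells = 1000L, n_genes = 50L,
                                     n_factors = 3L, hidden = 8L,
                                     weight_scale = 5, theta = 5,
                                     depth_log_mean = log(1000),
                                     depth_log_sd = 0.4, seed = 1L) {
  n <- .check_scalar_count(n_cells, "n_cells")
  G <- .check_scalar_count(n_genes, "n_genes")
  D <- .check_scalar_count(n_factors, "n_factors")
  h <- .check_scalar_count(hidden, "hidden")
  .with_seed(seed, {
    V1 <- matrix(stats::rnorm(D * h, sd = weight_scale / sqrt(D)), D, h)
    V2 <- matrix(stats::rnorm(h * G, sd = 1.5 / sqrt(h)), h, G)
    z <- matrix(stats::rnorm(n * D), n, D)
    mu <- .softmax_rows(tanh(z %*% V1) %*% V2)
    s <- exp(stats::rnorm(n, depth_log_mean, depth_log_sd))
    th <- rep(theta, G)
    v <- matrix(stats::rgamma(n * G, shape = rep(th, each = n),
                              rate = rep(th, each = n) / mu), n, G)
    y <- matrix(stats::rpois(n * G, v * s), n, G)
    list(counts = count_matrix(y), latent = list(z = z, s = s, mu = mu),
         params = list(V1 = V1, V2 = V2, theta = th))
  })
}

# Rank-sum AUC: probability that a random program gene outranks a random
# background gene.
#' @noRd
.rank_auc <- function(w_prog, w_bg) {
  np <- length(w_prog)
  nb <- length(w_bg)
  r <- rank(c(w_prog, w_bg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Recovery metrics against ground truth
#'
#' Compares estimated loadings and latent coordinates with the simulation
#' truth. Loading subspaces are compared modulo the model's invariances: the
#' softmax decoder is unchanged by adding a per-factor constant to all gene
#' logits, so columns are gene-centered before computing principal angles,
#' and the normal-latent model is rotation-invariant, so the comparison is
#' between column spaces rather than individual columns.
#'
#' @param true_W,est_W G x D loading matrices.
#' @param true_Z,est_Z optional N x D latent coordinates; when given, the
#'   mean canonical correlation between them is reported.
#' @param programs optional list of program gene index vectors; when given,
#'   each program's rank-sum AUC (program genes vs background genes by
#'   absolute centered weight, maximized over estimated factors) is reported.
#' @param background background gene indices (defaults to all genes outside
#'   every program).
#' @return list with \code{principal_angles_deg} (decreasing),
#'   \code{max_principal_angle_deg}, optionally
#'   \code{mean_canonical_correlation} and \code{program_auc}.
#' @export
recovery_metrics <- function(true_W, est_W, true_Z = NULL, est_Z = NULL,
                             programs = NULL, background = NULL) {
  true_W <- as.matrix(true_W)
  est_W <- as.matrix(est_W)
  if (!all(dim(true_W) == dim(est_W))) .stopf("loading matrices must share dimensions")
  ctr <- function(W) sweep(W, 2L, colMeans(W))
  basis <- function(W) {
    s <- svd(ctr(W))
    r <- sum(s$d > max(dim(W)) * .Machine$double.eps * max(s$d, 1))
    s$u[, seq_len(max(r, 1L)), drop = FALSE]
  }
  Q1 <- basis(true_W)
  Q2 <- basis(est_W)
  cosines <- svd(crossprod(Q1, Q2))$d
  k <- min(ncol(Q1), ncol(Q2))
  angles <- acos(.clamp(cosines[seq_len(k)], -1, 1)) * 180 / pi
  if (ncol(Q1) != ncol(Q2)) angles <- c(angles, rep(90, abs(ncol(Q1) - ncol(Q2))))
  out <- list(principal_angles_deg = sort(angles, decreasing = TRUE),
              max_principal_angle_deg = max(angles))
  if (!is.null(true_Z) && !is.null(est_Z)) {
    if (nrow(true_Z) != nrow(est_Z)) .stopf("latent matrices must share rows")
    cc <- stats::cancor(as.matrix(true_Z), as.matrix(est_Z))
    out$mean_canonical_correlation <- mean(cc$cor)
  }
  if (!is.null(programs)) {
    if (is.null(background)) background <- setdiff(seq_len(nrow(true_W)), unlist(programs))
    if (!length(background)) .stopf("no background genes available for program AUC")
    Wc <- abs(ctr(est_W))
    out$program_auc <- vapply(programs, function(idx) {
      max(vapply(seq_len(ncol(Wc)), function(d) {
        .rank_auc(Wc[idx, d], Wc[background, d])
      }, numeric(1)))
    }, numeric(1))
  }
  out
}
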