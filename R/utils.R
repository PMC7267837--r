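# Internal numerical helpers shared across modules.

# Batch-norm variance epsilon (fixed, matches the common deep-learning default).
.bn_eps <- 1e-5

# Floor for Poisson/NB means inside the training objective; keeps log() finite
# when softmax underflows for extreme logits.
.mean_floor <- 1e-10

#' @noRd
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Row-wise softmax with max-subtraction for overflow safety.
#' @noRd
.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

#' @noRd
.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seeded operations in the package go
# through this so library code never clobbers the user's RNG stream.
#' @noRd
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Dense numeric matrix from whatever counts container we were handed.
#' @noRd
.as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

#' @noRd
.check_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    .stopf("'%s' must be a single integer >= 1", name)
  }
  as.integer(x)
}
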