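# Internal numerical and bookkeeping helpers.

MERSENNE31 <- 2147483647 # 2^31 - 1, modulus of the seed-mixing LCG

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows through a single master seed that is
#' split deterministically into stage seeds: one per (key, index) pair, where
#' `key` names the stage (e.g. `"baseline"`, or a scenario's data-generation
#' id) and `index` counts replications. Mixing uses a Lehmer-style
#' multiplicative congruential step on a rolling hash of the key, so stage
#' streams are stable under changes elsewhere in the pipeline (adding a
#' scenario, changing N) and every derived seed stays below 2^31.
#'
#' @param master Integer master seed.
#' @param key Character stage label.
#' @param index Non-negative integer replication index (default 0).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(key),
            length(key) == 1, is.numeric(index), length(index) == 1, index >= 0)
  h <- 7
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% MERSENNE31
  }
  s <- (abs(master) %% MERSENNE31)
  s <- (s * 48271 + h + 1) %% MERSENNE31
  s <- (s * 48271 + index + 1) %% MERSENNE31
  s <- (s * 48271 + 11) %% MERSENNE31
  as.integer(s %% (MERSENNE31 - 2L) + 1L)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp over a matrix (subjects x quadrature points).
row_log_sum_exp <- function(x) {
  xs <- x
  xs[!is.finite(xs)] <- -.Machine$double.xmax
  m <- x[cbind(seq_len(nrow(x)), max.col(xs, ties.method = "first"))]
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the physicists' Gauss-Hermite rule (weight function
#' `exp(-x^2)`), computed by the Golub-Welsch eigendecomposition of the
#' symmetric tridiagonal Jacobi matrix.
#'
#' @param n Number of nodes (>= 1).
#' @return A list with numeric vectors `nodes` and `weights`;
#'   `sum(weights) == sqrt(pi)`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  key <- as.character(n)
  hit <- .gh_cache[[key]]
  if (!is.null(hit)) return(hit)
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  out <- list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
  .gh_cache[[key]] <- out
  out
}

.gh_cache <- new.env(parent = emptyenv())

# Product Gauss-Hermite grid in d dimensions. Returns nodes (K x d) and
# log-weights, with t't stored for the adaptive correction exp(|t|^2).
# `prune` optionally drops grid corners by relative raw weight; it is off by
# default because the exp(|t|^2) correction keeps nominally tiny-weight
# nodes relevant whenever the integrand's tails are heavier than the
# Gaussian envelope.
gh_grid <- function(points, d, prune = 0) {
  gh <- gauss_hermite(points)
  if (d == 1) {
    nodes <- matrix(gh$nodes, ncol = 1)
    logw <- log(gh$weights)
  } else {
    ix <- as.matrix(expand.grid(rep(list(seq_len(points)), d)))
    nodes <- matrix(gh$nodes[ix], ncol = d)
    logw <- rowSums(matrix(log(gh$weights)[ix], ncol = d))
    if (prune > 0) {
      keep <- logw - max(logw) > log(prune)
      nodes <- nodes[keep, , drop = FALSE]
      logw <- logw[keep]
    }
  }
  list(nodes = nodes, logw = logw, tsq = rowSums(nodes^2))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
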