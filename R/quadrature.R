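#' Tensor-product Gauss-Hermite grid for the latent prior
#'
#' Builds the `m^q`-node tensor product of the `m`-point Gauss-Hermite rule,
#' rescaled to the standard normal (nodes times `sqrt(2)`, weights divided
#' by `sqrt(pi)`, per dimension), so that the grid integrates polynomials of
#' degree up to `2m - 1` in each coordinate exactly against N(0, 1). Node
#' ordering is lexicographic with the first dimension varying fastest, so
#' cached integrals are bit-for-bit reproducible. A correlated prior is
#' handled downstream by transforming nodes (`z = L t`), never by changing
#' the weights.
#'
#' @param m nodes per latent dimension (>= 2). Default 100 for `q = 1`
#'   and 35 per dimension for `q = 2`, the package's standard rules.
#' @param q number of latent dimensions.
#' @param budget maximum allowed total number of nodes.
#' @return an object of class `lss_grid`: list with `m`, `q`, `nodes`
#'   (`m^q x q` matrix, standard-normal scale), `weights` (sums to 1), and
#'   `log_weights`.
#' @examples
#' g <- gh_grid(45, 2); nrow(g$nodes)  # 2025
#' @export
gh_grid <- function(m = if (q == 1) 100 else 35, q = 1, budget = 250000) {
  if (m < 2) stop("need at least m = 2 quadrature points", call. = FALSE)
  if (q < 1) stop("q must be >= 1", call. = FALSE)
  if (m^q > budget)
    stop(sprintf(paste("m^q = %d nodes exceeds the budget of %d; use fewer",
                       "points per dimension or fewer latent variables",
                       "(adaptive rules are not provided)"),
                 m^q, budget), call. = FALSE)
  gh <- pracma::gaussHermite(m)
  x <- gh$x * sqrt(2)
  w <- gh$w / sqrt(pi)
  w <- w / sum(w)                     # absorb rounding in the tails
  nodes <- as.matrix(do.call(expand.grid, rep(list(x), q)))
  dimnames(nodes) <- list(NULL, paste0("t", seq_len(q)))
  wgrid <- Reduce(function(a, b) as.vector(outer(a, b)), rep(list(w), q))
  structure(list(m = m, q = q, nodes = nodes, weights = wgrid,
                 log_weights = log(wgrid)),
            class = "lss_grid")
}

#' @export
print.lss_grid <- function(x, ...) {
  cat(sprintf("<lss_grid> %d^%d = %d Gauss-Hermite nodes (standard-normal scale)\n",
              x$m, x$q, nrow(x$nodes)))
  invisible(x)
}

#' Posterior node weights for one response pattern
#'
#' Normalized posterior weights of the latent variables over the quadrature
#' nodes, proportional to prior weight times the conditional likelihood of
#' the observed (non-missing) entries of `y_row`. Computed with log-sum-exp;
#' an all-missing row returns the prior weights.
#'
#' @param y_row numeric vector, one value per model item (NA = missing).
#' @param delta packed parameter vector.
#' @param model an `lss_model`.
#' @param grid an `lss_grid` with `q` matching the model.
#' @return numeric weight vector over nodes, nonnegative, summing to 1.
#' @export
posterior_weights <- function(y_row, delta, model, grid) {
  Y <- matrix(as.numeric(y_row), nrow = 1)
  colnames(Y) <- model$item_names
  ev <- eval_model(Y, delta, model, grid, what = "weights")
  drop(ev$W)
}

#' Posterior moments of the latent variables from node weights
#'
#' First and second posterior moments of `z` under a weight vector over the
#' grid nodes, after transforming the standard-scale nodes by the Cholesky
#' factor `L` of the latent correlation matrix.
#'
#' @param weights normalized weight vector over nodes.
#' @param grid an `lss_grid`.
#' @param L lower-triangular Cholesky factor of the latent covariance
#'   (identity by default).
#' @return list with `mean` (length `q`), `second_moment` (`q x q`), and
#'   `variance` (`second_moment - mean mean'`).
#' @export
posterior_moments <- function(weights, grid, L = diag(grid$q)) {
  stopifnot(length(weights) == nrow(grid$nodes))
  Z <- grid$nodes %*% t(L)
  mu <- drop(crossprod(Z, weights))
  M2 <- crossprod(Z, Z * weights)
  M2 <- (M2 + t(M2)) / 2
  list(mean = mu, second_moment = M2, variance = M2 - tcrossprod(mu))
}
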