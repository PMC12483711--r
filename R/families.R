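#' Standard Beta shapes from the location-scale parametrization
#'
#' The location-scale Beta used throughout this package is indexed by a mean
#' `mu` in (0,1) and a scale `sigma` in (0,1), with implied precision
#' \eqn{\phi = (1 - \sigma^2)/\sigma^2}, shapes \eqn{a = \mu\phi},
#' \eqn{b = (1-\mu)\phi}, and variance \eqn{\sigma^2 \mu (1-\mu)}.
#'
#' @param mu mean, in (0,1); vectorized.
#' @param sigma scale, in (0,1); vectorized.
#' @return a list with numeric components `a` and `b`.
#' @examples
#' beta_ls_shapes(0.5, sqrt(1/3))  # a = b = 1 (uniform)
#' @export
beta_ls_shapes <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop("beta_ls: mu must lie strictly inside (0, 1)", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0) || any(sigma >= 1))
    stop("beta_ls: sigma must lie strictly inside (0, 1)", call. = FALSE)
  phi <- (1 - sigma^2) / sigma^2
  list(a = mu * phi, b = (1 - mu) * phi)
}

#' Moments of the Skew-Normal in the (xi, omega, nu) parametrization
#'
#' The Skew-Normal family is parameterized by location `xi` (identity link),
#' scale `omega > 0` (log link) and a shape `nu` in (0,1) (logit link) with
#' slant \eqn{\delta = 2\nu - 1}; the classical slant is
#' \eqn{\alpha = \delta/\sqrt{1-\delta^2}}. With \eqn{b = \sqrt{2/\pi}}, the
#' moments are \eqn{E = \xi + \omega b \delta},
#' \eqn{V = \omega^2 (1 - b^2\delta^2)} and skewness
#' \eqn{\gamma_1 = \frac{4-\pi}{2} (b\delta)^3 (1-b^2\delta^2)^{-3/2}}, so
#' \eqn{|\gamma_1| < 0.9953}.
#'
#' @param xi location (real); vectorized.
#' @param omega scale, strictly positive.
#' @param nu shape, strictly inside (0,1).
#' @return a list with components `mean`, `variance`, `skewness`.
#' @examples
#' sn_moments(0, 1, 0.5)  # standard normal: mean 0, variance 1, skewness 0
#' @export
sn_moments <- function(xi, omega, nu) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("skew_normal: omega must be strictly positive", call. = FALSE)
  if (any(!is.finite(nu)) || any(nu <= 0) || any(nu >= 1))
    stop("skew_normal: nu must lie strictly inside (0, 1)", call. = FALSE)
  delta <- 2 * nu - 1
  b <- sqrt(2 / pi)
  m1 <- b * delta
  list(mean = xi + omega * m1,
       variance = omega^2 * (1 - m1^2),
       skewness = (4 - pi) / 2 * m1^3 / (1 - m1^2)^1.5)
}

## canonical theta names per family, in (location, scale, shape) order
family_roles <- function(name) {
  switch(name,
    bernoulli   = "mu",
    normal      = c("mu", "sigma"),
    beta_ls     = c("mu", "sigma"),
    skew_normal = c("mu", "sigma", "nu"),
    stop(sprintf("unknown family: '%s'", name), call. = FALSE))
}

#' Retrieve a measurement family
#'
#' A family bundles the conditional distribution of one observed variable:
#' its distributional parameters (location `mu`, scale `sigma`, shape `nu`),
#' their default links, the log-density, analytic derivatives of the
#' log-density with respect to each distributional parameter, moment
#' formulas, support checks, and a random generator.
#'
#' Supported families: `"bernoulli"` (mu = success probability, logit link),
#' `"normal"` (mu identity, sigma log), `"beta_ls"` (location-scale Beta; mu
#' and sigma both in (0,1), logit links; see [beta_ls_shapes()]), and
#' `"skew_normal"` (xi identity, omega log, nu logit; see [sn_moments()]).
#'
#' @param name family name.
#' @return an object of class `lss_family`.
#' @export
get_family <- function(name) {
  name <- as.character(name)[1]
  roles <- family_roles(name)
  fam <- list(name = name, D = length(roles), roles = roles)
  fam$links <- switch(name,
    bernoulli   = list(mu = make_link("logit")),
    normal      = list(mu = make_link("identity"), sigma = make_link("log")),
    beta_ls     = list(mu = make_link("logit"), sigma = make_link("logit")),
    skew_normal = list(mu = make_link("identity"), sigma = make_link("log"),
                       nu = make_link("logit")))
  fam$support <- switch(name,
    bernoulli   = function(y) y %in% c(0, 1),
    normal      = function(y) is.finite(y),
    beta_ls     = function(y) is.finite(y) & y > 0 & y < 1,
    skew_normal = function(y) is.finite(y))
  fam$discrete <- name == "bernoulli"
  class(fam) <- "lss_family"
  fam
}

#' @export
print.lss_family <- function(x, ...) {
  cat(sprintf("<lss_family> %s (D = %d): %s\n", x$name, x$D,
              paste(sprintf("%s[%s]", x$roles,
                            vapply(x$links, `[[`, "", "name")),
                    collapse = ", ")))
  invisible(x)
}

check_theta <- function(family, theta) {
  roles <- family$roles
  if (!all(roles %in% names(theta)))
    stop(sprintf("family '%s' needs parameters: %s", family$name,
                 paste(roles, collapse = ", ")), call. = FALSE)
  for (r in roles) {
    b <- family$links[[r]]$bounds
    v <- theta[[r]]
    if (any(!is.finite(v)) || any(v <= b[1]) || any(v >= b[2]))
      stop(sprintf("family '%s': parameter '%s' outside its open domain (%g, %g)",
                   family$name, r, b[1], b[2]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Family log-density
#'
#' Vectorized log-density of `y` under `family` at distributional parameters
#' `theta` (a named list, one entry per parameter role, recycled against
#' `y`). Values outside the family's support raise an error identifying the
#' offending observations.
#'
#' @param family an `lss_family` or a family name.
#' @param y observations.
#' @param theta named list of distributional parameter values.
#' @return numeric vector of log-densities.
#' @examples
#' family_logpdf("bernoulli", 1, list(mu = 0.5))  # log(0.5)
#' @export
family_logpdf <- function(family, y, theta) {
  if (is.character(family)) family <- get_family(family)
  check_theta(family, theta)
  bad <- which(!is.na(y) & !family$support(y))
  if (length(bad))
    stop(sprintf("family '%s': %d observation(s) outside the support (first at row %d, value %g)",
                 family$name, length(bad), bad[1], y[bad[1]]), call. = FALSE)
  switch(family$name,
    bernoulli = stats::dbinom(y, 1, theta$mu, log = TRUE),
    normal    = stats::dnorm(y, theta$mu, theta$sigma, log = TRUE),
    beta_ls   = {
      sh <- beta_ls_shapes(theta$mu, theta$sigma)
      stats::dbeta(y, sh$a, sh$b, log = TRUE)
    },
    skew_normal = {
      delta <- 2 * theta$nu - 1
      alpha <- delta / sqrt(1 - delta^2)
      t <- (y - theta$mu) / theta$sigma
      log(2) - log(theta$sigma) + stats::dnorm(t, log = TRUE) +
        stats::pnorm(alpha * t, log.p = TRUE)
    })
}

#' Analytic derivatives of the family log-density
#'
#' Derivative of [family_logpdf()] with respect to each distributional
#' parameter, on the parameter's natural scale (not the linked scale).
#'
#' @inheritParams family_logpdf
#' @return a numeric matrix, one column per parameter role (named).
#' @export
family_dlogpdf <- function(family, y, theta) {
  if (is.character(family)) family <- get_family(family)
  check_theta(family, theta)
  n <- max(length(y), lengths(theta))
  y <- rep_len(y, n)
  th <- lapply(theta[family$roles], rep_len, n)
  out <- switch(family$name,
    bernoulli = cbind(mu = y / th$mu - (1 - y) / (1 - th$mu)),
    normal = {
      t <- (y - th$mu) / th$sigma
      cbind(mu = t / th$sigma, sigma = (t^2 - 1) / th$sigma)
    },
    beta_ls = {
      phi <- (1 - th$sigma^2) / th$sigma^2
      a <- th$mu * phi
      b <- (1 - th$mu) * phi
      dla <- log(y) - digamma(a) + digamma(a + b)
      dlb <- log1p(-y) - digamma(b) + digamma(a + b)
      dphi <- -2 / th$sigma^3
      cbind(mu = phi * (dla - dlb),
            sigma = (th$mu * dla + (1 - th$mu) * dlb) * dphi)
    },
    skew_normal = {
      delta <- 2 * th$nu - 1
      alpha <- delta / sqrt(1 - delta^2)
      t <- (y - th$mu) / th$sigma
      at <- alpha * t
      zeta <- exp(stats::dnorm(at, log = TRUE) - stats::pnorm(at, log.p = TRUE))
      cbind(mu = t / th$sigma - alpha / th$sigma * zeta,
            sigma = (t^2 - 1) / th$sigma - at / th$sigma * zeta,
            nu = 2 * t * zeta / (1 - delta^2)^1.5)
    })
  out[is.na(y), ] <- NA_real_
  out
}

#' Family moments
#'
#' Conditional mean, variance, and (where defined) skewness implied by the
#' distributional parameters.
#'
#' @inheritParams family_logpdf
#' @return a list with `mean`, `variance`, and `skewness` (NA where the
#'   family has none beyond what the first two moments force).
#' @export
family_moments <- function(family, theta) {
  if (is.character(family)) family <- get_family(family)
  check_theta(family, theta)
  switch(family$name,
    bernoulli = list(mean = theta$mu, variance = theta$mu * (1 - theta$mu),
                     skewness = (1 - 2 * theta$mu) /
                       sqrt(theta$mu * (1 - theta$mu))),
    normal = list(mean = theta$mu, variance = theta$sigma^2, skewness = 0),
    beta_ls = {
      v <- theta$sigma^2 * theta$mu * (1 - theta$mu)
      sh <- beta_ls_shapes(theta$mu, theta$sigma)
      sk <- 2 * (sh$b - sh$a) * sqrt(sh$a + sh$b + 1) /
        ((sh$a + sh$b + 2) * sqrt(sh$a * sh$b))
      list(mean = theta$mu, variance = v, skewness = sk)
    },
    skew_normal = sn_moments(theta$mu, theta$sigma, theta$nu))
}

#' Draw from a family
#'
#' @inheritParams family_logpdf
#' @param n number of draws; `theta` entries are recycled to `n`.
#' @param seed optional integer seed applied via [set.seed()].
#' @return numeric vector of length `n`.
#' @export
family_sample <- function(family, n, theta, seed = NULL) {
  if (is.character(family)) family <- get_family(family)
  check_theta(family, theta)
  if (!is.null(seed)) set.seed(seed)
  th <- lapply(theta[family$roles], rep_len, n)
  switch(family$name,
    bernoulli = stats::rbinom(n, 1, th$mu),
    normal    = stats::rnorm(n, th$mu, th$sigma),
    beta_ls   = {
      sh <- beta_ls_shapes(th$mu, th$sigma)
      stats::rbeta(n, sh$a, sh$b)
    },
    skew_normal = {
      delta <- 2 * th$nu - 1
      u0 <- stats::rnorm(n)
      u1 <- stats::rnorm(n)
      th$mu + th$sigma * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
    })
}

#' Nudge unit-interval observations off the boundary
#'
#' Doubly-bounded responses recorded exactly at 0 or 1 have no density under
#' a Beta model; they are replaced by `eps` and `1 - eps`.
#'
#' @param y numeric vector.
#' @param eps boundary offset (default 1e-3).
#' @return list with `y` (nudged values) and `n_nudged` (count of values moved).
#' @export
nudge_unit_interval <- function(y, eps = 1e-3) {
  stopifnot(eps > 0, eps < 0.5)
  hit <- !is.na(y) & (y <= 0 | y >= 1)
  y[!is.na(y) & y <= 0] <- eps
  y[!is.na(y) & y >= 1] <- 1 - eps
  list(y = y, n_nudged = sum(hit))
}
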