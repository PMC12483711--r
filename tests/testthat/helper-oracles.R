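# central finite-difference gradient of f at x
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    hp <- h * (1 + abs(x[k]))
    xp <- x; xm <- x
    xp[k] <- xp[k] + hp
    xm[k] <- xm[k] - hp
    (f(xp) - f(xm)) / (2 * hp)
  }, 0)
}

# random distributional parameters inside each family's domain
random_theta <- function(fname) {
  switch(fname,
    bernoulli   = list(mu = runif(1, 0.05, 0.95)),
    normal      = list(mu = runif(1, -2, 2), sigma = runif(1, 0.3, 2)),
    beta_ls     = list(mu = runif(1, 0.15, 0.85), sigma = runif(1, 0.25, 0.75)),
    skew_normal = list(mu = runif(1, -2, 2), sigma = runif(1, 0.3, 2),
                       nu = runif(1, 0.1, 0.9)))
}

# a draw from the family's support for log-density tests
random_y <- function(fname, theta) {
  switch(fname,
    bernoulli   = rbinom(1, 1, 0.5),
    normal      = rnorm(1, theta$mu, 2 * theta$sigma),
    beta_ls     = runif(1, 0.03, 0.97),
    skew_normal = rnorm(1, theta$mu, 2 * theta$sigma))
}

# small mixed-family model for gradient and invariance checks:
# q = 1 (identity) or q = 2 (free correlation, confirmatory zeros)
mixed_model <- function(q = 1) {
  if (q == 1) {
    build_model(list(
      items = list(
        list(name = "b1", family = "bernoulli",
             equations = list(mu = list(intercept = "free",
                                        loadings = list("free")))),
        list(name = "n1", family = "normal"),
        list(name = "y1", family = "beta_ls"),
        list(name = "t1", family = "skew_normal")),
      latent = list(q = 1, mode = "identity")))
  } else {
    eq1 <- list(intercept = "free", loadings = list("free", 0))
    eq2 <- list(intercept = "free", loadings = list(0, "free"))
    build_model(list(
      items = list(
        list(name = "b1", family = "bernoulli", equations = list(mu = eq1)),
        list(name = "b2", family = "bernoulli", equations = list(mu = eq1)),
        list(name = "n1", family = "normal",
             equations = list(mu = eq2, sigma = eq2)),
        list(name = "t1", family = "skew_normal",
             equations = list(mu = eq2, sigma = eq2, nu = eq2)),
        list(name = "y1", family = "beta_ls",
             equations = list(mu = eq1, sigma = eq1))),
      latent = list(q = 2, mode = "correlation")))
  }
}

# a tame random parameter vector for a model (loadings moderate, scales sane)
random_delta <- function(model) {
  idx <- model$index
  d <- numeric(nrow(idx))
  for (p in seq_len(nrow(idx))) {
    if (idx$role[p] == "rho") { d[p] <- runif(1, -0.5, 0.5); next }
    fam <- model$items[[idx$item[p]]]$family$name
    role <- idx$role[p]
    d[p] <- if (idx$comp[p] == "intercept") {
      if (role == "sigma" && fam %in% c("normal", "skew_normal"))
        runif(1, -0.5, 0.5)
      else if (role == "sigma") runif(1, -1.2, -0.6)    # beta scale
      else runif(1, -0.8, 0.8)
    } else {
      runif(1, 0.2, 0.8) * sample(c(-1, 1), 1)
    }
  }
  d
}
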