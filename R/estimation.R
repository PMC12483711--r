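## ---- data validation ------------------------------------------------------

# coerce person-by-item data to a numeric matrix in model item order and
# check supports, naming the first offending row/item
validate_data <- function(data, model) {
  Y <- data.matrix(as.data.frame(data))
  p <- length(model$items)
  if (!is.null(colnames(Y)) && all(model$item_names %in% colnames(Y))) {
    Y <- Y[, model$item_names, drop = FALSE]
  } else if (ncol(Y) == p) {
    colnames(Y) <- model$item_names
  } else {
    stop(sprintf("data columns {%s} do not match model items {%s}",
                 paste(colnames(Y), collapse = ", "),
                 paste(model$item_names, collapse = ", ")), call. = FALSE)
  }
  storage.mode(Y) <- "double"
  for (i in seq_len(p)) {
    fam <- model$items[[i]]$family
    y <- Y[, i]
    bad <- which(!is.na(y) & !fam$support(y))
    if (length(bad)) {
      hint <- if (fam$name == "beta_ls")
        " (boundary values can be moved inside (0,1) with nudge_unit_interval())"
      else ""
      stop(sprintf("item '%s' (family %s): value %g at row %d outside the support%s",
                   model$item_names[i], fam$name, y[bad[1]], bad[1], hint),
           call. = FALSE)
    }
  }
  Y
}

## ---- per-item node evaluation ---------------------------------------------

ll_kernel <- function(fname, y, thetas, grad) {
  switch(fname,
    bernoulli   = .ll_bernoulli(y, thetas$mu, grad),
    normal      = .ll_normal(y, thetas$mu, thetas$sigma, grad),
    beta_ls     = .ll_beta_ls(y, thetas$mu, thetas$sigma, grad),
    skew_normal = .ll_skew_normal(y, thetas$mu, thetas$sigma, thetas$nu, grad),
    stop(sprintf("unknown family: '%s'", fname), call. = FALSE))
}

acc_kernel <- function(fname, y, thetas, map, LL) {
  switch(fname,
    bernoulli   = .acc_bernoulli(y, thetas$mu, map, LL),
    normal      = .acc_normal(y, thetas$mu, thetas$sigma, map, LL),
    beta_ls     = .acc_beta_ls(y, thetas$mu, thetas$sigma, map, LL),
    skew_normal = .acc_skew_normal(y, thetas$mu, thetas$sigma, thetas$nu,
                                   map, LL),
    stop(sprintf("unknown family: '%s'", fname), call. = FALSE))
}

# Structural thinning: on the tensor grid (first dimension fastest), an item
# whose nonzero loadings touch only factors 1..r takes m^r distinct
# parameter values, repeating with period m^r across the nodes.
item_thin <- function(vi, roles, m, N) {
  maxa <- 0L
  for (r in roles) {
    nz <- which(vi[[r]]$loadings != 0)
    if (length(nz)) maxa <- max(maxa, max(nz))
  }
  U <- as.integer(min(m^maxa, N))
  list(U = U,
       map = if (U < N) rep.int(seq_len(U), N %/% U) else seq_len(N))
}

# Thin evaluation of one item at the (transformed) nodes: distributional
# parameters, optional thin log-density/derivative matrices (n x U) and
# link-inverse derivatives, plus the node -> thin column map.
item_parts <- function(y, item, vi, Z, m, grad = FALSE, thin_ll = TRUE,
                       item_name = "?") {
  fam <- item$family
  N <- nrow(Z)
  th <- item_thin(vi, fam$roles, m, N)
  Zu <- Z[seq_len(th$U), , drop = FALSE]
  etas <- thetas <- stats::setNames(vector("list", fam$D), fam$roles)
  for (r in fam$roles) {
    lk <- fam$links[[r]]
    eta <- vi[[r]]$intercept + drop(Zu %*% vi[[r]]$loadings)
    eta <- pmin(pmax(eta, lk$eta_clamp[1]), lk$eta_clamp[2])
    etas[[r]] <- eta
    thetas[[r]] <- lk$linkinv(eta)
  }
  out <- list(U = th$U, map = th$map, thetas = thetas)
  if (grad)
    out$me <- stats::setNames(lapply(fam$roles, function(r)
      fam$links[[r]]$mu.eta(etas[[r]])), fam$roles)
  if (thin_ll || grad) {
    kr <- ll_kernel(fam$name, y, thetas, grad)
    if (!all(is.finite(kr$ll))) {
      bad <- which(!is.finite(kr$ll), arr.ind = TRUE)
      stop(sprintf("non-finite log-density for item '%s' at row %d; check the data domain and parameter values",
                   item_name, bad[1, 1]), call. = FALSE)
    }
    out$ll <- kr$ll
    out$d <- kr$d
  }
  out
}

## ---- core evaluation ------------------------------------------------------

# One pass over data x quadrature nodes. `what` selects the outputs:
#   "loglik"     - marginal log-likelihood only
#   "weights"    - + per-case posterior node weights W
#   "score"      - + total analytic score (length K)
#   "score_rows" - + per-case score matrix (n x K), for the information matrix
# For correlated factors the covariance part of the score is computed against
# `dL_list` (defaults to dL/drho; the optimizer passes dL/dgamma instead).
eval_model <- function(Y, delta, model, grid, what = "loglik",
                       dL_list = NULL) {
  q <- model$latent$q
  vals <- unpack_params(model, delta)
  corr <- model$latent$mode == "correlation"
  L <- if (corr) correlation_cholesky(vals$rho, q) else diag(q)
  Z <- grid$nodes %*% t(L)
  n <- nrow(Y); N <- nrow(Z)
  grad <- what %in% c("score", "score_rows")
  LL <- matrix(0, n, N)
  parts <- vector("list", length(model$items))
  for (i in seq_along(model$items)) {
    # Bernoulli score terms reduce to posterior-expected residuals (y - pi)
    # and never need the derivative matrices
    pt <- item_parts(Y[, i], model$items[[i]], vals$items[[i]], Z, grid$m,
                     grad = grad && model$items[[i]]$family$name != "bernoulli",
                     thin_ll = FALSE, item_name = model$item_names[i])
    ok <- acc_kernel(model$items[[i]]$family$name, Y[, i], pt$thetas,
                     pt$map, LL)
    if (!ok) {
      bad <- which(!is.finite(LL), arr.ind = TRUE)
      row <- if (nrow(bad)) bad[1, 1] else 1L
      stop(sprintf("non-finite log-density at item '%s', row %d; check the data domain and parameter values",
                   model$item_names[i], row), call. = FALSE)
    }
    if (grad) parts[[i]] <- pt
  }
  want_w <- what != "loglik"
  pw <- .post_weights(LL, grid$log_weights, want_w)
  if (!all(is.finite(pw$loglik)))
    stop(sprintf("non-finite marginal log-likelihood at row %d",
                 which(!is.finite(pw$loglik))[1]), call. = FALSE)
  out <- list(loglik = sum(pw$loglik), loglik_rows = pw$loglik,
              L = L, Z = Z, LL = LL, vals = vals)
  if (want_w) out$W <- pw$W
  if (!grad) return(out)

  idx <- model$index
  K <- nrow(idx)
  pmap <- model$pmap
  if (corr && is.null(dL_list)) dL_list <- dL_drho(vals$rho, q)
  rho_pos <- which(idx$role == "rho")

  if (what == "score") {
    sc <- numeric(K)
    SL <- if (corr) matrix(0, q, q)
    cW <- colSums(out$W)
    for (i in seq_along(model$items)) {
      fam <- model$items[[i]]$family
      pt <- parts[[i]]
      for (di in seq_along(fam$roles)) {
        r <- fam$roles[di]
        cs <- if (fam$name == "bernoulli") {
          yv <- Y[, i]; obs <- !is.na(yv)
          mu_full <- pt$thetas$mu[pt$map]
          Wty <- drop(crossprod(out$W, ifelse(obs, yv, 0)))
          Wto <- if (all(obs)) cW else
            drop(crossprod(out$W, as.numeric(obs)))
          Wty - mu_full * Wto                 # already on the eta scale
        } else {
          .wcolsums(out$W, pt$d[[di]], pt$map) * pt$me[[r]][pt$map]
        }
        pm <- pmap[[i]][[r]]
        if (!is.na(pm$int)) sc[pm$int] <- sum(cs)
        for (j in which(!is.na(pm$load))) sc[pm$load[j]] <- sum(cs * Z[, j])
        if (corr) {
          lam <- vals$items[[i]][[r]]$loadings
          SL <- SL + tcrossprod(lam, drop(crossprod(grid$nodes, cs)))
        }
      }
    }
    for (g in seq_along(rho_pos))
      sc[rho_pos[g]] <- sum(SL * dL_list[[g]])
    out$score <- sc
    return(out)
  }

  # what == "score_rows"
  SR <- matrix(0, n, K)
  SLrows <- if (corr) matrix(0, n, q * q)
  for (i in seq_along(model$items)) {
    fam <- model$items[[i]]$family
    pt <- parts[[i]]
    for (di in seq_along(fam$roles)) {
      r <- fam$roles[di]
      pm <- pmap[[i]][[r]]
      js <- which(!is.na(pm$load))
      B0 <- cbind(if (!is.na(pm$int)) rep(1, N),
                  if (length(js)) Z[, js, drop = FALSE],
                  if (corr) grid$nodes)
      if (fam$name == "bernoulli") {
        yv <- Y[, i]; obs <- !is.na(yv)
        mu_full <- pt$thetas$mu[pt$map]
        M <- ifelse(obs, yv, 0) * (out$W %*% B0) -
          out$W %*% (mu_full * B0)
        if (!all(obs)) M[!obs, ] <- 0
      } else {
        M <- .wmatprod(out$W, pt$d[[di]], pt$map,
                       pt$me[[r]][pt$map] * B0)
      }
      cidx <- 1L
      if (!is.na(pm$int)) { SR[, pm$int] <- M[, cidx]; cidx <- cidx + 1L }
      for (j in js) { SR[, pm$load[j]] <- M[, cidx]; cidx <- cidx + 1L }
      if (corr) {
        lam <- vals$items[[i]][[r]]$loadings
        Mn <- M[, cidx:(cidx + q - 1L), drop = FALSE]
        for (a in which(lam != 0))
          for (b in seq_len(q))
            SLrows[, (b - 1L) * q + a] <- SLrows[, (b - 1L) * q + a] +
              lam[a] * Mn[, b]
      }
    }
  }
  if (corr)
    for (g in seq_along(rho_pos))
      SR[, rho_pos[g]] <- SLrows %*% as.vector(dL_list[[g]])
  out$score_rows <- SR
  out$score <- colSums(SR)
  out
}

## ---- exported likelihood / score ------------------------------------------

#' Marginal log-likelihood
#'
#' Sum over rows of the log of the latent-variable integral of the
#' conditional (local-independence) likelihood, evaluated on a Gauss-Hermite
#' grid with log-sum-exp. Missing entries are skipped within each row's
#' conditional product (available-case, MAR).
#'
#' @param data person-by-item data (data frame or matrix), columns matching
#'   the model's items (by name if named).
#' @param delta packed free-parameter vector (length `K`).
#' @param model an `lss_model`.
#' @param grid an `lss_grid`; defaults to the package's standard rule for
#'   the model's `q`.
#' @return the marginal log-likelihood (scalar); per-row contributions in
#'   attribute `"rows"`.
#' @export
marginal_loglik <- function(data, delta, model,
                            grid = gh_grid(q = model$latent$q)) {
  Y <- validate_data(data, model)
  ev <- eval_model(Y, delta, model, grid, what = "loglik")
  structure(ev$loglik, rows = ev$loglik_rows)
}

#' Analytic score of the marginal log-likelihood
#'
#' Exact gradient of [marginal_loglik()] under the fixed quadrature grid:
#' posterior-weighted family derivatives chained through the links for
#' intercepts and loadings, and through the Cholesky factor of the latent
#' correlation matrix for its free entries.
#'
#' @inheritParams marginal_loglik
#' @return numeric vector of length `K`, named by parameter labels.
#' @export
marginal_score <- function(data, delta, model,
                           grid = gh_grid(q = model$latent$q)) {
  Y <- validate_data(data, model)
  sc <- eval_model(Y, delta, model, grid, what = "score")$score
  names(sc) <- model$index$label
  sc
}

#' Akaike and Bayesian information criteria
#'
#' @param loglik maximized marginal log-likelihood.
#' @param K number of free parameters.
#' @param n number of observations (rows).
#' @return list with `AIC = -2 loglik + 2K` and `BIC = -2 loglik + K log n`.
#' @export
aic_bic <- function(loglik, K, n) {
  stopifnot(n >= 1, K >= 1)
  list(AIC = -2 * loglik + 2 * K, BIC = -2 * loglik + K * log(n))
}

## ---- starting values ------------------------------------------------------

# link-scale starting intercepts from item-wise sample statistics
start_intercepts <- function(y, fam) {
  y <- y[!is.na(y)]
  m <- mean(y); v <- stats::var(y)
  switch(fam$name,
    bernoulli = list(mu = stats::qlogis(min(max(m, 0.02), 0.98))),
    normal = list(mu = m, sigma = log(max(sqrt(v), 1e-3))),
    beta_ls = {
      m <- min(max(m, 0.02), 0.98)
      s <- sqrt(min(max(v / (m * (1 - m)), 1e-4), 0.98))
      list(mu = stats::qlogis(m), sigma = stats::qlogis(s))
    },
    skew_normal = {
      # method-of-moments slant from the sample skewness; starting at the
      # symmetric point delta = 0 would sit on a stationary saddle of the
      # likelihood where every gradient vanishes
      g1 <- mean((y - m)^3) / max(v, 1e-12)^1.5
      g1 <- sign(g1) * min(abs(g1), 0.9)
      u <- (2 * abs(g1) / (4 - pi))^(2 / 3)
      k <- sign(g1) * sqrt(u / (1 + u))          # b * delta
      delta <- max(min(k * sqrt(pi / 2), 0.98), -0.98)
      om <- sqrt(v / max(1 - k^2, 0.1))
      list(mu = m - om * k, sigma = log(max(om, 1e-3)),
           nu = stats::qlogis((delta + 1) / 2))
    })
}

#' Warm-start parameter values from principal components
#'
#' Computes the first `q` principal-component scores of the (centered,
#' scaled, mean-imputed) data matrix and runs, for every item, a
#' complete-data distributional regression of the item on those scores in
#' the item's own family, respecting the model's free/fixed pattern. The
#' resulting coefficients initialize the intercepts and loadings; free
#' latent correlations start at 0. Deterministic given the data.
#'
#' @inheritParams marginal_loglik
#' @return packed start vector `delta0` of length `K`.
#' @export
warm_start <- function(data, model) {
  Y <- validate_data(data, model)
  q <- model$latent$q
  Yc <- Y
  const <- logical(ncol(Y))
  for (i in seq_len(ncol(Y))) {
    mu_i <- mean(Y[, i], na.rm = TRUE)
    Yc[is.na(Y[, i]), i] <- mu_i
    const[i] <- stats::sd(Yc[, i]) < 1e-10
  }
  if (sum(!const) < q + 1)
    stop("warm start needs at least q + 1 items with non-degenerate variance",
         call. = FALSE)
  pc <- stats::prcomp(Yc[, !const, drop = FALSE], center = TRUE, scale. = TRUE)
  Fs <- pc$x[, seq_len(q), drop = FALSE]
  Fs <- scale(Fs)                      # unit-variance factor score proxies

  vals <- values_template(model)
  for (i in seq_along(model$items)) {
    it <- model$items[[i]]
    fam <- it$family
    y <- Y[, i]
    ok <- !is.na(y)
    if (const[i]) {
      warning(sprintf("item '%s' is constant; its loadings start at 0",
                      model$item_names[i]), call. = FALSE)
      st <- start_intercepts(c(y[ok], if (fam$name == "bernoulli") c(0, 1)),
                             fam)
      for (r in fam$roles) {
        if (it$eq[[r]]$int_free) vals$items[[i]][[r]]$intercept <- st[[r]]
        vals$items[[i]][[r]]$loadings[it$eq[[r]]$load_free] <- 0
      }
      next
    }
    st <- start_intercepts(y, fam)
    # block coordinates: per role, free intercept then free loadings
    b0 <- c(); slots <- list()
    for (r in fam$roles) {
      e <- it$eq[[r]]
      if (e$int_free) {
        b0 <- c(b0, st[[r]])
        slots[[length(slots) + 1]] <- c(i = NA, r = r, what = "int")
      }
      for (j in which(e$load_free)) {
        b0 <- c(b0, 0)
        slots[[length(slots) + 1]] <- c(i = j, r = r, what = "load")
      }
    }
    if (!length(b0)) next
    set_b <- function(vi, b) {
      for (s in seq_along(slots)) {
        sl <- slots[[s]]
        if (sl[["what"]] == "int") vi[[sl[["r"]]]]$intercept <- b[s]
        else vi[[sl[["r"]]]]$loadings[as.integer(sl[["i"]])] <- b[s]
      }
      vi
    }
    item_etas <- function(vi) {
      etas <- lapply(fam$roles, function(r) {
        lk <- fam$links[[r]]
        eta <- vi[[r]]$intercept +
          drop(Fs[ok, , drop = FALSE] %*% vi[[r]]$loadings)
        pmin(pmax(eta, lk$eta_clamp[1]), lk$eta_clamp[2])
      })
      names(etas) <- fam$roles
      etas
    }
    negll <- function(b) {
      vi <- set_b(vals$items[[i]], b)
      etas <- item_etas(vi)
      th <- lapply(fam$roles, function(r) fam$links[[r]]$linkinv(etas[[r]]))
      names(th) <- fam$roles
      -sum(family_logpdf(fam, y[ok], th))
    }
    neggr <- function(b) {
      vi <- set_b(vals$items[[i]], b)
      etas <- item_etas(vi)
      th <- lapply(fam$roles, function(r) fam$links[[r]]$linkinv(etas[[r]]))
      names(th) <- fam$roles
      D <- family_dlogpdf(fam, y[ok], th)
      g <- numeric(length(b))
      for (s in seq_along(slots)) {
        sl <- slots[[s]]
        r <- sl[["r"]]
        gr_eta <- D[, r] * fam$links[[r]]$mu.eta(etas[[r]])
        g[s] <- if (sl[["what"]] == "int") sum(gr_eta) else
          sum(gr_eta * Fs[ok, as.integer(sl[["i"]])])
      }
      -g
    }
    op <- stats::optim(b0, negll, neggr, method = "BFGS",
                       control = list(maxit = 100, reltol = 1e-10))
    vals$items[[i]] <- set_b(vals$items[[i]], op$par)
  }
  if (length(vals$rho)) vals$rho[] <- 0
  pack_params(model, vals)
}

## ---- EM warm-up -----------------------------------------------------------

# marginal log-likelihood after swapping one item's node log-density block
swap_item_ll <- function(LL, old_pt, new_pt, logw) {
  LLn <- LL - old_pt$ll[, old_pt$map, drop = FALSE] +
    new_pt$ll[, new_pt$map, drop = FALSE]
  list(loglik = sum(.post_weights(LLn, logw, FALSE)$loglik), LL = LLn)
}

# write a flat block vector back into one item's values (free entries only,
# in packing order), and read it back out
set_item_block <- function(vi, item, b) {
  s <- 1L
  for (r in item$family$roles) {
    e <- item$eq[[r]]
    if (e$int_free) { vi[[r]]$intercept <- b[s]; s <- s + 1L }
    for (j in which(e$load_free)) { vi[[r]]$loadings[j] <- b[s]; s <- s + 1L }
  }
  vi
}

get_item_block <- function(vi, item) {
  b <- c()
  for (r in item$family$roles) {
    e <- item$eq[[r]]
    if (e$int_free) b <- c(b, vi[[r]]$intercept)
    b <- c(b, vi[[r]]$loadings[e$load_free])
  }
  b
}

# gradient of the expected complete-data log-likelihood for item i's free
# block, holding the posterior weights W fixed; returns the thin parts too
item_block_grad <- function(b, i, model, vals, Y, Z, W, grid) {
  pm <- model$pmap[[i]]
  item <- model$items[[i]]
  fam <- item$family
  vi <- set_item_block(vals$items[[i]], item, b)
  bern <- fam$name == "bernoulli"
  pt <- item_parts(Y[, i], item, vi, Z, grid$m, grad = !bern,
                   thin_ll = FALSE, item_name = model$item_names[i])
  g <- numeric(length(b)); s <- 1L
  for (di in seq_along(fam$roles)) {
    r <- fam$roles[di]
    cs <- if (bern) {
      yv <- Y[, i]; obs <- !is.na(yv)
      mu_full <- pt$thetas$mu[pt$map]
      drop(crossprod(W, ifelse(obs, yv, 0))) -
        mu_full * drop(crossprod(W, as.numeric(obs)))
    } else {
      .wcolsums(W, pt$d[[di]], pt$map) * pt$me[[r]][pt$map]
    }
    if (!is.na(pm[[r]]$int)) { g[s] <- sum(cs); s <- s + 1L }
    for (j in which(!is.na(pm[[r]]$load))) {
      g[s] <- sum(cs * Z[, j]); s <- s + 1L
    }
  }
  list(grad = g)
}

# one EM iteration: E-step posterior weights, then per-block damped updates
# (Newton or adaptive gradient) accepted only if the marginal log-likelihood
# does not decrease by more than `mono_tol`
em_iteration <- function(state, method = "newton", mono_tol = 1e-8) {
  model <- state$model; grid <- state$grid; Y <- state$Y
  q <- model$latent$q
  ev <- eval_model(Y, state$delta, model, grid, what = "weights")
  W <- ev$W; Z <- ev$Z
  vals <- ev$vals
  LL <- ev$LL
  mll <- ev$loglik
  pts <- lapply(seq_along(model$items), function(i)
    item_parts(Y[, i], model$items[[i]], vals$items[[i]], Z, grid$m,
               item_name = model$item_names[i]))

  for (i in seq_along(model$items)) {
    b <- get_item_block(vals$items[[i]], model$items[[i]])
    if (!length(b)) next
    bg <- item_block_grad(b, i, model, vals, Y, Z, W, grid)
    g <- bg$grad
    if (method == "newton") {
      H <- matrix(0, length(b), length(b))
      h <- 1e-5 * (1 + abs(b))
      for (s in seq_along(b)) {
        bp <- b; bp[s] <- bp[s] + h[s]
        H[, s] <- (item_block_grad(bp, i, model, vals, Y, Z, W,
                                   grid)$grad - g) / h[s]
      }
      H <- (H + t(H)) / 2
      step <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)) || sum(step * g) <= 0)
        step <- g / max(sqrt(sum(g^2)), 1)       # fallback: normalized ascent
    } else {
      step <- state$lr[i] * g
    }
    lam <- 1
    accepted <- FALSE
    for (try in 1:20) {
      bn <- b + lam * step
      pt_new <- tryCatch(
        item_parts(Y[, i], model$items[[i]],
                   set_item_block(vals$items[[i]], model$items[[i]], bn),
                   Z, grid$m, item_name = model$item_names[i]),
        error = function(e) NULL)
      if (!is.null(pt_new)) {
        sw <- swap_item_ll(LL, pts[[i]], pt_new, grid$log_weights)
        if (is.finite(sw$loglik) && sw$loglik >= mll - mono_tol) {
          vals$items[[i]] <- set_item_block(vals$items[[i]],
                                            model$items[[i]], bn)
          LL <- sw$LL
          pts[[i]] <- pt_new
          mll <- sw$loglik
          accepted <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (method == "gradient")
      state$lr[i] <- if (accepted && lam == 1) min(state$lr[i] * 1.5, 10) else
        max(state$lr[i] * lam, 1e-6)
  }

  if (model$latent$mode == "correlation") {
    # covariance block in the unconstrained (tanh-spherical) coordinates
    rho <- vals$rho
    gam <- gamma_from_rho(rho, q)
    gam_grad <- function(gm) {
      cg <- chol_from_gamma(gm, q, jacobian = TRUE)
      Zg <- grid$nodes %*% t(cg$L)
      SL <- matrix(0, q, q)
      for (i in seq_along(model$items)) {
        fam <- model$items[[i]]$family
        bern <- fam$name == "bernoulli"
        pt <- item_parts(Y[, i], model$items[[i]], vals$items[[i]], Zg,
                         grid$m, grad = !bern, thin_ll = FALSE,
                         item_name = model$item_names[i])
        for (di in seq_along(fam$roles)) {
          r <- fam$roles[di]
          cs <- if (bern) {
            yv <- Y[, i]; obs <- !is.na(yv)
            mu_full <- pt$thetas$mu[pt$map]
            drop(crossprod(W, ifelse(obs, yv, 0))) -
              mu_full * drop(crossprod(W, as.numeric(obs)))
          } else {
            .wcolsums(W, pt$d[[di]], pt$map) * pt$me[[r]][pt$map]
          }
          lam_i <- vals$items[[i]][[r]]$loadings
          SL <- SL + tcrossprod(lam_i, drop(crossprod(grid$nodes, cs)))
        }
      }
      vapply(cg$dL, function(D) sum(SL * D), 0)
    }
    g <- gam_grad(gam)
    H <- matrix(0, length(gam), length(gam))
    h <- 1e-5 * (1 + abs(gam))
    for (s in seq_along(gam)) {
      gp <- gam; gp[s] <- gp[s] + h[s]
      H[, s] <- (gam_grad(gp) - g) / h[s]
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || sum(step * g) <= 0)
      step <- g / max(sqrt(sum(g^2)), 1)
    lam <- 1
    for (try in 1:20) {
      gn <- gam + lam * step
      rho_new <- rho_from_gamma(gn, q)
      vals_try <- vals; vals_try$rho <- rho_new
      delta_try <- pack_params(model, vals_try)
      mll_new <- tryCatch(
        eval_model(Y, delta_try, model, grid, what = "loglik")$loglik,
        error = function(e) NA_real_)
      if (is.finite(mll_new) && mll_new >= mll - mono_tol) {
        vals <- vals_try
        mll <- mll_new
        break
      }
      lam <- lam / 2
    }
  }

  state$delta <- pack_params(model, vals)
  state$loglik <- mll
  state
}

## ---- fitting --------------------------------------------------------------

#' Fit a latent location-scale-shape model by marginal maximum likelihood
#'
#' Full-information marginal ML on a fixed Gauss-Hermite grid: an EM warm-up
#' (expected complete-data updates per item block, damped Newton by default
#' or an adaptive gradient rule) followed by direct BFGS maximization of the
#' marginal log-likelihood with the analytic score. Free latent correlations
#' are optimized through an unconstrained tanh-spherical Cholesky
#' parametrization, so every iterate corresponds to a valid correlation
#' matrix. Standard errors come from the empirical cross-product of
#' case-wise scores (Fisher identity), which doubles as the empirical
#' local-identification diagnostic.
#'
#' @inheritParams marginal_loglik
#' @param start `"warm"` (PCA-based distributional regressions, the
#'   default), `"spec"` (the start values stored in the model), or a numeric
#'   vector of length `K`.
#' @param em_iters maximum EM warm-up iterations (default 50).
#' @param em_method `"newton"` (damped Newton per block) or `"gradient"`
#'   (adaptive-learning-rate gradient ascent per block).
#' @param em_rel_tol relative log-likelihood change at which the EM warm-up
#'   stops early.
#' @param maxit BFGS iteration cap.
#' @param reltol BFGS relative-improvement stopping tolerance.
#' @param precondition scale the BFGS search by inverse root curvatures
#'   (diagonal of the empirical information at the warm-up solution)?
#' @param grad_tol convergence threshold for the sup-norm of the
#'   per-observation score; default `1e-4 * sqrt(K)`.
#' @param se compute the information matrix and standard errors?
#' @param n_starts number of optimizer starts; starts beyond the first
#'   jitter the start vector with N(0, `jitter_sd`^2) noise (seeded).
#' @param jitter_sd jitter standard deviation for multi-starts.
#' @param seed seed for the multi-start jitter only.
#' @param verbose print progress?
#' @return an object of class `lss_fit`; see [summary.lss_fit()],
#'   [coef.lss_fit()], [eap_scores()].
#' @export
lss_fit <- function(data, model, grid = gh_grid(q = model$latent$q),
                    start = "warm", em_iters = 50,
                    em_method = c("newton", "gradient"),
                    em_rel_tol = 1e-6, maxit = 200, reltol = 1e-10,
                    precondition = TRUE,
                    grad_tol = 1e-4 * sqrt(n_free_params(model)),
                    se = TRUE, n_starts = 1, jitter_sd = 0.25, seed = NULL,
                    verbose = FALSE) {
  em_method <- match.arg(em_method)
  Y <- validate_data(data, model)
  n <- nrow(Y)
  K <- n_free_params(model)
  q <- model$latent$q
  corr <- model$latent$mode == "correlation"

  delta0 <- if (is.numeric(start)) {
    if (length(start) != K)
      stop(sprintf("start has length %d, expected K = %d", length(start), K),
           call. = FALSE)
    start
  } else if (identical(start, "spec")) model_start(model) else
    warm_start(Y, model)

  if (!is.null(seed)) set.seed(seed)
  starts <- list(delta0)
  if (n_starts > 1) {
    is_rho <- model$index$role == "rho"
    for (s in seq_len(n_starts - 1)) {
      d <- delta0 + stats::rnorm(K, 0, jitter_sd)
      d[is_rho] <- pmin(pmax(d[is_rho], -0.9), 0.9)
      starts[[s + 1]] <- d
    }
  }

  to_working <- function(delta) {
    if (!corr) return(delta)
    sp <- split_delta(model, delta)
    delta[sp$is_rho] <- gamma_from_rho(sp$rho, q)
    delta
  }
  from_working <- function(x) {
    if (!corr) return(x)
    is_rho <- model$index$role == "rho"
    x[is_rho] <- rho_from_gamma(x[is_rho], q)
    x
  }
  neg_fn <- function(x)
    -eval_model(Y, from_working(x), model, grid, what = "loglik")$loglik
  neg_gr <- function(x) {
    dL_list <- if (corr)
      chol_from_gamma(x[model$index$role == "rho"], q, jacobian = TRUE)$dL
    -eval_model(Y, from_working(x), model, grid, what = "score",
                dL_list = dL_list)$score
  }

  best <- NULL
  for (s in seq_along(starts)) {
    state <- list(Y = Y, model = model, grid = grid, delta = starts[[s]],
                  lr = rep(0.5, length(model$items)))
    em_trace <- c()
    ll_prev <- -Inf
    em_used <- 0L
    if (em_iters > 0) {
      for (it in seq_len(em_iters)) {
        state <- em_iteration(state, method = em_method)
        em_trace <- c(em_trace, state$loglik)
        em_used <- it
        if (verbose)
          message(sprintf("start %d, EM iter %d: loglik = %.6f", s, it,
                          state$loglik))
        if (is.finite(ll_prev) &&
            abs(state$loglik - ll_prev) < em_rel_tol * (abs(ll_prev) + 1))
          break
        ll_prev <- state$loglik
      }
    }
    ctrl <- list(maxit = maxit, reltol = reltol)
    if (precondition) {
      SR0 <- tryCatch(
        eval_model(Y, state$delta, model, grid, "score_rows")$score_rows,
        error = function(e) NULL)
      if (!is.null(SR0)) {
        ps <- 1 / sqrt(pmax(colSums(SR0^2), 1e-2))
        if (all(is.finite(ps))) ctrl$parscale <- ps
      }
    }
    op <- stats::optim(to_working(state$delta), neg_fn, neg_gr,
                       method = "BFGS", control = ctrl)
    cand <- list(delta = from_working(op$par), loglik = -op$value,
                 em_trace = em_trace, em_iters = em_used,
                 optim_counts = op$counts, optim_convergence = op$convergence)
    if (verbose)
      message(sprintf("start %d: final loglik = %.6f", s, cand$loglik))
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }

  sc <- eval_model(Y, best$delta, model, grid, what = "score")$score
  grad_norm <- max(abs(sc)) / n
  converged <- best$optim_convergence == 0 && grad_norm < grad_tol

  info <- NULL
  ses <- rep(NA_real_, K)
  ident <- list(min_eigenvalue = NA_real_, condition_number = NA_real_,
                singular = NA)
  if (se) {
    ia <- information_and_se(Y, best$delta, model, grid)
    info <- ia$information
    ses <- ia$se
    ident <- ia$diagnostic
  }
  ic <- aic_bic(best$loglik, K, n)
  delta_hat <- stats::setNames(best$delta, model$index$label)
  structure(list(
    model = model, delta = delta_hat,
    se = stats::setNames(ses, model$index$label),
    loglik = best$loglik, K = K, n = n, AIC = ic$AIC, BIC = ic$BIC,
    information = info, identification = ident,
    convergence = list(converged = converged, em_iters = best$em_iters,
                       em_trace = best$em_trace,
                       optim_counts = best$optim_counts,
                       optim_convergence = best$optim_convergence,
                       grad_norm = grad_norm, grad_tol = grad_tol),
    grid = list(m = grid$m, q = grid$q)),
    class = "lss_fit")
}

#' Empirical information matrix, standard errors and identification check
#'
#' Estimates the expected information at `delta` by the sum over rows of the
#' outer products of case-wise score vectors. Standard errors are the square
#' roots of the diagonal of its inverse. The diagnostic reports the smallest
#' eigenvalue and the condition number; the estimate is flagged as
#' empirically non-identified (singular) when the condition number exceeds
#' 1e10, in which case no standard errors are returned (no exception is
#' raised).
#'
#' @inheritParams marginal_loglik
#' @return list with `information` (K x K), `se` (length K; NA when
#'   singular), and `diagnostic` (`min_eigenvalue`, `condition_number`,
#'   `singular`).
#' @export
information_and_se <- function(data, delta, model,
                               grid = gh_grid(q = model$latent$q)) {
  Y <- validate_data(data, model)
  SR <- eval_model(Y, delta, model, grid, what = "score_rows")$score_rows
  info <- crossprod(SR)
  info <- (info + t(info)) / 2
  evs <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(evs)
  cond <- if (min_ev <= 0) Inf else max(evs) / min_ev
  singular <- !is.finite(cond) || cond > 1e10
  se <- rep(NA_real_, ncol(info))
  if (!singular)
    se <- sqrt(diag(chol2inv(chol(info))))
  dimnames(info) <- list(model$index$label, model$index$label)
  list(information = info,
       se = stats::setNames(se, model$index$label),
       diagnostic = list(min_eigenvalue = min_ev, condition_number = cond,
                         singular = singular))
}

#' Expected a posteriori factor scores
#'
#' Posterior mean and variance of the latent variables for every row of
#' `data`, at the fitted parameters, using the fixed quadrature grid. Rows
#' with all items missing return the prior mean (0) and prior variance.
#'
#' @param data person-by-item data matching the fitted model.
#' @param fit an `lss_fit`.
#' @param grid quadrature grid; defaults to the rule used in the fit.
#' @return data frame with one row per observation: `eap.z*` posterior
#'   means and `var.z*` posterior variances per factor.
#' @export
eap_scores <- function(data, fit, grid = NULL) {
  model <- fit$model
  if (is.null(grid)) grid <- gh_grid(fit$grid$m, fit$grid$q)
  Y <- validate_data(data, model)
  ev <- eval_model(Y, unname(fit$delta), model, grid, what = "weights")
  Z <- ev$Z
  q <- model$latent$q
  M1 <- ev$W %*% Z
  V <- matrix(0, nrow(Y), q)
  for (r in seq_len(q)) V[, r] <- ev$W %*% (Z[, r]^2) - M1[, r]^2
  out <- data.frame(M1, V)
  names(out) <- c(paste0("eap.z", seq_len(q)), paste0("var.z", seq_len(q)))
  out
}

## ---- methods --------------------------------------------------------------

#' @export
print.lss_fit <- function(x, ...) {
  cat(sprintf("<lss_fit> K = %d parameters, n = %d\n", x$K, x$n))
  cat(sprintf("  marginal logLik = %.3f | AIC = %.2f | BIC = %.2f\n",
              x$loglik, x$AIC, x$BIC))
  cat(sprintf("  converged: %s (EM iters %d, per-obs grad sup-norm %.2e)\n",
              x$convergence$converged, x$convergence$em_iters,
              x$convergence$grad_norm))
  if (isTRUE(x$identification$singular))
    cat("  WARNING: information matrix numerically singular; model not empirically identified\n")
  invisible(x)
}

#' @export
coef.lss_fit <- function(object, ...) object$delta

#' @export
logLik.lss_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n, class = "logLik")
}

#' Parameter table for a fitted model
#'
#' @param object an `lss_fit`.
#' @param ... unused.
#' @return data frame with columns `parameter`, `estimate`, `se`.
#' @export
summary.lss_fit <- function(object, ...) {
  data.frame(parameter = names(object$delta),
             estimate = unname(object$delta),
             se = unname(object$se),
             row.names = NULL)
}
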