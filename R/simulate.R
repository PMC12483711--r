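## ---- true-parameter fixtures ----------------------------------------------

#' Draw true parameters for the one-factor heteroscedastic Beta design
#'
#' Location intercepts are uniform on `ranges$mu_int`, location slopes
#' uniform in absolute value on `ranges$mu_slope`, scale intercepts uniform
#' on `ranges$sigma_int`, scale slopes uniform in absolute value on
#' `ranges$sigma_slope`; slope signs are +1/-1 with probability 0.5. Every
#' item is redrawn until both implied Beta shapes exceed 1 for all latent
#' values on a grid over [-3, 3], which keeps the conditional densities
#' unimodal.
#'
#' @param p number of items (>= 2).
#' @param seed integer seed (drawing is deterministic given it).
#' @param ranges list of the four uniform ranges described above.
#' @param max_tries redraw cap per item before failing with advice.
#' @return list with `model` (the [study1_model()]), `delta` (packed true
#'   vector) and `values` (structured form).
#' @export
study1_true_params <- function(p, seed = 1,
                               ranges = list(mu_int = c(-1, 1),
                                             mu_slope = c(0.5, 1.5),
                                             sigma_int = c(-1.5, -0.5),
                                             sigma_slope = c(0.1, 0.5)),
                               max_tries = 1000) {
  if (p < 2) stop("need at least p = 2 items", call. = FALSE)
  set.seed(seed)
  model <- study1_model(p)
  vals <- values_template(model)
  zg <- seq(-3, 3, by = 0.05)
  for (i in seq_len(p)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a0m <- stats::runif(1, ranges$mu_int[1], ranges$mu_int[2])
      lm_ <- sample(c(-1, 1), 1) * stats::runif(1, ranges$mu_slope[1],
                                                ranges$mu_slope[2])
      a0s <- stats::runif(1, ranges$sigma_int[1], ranges$sigma_int[2])
      ls_ <- sample(c(-1, 1), 1) * stats::runif(1, ranges$sigma_slope[1],
                                                ranges$sigma_slope[2])
      mu <- stats::plogis(a0m + lm_ * zg)
      sg <- stats::plogis(a0s + ls_ * zg)
      phi <- (1 - sg^2) / sg^2
      if (all(mu * phi > 1) && all((1 - mu) * phi > 1)) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(paste("item %d: no unimodal draw in %d tries; widen the",
                         "scale ranges toward smaller sigma"), i, max_tries),
           call. = FALSE)
    vals$items[[i]]$mu <- list(intercept = a0m, loadings = lm_)
    vals$items[[i]]$sigma <- list(intercept = a0s, loadings = ls_)
  }
  list(model = model, delta = pack_params(model, vals), values = vals)
}

#' Fixed true parameters for the two-factor IR/RT design
#'
#' A documented, replaceable fixture for the binary-items-plus-response-times
#' design: item difficulties (intercepts) uniform on (-1.5, 1.5) and
#' discriminations on (0.8, 2) for the Bernoulli items; response-time
#' location intercepts on (-0.7, 0.3) with negative speed loadings on
#' (-0.5, -0.2); small mixed-sign scale and shape equations; and a
#' speed-ability correlation of `rho` (default -0.28). The response-time
#' items load on factor 1 (speed) and the binary items on factor 2
#' (ability). Deterministic given
#' `seed`; the default seed is the shipped fixture.
#'
#' @param seed integer seed for the draw (default 1234, the fixture).
#' @param rho true factor correlation.
#' @param p_bin,p_sn numbers of binary and Skew-Normal items.
#' @return list with `model` (the [study2_model()]), `delta`, and `values`.
#' @export
study2_true_params <- function(seed = 1234, rho = -0.28, p_bin = 8, p_sn = 8) {
  set.seed(seed)
  model <- study2_model(p_bin, p_sn)
  vals <- values_template(model)
  for (i in seq_len(p_bin)) {
    vals$items[[i]]$mu <- list(
      intercept = stats::runif(1, -1.5, 1.5),
      loadings = c(0, stats::runif(1, 0.8, 2)))
  }
  for (i in seq_len(p_sn)) {
    k <- p_bin + i
    vals$items[[k]]$mu <- list(
      intercept = stats::runif(1, -0.7, 0.3),
      loadings = c(stats::runif(1, -0.5, -0.2), 0))
    vals$items[[k]]$sigma <- list(
      intercept = stats::runif(1, -1.2, -0.8),
      loadings = c(sample(c(-1, 1), 1) * stats::runif(1, 0.1, 0.3), 0))
    vals$items[[k]]$nu <- list(
      intercept = stats::runif(1, -0.5, 0.5),
      loadings = c(sample(c(-1, 1), 1) * stats::runif(1, 0.1, 0.3), 0))
  }
  vals$rho <- rho
  list(model = model, delta = pack_params(model, vals), values = vals)
}

## ---- data generation ------------------------------------------------------

#' Simulate person-by-item data from a model
#'
#' Draws latent variables from N(0, Sigma) (Sigma the identity or the
#' model's correlation matrix at `delta`), evaluates every item's
#' distributional parameters at each draw through the measurement equations,
#' and samples each response from its family. Fully deterministic given
#' `seed`.
#'
#' @param model an `lss_model`.
#' @param delta packed parameter vector to simulate from.
#' @param n number of rows.
#' @param seed integer seed.
#' @return data frame with `n` rows and one named column per item; the
#'   latent draws are attached as attribute `"z"`.
#' @export
simulate_lss <- function(model, delta, n, seed = 1) {
  set.seed(seed)
  q <- model$latent$q
  vals <- unpack_params(model, delta)
  L <- if (model$latent$mode == "correlation")
    correlation_cholesky(vals$rho, q) else diag(q)
  Zl <- matrix(stats::rnorm(n * q), n, q) %*% t(L)
  out <- vector("list", length(model$items))
  for (i in seq_along(model$items)) {
    fam <- model$items[[i]]$family
    th <- lapply(fam$roles, function(r) {
      vi <- vals$items[[i]][[r]]
      fam$links[[r]]$linkinv(vi$intercept + drop(Zl %*% vi$loadings))
    })
    names(th) <- fam$roles
    y <- family_sample(fam, n, th)
    if (fam$name == "beta_ls") {
      # rbeta can round into the closed boundary in extreme tails; the
      # support is open, so pull such draws one ulp inside
      eps <- .Machine$double.eps
      y <- pmin(pmax(y, eps), 1 - eps)
    }
    out[[i]] <- y
  }
  names(out) <- model$item_names
  structure(as.data.frame(out), z = Zl)
}

## ---- recovery metrics -----------------------------------------------------

# parameter group used in recovery reports
param_group <- function(index) {
  role <- index$role
  is_int <- index$comp == "intercept"
  out <- character(nrow(index))
  out[role == "mu"] <- ifelse(is_int[role == "mu"],
                              "location intercepts", "location loadings")
  out[role == "sigma"] <- ifelse(is_int[role == "sigma"],
                                 "scale intercepts", "scale loadings")
  out[role == "nu"] <- ifelse(is_int[role == "nu"],
                              "shape intercepts", "shape loadings")
  out[role == "rho"] <- "correlation"
  out
}

#' Align estimated factor-loading signs to the truth
#'
#' The marginal likelihood is invariant to jointly flipping the sign of one
#' factor's loadings (and the matching rows/columns of the latent
#' correlation matrix), so recovery metrics are computed after flipping each
#' factor of the estimate to best agree with the true loadings.
#'
#' @param delta_hat estimated packed vector.
#' @param delta_true true packed vector.
#' @param model the `lss_model` both refer to.
#' @return sign-aligned copy of `delta_hat`.
#' @export
align_signs <- function(delta_hat, delta_true, model) {
  idx <- model$index
  q <- model$latent$q
  s <- rep(1, q)
  for (r in seq_len(q)) {
    pos <- which(idx$comp == paste0("z", r) & idx$role != "rho")
    if (length(pos) && sum(delta_hat[pos] * delta_true[pos]) < 0) s[r] <- -1
  }
  for (r in which(s < 0)) {
    pos <- which(idx$comp == paste0("z", r) & idx$role != "rho")
    delta_hat[pos] <- -delta_hat[pos]
  }
  rpos <- which(idx$role == "rho")
  if (length(rpos)) {
    ij <- vech_index(q)
    for (g in seq_along(rpos))
      delta_hat[rpos[g]] <- delta_hat[rpos[g]] * s[ij[g, 1]] * s[ij[g, 2]]
  }
  delta_hat
}

#' Recovery metrics over replications
#'
#' Per-parameter mean squared error `MSE_k = mean_r (est - true)^2`,
#' absolute bias `AB_k = mean_r |est - true|`, and coverage rate `CR_k`,
#' the proportion of replications whose Wald interval
#' `est +/- z_{(1+level)/2} * SE` contains the truth; replications without
#' standard errors (singular fits) are excluded from CR and counted.
#' Estimates should be sign-aligned (`align = TRUE` applies
#' [align_signs()] per replication). Group averages (AvMSE/AvAB/AvCR) are
#' reported per parameter block: location/scale/shape intercepts and
#' loadings, and the correlation.
#'
#' @param estimates R x K matrix of per-replication packed estimates.
#' @param ses R x K matrix of per-replication standard errors (NA allowed).
#' @param delta_true true packed vector.
#' @param model the `lss_model`.
#' @param level nominal confidence level (default 0.95).
#' @param align sign-align each replication first?
#' @return an object of class `lss_report`: list with `table` (one row per
#'   parameter group), `per_param`, `n_reps`, `n_se_missing`.
#' @export
recovery_metrics <- function(estimates, ses, delta_true, model,
                             level = 0.95, align = TRUE) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  R <- nrow(estimates)
  K <- n_free_params(model)
  stopifnot(ncol(estimates) == K, all(dim(ses) == dim(estimates)))
  if (align)
    for (r in seq_len(R))
      estimates[r, ] <- align_signs(estimates[r, ], delta_true, model)
  zq <- stats::qnorm((1 + level) / 2)
  err <- sweep(estimates, 2, delta_true)
  covered <- abs(err) <= zq * ses          # NA where SE missing
  per <- data.frame(
    label = model$index$label,
    group = param_group(model$index),
    true = delta_true,
    MSE = colMeans(err^2),
    AB = colMeans(abs(err)),
    CR = colMeans(covered, na.rm = TRUE),
    row.names = NULL)
  se_missing <- sum(apply(is.na(ses), 1, any))
  groups <- unique(per$group)
  tab <- do.call(rbind, lapply(groups, function(g) {
    sel <- per$group == g
    data.frame(group = g, AvMSE = mean(per$MSE[sel]),
               AvAB = mean(per$AB[sel]), AvCR = mean(per$CR[sel]))
  }))
  structure(list(table = tab, per_param = per, n_reps = R,
                 n_se_missing = se_missing, level = level),
            class = "lss_report")
}

#' @export
print.lss_report <- function(x, ...) {
  cat(sprintf("<lss_report> %d replication(s); %d without SEs\n",
              x$n_reps, x$n_se_missing))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

## ---- study designs --------------------------------------------------------

#' Recovery-study designs
#'
#' `study1_design()` is the one-factor heteroscedastic Beta recovery design
#' (sample sizes 200/500/1000/5000 and test lengths 5/10/20 form its full
#' factorial); `study2_design()` is the two-factor IR/RT design with the
#' fixed [study2_true_params()] fixture; `lss_design()` wraps an arbitrary
#' model and truth. Replication `r` of a design uses seed `seed + r`, and
#' the truth (when drawn) uses `seed` itself, so every report is fully
#' reproducible from the design alone.
#'
#' @param n sample size per replication.
#' @param p number of items (study 1).
#' @param R number of replications.
#' @param seed master seed.
#' @param m quadrature points per latent dimension.
#' @param rho true factor correlation (study 2).
#' @param estimator list of [lss_fit()] options (e.g. `em_iters`, `maxit`).
#' @param model,delta_true model and truth for a custom design.
#' @return an object of class `lss_design`.
#' @export
study1_design <- function(n, p = 5, R = 50, seed = 1, m = 21,
                          estimator = list()) {
  structure(list(study = "study1", n = n, p = p, R = R, seed = seed, m = m,
                 estimator = estimator), class = "lss_design")
}

#' @rdname study1_design
#' @export
study2_design <- function(n, R = 20, seed = 1, m = 21, rho = -0.28,
                          estimator = list()) {
  structure(list(study = "study2", n = n, R = R, seed = seed, m = m,
                 rho = rho, estimator = estimator), class = "lss_design")
}

#' @rdname study1_design
#' @export
lss_design <- function(model, delta_true, n, R = 50, seed = 1, m = 21,
                       estimator = list()) {
  structure(list(study = "custom", model = model, delta_true = delta_true,
                 n = n, R = R, seed = seed, m = m, estimator = estimator),
            class = "lss_design")
}

#' @export
print.lss_design <- function(x, ...) {
  cat(sprintf("<lss_design> %s: n = %d, R = %d, seed = %d, m = %d\n",
              x$study, x$n, x$R, x$seed, x$m))
  invisible(x)
}

design_truth <- function(design) {
  switch(design$study,
    study1 = study1_true_params(design$p, seed = design$seed),
    study2 = study2_true_params(rho = design$rho),
    custom = list(model = design$model, delta = design$delta_true))
}

#' Run a seeded parameter-recovery study
#'
#' Simulates `R` datasets from the design's truth, fits each by marginal
#' maximum likelihood, sign-aligns the estimates, and summarizes recovery
#' with AvMSE, AvAB, and AvCR per parameter group. Replication failures are
#' caught and counted, never fatal. Fully deterministic given the design.
#'
#' @param design an `lss_design`.
#' @param verbose print per-replication progress?
#' @return an `lss_report` with extra fields: `estimates`, `ses` (R x K),
#'   `delta_true`, `design`, `n_failed`, `n_nonconverged`, `avg_fit_time`
#'   (seconds), and `replications` (per-replication seed, failure and
#'   convergence flags, fit time).
#' @export
run_study <- function(design, verbose = FALSE) {
  truth <- design_truth(design)
  model <- truth$model
  K <- n_free_params(model)
  grid <- gh_grid(design$m, model$latent$q)
  est_opts <- utils::modifyList(
    list(em_iters = 5, maxit = 200, reltol = 1e-9, start = "warm"),
    design$estimator)
  est <- matrix(NA_real_, design$R, K)
  ses <- matrix(NA_real_, design$R, K)
  conv <- logical(design$R)
  failed <- logical(design$R)
  times <- rep(NA_real_, design$R)
  for (r in seq_len(design$R)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      dat <- simulate_lss(model, truth$delta, design$n,
                          seed = design$seed + r)
      do.call(lss_fit, c(list(data = dat, model = model, grid = grid),
                         est_opts))
    }, error = function(e) e)
    times[r] <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed[r] <- TRUE
      if (verbose) message(sprintf("rep %d failed: %s", r, conditionMessage(res)))
      next
    }
    est[r, ] <- unname(res$delta)
    ses[r, ] <- unname(res$se)
    conv[r] <- isTRUE(res$convergence$converged)
    if (verbose)
      message(sprintf("rep %d: loglik %.2f, converged %s", r, res$loglik,
                      conv[r]))
  }
  keep <- !failed
  rep_out <- recovery_metrics(est[keep, , drop = FALSE],
                              ses[keep, , drop = FALSE],
                              truth$delta, model)
  rep_out$estimates <- est[keep, , drop = FALSE]
  rep_out$ses <- ses[keep, , drop = FALSE]
  rep_out$delta_true <- truth$delta
  rep_out$design <- design
  rep_out$n_failed <- sum(failed)
  rep_out$n_nonconverged <- sum(keep & !conv)
  rep_out$avg_fit_time <- mean(times[keep])
  rep_out$replications <- data.frame(rep = seq_len(design$R),
                                     seed = design$seed + seq_len(design$R),
                                     failed = failed, converged = conv,
                                     seconds = times)
  rep_out
}
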