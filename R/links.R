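#' Construct a link function
#'
#' A link maps a distributional parameter from its natural space onto the
#' unconstrained real line, where the linear predictor
#' \eqn{\eta = \alpha_0 + \alpha^\top z} lives. `linkfun` is the forward map
#' (parameter space to reals), `linkinv` its inverse, and `mu.eta` the
#' derivative of the inverse, which is strictly positive for every supported
#' link.
#'
#' @param name one of `"identity"`, `"log"`, `"logit"`, `"scaled_logit"`
#'   (`"scaled-logit"` is accepted as an alias).
#' @param lower,upper open-interval endpoints for `scaled_logit`; ignored
#'   otherwise.
#' @return an object of class `lss_link`: a list with elements `name`,
#'   `linkfun`, `linkinv`, `mu.eta`, and the parameter-space `bounds`.
#' @examples
#' lk <- make_link("logit")
#' lk$linkfun(0.5)        # 0
#' lk$mu.eta(0)           # 0.25
#' @export
make_link <- function(name, lower = -1, upper = 1) {
  name <- gsub("-", "_", as.character(name)[1])
  switch(name,
    identity = structure(list(
      name = "identity",
      linkfun = function(x) x,
      linkinv = function(eta) eta,
      mu.eta  = function(eta) rep_len(1, length(eta)),
      bounds  = c(-Inf, Inf), eta_clamp = c(-Inf, Inf)), class = "lss_link"),
    log = structure(list(
      name = "log",
      linkfun = function(x) log(x),
      linkinv = function(eta) exp(eta),
      mu.eta  = function(eta) exp(eta),
      bounds  = c(0, Inf), eta_clamp = c(-300, 300)), class = "lss_link"),
    logit = structure(list(
      name = "logit",
      linkfun = function(x) stats::qlogis(x),
      linkinv = function(eta) stats::plogis(eta),
      mu.eta  = function(eta) {
        p <- stats::plogis(eta)
        p * (1 - p)
      },
      bounds  = c(0, 1), eta_clamp = c(-30, 30)), class = "lss_link"),
    scaled_logit = {
      if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
        stop("scaled_logit needs finite bounds with lower < upper", call. = FALSE)
      d <- upper - lower
      structure(list(
        name = "scaled_logit",
        linkfun = function(x) stats::qlogis((x - lower) / d),
        linkinv = function(eta) lower + d * stats::plogis(eta),
        mu.eta  = function(eta) {
          p <- stats::plogis(eta)
          d * p * (1 - p)
        },
        bounds  = c(lower, upper), eta_clamp = c(-30, 30)), class = "lss_link")
    },
    stop(sprintf("unknown link function: '%s'", name), call. = FALSE)
  )
}

#' @export
print.lss_link <- function(x, ...) {
  cat(sprintf("<lss_link> %s on (%g, %g)\n", x$name, x$bounds[1], x$bounds[2]))
  invisible(x)
}
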