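#' Model parameters
#'
#' All tunable parameters of the scoring model with their defaults: the
#' similarity blend weights, kernel bandwidth multipliers, the propagation
#' decay `mu` (analogous to a restart probability), the dual-path decay
#' exponent `gamma`, the six per-pattern bias ratings, and the fixed-point
#' stopping rule.
#'
#' @param alpha blend weight of semantic vs kernel disease similarity, in
#'   `[0, 1]`. Default 0.6.
#' @param beta blend weight of functional vs kernel microbe similarity, in
#'   `[0, 1]`. Default 0.7.
#' @param mu propagation decay factor in (0, 1); larger values weight the
#'   meta-graph terms over the raw association anchor. Default 0.9.
#' @param gamma dual-path decay exponent (> 0) applied elementwise to the
#'   two dual-path pattern terms. Default 0.1.
#' @param bias numeric vector of six bias ratings in `[0, 1]`, one per
#'   meta-graph pattern a-f. Default `c(0.35, 0.1, 0.1, 0.05, 0.2, 0.2)`.
#' @param delta semantic decay factor used when building disease DAGs.
#'   Default 0.5.
#' @param bandwidth_mult_d,bandwidth_mult_m positive kernel bandwidth
#'   multipliers. Default 1.
#' @param tol convergence tolerance on the max absolute elementwise change
#'   between iterations. Default 1e-6.
#' @param max_iter iteration cap. Default 1000.
#' @param init initialization of the score matrix: `"global-max"` divides
#'   the association matrix by its largest entry (identity for binary
#'   input), `"row-stochastic"` divides each nonzero row by its sum.
#' @return list of class `wmg_params`.
#' @export
wmg_params <- function(alpha = 0.6, beta = 0.7, mu = 0.9, gamma = 0.1,
                       bias = c(0.35, 0.1, 0.1, 0.05, 0.2, 0.2),
                       delta = 0.5,
                       bandwidth_mult_d = 1, bandwidth_mult_m = 1,
                       tol = 1e-6, max_iter = 1000,
                       init = c("global-max", "row-stochastic")) {
  init <- match.arg(init)
  stopifnot(
    alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
    mu > 0, mu < 1, gamma > 0,
    is.numeric(bias), length(bias) == 6L, all(bias >= 0), all(bias <= 1),
    delta > 0, delta < 1,
    bandwidth_mult_d > 0, bandwidth_mult_m > 0,
    max_iter >= 1
  )
  if (!(is.numeric(tol) && length(tol) == 1L && tol > 0)) {
    stop("tol must be a positive scalar")
  }
  structure(
    list(alpha = alpha, beta = beta, mu = mu, gamma = gamma, bias = bias,
         delta = delta,
         bandwidth_mult_d = bandwidth_mult_d, bandwidth_mult_m = bandwidth_mult_m,
         tol = tol, max_iter = max_iter, init = init),
    class = "wmg_params"
  )
}
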