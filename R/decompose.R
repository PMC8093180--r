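#' Decompose the phenotypic variance at equilibrium
#'
#' Splits `V_Y` into the full additive genetic variance `V_A`, the
#' vertical-transmission variance `V_F`, the gene--environment covariance due
#' to genetic nurture `2(a v + delta w)`, and the residual `V_eps`. Also
#' reports the base-population additive variance `V_A0` and the
#' Kong-style quantities: direct genetic nurture `eta = 2 f Omega`, its
#' AM inflation `phi_eta = 2 f Omega mu V_Y` (so `eta + phi_eta = w`), and
#' the AM-induced genetic part of the nontransmitted-score covariance
#' `phi_delta = 4 delta g`.
#'
#' @param state a converged [equilibrium_state()].
#' @return One-row tibble with columns `V_A`, `V_A0`, `V_F`, `nurture_cov`,
#'   `V_eps`, `V_Y`, `eta`, `phi_eta`, `phi_delta`, and the trait-variance
#'   proportions `h2_full` (`V_A / V_Y`) and `vf_share` (`V_F / V_Y`).
#' @examples
#' st <- equilibrium_state(model_params(delta = 0.5, f = 0.2, V_eps = 0.545))
#' decompose_variance(st)
#' @export
decompose_variance <- function(state) {
  stopifnot(inherits(state, "equilibrium_state"))
  if (!state$converged) {
    abort("equilibrium state did not converge")
  }
  nurture_cov <- 2 * (state$a * state$v + state$delta * state$w)
  V_A0 <- 2 * state$a^2 * state$j + 2 * state$delta^2 * state$k
  tibble(
    V_A = state$V_A,
    V_A0 = V_A0,
    V_F = state$V_F,
    nurture_cov = nurture_cov,
    V_eps = state$V_eps,
    V_Y = state$V_Y,
    eta = 2 * state$f * state$Omega,
    phi_eta = 2 * state$f * state$Omega * state$mu * state$V_Y,
    phi_delta = 4 * state$delta * state$g,
    h2_full = state$V_A / state$V_Y,
    vf_share = state$V_F / state$V_Y
  )
}

#' Closed-form Model 0 solution from three observed statistics
#'
#' When there is no assortative mating (and the haplotypic PGS variances are
#' the base-population constant `1/2`), the vertical-transmission path and
#' the full `V_F` follow in closed form from just three observed statistics:
#' `f = theta_NT / theta_T`, `delta = theta_T - theta_NT`, `w = theta_NT`,
#' and `V_F = 2 f^2 V_Y`. Because `delta` cancels in the ratio, the point
#' estimate of `f` does not depend on how predictive the PGS is.
#'
#' @param theta_NT covariance between the offspring phenotype and the sum of
#'   the two nontransmitted haplotypic PGSs.
#' @param theta_T covariance between the offspring phenotype and the sum of
#'   the two transmitted haplotypic PGSs; must be nonzero.
#' @param V_Y phenotypic variance.
#' @return Tibble with columns `f`, `delta`, `w`, `V_F` (one row per input
#'   element; inputs are recycled). Valid under the no-AM assumption only.
#' @examples
#' closed_form_model0(theta_NT = 0.125, theta_T = 0.625, V_Y = 1)
#' @export
closed_form_model0 <- function(theta_NT, theta_T, V_Y) {
  stopifnot(is.numeric(theta_NT), is.numeric(theta_T), is.numeric(V_Y))
  if (any(theta_T == 0)) {
    abort("theta_T must be nonzero")
  }
  f <- theta_NT / theta_T
  if (any(abs(f) >= 1)) {
    abort(sprintf(
      "implied f = %.3f lies outside (-1, 1); inconsistent with the model",
      f[which.max(abs(f))]
    ))
  }
  tibble(
    f = f,
    delta = theta_T - theta_NT,
    w = theta_NT,
    V_F = 2 * f^2 * V_Y
  )
}
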