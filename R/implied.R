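#' Model-implied covariance matrix of the observed family variables
#'
#' Fills the covariance matrix among the four haplotypic PGSs and the
#' offspring phenotype (5-by-5), optionally extended with the two parental
#' phenotypes (7-by-7, Model 2), implied by an equilibrium state. All means
#' are fixed at zero: the models are covariance-structure models and
#' consumers must center observed data.
#'
#' @details
#' Entries, with the cis AM terms dropped under the disequilibrium regime:
#' \itemize{
#'   \item `var([N]T_*) = k + g` — base variance plus the AM-induced increase;
#'   \item `cov(T_*, NT_*) = g` (cis, within a parent);
#'   \item `cov([N]T_p, [N]T_m) = g` (trans, across mates; chain
#'     `[N]T_p -> Y_p - mu - Y_m -> [N]T_m = Omega mu Omega`);
#'   \item `cov(Y_o, T_*) = theta_T / 2`, `cov(Y_o, NT_*) = theta_NT / 2`;
#'   \item `cov(Y_*, [N]T_*) = Omega` (a parent with their own scores);
#'   \item `cov(Y_p, [N]T_m) = cov(Y_m, [N]T_p) = Omega mu V_Y` (chain
#'     through the copath: `[N]T_m -> Y_m - mu - Y_p`, i.e.
#'     `Omega * mu * V_Y`);
#'   \item `cov(Y_p, Y_m) = mu V_Y^2` (copath joining the two variance
#'     chains);
#'   \item `cov(Y_o, Y_*) = (delta Omega + a Gamma + f V_Y)(1 + mu V_Y)` —
#'     the sum of four chain families: genetic via the transmitted PGS
#'     (`delta * Omega` direct plus `delta * Omega * mu V_Y` via the mate),
#'     genetic via the transmitted LGS (`a * Gamma` and its mate analog),
#'     vertical transmission (`f * V_Y`), and VT via the mate
#'     (`f * mu V_Y^2`);
#'   \item `var(Y) = V_Y` for all phenotypes (equilibrium assumption).
#' }
#'
#' @param state a converged [equilibrium_state()].
#' @param with_parents include the parental phenotypes `Y_p`, `Y_m`
#'   (7-by-7)? Defaults to `TRUE` for Model 2.
#'
#' @return An object of class `implied_moments`: list with `variables`,
#'   the covariance matrix `cov`, and the zero `means` vector.
#' @examples
#' st <- equilibrium_state(model_params(delta = 0.5, f = 0.2, V_eps = 0.545))
#' implied_covariance(st)
#' @export
implied_covariance <- function(state, with_parents = state$model == "m2") {
  stopifnot(inherits(state, "equilibrium_state"))
  if (!state$converged) {
    abort("equilibrium state did not converge; refusing to build implied moments")
  }
  cis <- if (state$am_regime == "disequilibrium") 0 else 1
  g <- state$g
  k <- state$k
  V_Y <- state$V_Y
  mu <- state$mu
  Omega <- state$Omega
  Gamma <- state$Gamma
  delta <- state$delta
  a <- state$a
  f <- state$f

  vars <- c("NT_p", "T_p", "NT_m", "T_m", "Y_o")
  if (with_parents) vars <- c(vars, "Y_p", "Y_m")
  p <- length(vars)
  S <- matrix(0, p, p, dimnames = list(vars, vars))

  hapvar <- k + cis * g
  score <- c("NT_p", "T_p", "NT_m", "T_m")
  parent_of <- c(NT_p = "p", T_p = "p", NT_m = "m", T_m = "m")
  for (x in score) {
    for (y in score) {
      S[x, y] <- if (x == y) {
        hapvar
      } else if (parent_of[[x]] == parent_of[[y]]) {
        cis * g
      } else {
        g
      }
    }
  }
  S[score, "Y_o"] <- S["Y_o", score] <-
    c(state$theta_NT, state$theta_T, state$theta_NT, state$theta_T) / 2
  S["Y_o", "Y_o"] <- V_Y

  if (with_parents) {
    S["Y_p", "Y_p"] <- S["Y_m", "Y_m"] <- V_Y
    S["Y_p", "Y_m"] <- S["Y_m", "Y_p"] <- mu * V_Y^2
    own <- Omega
    mate <- Omega * mu * V_Y
    S[c("NT_p", "T_p"), "Y_p"] <- S["Y_p", c("NT_p", "T_p")] <- own
    S[c("NT_m", "T_m"), "Y_m"] <- S["Y_m", c("NT_m", "T_m")] <- own
    S[c("NT_m", "T_m"), "Y_p"] <- S["Y_p", c("NT_m", "T_m")] <- mate
    S[c("NT_p", "T_p"), "Y_m"] <- S["Y_m", c("NT_p", "T_p")] <- mate
    po <- (delta * Omega + a * Gamma + f * V_Y) * (1 + mu * V_Y)
    S["Y_o", c("Y_p", "Y_m")] <- S[c("Y_p", "Y_m"), "Y_o"] <- po
  }

  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort(sprintf(
      "implied covariance matrix is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)
    ))
  }

  structure(
    list(variables = vars, cov = S, means = setNames(rep(0, p), vars)),
    class = "implied_moments"
  )
}

#' @export
print.implied_moments <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<implied_moments> %d x %d (means fixed at 0)\n",
    length(x$variables), length(x$variables)
  ))
  print(round(x$cov, digits))
  invisible(x)
}

#' @describeIn implied_covariance long tibble of the unique implied moments.
#' @param x an `implied_moments` object.
#' @param ... unused.
#' @export
tidy.implied_moments <- function(x, ...) {
  S <- x$cov
  idx <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
  tibble(
    var1 = rownames(S)[idx[, 1]],
    var2 = colnames(S)[idx[, 2]],
    covariance = S[idx]
  )
}
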