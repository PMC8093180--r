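#' Equilibrium expectations of the parental-effects models
#'
#' Iterates the recursive expectations of Models 0, 1 and 2 to their fixed
#' point. Most derived quantities (the AM-induced score covariances `g`, `h`,
#' `i`, the genetic-nurture covariances `w`, `v`, the phenotypic variance
#' `V_Y`, and the familial variance `V_F`) are mutually recursive nonlinear
#' constraints; plain successive substitution from the no-AM, no-VT start
#' values converges in a handful of iterations for realistic parameters —
#' one iteration corresponds to one generation of mating.
#'
#' @details
#' The per-iteration updates are, writing `k`, `j` for the base-population
#' haplotypic score variances implied by the scaling convention:
#' \itemize{
#'   \item `Omega = delta*k + 2*delta*g + 2*a*i + w/2` (covariance between a
#'     parent's phenotype and either of that parent's haplotypic PGSs),
#'   \item `Gamma = a*j + 2*a*h + 2*delta*i + v/2` (the latent-score analog),
#'   \item `g = Omega^2 * mu`, with `h = g a^2/delta^2` and
#'     `i = g a/delta = sqrt(g h)` via the proportionate-increase constraints,
#'   \item `w = 2 f Omega (1 + mu V_Y)` and `v = w a / delta`,
#'   \item `V_F = 2 f^2 V_Y (1 + mu V_Y)`,
#'   \item `V_Y = V_A + V_F + 2(a v + delta w) + V_eps` with
#'     `V_A = 2 a^2 (j + 2h) + 2 delta^2 (k + 2g) + 8 a i delta`.
#' }
#' Model 0 is the special case `mu = 0, a = 0`; Model 1 allows `mu != 0` with
#' `a = 0`. When the user supplies the spousal correlation `r_mate` instead
#' of `mu`, `mu = r_mate / V_Y` is re-derived inside each iteration (the
#' correlation, not the copath, is assumed constant across generations).
#'
#' Under the `"disequilibrium"` regime (a single generation of assortment),
#' the cis (within-person) parts of `g`, `h`, `i` are set to zero in the
#' haplotypic variances, in `Omega`/`Gamma` and in `V_A`, while the
#' mu-mediated trans paths are retained: the trans covariances remain
#' `Omega^2 mu` and the offspring-score covariances become
#' `theta_NT = 2 f Omega (1 + mu V_Y) + 2 delta g + 2 a i`.
#'
#' @param params a [model_params()] object.
#' @param model `"m0"`, `"m1"` or `"m2"`; `NULL` (default) picks the smallest
#'   model consistent with `params` (`a != 0` needs m2, AM needs m1).
#' @param am_regime `"equilibrium"` (default) or `"disequilibrium"`.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   iterated quantities.
#' @param max_iter maximum number of iterations.
#' @param keep_trajectory if `TRUE`, record the value of every derived
#'   quantity at each iteration (for convergence diagnostics and plotting).
#'
#' @return An object of class `equilibrium_state`: a list with the structural
#'   parameters, the derived equilibrium quantities (`k`, `j`, `g`, `h`, `i`,
#'   `w`, `v`, `Omega`, `Gamma`, `V_Y`, `V_F`, `theta_T`, `theta_NT`,
#'   `theta_LT`, `theta_LNT`, `mu`, `r_mate`), and the convergence report
#'   (`n_iter`, `converged`). Use [tidy()] for a tibble of the quantities and
#'   [implied_covariance()] / [decompose_variance()] for downstream results.
#' @examples
#' p <- model_params(delta = 0.5, f = 0.2, V_eps = 0.545)
#' st <- equilibrium_state(p, model = "m0")
#' tidy(st)
#' @export
equilibrium_state <- function(params,
                              model = NULL,
                              am_regime = c("equilibrium", "disequilibrium"),
                              tol = 1e-12, max_iter = 10000L,
                              keep_trajectory = FALSE) {
  stopifnot(inherits(params, "model_params"))
  am_regime <- match.arg(am_regime)

  delta <- params$delta
  a <- params$a
  f <- params$f
  V_eps <- params$V_eps
  scaling <- params$scaling
  use_r_mate <- !is.null(params$r_mate)
  mu_fixed <- params$mu %||% 0
  r_mate <- params$r_mate %||% NA_real_

  if (is.null(model)) {
    has_am <- (use_r_mate && r_mate != 0) || (!use_r_mate && mu_fixed != 0)
    model <- if (a != 0) "m2" else if (has_am) "m1" else "m0"
  }
  model <- match.arg(model, c("m0", "m1", "m2"))
  if (model %in% c("m0", "m1") && a != 0) {
    abort(sprintf("model %s requires a = 0 (got a = %g)", model, a))
  }
  if (model == "m0") {
    if ((use_r_mate && r_mate != 0) || (!use_r_mate && mu_fixed != 0)) {
      abort("Model 0 assumes no assortative mating (mu = 0)")
    }
  }
  diseq <- am_regime == "disequilibrium"
  # cis multiplier: 0 kills the within-person AM covariances
  cis <- if (diseq) 0 else 1

  # start values: no AM, no VT
  kj0 <- base_constants(scaling, 0, 0)
  g <- h <- i <- w <- v <- 0
  V_Y <- 2 * delta^2 * kj0$k +
    (if (model == "m2") 2 * a^2 * kj0$j else 0) + V_eps

  deriv <- function(g, h, i, w, v, V_Y) {
    kj <- base_constants(scaling, cis * g, cis * h)
    mu <- if (use_r_mate) r_mate / V_Y else mu_fixed
    Omega <- delta * kj$k + 2 * delta * cis * g + 2 * a * cis * i + w / 2
    Gamma <- if (model == "m2") {
      a * kj$j + 2 * a * cis * h + 2 * delta * cis * i + v / 2
    } else {
      0
    }
    list(kj = kj, mu = mu, Omega = Omega, Gamma = Gamma)
  }

  traj <- if (keep_trajectory) vector("list", max_iter) else NULL
  converged <- FALSE
  n_iter <- 0L

  for (it in seq_len(max_iter)) {
    d <- deriv(g, h, i, w, v, V_Y)
    mu <- d$mu
    Omega <- d$Omega
    Gamma <- d$Gamma
    infl <- 1 + mu * V_Y

    g_new <- Omega^2 * mu
    if (model == "m2") {
      if (delta != 0) {
        h_new <- g_new * a^2 / delta^2
        i_new <- g_new * a / delta
      } else {
        h_new <- Gamma^2 * mu
        i_new <- Omega * Gamma * mu
      }
    } else {
      h_new <- 0
      i_new <- 0
    }
    w_new <- 2 * f * Omega * infl
    v_new <- if (model == "m2") {
      if (delta != 0) w_new * a / delta else 2 * f * Gamma * infl
    } else {
      0
    }
    V_F <- 2 * f^2 * V_Y * infl
    V_A <- 2 * a^2 * (d$kj$j + 2 * cis * h_new) +
      2 * delta^2 * (d$kj$k + 2 * cis * g_new) +
      8 * a * cis * i_new * delta
    V_Y_new <- V_A + V_F + 2 * (a * v_new + delta * w_new) + V_eps

    if (!is.finite(V_Y_new) || V_Y_new > 1e10) {
      abort(sprintf(
        paste0(
          "equilibrium recursion diverged at iteration %d ",
          "(delta = %g, a = %g, f = %g, %s = %g, V_eps = %g): ",
          "V_Y exceeds bound"
        ),
        it, delta, a, f,
        if (use_r_mate) "r_mate" else "mu",
        if (use_r_mate) r_mate else mu_fixed, V_eps
      ))
    }

    if (keep_trajectory) {
      traj[[it]] <- c(
        iter = it, g = g_new, h = h_new, i = i_new, w = w_new, v = v_new,
        Omega = Omega, Gamma = Gamma, V_Y = V_Y_new, V_F = V_F, mu = mu
      )
    }

    step <- max(abs(c(
      g_new - g, h_new - h, i_new - i,
      w_new - w, v_new - v, V_Y_new - V_Y
    )))
    g <- g_new; h <- h_new; i <- i_new
    w <- w_new; v <- v_new; V_Y <- V_Y_new
    n_iter <- it
    if (step < tol) {
      converged <- TRUE
      break
    }
  }

  if (!converged) {
    warn(sprintf(
      "equilibrium recursion did not converge in %d iterations (last change %.3g)",
      max_iter, step
    ))
  }

  # final consistency pass: recompute all derived quantities from the
  # converged state so that the equilibrium identities hold exactly
  d <- deriv(g, h, i, w, v, V_Y)
  mu <- d$mu
  Omega <- d$Omega
  Gamma <- d$Gamma
  infl <- 1 + mu * V_Y
  g <- Omega^2 * mu
  if (model == "m2") {
    if (delta != 0) {
      h <- g * a^2 / delta^2
      i <- g * a / delta
    } else {
      h <- Gamma^2 * mu
      i <- Omega * Gamma * mu
    }
  } else {
    h <- 0; i <- 0
  }
  w <- 2 * f * Omega * infl
  v <- if (model == "m2") {
    if (delta != 0) w * a / delta else 2 * f * Gamma * infl
  } else {
    0
  }
  kj <- base_constants(scaling, cis * g, cis * h)
  V_F <- 2 * f^2 * V_Y * infl
  V_A <- 2 * a^2 * (kj$j + 2 * cis * h) +
    2 * delta^2 * (kj$k + 2 * cis * g) + 8 * a * cis * i * delta
  V_Y <- V_A + V_F + 2 * (a * v + delta * w) + V_eps

  # offspring-score covariances; under disequilibrium only the trans chains
  # (via the mate's scores) contribute the AM-induced genetic terms
  am_gen <- if (diseq) 2 else 4
  theta_NT <- 2 * f * Omega * infl + am_gen * delta * g + am_gen * a * i
  theta_T <- theta_NT + 2 * delta * kj$k
  theta_LNT <- if (model == "m2") {
    2 * f * Gamma * infl + am_gen * a * h + am_gen * delta * i
  } else {
    0
  }
  theta_LT <- theta_LNT + if (model == "m2") 2 * a * kj$j else 0

  spousal_cor <- mu * V_Y
  if (abs(spousal_cor) >= 1) {
    abort(sprintf(
      "implied spousal correlation mu*V_Y = %.3f lies outside (-1, 1)",
      spousal_cor
    ))
  }

  structure(
    list(
      model = model, am_regime = am_regime, params = params,
      delta = delta, a = a, f = f, mu = mu, r_mate = spousal_cor,
      V_eps = V_eps, scaling = scaling,
      k = kj$k, j = if (model == "m2") kj$j else 0,
      g = g, h = h, i = i, w = w, v = v,
      Omega = Omega, Gamma = Gamma,
      V_Y = V_Y, V_F = V_F, V_A = V_A,
      theta_T = theta_T, theta_NT = theta_NT,
      theta_LT = theta_LT, theta_LNT = theta_LNT,
      n_iter = n_iter, converged = converged,
      trajectory = if (keep_trajectory) {
        as_tibble(do.call(rbind, traj[seq_len(n_iter)]))
      } else {
        NULL
      }
    ),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_state> model %s (%s), %s after %d iterations\n",
    x$model, x$am_regime,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  cat(sprintf(
    "  delta = %.4g, a = %.4g, f = %.4g, mu = %.4g (r_mate = %.4g)\n",
    x$delta, x$a, x$f, x$mu, x$r_mate
  ))
  cat(sprintf(
    "  V_Y = %.4g, V_F = %.4g, V_A = %.4g, w = %.4g, v = %.4g\n",
    x$V_Y, x$V_F, x$V_A, x$w, x$v
  ))
  cat(sprintf(
    "  g = %.4g, h = %.4g, i = %.4g, Omega = %.4g, Gamma = %.4g\n",
    x$g, x$h, x$i, x$Omega, x$Gamma
  ))
  cat(sprintf(
    "  theta_T = %.4g, theta_NT = %.4g\n", x$theta_T, x$theta_NT
  ))
  invisible(x)
}

#' @describeIn equilibrium_state one row per derived equilibrium quantity.
#' @param x an `equilibrium_state`.
#' @param ... unused.
#' @export
tidy.equilibrium_state <- function(x, ...) {
  vals <- c(
    delta = x$delta, a = x$a, f = x$f, mu = x$mu, r_mate = x$r_mate,
    V_eps = x$V_eps, k = x$k, j = x$j,
    g = x$g, h = x$h, i = x$i, w = x$w, v = x$v,
    Omega = x$Omega, Gamma = x$Gamma,
    V_Y = x$V_Y, V_F = x$V_F, V_A = x$V_A,
    theta_T = x$theta_T, theta_NT = x$theta_NT,
    theta_LT = x$theta_LT, theta_LNT = x$theta_LNT
  )
  tibble(quantity = names(vals), value = unname(vals))
}

#' @export
glance.equilibrium_state <- function(x, ...) {
  tibble(
    model = x$model, am_regime = x$am_regime,
    converged = x$converged, n_iter = x$n_iter,
    V_Y = x$V_Y, V_F = x$V_F, V_A = x$V_A,
    nurture_cov = 2 * (x$a * x$v + x$delta * x$w),
    r_mate = x$r_mate
  )
}
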