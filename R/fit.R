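#' Fit a parental-effects model to family data by FIML
#'
#' Maximizes the full-information likelihood over the free structural
#' parameters (Model 0: `delta`, `f`, `V_eps`; Model 1 adds the spousal
#' correlation; Model 2 adds the latent-score effect `a`), solving the
#' equilibrium fixed point inside every likelihood evaluation so the
#' nonlinear constraints among the derived quantities hold exactly by
#' construction. The optimizer works on transformed, unbounded scales
#' (`|f| <= 0.95`, `V_eps >= 1e-6`, spousal correlation magnitude
#' `<= 0.95`) and is restarted from jittered initializations.
#'
#' @param data family table (tibble / data frame) with a subset of columns
#'   `NT_p`, `T_p`, `NT_m`, `T_m`, `Y_o`, `Y_p`, `Y_m`; missing values
#'   allowed. Data are centered per variable before fitting.
#' @param model `"m0"`, `"m1"` or `"m2"`.
#' @param am_regime `"equilibrium"` or `"disequilibrium"`.
#' @param scaling scaling convention the scores are on; defaults to the
#'   table's `"scaling"` attribute or `"base_standardized"`.
#' @param use_parental_phenotypes use `Y_p`, `Y_m` (Model 2 only)? When
#'   `FALSE`, Model 2 requires `assumed_base_h2`.
#' @param assumed_base_h2 assumed base-population additive genetic variance
#'   on the standardized-trait scale (`a^2 + delta^2`); when supplied, `a`
#'   is derived as `sqrt(assumed_base_h2 - delta^2)` rather than estimated.
#'   Estimates of `w` and `V_F` are biased downward to the degree this value
#'   is set too high, and upward if too low.
#' @param se_method `"hessian"` (numerically differentiated observed
#'   information with delta-method propagation to derived quantities) or
#'   `"bootstrap"` (family resampling).
#' @param boot_reps bootstrap replicates when `se_method = "bootstrap"`.
#' @param n_starts number of jittered optimizer starts.
#' @param seed seed for start jitter and bootstrap.
#' @param control passed to [stats::optim()] (Nelder-Mead).
#'
#' @return A `nurture_fit` object: tibble of estimates and standard errors
#'   (structural and derived quantities), the equilibrium state and variance
#'   decomposition at the optimum, `-2 log L`, convergence diagnostics,
#'   boundary flags, and the per-pattern family counts. Use [tidy()] /
#'   [glance()] for tibble summaries.
#' @export
fit_model <- function(data,
                      model = c("m0", "m1", "m2"),
                      am_regime = c("equilibrium", "disequilibrium"),
                      scaling = NULL,
                      use_parental_phenotypes = TRUE,
                      assumed_base_h2 = NULL,
                      se_method = c("hessian", "bootstrap", "none"),
                      boot_reps = 200,
                      n_starts = 5,
                      seed = NULL,
                      control = list(maxit = 2000, reltol = 1e-10)) {
  model <- match.arg(model)
  am_regime <- match.arg(am_regime)
  se_method <- match.arg(se_method)
  scaling <- scaling %||% attr(data, "scaling") %||% "base_standardized"
  if (!is.null(seed)) set.seed(seed)

  if (model == "m2" && !use_parental_phenotypes && is.null(assumed_base_h2)) {
    abort("Model 2 without parental phenotypes requires assumed_base_h2")
  }
  if (!is.null(assumed_base_h2)) {
    stopifnot(assumed_base_h2 > 0, assumed_base_h2 < 1)
  }
  with_parents <- model == "m2" && use_parental_phenotypes

  vars <- fiml_variables(model, with_parents)
  vars <- intersect(vars, names(data))
  if (!"Y_o" %in% vars || length(intersect(c("T_p", "T_m"), vars)) == 0) {
    abort("data must contain Y_o and transmitted scores")
  }
  X <- as.matrix(data[vars])
  sds <- apply(X, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds < 1e-12)) {
    abort(sprintf(
      "degenerate input: variable(s) %s have zero variance",
      paste(vars[!is.finite(sds) | sds < 1e-12], collapse = ", ")
    ))
  }
  X <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  patterns <- fiml_patterns(X)
  n_fam <- sum(vapply(patterns, function(g) g$n, numeric(1)))

  free <- switch(model,
    m0 = c("delta", "tf", "lv"),
    m1 = c("delta", "tf", "lv", "tr"),
    m2 = if (is.null(assumed_base_h2)) {
      c("delta", "tf", "lv", "tr", "a")
    } else {
      c("delta", "tf", "lv", "tr")
    }
  )

  to_params <- function(theta) {
    th <- setNames(theta, free)
    delta <- th[["delta"]]
    a <- if ("a" %in% free) {
      th[["a"]]
    } else if (!is.null(assumed_base_h2)) {
      sqrt(max(assumed_base_h2 - delta^2, 0))
    } else {
      0
    }
    f <- 0.95 * tanh(th[["tf"]])
    V_eps <- 1e-6 + exp(th[["lv"]])
    r_mate <- if ("tr" %in% free) 0.95 * tanh(th[["tr"]]) else NULL
    model_params(
      delta = delta, a = a, f = f, r_mate = r_mate,
      V_eps = V_eps, scaling = scaling
    )
  }

  objective <- function(theta) {
    if (any(!is.finite(theta))) return(1e12)
    # assumed-a mode: keep delta^2 inside the assumed heritability
    if (!is.null(assumed_base_h2) && theta[1]^2 > assumed_base_h2) {
      return(1e10 + 1e6 * (theta[1]^2 - assumed_base_h2))
    }
    p <- tryCatch(to_params(theta), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    st <- tryCatch(
      suppressWarnings(equilibrium_state(
        p, model = model, am_regime = am_regime,
        tol = 1e-12, max_iter = 5000
      )),
      error = function(e) NULL
    )
    if (is.null(st) || !st$converged) return(1e12)
    Sigma <- tryCatch(
      implied_covariance(st, with_parents = with_parents)$cov,
      error = function(e) NULL
    )
    if (is.null(Sigma)) return(1e12)
    Sigma <- Sigma[vars, vars, drop = FALSE]
    val <- fiml_m2ll(Sigma, patterns)
    if (!is.finite(val)) return(1e12)
    val
  }

  # data-driven start values
  cc <- stats::complete.cases(X[, intersect(c("T_p", "NT_p", "T_m", "NT_m", "Y_o"), vars)])
  Scc <- if (sum(cc) > 10) cov(X[cc, , drop = FALSE]) else diag(length(vars))
  dimnames(Scc) <- list(vars, vars)
  th_T <- mean(c(
    if (all(c("T_p", "Y_o") %in% vars)) 2 * Scc["T_p", "Y_o"] else NA,
    if (all(c("T_m", "Y_o") %in% vars)) 2 * Scc["T_m", "Y_o"] else NA
  ), na.rm = TRUE)
  th_NT <- mean(c(
    if (all(c("NT_p", "Y_o") %in% vars)) 2 * Scc["NT_p", "Y_o"] else NA,
    if (all(c("NT_m", "Y_o") %in% vars)) 2 * Scc["NT_m", "Y_o"] else NA
  ), na.rm = TRUE)
  if (!is.finite(th_T)) th_T <- 0.3
  if (!is.finite(th_NT)) th_NT <- 0.05
  k0 <- attr(data, "k") %||% 0.5
  delta0 <- (th_T - th_NT) / (2 * k0)
  f0 <- min(max(th_NT / max(th_T, 1e-3), -0.6), 0.6)
  vy0 <- if ("Y_o" %in% vars) Scc["Y_o", "Y_o"] else 1
  veps0 <- max(0.3 * vy0, 1e-3)
  r0 <- if (all(c("Y_p", "Y_m") %in% vars)) {
    min(max(Scc["Y_p", "Y_m"] / sqrt(Scc["Y_p", "Y_p"] * Scc["Y_m", "Y_m"]), -0.8), 0.8)
  } else {
    0.1
  }
  a0 <- if (!is.null(assumed_base_h2)) 0 else max(sqrt(max(0.3 * vy0 - delta0^2, 0.01)), 0.05)

  start0 <- c(
    delta = delta0, tf = atanh(min(max(f0 / 0.95, -0.9), 0.9)),
    lv = log(veps0), tr = atanh(min(max(r0 / 0.95, -0.9), 0.9)), a = a0
  )[free]

  starts <- vector("list", n_starts)
  starts[[1]] <- start0
  if (n_starts > 1) {
    for (s in 2:n_starts) {
      starts[[s]] <- start0 + rnorm(length(free), 0, 0.25)
    }
  }

  runs <- purrr::map(starts, function(s) {
    o <- tryCatch(
      optim(s, objective, method = "Nelder-Mead", control = control),
      error = function(e) NULL
    )
    if (is.null(o)) return(NULL)
    # quasi-Newton polish
    o2 <- tryCatch(
      optim(o$par, objective, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(o2) && is.finite(o2$value) && o2$value <= o$value) o2 else o
  })
  runs <- purrr::compact(runs)
  if (!length(runs)) abort("all optimizer starts failed")
  vals <- vapply(runs, function(o) o$value, numeric(1))
  norms <- vapply(runs, function(o) sum(o$par^2), numeric(1))
  best <- order(vals, norms)[1]
  opt <- runs[[best]]
  if (opt$value >= 1e10) {
    abort("optimization failed: no admissible parameter region found")
  }

  params_hat <- to_params(opt$par)
  if (!is.null(assumed_base_h2) && params_hat$delta^2 > assumed_base_h2) {
    abort(sprintf(
      "assumed base heritability %.3f is below delta^2 = %.3f at the optimum",
      assumed_base_h2, params_hat$delta^2
    ))
  }
  state_hat <- equilibrium_state(params_hat, model = model, am_regime = am_regime)
  decomp <- decompose_variance(state_hat)

  derived_fun <- function(theta) {
    p <- to_params(theta)
    st <- suppressWarnings(
      equilibrium_state(p, model = model, am_regime = am_regime)
    )
    c(
      delta = p$delta, a = p$a, f = p$f, r_mate = st$r_mate, mu = st$mu,
      V_eps = p$V_eps, V_Y = st$V_Y, V_F = st$V_F, V_A = st$V_A,
      w = st$w, v = st$v,
      nurture_cov = 2 * (st$a * st$v + st$delta * st$w),
      eta = 2 * st$f * st$Omega,
      phi_eta = 2 * st$f * st$Omega * st$mu * st$V_Y,
      phi_delta = 4 * st$delta * st$g
    )
  }
  est <- derived_fun(opt$par)

  boundary <- character(0)
  if (abs(params_hat$f) > 0.94) boundary <- c(boundary, "f near bound |f| = 0.95")
  if (params_hat$V_eps < 1e-5) boundary <- c(boundary, "V_eps near lower bound")
  if (!is.null(params_hat$r_mate) && abs(params_hat$r_mate) > 0.94) {
    boundary <- c(boundary, "spousal correlation near bound 0.95")
  }
  if (length(boundary)) {
    warn(paste("boundary solution:", paste(boundary, collapse = "; ")))
  }

  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  se_used <- se_method
  if (se_method == "hessian") {
    se_try <- tryCatch(
      hessian_se(objective, opt$par, derived_fun),
      error = function(e) NULL
    )
    if (is.null(se_try)) {
      warn("observed information is singular; falling back to bootstrap standard errors")
      se_used <- "bootstrap"
    } else {
      se <- se_try
    }
  }
  boot <- NULL
  if (se_used == "bootstrap") {
    boot <- bootstrap_se(
      data, vars, opt$par, objective_factory = function(Xb) {
        pat_b <- fiml_patterns(Xb)
        function(theta) {
          p <- tryCatch(to_params(theta), error = function(e) NULL)
          if (is.null(p)) return(1e12)
          st <- tryCatch(
            suppressWarnings(equilibrium_state(p, model = model, am_regime = am_regime)),
            error = function(e) NULL
          )
          if (is.null(st) || !st$converged) return(1e12)
          Sg <- tryCatch(implied_covariance(st, with_parents = with_parents)$cov,
            error = function(e) NULL
          )
          if (is.null(Sg)) return(1e12)
          fiml_m2ll(Sg[vars, vars, drop = FALSE], pat_b)
        }
      },
      derived_fun = derived_fun, boot_reps = boot_reps
    )
    se <- boot$se
  }

  estimates <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se[names(est)]),
    class = ifelse(
      names(est) %in% c("delta", "a", "f", "r_mate", "V_eps"),
      "structural", "derived"
    )
  )

  structure(
    list(
      estimates = estimates,
      state = state_hat,
      decomposition = decomp,
      m2lnL = opt$value,
      logLik = -opt$value / 2,
      n_families = n_fam,
      patterns = tibble(
        pattern = vapply(patterns, function(g) {
          paste(vars[g$vars], collapse = "+")
        }, character(1)),
        n = vapply(patterns, function(g) g$n, numeric(1))
      ),
      model = model, am_regime = am_regime, scaling = scaling,
      assumed_base_h2 = assumed_base_h2,
      se_method = se_used,
      convergence = tibble(
        start = seq_along(vals), m2lnL = vals,
        code = vapply(runs, function(o) o$convergence, numeric(1)),
        best = seq_along(vals) == best
      ),
      boundary = boundary,
      bootstrap = boot$draws %||% NULL,
      par = opt$par
    ),
    class = "nurture_fit"
  )
}

# Observed-information standard errors on the natural/derived scale:
# var(theta_hat) = 2 H^{-1} for the -2 log L Hessian, propagated through the
# transformed-to-derived map by a central-difference Jacobian. Derived
# quantities that are strongly curved in the parameters (V_F is quadratic in
# f) get the second-order delta-method term 1/2 tr[(H_q V)^2], which keeps
# their standard errors from collapsing when the point estimate sits near
# the flat region of the map.
hessian_se <- function(objective, par, derived_fun) {
  H <- stats::optimHess(par, objective)
  V <- 2 * solve((H + t(H)) / 2)
  if (any(!is.finite(V)) || any(diag(V) <= 0)) {
    abort("singular information")
  }
  d0 <- derived_fun(par)
  p <- length(par)
  q <- length(d0)
  J <- matrix(0, q, p)
  hstep <- pmax(1e-4, 1e-4 * abs(par))
  for (k in seq_len(p)) {
    up <- par; up[k] <- up[k] + hstep[k]
    dn <- par; dn[k] <- dn[k] - hstep[k]
    J[, k] <- (derived_fun(up) - derived_fun(dn)) / (2 * hstep[k])
  }
  var1 <- diag(J %*% V %*% t(J))

  # numeric Hessian of each derived quantity over the parameter pairs
  var2 <- numeric(q)
  Hq <- array(0, c(q, p, p))
  f0 <- d0
  for (k in seq_len(p)) {
    for (l in k:p) {
      pp <- par; pp[k] <- pp[k] + hstep[k]; pp[l] <- pp[l] + hstep[l]
      pm <- par; pm[k] <- pm[k] + hstep[k]; pm[l] <- pm[l] - hstep[l]
      mp <- par; mp[k] <- mp[k] - hstep[k]; mp[l] <- mp[l] + hstep[l]
      mm <- par; mm[k] <- mm[k] - hstep[k]; mm[l] <- mm[l] - hstep[l]
      hkl <- (derived_fun(pp) - derived_fun(pm) - derived_fun(mp) + derived_fun(mm)) /
        (4 * hstep[k] * hstep[l])
      Hq[, k, l] <- hkl
      Hq[, l, k] <- hkl
    }
  }
  for (i in seq_len(q)) {
    M <- Hq[i, , ] %*% V
    var2[i] <- 0.5 * sum(M * t(M))
  }
  setNames(sqrt(pmax(var1 + pmax(var2, 0), 0)), names(d0))
}

bootstrap_se <- function(data, vars, par_hat, objective_factory, derived_fun,
                         boot_reps) {
  n <- nrow(data)
  draws <- matrix(NA_real_, boot_reps, length(derived_fun(par_hat)))
  colnames(draws) <- names(derived_fun(par_hat))
  for (b in seq_len(boot_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- as.matrix(data[idx, vars, drop = FALSE])
    Xb <- sweep(Xb, 2, colMeans(Xb, na.rm = TRUE))
    obj_b <- objective_factory(Xb)
    ob <- tryCatch(
      optim(par_hat, obj_b, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (!is.null(ob) && ob$value < 1e10) {
      draws[b, ] <- derived_fun(ob$par)
    }
  }
  list(
    se = apply(draws, 2, sd, na.rm = TRUE),
    draws = as_tibble(draws)
  )
}

#' Fit Model 2 with an assumed base-population heritability
#'
#' Convenience wrapper for fitting Model 2 without parental phenotypes: the
#' latent-score effect is derived from an assumed base-population additive
#' genetic variance via `a^2 = base_h2 - delta^2` during optimization.
#' Estimates of `w` and `V_F` are downwardly biased to the degree `base_h2`
#' is set too high (and vice-versa).
#'
#' @param data family table.
#' @param base_h2 assumed base-population additive genetic variance of the
#'   standardized trait, in (0, 1).
#' @param ... further arguments to [fit_model()].
#' @return A `nurture_fit`.
#' @export
fit_assumed_a <- function(data, base_h2, ...) {
  inform(paste(
    "assumed-heritability mode: w and V_F are biased downward if",
    "base_h2 is set too high, upward if too low"
  ))
  fit_model(
    data,
    model = "m2", use_parental_phenotypes = FALSE,
    assumed_base_h2 = base_h2, ...
  )
}

#' Standard errors of a fitted model
#'
#' Recomputes (or extracts) the standard-error table of a [fit_model()]
#' result. Derived quantities (`V_F`, `w`, `V_A`, ...) always carry
#' delta-method (or bootstrap) standard errors and are flagged as derived.
#'
#' @param fit a `nurture_fit`.
#' @param method `"hessian"` or `"bootstrap"` (default: whatever the fit
#'   used).
#' @return Tibble with `term`, `estimate`, `std.error`, `class`.
#' @export
standard_errors <- function(fit, method = NULL) {
  stopifnot(inherits(fit, "nurture_fit"))
  if (is.null(method) || identical(method, fit$se_method)) {
    return(fit$estimates)
  }
  abort("refit with fit_model(se_method = ...) to change the SE method")
}

#' @export
print.nurture_fit <- function(x, ...) {
  cat(sprintf(
    "<nurture_fit> model %s (%s), %d families, -2lnL = %.2f\n",
    x$model, x$am_regime, x$n_families, x$m2lnL
  ))
  if (!is.null(x$assumed_base_h2)) {
    cat(sprintf("  assumed base h2 = %.3f\n", x$assumed_base_h2))
  }
  est <- x$estimates
  key <- est[est$term %in% c("delta", "a", "f", "r_mate", "V_eps", "V_F", "w", "v", "V_A"), ]
  for (r in seq_len(nrow(key))) {
    cat(sprintf(
      "  %-8s %9.4f (SE %.4f)\n",
      key$term[r], key$estimate[r], key$std.error[r]
    ))
  }
  if (length(x$boundary)) {
    cat("  boundary:", paste(x$boundary, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @describeIn fit_model estimates and standard errors, one row per quantity.
#' @param x a `nurture_fit`.
#' @param ... unused.
#' @export
tidy.nurture_fit <- function(x, ...) {
  x$estimates
}

#' @describeIn fit_model one-row model-level summary.
#' @export
glance.nurture_fit <- function(x, ...) {
  est <- setNames(x$estimates$estimate, x$estimates$term)
  tibble(
    model = x$model, am_regime = x$am_regime,
    n_families = x$n_families,
    m2lnL = x$m2lnL, logLik = x$logLik,
    V_F = est[["V_F"]], V_A = est[["V_A"]], V_Y = est[["V_Y"]],
    nurture_cov = est[["nurture_cov"]],
    converged = any(x$convergence$code == 0 & x$convergence$best),
    boundary = length(x$boundary) > 0
  )
}
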