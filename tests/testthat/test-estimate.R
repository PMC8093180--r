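# FIML likelihood and model fitting.

test_that("FIML equals the direct multivariate-normal log-density", {
  # oracle: per-record zero-mean normal density over observed coordinates
  set.seed(5)
  st <- equilibrium_state(
    model_params(delta = 0.5, f = 0.2, V_eps = 0.545), model = "m0"
  )
  Sigma <- implied_covariance(st)$cov
  n <- 200
  L <- chol(Sigma)
  X <- matrix(rnorm(n * 5), n) %*% L
  colnames(X) <- colnames(Sigma)
  X[sample(length(X), 150)] <- NA
  X <- X[rowSums(!is.na(X)) > 0, ]
  Xc <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  direct <- sum(vapply(seq_len(nrow(Xc)), function(i) {
    obs <- which(!is.na(Xc[i, ]))
    S <- Sigma[obs, obs, drop = FALSE]
    x <- Xc[i, obs]
    -0.5 * (length(obs) * log(2 * pi) + determinant(S)$modulus +
      sum(x * solve(S, x)))
  }, numeric(1)))
  ll <- loglik_family(
    as_tibble(X),
    model_params(delta = 0.5, f = 0.2, V_eps = 0.545), model = "m0"
  )
  expect_equal(ll, direct, tolerance = 1e-8)
})

test_that("likelihood prefers the truth over perturbed parameters", {
  ft <- extract_family_table(pop_m0())
  dat <- ft[, c("NT_p", "T_p", "NT_m", "T_m", "Y_o")]
  p_true <- model_params(delta = 0.5, f = 0.2, V_eps = 0.545)
  p_off <- model_params(delta = 0.5, f = 0.3, V_eps = 0.545)
  expect_gt(
    loglik_family(dat, p_true, model = "m0"),
    loglik_family(dat, p_off, model = "m0")
  )
})

test_that("records with a single observed variable contribute univariate terms", {
  st <- equilibrium_state(
    model_params(delta = 0.5, f = 0.2, V_eps = 0.545), model = "m0"
  )
  set.seed(2)
  y <- rnorm(50, 0, sqrt(st$V_Y))
  dat <- tibble(
    NT_p = NA_real_, T_p = NA_real_, NT_m = NA_real_, T_m = NA_real_,
    Y_o = y
  )
  ll <- loglik_family(dat, model_params(delta = 0.5, f = 0.2, V_eps = 0.545),
    model = "m0")
  yc <- y - mean(y)
  expect_equal(ll, sum(dnorm(yc, 0, sqrt(st$V_Y), log = TRUE)), tolerance = 1e-8)
})

test_that("covariance entry point equals the record-level likelihood", {
  ft <- extract_family_table(pop_m0())
  vars <- c("NT_p", "T_p", "NT_m", "T_m", "Y_o")
  X <- as.matrix(ft[vars])
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / nrow(Xc)
  p <- model_params(delta = 0.5, f = 0.2, V_eps = 0.545)
  expect_equal(
    loglik_cov(S, nrow(Xc), p, model = "m0"),
    loglik_family(ft[vars], p, model = "m0"),
    tolerance = 1e-8
  )
})

test_that("just-identified Model 0 ML equals the closed form", {
  # with the haplotypic score block fixed at its constrained values, the
  # remaining three statistics determine the three free parameters exactly
  st <- equilibrium_state(
    model_params(delta = 0.45, f = 0.25, V_eps = 0.6), model = "m0"
  )
  S <- implied_covariance(st)$cov
  # perturb the informative cells to fake sampled moments
  S["Y_o", "T_p"] <- S["T_p", "Y_o"] <- S["T_p", "Y_o"] * 1.04
  S["Y_o", "NT_m"] <- S["NT_m", "Y_o"] <- S["NT_m", "Y_o"] * 0.95
  thT <- S["Y_o", "T_p"] + S["Y_o", "T_m"]
  thNT <- S["Y_o", "NT_p"] + S["Y_o", "NT_m"]
  cf <- closed_form_model0(thNT, thT, S["Y_o", "Y_o"])

  # ML via the covariance entry point
  obj <- function(theta) {
    tryCatch(
      -2 * loglik_cov(S, 10000,
        model_params(delta = theta[1], f = 0.95 * tanh(theta[2]),
          V_eps = exp(theta[3])),
        model = "m0"),
      error = function(e) 1e10
    )
  }
  opt <- optim(c(0.4, atanh(0.2 / 0.95), log(0.6)), obj,
    method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(opt$par[1], cf$delta, tolerance = 1e-4)
  expect_equal(0.95 * tanh(opt$par[2]), cf$f, tolerance = 1e-4)
})

test_that("Model 0 fit recovers simulated truth with sane SEs", {
  ft <- extract_family_table(pop_m0())
  fit <- fit_model(ft[, c("family_id", "T_p", "NT_p", "T_m", "NT_m", "Y_o")],
    model = "m0", se_method = "hessian", n_starts = 3, seed = 1)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  se <- setNames(fit$estimates$std.error, fit$estimates$term)
  expect_lt(abs(est[["f"]] - 0.2), 3 * se[["f"]])
  expect_lt(abs(est[["delta"]] - 0.5), 3 * se[["delta"]])
  expect_lt(abs(est[["V_F"]] - 0.08), 3 * se[["V_F"]])
  expect_true(all(is.finite(se[c("f", "delta", "V_F", "w")])))
  expect_equal(fit$n_families, nrow(ft))
  # derived quantities satisfy the equilibrium identity at the optimum
  expect_equal(est[["V_F"]],
    2 * est[["f"]]^2 * est[["V_Y"]] * (1 + est[["mu"]] * est[["V_Y"]]),
    tolerance = 1e-8)
  # tidy/glance interfaces
  expect_true(all(c("term", "estimate", "std.error") %in% names(tidy(fit))))
  expect_equal(glance(fit)$n_families, nrow(ft))
})

test_that("SE of V_F grows as the PGS explains less variance", {
  fits <- lapply(c(0.6, 0.3), function(d) {
    pop <- simulate_population(sim_config(
      n_families = 8000, m_obs = 30, m_lat = 0, delta = d, f = 0.2,
      V_eps = 0.5, n_generations = 8, seed = 900 + round(100 * d)
    ))
    ft <- extract_family_table(pop)
    fit_model(ft[, c("family_id", "T_p", "NT_p", "T_m", "NT_m", "Y_o")],
      model = "m0", se_method = "hessian", n_starts = 2, seed = 1)
  })
  se_vf <- vapply(fits, function(f) {
    f$estimates$std.error[f$estimates$term == "V_F"]
  }, numeric(1))
  expect_gt(se_vf[2], se_vf[1])
})

test_that("bootstrap and hessian standard errors broadly agree", {
  pop <- simulate_population(sim_config(
    n_families = 4000, m_obs = 30, m_lat = 0, delta = 0.5, f = 0.2,
    V_eps = 0.545, n_generations = 6, seed = 31
  ))
  ft <- extract_family_table(pop)[, c("family_id", "T_p", "NT_p", "T_m", "NT_m", "Y_o")]
  fh <- fit_model(ft, model = "m0", se_method = "hessian", n_starts = 2, seed = 3)
  fb <- fit_model(ft, model = "m0", se_method = "bootstrap", boot_reps = 100,
    n_starts = 2, seed = 3)
  for (term in c("f", "delta", "V_F")) {
    r <- fb$estimates$std.error[fb$estimates$term == term] /
      fh$estimates$std.error[fh$estimates$term == term]
    expect_gt(r, 0.65)
    expect_lt(r, 1.5)
  }
})

test_that("assumed-heritability mode recovers truth and shows the documented bias", {
  pop <- pop_m2()
  ft <- extract_family_table(pop)
  dat <- ft[, c("family_id", "T_p", "NT_p", "T_m", "NT_m", "Y_o")]
  truth <- equilibrium_state(params_m2(), model = "m2")

  suppressMessages({
    f_ok <- fit_model(dat, model = "m2", use_parental_phenotypes = FALSE,
      assumed_base_h2 = 0.5, se_method = "hessian", n_starts = 2, seed = 4)
    f_hi <- fit_model(dat, model = "m2", use_parental_phenotypes = FALSE,
      assumed_base_h2 = 0.6, se_method = "none", n_starts = 2, seed = 4)
  })
  est <- setNames(f_ok$estimates$estimate, f_ok$estimates$term)
  se <- setNames(f_ok$estimates$std.error, f_ok$estimates$term)
  # correct assumed h2 recovers V_F
  expect_lt(abs(est[["V_F"]] - truth$V_F), 3 * se[["V_F"]])
  # overstated h2 biases V_F downward (sign of bias only)
  est_hi <- setNames(f_hi$estimates$estimate, f_hi$estimates$term)
  expect_lt(est_hi[["V_F"]], est[["V_F"]])

  # with no latent genetics, assumed h2 = delta^2 reduces to Model 1
  pop0 <- pop_am()
  ft0 <- extract_family_table(pop0)
  dat0 <- ft0[, c("family_id", "T_p", "NT_p", "T_m", "NT_m", "Y_o")]
  f1 <- fit_model(dat0, model = "m1", se_method = "none", n_starts = 2, seed = 5)
  suppressMessages(
    fa <- fit_assumed_a(dat0, base_h2 = 0.5^2 + 1e-4, se_method = "none",
      n_starts = 2, seed = 5)
  )
  e1 <- setNames(f1$estimates$estimate, f1$estimates$term)
  ea <- setNames(fa$estimates$estimate, fa$estimates$term)
  expect_lt(abs(ea[["V_F"]] - e1[["V_F"]]), 0.02)
  expect_lt(abs(ea[["f"]] - e1[["f"]]), 0.04)
  # delta is capped at sqrt(base_h2) in assumed-a mode, so allow the
  # sampling fluctuation of the unconstrained Model 1 estimate
  expect_lt(abs(ea[["delta"]] - e1[["delta"]]), 0.04)
})

test_that("degenerate input errors instead of returning silent zeros", {
  ft <- extract_family_table(pop_m0())[1:200, ]
  ft$Y_o <- 1.7
  expect_error(
    fit_model(ft[, c("T_p", "NT_p", "T_m", "NT_m", "Y_o")], model = "m0"),
    "zero variance"
  )
})
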