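# Equilibrium expectations: scaling constants, fixed points, implied moments.

test_that("base constants follow the scaling convention", {
  expect_equal(base_constants("base_standardized", g = 0.03, h = 0.05),
    list(k = 0.5, j = 0.5))
  expect_equal(base_constants("full_pgs_standardized_now", g = 0.03, h = 0.05),
    list(k = 0.44, j = 0.40))
  expect_equal(base_constants("haplotypic_half_now", g = 0, h = 0),
    list(k = 0.5, j = 0.5))
  expect_error(base_constants("full_pgs_standardized_now", g = 0.25),
    "too strong")
})

test_that("Model 0 fixed point matches the closed-form solution", {
  # no VT, no AM: V_Y = 2 delta^2 k + V_eps
  st0 <- equilibrium_state(
    model_params(delta = 0.5, f = 0, V_eps = 0.5), model = "m0"
  )
  expect_equal(st0$Omega, 0.25)
  expect_equal(st0$theta_T, 0.5)
  expect_equal(st0$theta_NT, 0)
  expect_equal(st0$V_Y, 0.75)
  expect_equal(st0$g, 0)
  expect_equal(st0$w, 0)

  # with VT: Omega = delta / (2 (1 - f)), V_Y solves linearly
  st <- equilibrium_state(
    model_params(delta = 0.5, f = 0.2, V_eps = 0.545), model = "m0"
  )
  expect_true(st$converged)
  expect_equal(st$Omega, 0.3125, tolerance = 1e-9)
  expect_equal(st$w, 0.125, tolerance = 1e-9)
  expect_equal(st$theta_NT, 0.125, tolerance = 1e-9)
  expect_equal(st$theta_T, 0.625, tolerance = 1e-9)
  expect_equal(st$V_Y, 1.0, tolerance = 1e-9)
  expect_equal(st$V_F, 0.08, tolerance = 1e-9)
})

test_that("geometric-series identity: theta_NT/theta_T = f for Model 0", {
  # |f| < 1 makes the theta recursion converge; the variance model
  # additionally needs 2 f^2 < 1 (V_F < V_Y) for a finite equilibrium
  for (delta in c(0.2, 0.5, 0.9)) {
    for (f in c(-0.6, -0.2, 0.1, 0.45, 0.65)) {
      # independent oracle: iterate theta_NT = f*delta + f*theta_NT from 0
      th <- 0
      for (i in 1:2000) th <- f * delta + f * th
      expect_equal(th, delta * f / (1 - f), tolerance = 1e-10)
      st <- equilibrium_state(
        model_params(delta = delta, f = f, V_eps = 1), model = "m0"
      )
      expect_equal(st$theta_NT / st$theta_T, f, tolerance = 1e-10)
      expect_equal(st$theta_NT, delta * f / (1 - f), tolerance = 1e-9)
    }
  }
  # beyond that bound the phenotypic variance has no fixed point
  expect_error(
    equilibrium_state(model_params(delta = 0.2, f = 0.8, V_eps = 1), model = "m0"),
    "diverged"
  )
})

test_that("models nest: m1 at mu = 0 is m0; m2 at a = 0 is m1", {
  p <- model_params(delta = 0.4, f = 0.25, V_eps = 0.6)
  s0 <- equilibrium_state(p, model = "m0")
  s1 <- equilibrium_state(
    model_params(delta = 0.4, f = 0.25, mu = 0, V_eps = 0.6), model = "m1"
  )
  for (q in c("Omega", "w", "V_Y", "V_F", "theta_T", "theta_NT", "g")) {
    expect_equal(s1[[q]], s0[[q]], tolerance = 1e-12)
  }
  p1 <- model_params(delta = 0.4, f = 0.15, r_mate = 0.3, V_eps = 0.6)
  s1b <- equilibrium_state(p1, model = "m1")
  s2 <- equilibrium_state(
    model_params(delta = 0.4, a = 0, f = 0.15, r_mate = 0.3, V_eps = 0.6),
    model = "m2"
  )
  for (q in c("Omega", "w", "V_Y", "V_F", "theta_T", "theta_NT", "g", "h", "i", "v")) {
    expect_equal(s2[[q]], s1b[[q]], tolerance = 1e-12)
  }
})

test_that("AM inflates V_F by exactly (1 + mu V_Y)", {
  st <- equilibrium_state(
    model_params(delta = 0.5, f = 0.2, r_mate = 0.35, V_eps = 0.5),
    model = "m1"
  )
  # mu = 0 counterpart with the same f and V_Y has V_F = 2 f^2 V_Y
  expect_equal(st$V_F / (2 * st$f^2 * st$V_Y), 1 + st$mu * st$V_Y,
    tolerance = 1e-12)
  # and V_F exceeds the no-AM value computed at the same V_eps
  st_no <- equilibrium_state(
    model_params(delta = 0.5, f = 0.2, V_eps = 0.5), model = "m0"
  )
  expect_gt(st$V_F, st_no$V_F)
})

test_that("equilibrium identities hold at the fixed point on a grid", {
  grid <- expand.grid(
    delta = c(0.25, 0.5), a = c(0, 0.45),
    f = c(0, 0.15, 0.3), r = c(0, 0.2, 0.4)
  )
  for (row in seq_len(nrow(grid))) {
    gp <- grid[row, ]
    st <- equilibrium_state(
      model_params(
        delta = gp$delta, a = gp$a, f = gp$f,
        r_mate = if (gp$r > 0) gp$r else NULL, V_eps = 0.5
      ),
      model = if (gp$a > 0) "m2" else if (gp$r > 0) "m1" else "m0"
    )
    expect_true(st$converged)
    expect_equal(st$g, st$Omega^2 * st$mu, tolerance = 1e-10)
    expect_equal(st$i^2, st$g * st$h, tolerance = 1e-10)
    expect_equal(st$h * st$delta^2, st$g * st$a^2, tolerance = 1e-10)
    expect_equal(st$v * st$delta, st$w * st$a, tolerance = 1e-10)
    d <- decompose_variance(st)
    expect_equal(d$V_Y, d$V_A + d$V_F + d$nurture_cov + d$V_eps,
      tolerance = 1e-10)
    expect_equal(d$eta + d$phi_eta, st$w, tolerance = 1e-10)
    # with no AM all AM-induced covariances vanish
    if (gp$r == 0) {
      expect_equal(st$g, 0)
      expect_equal(st$h, 0)
      expect_equal(st$i, 0)
    }
  }
})

test_that("latent-score path tracing is self-consistent under base scaling", {
  st <- equilibrium_state(params_m2(), model = "m2")
  # Gamma/Omega = a/delta, hence h = Gamma^2 mu automatically
  expect_equal(st$Gamma * st$delta, st$Omega * st$a, tolerance = 1e-10)
  expect_equal(st$h, st$Gamma^2 * st$mu, tolerance = 1e-10)
})

test_that("implied covariance matrices are correct and PSD", {
  st0 <- equilibrium_state(
    model_params(delta = 0.5, f = 0, V_eps = 0.5), model = "m0"
  )
  im <- implied_covariance(st0)
  expect_equal(unname(diag(im$cov)), c(0.5, 0.5, 0.5, 0.5, 0.75))
  expect_equal(unname(im$cov["Y_o", c("T_p", "T_m")]), c(0.25, 0.25))
  expect_equal(unname(im$cov["Y_o", c("NT_p", "NT_m")]), c(0, 0))
  expect_equal(unname(im$cov["T_p", "NT_p"]), 0)

  # Model 1 at mu = 0 gives the identical matrix
  st1 <- equilibrium_state(
    model_params(delta = 0.5, f = 0, mu = 0, V_eps = 0.5), model = "m1"
  )
  expect_equal(implied_covariance(st1)$cov, im$cov, tolerance = 1e-12)

  # 7 x 7 with parents is symmetric PSD with copath cross-terms
  st2 <- equilibrium_state(params_m2(), model = "m2")
  im2 <- implied_covariance(st2)
  S <- im2$cov
  expect_equal(dim(S), c(7, 7))
  expect_equal(S, t(S))
  expect_equal(unname(S["Y_p", "Y_m"]), st2$mu * st2$V_Y^2, tolerance = 1e-12)
  expect_equal(unname(S["Y_p", "T_p"]), st2$Omega)
  expect_equal(unname(S["Y_p", "T_m"]), st2$Omega * st2$mu * st2$V_Y)
  expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
})

test_that("disequilibrium regime zeroes cis but keeps trans covariances", {
  p <- model_params(delta = 0.5, f = 0.1, r_mate = 0.3, V_eps = 0.6)
  std <- equilibrium_state(p, model = "m1", am_regime = "disequilibrium")
  S <- implied_covariance(std, with_parents = FALSE)$cov
  expect_equal(unname(S["T_p", "NT_p"]), 0)
  expect_equal(unname(S["T_m", "NT_m"]), 0)
  expect_equal(unname(S["T_p", "T_m"]), std$g)
  expect_equal(unname(diag(S)[1:4]), rep(std$k, 4))
  expect_gt(std$g, 0)
  # theta carries only the trans AM chains
  expect_equal(
    std$theta_NT,
    2 * std$f * std$Omega * (1 + std$mu * std$V_Y) + 2 * std$delta * std$g,
    tolerance = 1e-10
  )
})

test_that("variance decomposition reduces correctly without AM", {
  st <- equilibrium_state(
    model_params(delta = 0.5, f = 0.2, V_eps = 0.545), model = "m0"
  )
  d <- decompose_variance(st)
  expect_equal(d$V_A, 2 * 0.5^2 * 0.5)
  expect_equal(d$phi_eta, 0)
  expect_equal(d$phi_delta, 0)
  expect_equal(d$eta, st$w)
  expect_equal(d$V_A0, d$V_A)
})

test_that("closed-form Model 0 inverts the equilibrium expectations", {
  out <- closed_form_model0(theta_NT = 0.125, theta_T = 0.625, V_Y = 1)
  expect_equal(out$f, 0.2)
  expect_equal(out$delta, 0.5)
  expect_equal(out$w, 0.125)
  expect_equal(out$V_F, 0.08)

  out0 <- closed_form_model0(0, 0.5, 0.75)
  expect_equal(out0$f, 0)
  expect_equal(out0$V_F, 0)

  # delta cancels: rescaling both thetas leaves f unchanged
  for (c in c(0.2, 3)) {
    expect_equal(closed_form_model0(0.125 * c, 0.625 * c, 1)$f, 0.2)
  }
  expect_error(closed_form_model0(0.7, 0.6, 1), "outside")
  expect_error(closed_form_model0(0.1, 0, 1), "nonzero")
})

test_that("divergent parameter combinations raise with context", {
  expect_error(
    equilibrium_state(
      model_params(delta = 0.9, f = 0.9, r_mate = 0.9, V_eps = 2),
      model = "m1"
    ),
    "diverged|spousal"
  )
})

test_that("tidy and trajectory output are well-formed", {
  st <- equilibrium_state(params_m2(), model = "m2", keep_trajectory = TRUE)
  td <- tidy(st)
  expect_true(all(c("quantity", "value") %in% names(td)))
  expect_true(all(c("V_Y", "V_F", "g", "Gamma") %in% td$quantity))
  expect_s3_class(st$trajectory, "tbl_df")
  expect_equal(nrow(st$trajectory), st$n_iter)
})
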