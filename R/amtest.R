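# Moment-based tests of assortative-mating mechanisms.
#
# The four haplotypic PGS variances and six covariances collectively provide
# ten estimates of g, the AM-induced haplotypic covariance: 4 variance-based
# (var([N]T_*) - k), 2 cis (within-person, cov(T_*, NT_*)), and 4 trans
# (across mates). The cis group (variances + within-person covariances, 6
# estimates) and the trans group (4) agree at AM equilibrium; trans > cis
# indicates disequilibrium (recent onset) assortment.

g_labels <- function() {
  tibble(
    label = c(
      "var_T_p", "var_NT_p", "var_T_m", "var_NT_m",
      "cov_T_p_NT_p", "cov_T_m_NT_m",
      "cov_T_p_T_m", "cov_T_p_NT_m", "cov_NT_p_T_m", "cov_NT_p_NT_m"
    ),
    group = c(rep("cis", 6), rep("trans", 4))
  )
}

# X has columns T_p, NT_p, T_m, NT_m (in that order)
g_moments <- function(X, k) {
  C <- cov(X)
  c(
    C[1, 1] - k, C[2, 2] - k, C[3, 3] - k, C[4, 4] - k,
    C[1, 2], C[3, 4],
    C[1, 3], C[1, 4], C[2, 3], C[2, 4]
  )
}

#' The ten moment-based estimates of the AM-induced covariance g
#'
#' Computes the ten haplotypic-PGS moment estimates of `g` with their
#' sampling covariance (family-level nonparametric bootstrap; the ten
#' moments share families and are strongly dependent).
#'
#' @param data family table with complete PGS quadruples in columns `T_p`,
#'   `NT_p`, `T_m`, `NT_m` (incomplete rows are dropped).
#' @param scaling scaling convention of the scores (defaults to the table's
#'   attribute). Under `"base_standardized"` the base-generation variance
#'   must be known: supply `k` (e.g. `0.5` for simulator output); otherwise
#'   the variance-based estimates are excluded with a warning. Under the
#'   current-generation conventions `k` is resolved jointly with `g` from
#'   the observed cis moments.
#' @param k known base-population haplotypic variance, if any.
#' @param vcov_method `"influence"` (default): the asymptotic covariance of
#'   the ten sample (co)variances estimated from the per-family influence
#'   products (empirical fourth moments) — deterministic and well calibrated;
#'   `"bootstrap"`: family-level nonparametric bootstrap.
#' @param boot_reps bootstrap replicates (bootstrap method only).
#' @param seed optional seed for the bootstrap.
#' @return A `g_estimates` object: tibble with `label`, `group`
#'   (cis/trans), `estimate`, `std.error`; attributes `vcov`, `k`, `n`.
#' @export
g_estimates <- function(data, scaling = NULL, k = NULL,
                        vcov_method = c("influence", "bootstrap"),
                        boot_reps = 500, seed = NULL) {
  vcov_method <- match.arg(vcov_method)
  scaling <- scaling %||% attr(data, "scaling") %||% "base_standardized"
  k <- k %||% attr(data, "k")
  score_cols <- c("T_p", "NT_p", "T_m", "NT_m")
  stopifnot(all(score_cols %in% names(data)))
  X <- as.matrix(data[score_cols])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 30) abort("need at least 30 complete PGS quadruples")
  if (!is.null(seed)) set.seed(seed)

  drop_var <- FALSE
  if (is.null(k)) {
    if (scaling == "base_standardized") {
      warn(paste(
        "base-generation variance unknown under base_standardized scaling;",
        "variance-based g estimates excluded"
      ))
      drop_var <- TRUE
      k <- NA_real_
    } else {
      ft <- as_tibble(X)
      k <- resolve_k(ft, scaling)
    }
  }

  labs <- g_labels()
  est <- g_moments(X, if (drop_var) 0 else k)
  keep <- if (drop_var) 5:10 else 1:10
  labs <- labs[keep, ]
  est <- est[keep]

  if (vcov_method == "influence") {
    # per-family influence products of the centered scores; the sampling
    # covariance of the sample (co)variances is cov of these / n
    Xc <- sweep(X, 2, colMeans(X))
    pairs <- list(
      c(1, 1), c(2, 2), c(3, 3), c(4, 4),
      c(1, 2), c(3, 4), c(1, 3), c(1, 4), c(2, 3), c(2, 4)
    )[keep]
    Z <- vapply(pairs, function(p) Xc[, p[1]] * Xc[, p[2]], numeric(n))
    V <- cov(Z) / n
  } else {
    B <- boot_reps
    draws <- matrix(NA_real_, B, length(est))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      draws[b, ] <- g_moments(X[idx, , drop = FALSE], if (drop_var) 0 else k)[keep]
    }
    V <- cov(draws)
  }

  out <- labs
  out$estimate <- est
  out$std.error <- sqrt(diag(V))
  structure(
    out,
    vcov = V, k = k, n = n, vcov_method = vcov_method, scaling = scaling,
    class = c("g_estimates", class(out))
  )
}

# mean of a subset of the (correlated) estimates as a weight vector
mean_weights <- function(p, subset) {
  w <- rep(0, p)
  w[subset] <- 1 / length(subset)
  w
}

#' Test whether the mean g estimate exceeds zero
#'
#' Wald chi-squared(1) test on the average of the available `g` estimates
#' (variance from the full sampling covariance of the ten); a significantly
#' positive mean indicates that mate similarity (on this trait or one
#' genetically correlated with it) has produced gametic phase
#' disequilibrium, as primary AM predicts. The chi-squared p-value is
#' two-sided in form; for the directional hypothesis `g > 0` halve it when
#' the mean is positive.
#'
#' @param g a [g_estimates()] object.
#' @return One-row tibble: `mean_g`, `se`, `statistic`, `p_value`,
#'   `p_one_sided`.
#' @export
test_g_nonzero <- function(g) {
  stopifnot(inherits(g, "g_estimates"))
  V <- attr(g, "vcov")
  w <- mean_weights(nrow(g), seq_len(nrow(g)))
  m <- sum(w * g$estimate)
  v <- as.numeric(t(w) %*% V %*% w)
  stat <- m^2 / v
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tibble(
    mean_g = m, se = sqrt(v), statistic = stat, p_value = p,
    p_one_sided = ifelse(m > 0, p / 2, 1 - p / 2)
  )
}

#' Test equality of cis and trans g estimates
#'
#' Wald chi-squared(1) test of the difference between the average cis
#' (within-person) and trans (across-mate) `g` estimates, with the variance
#' of the difference taken from the full sampling covariance. At AM
#' equilibrium the two are equal; significantly larger trans estimates
#' indicate disequilibrium (AM of recent onset — a single generation of AM
#' gives trans > 0 with cis near 0).
#'
#' @param g a [g_estimates()] object containing both groups.
#' @return One-row tibble: `cis_mean`, `trans_mean`, `difference`, `se`,
#'   `statistic`, `p_value`, `direction`.
#' @export
test_cis_trans <- function(g) {
  stopifnot(inherits(g, "g_estimates"))
  ci <- which(g$group == "cis")
  tr <- which(g$group == "trans")
  if (!length(ci) || !length(tr)) abort("need both cis and trans estimates")
  V <- attr(g, "vcov")
  w_c <- mean_weights(nrow(g), ci)
  w_t <- mean_weights(nrow(g), tr)
  m_c <- sum(w_c * g$estimate)
  m_t <- sum(w_t * g$estimate)
  d <- w_c - w_t
  v <- as.numeric(t(d) %*% V %*% d)
  stat <- (m_c - m_t)^2 / v
  tibble(
    cis_mean = m_c, trans_mean = m_t,
    difference = m_c - m_t, se = sqrt(v),
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    direction = ifelse(m_t > m_c, "trans>cis (disequilibrium-like)", "cis>=trans")
  )
}

#' Compare observed spousal covariance with the g-implied value
#'
#' Social homogamy (mate similarity through environmental similarity)
#' predicts an observed `cov(Y_p, Y_m)` higher than the value implied by the
#' genetic `g` estimates; genetic homogamy (assortment on a trait more
#' genetically than phenotypically correlated with the measured one)
#' predicts a lower observed value. The implied value is `mu V_Y^2` with
#' `mu` recovered from `g = Omega^2 mu` and `Omega` estimated from
#' `cov(Y_*, [N]T_*)`.
#'
#' @param data family table with parental phenotypes (`Y_p`, `Y_m`) and the
#'   four scores.
#' @param g optional [g_estimates()] (recomputed if missing).
#' @param boot_reps bootstrap replicates for the CI of the difference.
#' @param alpha CI level is `1 - alpha`.
#' @param seed optional seed.
#' @param ... passed to [g_estimates()] when it is recomputed.
#' @return One-row tibble: `observed`, `implied`, `difference`, `conf.low`,
#'   `conf.high`, `label` in consistent / social-homogamy-like /
#'   genetic-homogamy-like.
#' @export
homogamy_diagnostic <- function(data, g = NULL, boot_reps = 500,
                                alpha = 0.05, seed = NULL, ...) {
  cols <- c("T_p", "NT_p", "T_m", "NT_m", "Y_p", "Y_m")
  stopifnot(all(cols %in% names(data)))
  X <- as.matrix(data[cols])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 30) {
    inform("fewer than 30 families with parental phenotypes; homogamy diagnostic skipped")
    return(tibble(
      observed = NA_real_, implied = NA_real_, difference = NA_real_,
      conf.low = NA_real_, conf.high = NA_real_, label = "skipped"
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(g)) g <- g_estimates(data, ...)

  stat_fun <- function(X) {
    obs <- cov(X[, "Y_p"], X[, "Y_m"])
    Omega <- mean(c(
      cov(X[, "Y_p"], X[, "T_p"]), cov(X[, "Y_p"], X[, "NT_p"]),
      cov(X[, "Y_m"], X[, "T_m"]), cov(X[, "Y_m"], X[, "NT_m"])
    ))
    V_Y <- mean(c(var(X[, "Y_p"]), var(X[, "Y_m"])))
    k_here <- attr(g, "k")
    gm <- g_moments(X[, 1:4, drop = FALSE], if (is.na(k_here)) 0 else k_here)
    gbar <- mean(if (is.na(k_here)) gm[5:10] else gm)
    mu_hat <- gbar / Omega^2
    implied <- mu_hat * V_Y^2
    c(observed = obs, implied = implied, diff = obs - implied)
  }

  pt <- stat_fun(X)
  n <- nrow(X)
  B <- boot_reps
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    diffs[b] <- stat_fun(X[idx, , drop = FALSE])[["diff"]]
  }
  ci <- quantile(diffs, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  label <- if (ci[1] <= 0 && ci[2] >= 0) {
    "consistent"
  } else if (pt[["diff"]] > 0) {
    "social-homogamy-like"
  } else {
    "genetic-homogamy-like"
  }
  tibble(
    observed = pt[["observed"]], implied = pt[["implied"]],
    difference = pt[["diff"]],
    conf.low = unname(ci[1]), conf.high = unname(ci[2]),
    label = label
  )
}

#' Full assortative-mating mechanism report
#'
#' Runs the `g > 0` and cis-vs-trans tests (and, when parental phenotypes
#' are available, the homogamy diagnostic) and issues the
#' single-generation-AM verdict: trans estimates significantly positive
#' while cis estimates are not.
#'
#' @param data family table.
#' @param alpha significance level for the verdicts (no multiple-testing
#'   correction across the battery; the three tests are reported jointly and
#'   labeled).
#' @param ... passed to [g_estimates()].
#' @return An `am_report` object (list of the component results plus
#'   verdicts); `tidy()` gives the test table.
#' @export
am_test_report <- function(data, alpha = 0.05, ...) {
  g <- g_estimates(data, ...)
  t_nonzero <- test_g_nonzero(g)
  t_ct <- test_cis_trans(g)

  V <- attr(g, "vcov")
  ci <- which(g$group == "cis")
  tr <- which(g$group == "trans")
  w_t <- mean_weights(nrow(g), tr)
  m_t <- sum(w_t * g$estimate)
  se_t <- sqrt(as.numeric(t(w_t) %*% V %*% w_t))
  w_c <- mean_weights(nrow(g), ci)
  m_c <- sum(w_c * g$estimate)
  se_c <- sqrt(as.numeric(t(w_c) %*% V %*% w_c))
  p_trans_pos <- stats::pnorm(m_t / se_t, lower.tail = FALSE)
  p_cis <- pchisq((m_c / se_c)^2, 1, lower.tail = FALSE)
  single_gen <- (p_trans_pos < alpha) && (p_cis >= alpha)

  hom <- if (all(c("Y_p", "Y_m") %in% names(data)) &&
    sum(stats::complete.cases(data[c("Y_p", "Y_m", "T_p", "NT_p", "T_m", "NT_m")])) >= 30) {
    homogamy_diagnostic(data, g = g)
  } else {
    NULL
  }

  structure(
    list(
      g = g,
      test_g_nonzero = t_nonzero,
      test_cis_trans = t_ct,
      trans_mean = m_t, trans_se = se_t,
      cis_mean = m_c, cis_se = se_c,
      single_generation_am = single_gen,
      homogamy = hom,
      alpha = alpha
    ),
    class = "am_report"
  )
}

#' @export
print.am_report <- function(x, ...) {
  cat("<am_report>\n")
  cat(sprintf(
    "  mean g = %.4f (chi2(1) = %.2f, p = %.3g)\n",
    x$test_g_nonzero$mean_g, x$test_g_nonzero$statistic, x$test_g_nonzero$p_value
  ))
  cat(sprintf(
    "  cis = %.4f, trans = %.4f (chi2(1) = %.2f, p = %.3g) %s\n",
    x$test_cis_trans$cis_mean, x$test_cis_trans$trans_mean,
    x$test_cis_trans$statistic, x$test_cis_trans$p_value,
    x$test_cis_trans$direction
  ))
  cat(sprintf(
    "  single-generation-AM verdict: %s\n",
    if (x$single_generation_am) "YES (trans > 0, cis ~ 0)" else "no"
  ))
  if (!is.null(x$homogamy)) {
    cat(sprintf(
      "  spousal covariance observed %.4f vs implied %.4f: %s\n",
      x$homogamy$observed, x$homogamy$implied, x$homogamy$label
    ))
  }
  invisible(x)
}

#' @describeIn am_test_report the two chi-squared tests as a tibble.
#' @param x an `am_report`.
#' @param ... unused.
#' @export
tidy.am_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(
      test = "g_nonzero",
      statistic = x$test_g_nonzero$statistic,
      p_value = x$test_g_nonzero$p_value,
      estimate = x$test_g_nonzero$mean_g
    ),
    tibble(
      test = "cis_vs_trans",
      statistic = x$test_cis_trans$statistic,
      p_value = x$test_cis_trans$p_value,
      estimate = x$test_cis_trans$difference
    )
  )
}
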