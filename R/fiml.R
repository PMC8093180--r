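# Full-information maximum likelihood machinery.
#
# Families contribute the zero-mean multivariate-normal log-density of
# whichever variables they have observed. Families are grouped by
# missingness pattern once; each likelihood evaluation then only needs the
# per-pattern second-moment matrices, which makes the nested
# optimization (outer search over structural parameters, inner equilibrium
# solve) cheap.

fiml_variables <- function(model, with_parents) {
  v <- c("NT_p", "T_p", "NT_m", "T_m", "Y_o")
  if (model == "m2" && with_parents) v <- c(v, "Y_p", "Y_m")
  v
}

# Precompute per-missingness-pattern sufficient statistics from a centered
# data matrix: n_g and S_g = sum_i x_i x_i' / n_g over observed coordinates.
fiml_patterns <- function(X) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  pat <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  split_idx <- split(seq_len(nrow(X)), pat)
  lapply(split_idx, function(ii) {
    mask <- obs[ii[1], ]
    Xg <- X[ii, mask, drop = FALSE]
    list(
      vars = which(mask),
      n = length(ii),
      S = crossprod(Xg) / length(ii)
    )
  })
}

# -2 log-likelihood given a full implied covariance matrix and precomputed
# pattern statistics. Returns +Inf (with attribute) for non-PD submatrices.
fiml_m2ll <- function(Sigma, patterns) {
  total <- 0
  for (g in patterns) {
    Sg <- Sigma[g$vars, g$vars, drop = FALSE]
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) {
      out <- Inf
      attr(out, "npd") <- TRUE
      return(out)
    }
    logdet <- 2 * sum(log(diag(ch)))
    tr <- sum(chol2inv(ch) * g$S)
    p <- length(g$vars)
    total <- total + g$n * (p * log(2 * pi) + logdet + tr)
  }
  total
}

#' Log-likelihood of family data under a parental-effects model
#'
#' Evaluates the full-information maximum likelihood (FIML) log-likelihood of
#' a family table at a given set of structural parameters: each family
#' contributes the zero-mean multivariate-normal log-density restricted to
#' its observed variables, with the covariance implied by the equilibrium
#' state of the parameters. Data are centered per variable first.
#'
#' @param data family table with (a subset of) columns `NT_p`, `T_p`,
#'   `NT_m`, `T_m`, `Y_o`, `Y_p`, `Y_m`; missing values allowed.
#' @param params a [model_params()] object.
#' @param model,am_regime model and AM regime, as in [equilibrium_state()].
#' @param with_parents include parental phenotypes (Model 2)?
#' @return The log-likelihood (a scalar; `-Inf` with a message when the
#'   implied covariance is not positive definite).
#' @examples
#' pop <- simulate_population(sim_config(
#'   n_families = 300, m_obs = 20, m_lat = 0,
#'   delta = 0.5, f = 0.2, V_eps = 0.545, n_generations = 2, seed = 1
#' ))
#' ft <- extract_family_table(pop)
#' p <- model_params(delta = 0.5, f = 0.2, V_eps = 0.545)
#' loglik_family(ft, p, model = "m0")
#' @export
loglik_family <- function(data, params, model = NULL,
                          am_regime = "equilibrium",
                          with_parents = TRUE) {
  st <- equilibrium_state(params, model = model, am_regime = am_regime)
  vars <- fiml_variables(st$model, with_parents)
  vars <- intersect(vars, names(data))
  X <- as.matrix(data[vars])
  X <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  patterns <- fiml_patterns(X)
  Sigma <- implied_covariance(st, with_parents = with_parents)$cov
  Sigma <- Sigma[vars, vars, drop = FALSE]
  -0.5 * fiml_m2ll(Sigma, patterns)
}

#' @describeIn loglik_family covariance-matrix entry point: the Wishart-based
#'   `-2 log L` for a sample covariance matrix `S` (maximum-likelihood
#'   denominator `n`) of complete data; equals the record-level value on
#'   complete centered data.
#' @param S sample covariance (ML denominator) of the observed variables,
#'   with dimnames naming them.
#' @param n number of families behind `S`.
#' @export
loglik_cov <- function(S, n, params, model = NULL,
                       am_regime = "equilibrium") {
  st <- equilibrium_state(params, model = model, am_regime = am_regime)
  vars <- rownames(S)
  Sigma <- implied_covariance(
    st,
    with_parents = any(c("Y_p", "Y_m") %in% vars)
  )$cov
  if (!all(vars %in% rownames(Sigma))) {
    abort("S has variables outside the model")
  }
  Sigma <- Sigma[vars, vars, drop = FALSE]
  patterns <- list(list(vars = seq_along(vars), n = n, S = S))
  colnames(patterns[[1]]$S) <- rownames(patterns[[1]]$S) <- NULL
  -0.5 * fiml_m2ll(Sigma, patterns)
}
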