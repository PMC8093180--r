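#' Scaling conventions for haplotypic polygenic scores
#'
#' The base-population variance of a haplotypic PGS (`k`) and of a haplotypic
#' latent genetic score (`j`) are fixed constants, not estimated quantities;
#' their values depend on how the user scales the scores.
#'
#' @details
#' Three conventions are supported:
#' \describe{
#'   \item{`base_standardized`}{the full PGS has unit variance in the base
#'     population (before any assortative mating or vertical transmission);
#'     `k = 1/2` and `j = 1/2`. Mostly useful for simulated data or when
#'     there is no assortative mating.}
#'   \item{`full_pgs_standardized_now`}{the full PGS (`T + NT`) is
#'     standardized in the current generation; `k = 1/2 - 2g` and
#'     `j = 1/2 - 2h`. The usual choice for real data.}
#'   \item{`haplotypic_half_now`}{each haplotypic PGS is scaled to variance
#'     `1/2` in the current generation; `k = 1/2 - g`, `j = 1/2 - h`.}
#' }
#' Here `g` and `h` are the AM-induced increases in the haplotypic PGS and
#' LGS (co)variances. Parameter estimates other than the score scale are
#' unaffected by the convention so long as `k` is consistent with how the
#' scores were scaled.
#'
#' @param scaling one of `"base_standardized"`, `"full_pgs_standardized_now"`,
#'   `"haplotypic_half_now"` (prefix matching allowed).
#' @param g,h nonnegative AM-induced haplotypic (co)variance increments.
#'
#' @return A named list with elements `k` and `j`.
#' @examples
#' base_constants("base_standardized")
#' base_constants("full_pgs_standardized_now", g = 0.03, h = 0.05)
#' @export
base_constants <- function(scaling = c(
                             "base_standardized",
                             "full_pgs_standardized_now",
                             "haplotypic_half_now"
                           ),
                           g = 0, h = 0) {
  scaling <- match.arg(scaling)
  stopifnot(is.numeric(g), is.numeric(h), g >= 0, h >= 0)
  out <- switch(scaling,
    base_standardized = list(k = 0.5, j = 0.5),
    full_pgs_standardized_now = list(k = 0.5 - 2 * g, j = 0.5 - 2 * h),
    haplotypic_half_now = list(k = 0.5 - g, j = 0.5 - h)
  )
  if (out$k <= 0 || out$j < 0 || (out$j <= 0 && (h > 0))) {
    abort(sprintf(
      "scaling '%s' implies k = %.4g, j = %.4g; assortative mating is too strong for this convention",
      scaling, out$k, out$j
    ))
  }
  out
}

#' Structural parameters of the parental-effects models
#'
#' Bundles the free structural parameters of the transmitted/nontransmitted
#' PGS models: `delta` (effect of a haplotypic PGS on the phenotype), `a`
#' (effect of a haplotypic latent genetic score), `f` (vertical-transmission
#' path from each parental phenotype to the offspring familial environment),
#' the assortative-mating copath `mu` (or, more conveniently, the spousal
#' phenotypic correlation `r_mate = mu * V_Y`), and the residual variance
#' `V_eps`.
#'
#' @param delta effect of one haplotypic PGS on the phenotype.
#' @param a effect of one haplotypic latent genetic score (LGS) on the
#'   phenotype; `0` for Models 0 and 1.
#' @param f vertical-transmission path coefficient; `|f| < 1`.
#' @param mu assortative-mating copath coefficient,
#'   `cov(Y_p, Y_m) / V_Y^2`. Supply either `mu` or `r_mate`, not both.
#' @param r_mate spousal phenotypic correlation (`mu * V_Y`); converted to
#'   `mu` inside the equilibrium solve. Usually the more intuitive choice.
#' @param V_eps residual (unique environmental) variance; `> 0`.
#' @param scaling scaling convention, see [base_constants()].
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(delta = 0.5, f = 0.2, V_eps = 0.545)
#' model_params(delta = 0.3, a = 0.55, f = 0.12, r_mate = 0.3, V_eps = 0.4)
#' @export
model_params <- function(delta, a = 0, f = 0, mu = NULL, r_mate = NULL,
                         V_eps,
                         scaling = c(
                           "base_standardized",
                           "full_pgs_standardized_now",
                           "haplotypic_half_now"
                         )) {
  scaling <- match.arg(scaling)
  if (!is.null(mu) && !is.null(r_mate)) {
    abort("supply either `mu` or `r_mate`, not both")
  }
  stopifnot(
    is.numeric(delta), length(delta) == 1L, is.finite(delta),
    is.numeric(a), length(a) == 1L, is.finite(a),
    is.numeric(f), length(f) == 1L, abs(f) < 1,
    is.numeric(V_eps), length(V_eps) == 1L, V_eps > 0
  )
  if (!is.null(r_mate)) {
    stopifnot(is.numeric(r_mate), length(r_mate) == 1L, abs(r_mate) < 1)
  }
  if (!is.null(mu)) {
    stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  }
  structure(
    list(
      delta = delta, a = a, f = f,
      mu = mu, r_mate = r_mate,
      V_eps = V_eps, scaling = scaling
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  delta = %g, a = %g, f = %g\n", x$delta, x$a, x$f))
  if (!is.null(x$r_mate)) {
    cat(sprintf("  mate correlation r_mate = %g\n", x$r_mate))
  } else if (!is.null(x$mu)) {
    cat(sprintf("  AM copath mu = %g\n", x$mu))
  } else {
    cat("  no assortative mating (mu = 0)\n")
  }
  cat(sprintf("  V_eps = %g, scaling = %s\n", x$V_eps, x$scaling))
  invisible(x)
}
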