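#' Configuration for the forward-time family simulator
#'
#' The simulator is a variant-level forward-in-time engine: a base population
#' with causal variants in linkage equilibrium, followed by generations of
#' primary phenotypic assortative mating, vertical transmission, and Mendelian
#' transmission with free recombination. It serves as the independent oracle
#' for the analytic equilibrium expectations and the estimators.
#'
#' @param n_families number of mated couples per generation; each couple
#'   produces exactly two offspring (one male, one female), keeping the
#'   population size constant at `2 * n_families`.
#' @param m_obs number of observed causal variants (those entering the PGS).
#' @param m_lat number of latent causal variants (the LGS; `0` means the PGS
#'   captures the full heritability).
#' @param maf_range allele-frequency interval, bounds in (0, 0.5].
#' @param delta,a,f structural coefficients on the base-population scale
#'   (haplotypic scores standardized to variance 1/2 in generation 0).
#' @param r_mate target spousal phenotypic correlation, in `[0, 1)`.
#' @param V_eps residual variance.
#' @param n_generations number of mated generations after the base
#'   population (generation 0).
#' @param am_onset first generation index (1-based mating round) at which
#'   assortative mating acts; earlier matings are random. `am_onset =
#'   n_generations` gives exactly one generation of AM (a disequilibrium
#'   scenario).
#' @param seed integer seed; identical configurations give bit-identical
#'   populations.
#' @param store `"all"` keeps every generation's score table; `"last"` keeps
#'   only the final generation and its parents (memory-lean for large runs).
#'   Per-generation summary moments are always kept.
#'
#' @return A `sim_config` object.
#' @examples
#' sim_config(n_families = 500, delta = 0.5, f = 0.2, V_eps = 0.545, seed = 1)
#' @export
sim_config <- function(n_families,
                       m_obs = 50, m_lat = 50,
                       maf_range = c(0.1, 0.5),
                       delta, a = 0, f = 0,
                       r_mate = 0, V_eps,
                       n_generations = 15,
                       am_onset = 1,
                       seed = NULL,
                       store = c("all", "last")) {
  store <- match.arg(store)
  stopifnot(
    n_families >= 2, m_obs >= 1, m_lat >= 0,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    r_mate >= 0, r_mate < 1, V_eps > 0,
    n_generations >= 1, am_onset >= 1, am_onset <= n_generations
  )
  if (a != 0 && m_lat < 1) {
    abort("a != 0 requires m_lat >= 1")
  }
  structure(
    list(
      n_families = as.integer(n_families),
      m_obs = as.integer(m_obs), m_lat = as.integer(m_lat),
      maf_range = maf_range,
      delta = delta, a = a, f = f,
      r_mate = r_mate, V_eps = V_eps,
      n_generations = as.integer(n_generations),
      am_onset = as.integer(am_onset),
      seed = seed, store = store
    ),
    class = "sim_config"
  )
}

#' Pair mates to a target phenotypic correlation
#'
#' Primary phenotypic assortment: a bivariate Gaussian copula is imposed on
#' the phenotype ranks. Couples are formed by drawing latent standard-normal
#' pairs with the target correlation and matching the rank of each latent
#' coordinate to the corresponding phenotype rank, which achieves the target
#' Pearson correlation in expectation (for near-Gaussian phenotypes) without
#' iterative rejection; each individual is used exactly once.
#'
#' @param y_male,y_female phenotype vectors of equal length (one per mating
#'   pool member).
#' @param r_mate target correlation in `[0, 1)`; `0` gives random pairing.
#'
#' @return A tibble with columns `male`, `female` (indices into the input
#'   vectors) and attribute `realized_r`, the realized phenotypic
#'   correlation. Warns if the realized correlation misses the target by
#'   more than `max(0.01, 4/sqrt(n))`.
#' @examples
#' set.seed(1)
#' pairs <- assort_mates(rnorm(500), rnorm(500), r_mate = 0.4)
#' attr(pairs, "realized_r")
#' @export
assort_mates <- function(y_male, y_female, r_mate = 0) {
  n <- length(y_male)
  stopifnot(length(y_female) == n, n >= 2, r_mate >= 0, r_mate < 1)
  if (r_mate == 0) {
    out <- tibble(male = sample.int(n), female = sample.int(n))
  } else {
    z1 <- rnorm(n)
    z2 <- r_mate * z1 + sqrt(1 - r_mate^2) * rnorm(n)
    ord_m <- order(y_male)
    ord_f <- order(y_female)
    out <- tibble(
      male = ord_m[rank(z1, ties.method = "first")],
      female = ord_f[rank(z2, ties.method = "first")]
    )
  }
  realized <- cor(y_male[out$male], y_female[out$female])
  if (abs(realized - r_mate) > max(0.01, 4 / sqrt(n))) {
    warn(sprintf(
      "realized mate correlation %.3f deviates from target %.3f",
      realized, r_mate
    ))
  }
  attr(out, "realized_r") <- realized
  out
}

#' Mendelian transmission with free recombination
#'
#' For each individual, draws a transmitted gamete from the parent's two
#' haplotypes: at each locus independently, the transmitted allele comes from
#' either haplotype with probability 1/2; the nontransmitted haplotype is the
#' locus-wise complement.
#'
#' @param h1,h2 integer 0/1 haplotype matrices (parents by loci).
#' @param parent integer vector of parent row indices, one per gamete to draw
#'   (defaults to one gamete per parent).
#' @return List with integer matrices `transmitted` and `nontransmitted`
#'   (`length(parent)` by loci).
#' @examples
#' h1 <- matrix(c(1L, 0L, 1L, 1L), 1)
#' h2 <- matrix(c(1L, 0L, 0L, 0L), 1)
#' set.seed(1)
#' transmit(h1, h2, parent = c(1L, 1L))
#' @export
transmit <- function(h1, h2, parent = seq_len(nrow(h1))) {
  stopifnot(
    is.matrix(h1), is.matrix(h2),
    nrow(h1) == nrow(h2), ncol(h1) == ncol(h2)
  )
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"
  meiosis_cpp(h1, h2, as.integer(parent))
}

# haplotypic score helper: rows by loci matrix times weights, minus the
# base-generation centering constant
hap_score <- function(hap, beta, center) {
  as.numeric(hap %*% beta) - center
}

#' Simulate a population forward in time
#'
#' Generation 0 is drawn with independent loci (linkage equilibrium);
#' per-locus effect sizes are drawn once (standard normal) and rescaled so
#' the haplotypic PGS and LGS have variance exactly 1/2 in the base
#' generation, making the scaling constants `k = j = 1/2` exact. Each later
#' generation is produced by assortative mating on the phenotype, vertical
#' transmission (`F_o = f * Y_p + f * Y_m`), Mendelian transmission with free
#' recombination, and phenotype assembly
#' `Y = delta * (PGS_hap1 + PGS_hap2) + a * (LGS_hap1 + LGS_hap2) + F + eps`.
#'
#' @param config a [sim_config()].
#' @return A `pop_sequence` object: the config, per-generation score tables
#'   (see Details), per-generation realized moments (`moments`), the variant
#'   table with PGS weights over the observed loci (`weights`), score
#'   centering constants, and the final two generations' haplotype matrices
#'   (for [export_fixture()]).
#' @details Each stored generation is a tibble with individual `id`, `father`
#'   and `mother` (row indices in the previous generation), `sex`, the
#'   haplotypic PGS of the paternally and maternally transmitted haplotypes
#'   (`T_p`, `T_m`), the corresponding nontransmitted scores (`NT_p`,
#'   `NT_m`), their latent analogs (`LT_p`, `LNT_p`, `LT_m`, `LNT_m`), the
#'   familial environment `F`, and the phenotype `Y`. Generation 0 has its
#'   own haplotypic scores in the `T_*` columns and `NA` elsewhere.
#' @examples
#' pop <- simulate_population(
#'   sim_config(
#'     n_families = 300, m_obs = 20, m_lat = 0, delta = 0.5,
#'     f = 0.2, V_eps = 0.545, n_generations = 3, seed = 7
#'   )
#' )
#' glance(pop)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_fam <- config$n_families
  N <- 2L * n_fam
  m_obs <- config$m_obs
  m_lat <- config$m_lat
  m <- m_obs + m_lat
  obs_idx <- seq_len(m_obs)
  lat_idx <- if (m_lat > 0) m_obs + seq_len(m_lat) else integer(0)

  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  draw_hap <- function() {
    matrix(rbinom(N * m, 1L, rep(maf, each = N)), N, m)
  }
  h1 <- draw_hap()
  h2 <- draw_hap()
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"

  # effect sizes, rescaled so the base-population haplotypic score variance
  # is exactly 1/2 under linkage equilibrium (sum beta^2 p (1-p) = 1/2);
  # k and j are then true population constants, not sample estimates
  beta_obs <- rnorm(m_obs)
  p_obs <- maf[obs_idx]
  beta_obs <- beta_obs * sqrt(0.5 / sum(beta_obs^2 * p_obs * (1 - p_obs)))
  center_obs <- sum(beta_obs * p_obs)

  if (m_lat > 0) {
    beta_lat <- rnorm(m_lat)
    p_lat <- maf[lat_idx]
    beta_lat <- beta_lat * sqrt(0.5 / sum(beta_lat^2 * p_lat * (1 - p_lat)))
    center_lat <- sum(beta_lat * p_lat)
  } else {
    beta_lat <- numeric(0)
    center_lat <- 0
  }

  pgs1 <- hap_score(h1[, obs_idx, drop = FALSE], beta_obs, center_obs)
  pgs2 <- hap_score(h2[, obs_idx, drop = FALSE], beta_obs, center_obs)
  if (m_lat > 0) {
    lgs1 <- hap_score(h1[, lat_idx, drop = FALSE], beta_lat, center_lat)
    lgs2 <- hap_score(h2[, lat_idx, drop = FALSE], beta_lat, center_lat)
  } else {
    lgs1 <- lgs2 <- numeric(N)
  }

  sex <- rep(c(1L, 2L), n_fam) # deterministic alternating halves
  eps <- rnorm(N, 0, sqrt(config$V_eps))
  Y <- config$delta * (pgs1 + pgs2) + config$a * (lgs1 + lgs2) + eps

  gen_tbl <- function(father, mother, sexv, tp, ntp, tm, ntm,
                      ltp, lntp, ltm, lntm, Fo, Y) {
    tibble(
      id = seq_along(Y), father = father, mother = mother, sex = sexv,
      T_p = tp, NT_p = ntp, T_m = tm, NT_m = ntm,
      LT_p = ltp, LNT_p = lntp, LT_m = ltm, LNT_m = lntm,
      F = Fo, Y = Y
    )
  }

  gens <- vector("list", config$n_generations + 1L)
  gens[[1]] <- gen_tbl(
    NA_integer_, NA_integer_, sex,
    pgs1, NA_real_, pgs2, NA_real_,
    lgs1, NA_real_, lgs2, NA_real_,
    0, Y
  )

  mom <- function(tbl, gen, realized_r) {
    full_pgs <- tbl$T_p + tbl$T_m
    cis <- if (gen == 0) NA_real_ else {
      mean(c(cov(tbl$T_p, tbl$NT_p), cov(tbl$T_m, tbl$NT_m)))
    }
    trans <- if (gen == 0) NA_real_ else {
      mean(c(
        cov(tbl$T_p, tbl$T_m), cov(tbl$T_p, tbl$NT_m),
        cov(tbl$NT_p, tbl$T_m), cov(tbl$NT_p, tbl$NT_m)
      ))
    }
    tibble(
      generation = gen,
      V_Y = var(tbl$Y),
      var_full_pgs = var(full_pgs),
      var_hap_pgs = mean(c(var(tbl$T_p), var(tbl$T_m))),
      cis_g = cis, trans_g = trans,
      r_mate_realized = realized_r
    )
  }
  moments <- vector("list", config$n_generations + 1L)
  moments[[1]] <- mom(gens[[1]], 0L, NA_real_)

  prev <- list(h1 = h1, h2 = h2, Y = Y, sex = sex)
  hap_last <- NULL

  for (t in seq_len(config$n_generations)) {
    males <- which(prev$sex == 1L)
    females <- which(prev$sex == 2L)
    r_t <- if (t >= config$am_onset) config$r_mate else 0
    pairing <- assort_mates(prev$Y[males], prev$Y[females], r_t)
    fathers <- males[pairing$male]
    mothers <- females[pairing$female]

    # two offspring per couple; fused meiosis + score accumulation
    fo <- rep(fathers, each = 2L)
    mo <- rep(mothers, each = 2L)
    kid <- offspring_scores_cpp(
      prev$h1, prev$h2, fo, mo, beta_obs, beta_lat,
      keep_haplotypes = TRUE
    )
    tp <- kid$T_p - center_obs
    ntp <- kid$NT_p - center_obs
    tm <- kid$T_m - center_obs
    ntm <- kid$NT_m - center_obs
    if (m_lat > 0) {
      ltp <- kid$LT_p - center_lat
      lntp <- kid$LNT_p - center_lat
      ltm <- kid$LT_m - center_lat
      lntm <- kid$LNT_m - center_lat
    } else {
      ltp <- lntp <- ltm <- lntm <- numeric(N)
    }

    Fo <- config$f * (prev$Y[fo] + prev$Y[mo])
    eps <- rnorm(N, 0, sqrt(config$V_eps))
    Yo <- config$delta * (tp + tm) + config$a * (ltp + ltm) + Fo + eps

    sexo <- rep(c(1L, 2L), n_fam)
    tbl <- gen_tbl(fo, mo, sexo, tp, ntp, tm, ntm, ltp, lntp, ltm, lntm, Fo, Yo)
    moments[[t + 1L]] <- mom(tbl, t, attr(pairing, "realized_r"))

    if (t == config$n_generations) {
      hap_last <- list(
        parents = list(h1 = prev$h1, h2 = prev$h2),
        offspring = list(h1 = kid$h1, h2 = kid$h2)
      )
    }
    if (config$store == "all" || t >= config$n_generations - 1L) {
      gens[[t + 1L]] <- tbl
    }
    prev <- list(h1 = kid$h1, h2 = kid$h2, Y = Yo, sex = sexo)
  }

  structure(
    list(
      config = config,
      generations = gens,
      moments = dplyr::bind_rows(moments),
      weights = tibble(
        variant_id = sprintf("rs%05d", seq_len(m_obs)),
        chromosome = "1",
        position = seq_len(m_obs) * 1000L,
        effect_allele = "A",
        other_allele = "G",
        weight = beta_obs,
        maf = maf[obs_idx]
      ),
      centers = list(obs = center_obs, lat = center_lat),
      haplotypes = hap_last,
      obs_loci = obs_idx
    ),
    class = "pop_sequence"
  )
}

#' @export
print.pop_sequence <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pop_sequence> %d families/generation, %d+%d loci, %d generations\n",
    cfg$n_families, cfg$m_obs, cfg$m_lat, cfg$n_generations
  ))
  cat(sprintf(
    "  delta = %g, a = %g, f = %g, r_mate = %g, V_eps = %g (AM from generation %d)\n",
    cfg$delta, cfg$a, cfg$f, cfg$r_mate, cfg$V_eps, cfg$am_onset
  ))
  cat(sprintf(
    "  final V_Y = %.4g\n",
    x$moments$V_Y[nrow(x$moments)]
  ))
  invisible(x)
}

#' @describeIn simulate_population per-generation realized summary moments.
#' @param x a `pop_sequence`.
#' @param ... unused.
#' @export
glance.pop_sequence <- function(x, ...) {
  x$moments
}
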