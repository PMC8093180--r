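# Small simulated populations shared across test files. Built once per test
# run; sizes chosen to keep the default suite fast while leaving Monte-Carlo
# error well below the asserted tolerances.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# no AM, VT only; PGS carries the full heritability
pop_m0 <- function() {
  cached("pop_m0", function() {
    simulate_population(sim_config(
      n_families = 10000, m_obs = 30, m_lat = 0,
      delta = 0.5, f = 0.2, V_eps = 0.545,
      n_generations = 10, seed = 101, store = "all"
    ))
  })
}

# equilibrium AM, no VT; enough loci that the finite-locus depression of the
# haplotypic variances (same-locus across-haplotype covariance, O(1/m)) is
# negligible against the assertions below
pop_am <- function() {
  cached("pop_am", function() {
    simulate_population(sim_config(
      n_families = 10000, m_obs = 150, m_lat = 0,
      delta = 0.5, f = 0, r_mate = 0.4, V_eps = 0.75,
      n_generations = 12, seed = 202, store = "all"
    ))
  })
}

# single final generation of AM (disequilibrium scenario)
pop_onegen <- function() {
  cached("pop_onegen", function() {
    simulate_population(sim_config(
      n_families = 8000, m_obs = 30, m_lat = 0,
      delta = 0.5, f = 0, r_mate = 0.4, V_eps = 0.75,
      n_generations = 3, am_onset = 3, seed = 303, store = "all"
    ))
  })
}

# full Model 2 world: AM + VT + latent genetics (PGS ~20% of heritability)
pop_m2 <- function() {
  cached("pop_m2", function() {
    simulate_population(sim_config(
      n_families = 20000, m_obs = 40, m_lat = 40,
      delta = sqrt(0.1), a = sqrt(0.4), f = 0.15, r_mate = 0.3,
      V_eps = 0.5, n_generations = 15, seed = 404, store = "last"
    ))
  })
}

params_m2 <- function() {
  model_params(
    delta = sqrt(0.1), a = sqrt(0.4), f = 0.15, r_mate = 0.3,
    V_eps = 0.5
  )
}

# MC standard error of a sample covariance between variables with variances
# vii, vjj and covariance vij (normal approximation)
cov_se <- function(vii, vjj, vij, n) sqrt((vii * vjj + vij^2) / n)
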