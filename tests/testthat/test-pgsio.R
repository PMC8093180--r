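# Haplotypic PGS construction from trio genotypes: transmission resolution,
# scoring policies, round trips through the VCF fixture.

test_that("unphased transmission resolution matches brute-force enumeration", {
  # independent oracle: enumerate every assignment of one allele from each
  # parent and classify by the number of consistent solutions
  oracle <- function(fd, md, od) {
    father_alleles <- list(c(0, 0), c(0, 1), c(1, 1))[[fd + 1]]
    mother_alleles <- list(c(0, 0), c(0, 1), c(1, 1))[[md + 1]]
    sols <- unique(do.call(rbind, lapply(father_alleles, function(tp) {
      do.call(rbind, lapply(mother_alleles, function(tm) {
        if (tp + tm == od) c(tp, tm) else NULL
      }))
    })))
    if (is.null(sols) || nrow(sols) == 0) {
      list(status = "mendelian_error", t_p = NA, t_m = NA)
    } else if (nrow(sols) > 1) {
      list(status = "ambiguous", t_p = NA, t_m = NA)
    } else {
      list(status = "ok", t_p = sols[1, 1], t_m = sols[1, 2])
    }
  }
  combos <- expand.grid(fd = 0:2, md = 0:2, od = 0:2)
  res <- resolve_transmission(combos$fd, combos$md, combos$od)
  for (r in seq_len(nrow(combos))) {
    exp <- oracle(combos$fd[r], combos$md[r], combos$od[r])
    expect_equal(res$status[r], exp$status,
      label = sprintf("status for (%d,%d,%d)", combos$fd[r], combos$md[r], combos$od[r])
    )
    if (exp$status == "ok") {
      expect_equal(res$t_p[r], exp$t_p)
      expect_equal(res$t_m[r], exp$t_m)
    }
  }
  # spot checks: forced, ambiguous, impossible
  expect_equal(resolve_transmission(2, 0, 1)$status, "ok")
  expect_equal(resolve_transmission(2, 0, 1)$t_p, 1)
  expect_equal(resolve_transmission(1, 1, 1)$status, "ambiguous")
  expect_equal(resolve_transmission(2, 2, 1)$status, "mendelian_error")
  expect_equal(resolve_transmission(NA, 1, 1)$status, "missing")
})

make_fixture <- function(n_families = 150, m_obs = 25, seed = 17) {
  pop <- simulate_population(sim_config(
    n_families = n_families, m_obs = m_obs, m_lat = 0,
    delta = 0.5, f = 0.2, V_eps = 0.545, n_generations = 3, seed = seed
  ))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  list(pop = pop, paths = export_fixture(pop, dir))
}

test_that("phased round trip reproduces the simulator scores exactly", {
  fx <- make_fixture()
  trios <- read_trios(fx$paths$vcf, fx$paths$pedigree, phased = TRUE)
  w <- read_weights(fx$paths$weights)
  expect_equal(nrow(w), 25)
  hs <- haplotypic_scores(trios, w)
  meta <- jsonlite::read_json(fx$paths$meta)
  ft <- extract_family_table(fx$pop)
  for (col in c("T_p", "NT_p", "T_m", "NT_m")) {
    expect_lt(max(abs(hs[[col]] - meta$score_center - ft[[col]])), 1e-9)
  }
  expect_true(all(hs$n_mendelian_errors == 0))
  expect_true(all(hs$n_sites_used == 25))
})

test_that("exported VCF is well-formed phased VCFv4.2", {
  fx <- make_fixture(n_families = 20, m_obs = 10)
  lines <- readLines(fx$paths$vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  header <- grep("^#CHROM", lines, value = TRUE)
  expect_equal(length(header), 1)
  cols <- strsplit(header, "\t")[[1]]
  expect_equal(cols[1:9], c(
    "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT"
  ))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 10)
  gts <- unlist(lapply(strsplit(body, "\t"), function(x) x[-(1:9)]))
  expect_true(all(grepl("^[01]\\|[01]$", gts)))
})

test_that("T + NT conserves the full parental PGS under the split policy", {
  fx <- make_fixture()
  trios <- read_trios(fx$paths$vcf, fx$paths$pedigree, phased = TRUE)
  w <- read_weights(fx$paths$weights)
  hs_ph <- haplotypic_scores(trios, w)
  un <- trios
  un$phased <- FALSE
  hs_un <- haplotypic_scores(un, w, ambiguity_policy = "split")
  # full parental scores identical between modes and policies
  expect_equal(hs_un$T_p + hs_un$NT_p, hs_ph$T_p + hs_ph$NT_p, tolerance = 1e-12)
  expect_equal(hs_un$T_m + hs_un$NT_m, hs_ph$T_m + hs_ph$NT_m, tolerance = 1e-12)
  # families without ambiguous sites agree exactly with phased truth
  clean <- hs_un$n_ambiguous == 0
  expect_gt(sum(clean), 0)
  expect_equal(hs_un$T_p[clean], hs_ph$T_p[clean], tolerance = 1e-12)
  # drop policy: also exact where nothing was dropped
  hs_dr <- haplotypic_scores(un, w, ambiguity_policy = "drop")
  expect_equal(hs_dr$T_m[clean], hs_ph$T_m[clean], tolerance = 1e-12)
  expect_gt(cor(hs_dr$T_p, hs_ph$T_p), 0.9)
})

test_that("ambiguity rate matches the analytic triple-heterozygote probability", {
  fx <- make_fixture(n_families = 400, m_obs = 40, seed = 23)
  trios <- read_trios(fx$paths$vcf, fx$paths$pedigree, phased = TRUE)
  un <- trios
  un$phased <- FALSE
  w <- read_weights(fx$paths$weights)
  hs <- haplotypic_scores(un, w)
  # P(father het, mother het, offspring het) = 2pq * 2pq * 1/2 = 2 p^2 q^2
  p <- fx$pop$weights$maf
  expected <- sum(2 * p^2 * (1 - p)^2)
  observed <- mean(hs$n_ambiguous)
  se <- sqrt(sum(2 * p^2 * (1 - p)^2) / 400) # Poisson-binomial scale
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("allele mismatches against the weight table are dropped and counted", {
  fx <- make_fixture(n_families = 30, m_obs = 10)
  trios <- read_trios(fx$paths$vcf, fx$paths$pedigree, phased = TRUE)
  w <- read_weights(fx$paths$weights)
  w$effect_allele[1] <- "T" # no longer matches REF or ALT
  hs <- haplotypic_scores(trios, w)
  expect_equal(attr(hs, "qc")$n_allele_mismatch, 1)
  expect_true(all(hs$n_sites_used == 9))
  # swapped effect/other allele flips the dosage orientation consistently
  w2 <- read_weights(fx$paths$weights)
  w2$effect_allele <- w2$other_allele
  w2$other_allele <- read_weights(fx$paths$weights)$effect_allele
  hs2 <- haplotypic_scores(trios, w2)
  hs1 <- haplotypic_scores(trios, read_weights(fx$paths$weights))
  # score with flipped orientation = weight_sum_per_hap - original score
  expect_equal(hs1$T_p + hs2$T_p, rep(sum(w2$weight), 30), tolerance = 1e-9)
})

test_that("weight table validation catches malformed input", {
  fx <- make_fixture(n_families = 5, m_obs = 4)
  w <- readr::read_tsv(fx$paths$weights, show_col_types = FALSE)
  w2 <- w
  w2$variant_id[2] <- w2$variant_id[1]
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(w2, f)
  expect_error(read_weights(f), "duplicate")
  w3 <- w
  w3$other_allele <- w3$effect_allele
  readr::write_tsv(w3, f)
  expect_error(read_weights(f), "differ")
})

test_that("standardize_scores applies conventions and reports k", {
  fx <- make_fixture(n_families = 300, m_obs = 30)
  trios <- read_trios(fx$paths$vcf, fx$paths$pedigree, phased = TRUE)
  hs <- haplotypic_scores(trios, read_weights(fx$paths$weights))
  full <- standardize_scores(hs, "full_pgs_standardized_now")
  v <- mean(c(var(full$T_p + full$NT_p), var(full$T_m + full$NT_m)))
  expect_equal(v, 1, tolerance = 1e-12)
  # no AM in this world: k close to 1/2 under every convention
  expect_lt(abs(attr(full, "k") - 0.5), 0.05)
  half <- standardize_scores(hs, "haplotypic_half_now")
  expect_equal(mean(c(var(half$T_p), var(half$NT_p), var(half$T_m), var(half$NT_m))),
    0.5, tolerance = 1e-12)
  expect_error(standardize_scores(hs, "base_standardized"), "k_base")
  base <- standardize_scores(hs, "base_standardized", k_base = 0.5)
  expect_equal(attr(base, "k"), 0.5)
})
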