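#' Extract the observed family table from a simulated population
#'
#' Builds the per-family table of observed variables — the four haplotypic
#' PGSs (computed over the observed loci only), the offspring phenotype, and
#' the two parental phenotypes — for one generation of a simulated
#' population. One row per mated couple; the first offspring of each couple
#' is the index offspring.
#'
#' @param pop a [simulate_population()] result.
#' @param generation generation index (>= 1); defaults to the final one.
#' @param scaling scaling convention applied to the scores; the matching `k`
#'   is attached as attribute `"k"`. `"base_standardized"` returns the
#'   simulator's native scale, for which `k = 1/2` exactly by construction.
#' @param missing_pattern `NULL` or `"complete"` for full data; `"pairs"`
#'   keeps exactly two variables per family (cycling through all unordered
#'   pairs so every pair is observed); a number in (0, 1) masks each cell
#'   completely at random with that probability (keeping at least one
#'   observed variable per row).
#'
#' @return Tibble with columns `family_id`, `T_p`, `NT_p`, `T_m`, `NT_m`,
#'   `Y_o`, `Y_p`, `Y_m`, and attributes `k` and `scaling`.
#' @examples
#' pop <- simulate_population(
#'   sim_config(
#'     n_families = 200, m_obs = 20, m_lat = 0, delta = 0.5,
#'     f = 0.2, V_eps = 0.545, n_generations = 2, seed = 1
#'   )
#' )
#' ft <- extract_family_table(pop)
#' attr(ft, "k")
#' @export
extract_family_table <- function(pop, generation = pop$config$n_generations,
                                 scaling = c(
                                   "base_standardized",
                                   "full_pgs_standardized_now",
                                   "haplotypic_half_now"
                                 ),
                                 missing_pattern = NULL) {
  stopifnot(inherits(pop, "pop_sequence"), generation >= 1)
  scaling <- match.arg(scaling)
  tbl <- pop$generations[[generation + 1L]]
  par <- pop$generations[[generation]]
  if (is.null(tbl) || is.null(par)) {
    abort(sprintf(
      "generation %d (or its parents) was not stored; rerun with store = 'all'",
      generation
    ))
  }
  off <- tbl[tbl$sex == 1L, ] # first offspring of each couple
  ft <- tibble(
    family_id = seq_len(nrow(off)),
    T_p = off$T_p, NT_p = off$NT_p, T_m = off$T_m, NT_m = off$NT_m,
    Y_o = off$Y, Y_p = par$Y[off$father], Y_m = par$Y[off$mother]
  )

  resc <- rescale_scores(ft, scaling)
  ft <- resc$table
  if (!is.null(missing_pattern) && !identical(missing_pattern, "complete")) {
    ft <- apply_missingness(ft, missing_pattern)
  }
  attr(ft, "k") <- resc$k
  attr(ft, "scaling") <- scaling
  ft
}

# Apply a scaling convention to the four haplotypic score columns of a
# family table and resolve the matching base-population constant k.
rescale_scores <- function(ft, scaling) {
  score_cols <- c("T_p", "NT_p", "T_m", "NT_m")
  X <- as.matrix(ft[score_cols])
  if (scaling == "base_standardized") {
    # simulator native scale: base-generation haplotypic variance is 1/2
    return(list(table = ft, k = 0.5))
  }
  if (scaling == "full_pgs_standardized_now") {
    s <- sqrt(mean(c(var(X[, "T_p"] + X[, "NT_p"]), var(X[, "T_m"] + X[, "NT_m"]))))
    X <- X / s
  } else { # haplotypic_half_now
    s <- sqrt(mean(apply(X, 2, var)) / 0.5)
    X <- X / s
  }
  ft[score_cols] <- as_tibble(X)
  list(table = ft, k = resolve_k(ft, scaling))
}

# Resolve k from the observed cis moments under a current-generation scaling.
# Writing vbar for the mean haplotypic variance and cbar for the mean cis
# covariance: under full-PGS standardization k = 1/2 - 2g with vbar = k + g,
# jointly solved by g = (4(vbar - k) + 2 cbar)/6 with k = k(g); under
# haplotypic scaling vbar = 1/2 by construction and g is informed by cbar
# alone.
resolve_k <- function(ft, scaling, k_base = NULL) {
  score_cols <- c("T_p", "NT_p", "T_m", "NT_m")
  cc <- ft[stats::complete.cases(ft[score_cols]), ]
  X <- as.matrix(cc[score_cols])
  vbar <- mean(apply(X, 2, var))
  cbar <- mean(c(cov(X[, "T_p"], X[, "NT_p"]), cov(X[, "T_m"], X[, "NT_m"])))
  k <- switch(scaling,
    base_standardized = k_base %||% 0.5,
    full_pgs_standardized_now = 0.5 - 2 * (1 - 2 * vbar - cbar),
    haplotypic_half_now = 0.5 - cbar
  )
  if (k <= 0) {
    abort(sprintf("scaling '%s' implies k = %.4g <= 0", scaling, k))
  }
  k
}

apply_missingness <- function(ft, missing_pattern) {
  vars <- setdiff(names(ft), "family_id")
  n <- nrow(ft)
  if (identical(missing_pattern, "pairs")) {
    pairs <- utils::combn(vars, 2, simplify = FALSE)
    assign <- sample(rep_len(seq_along(pairs), n))
    for (r in seq_len(n)) {
      keep <- pairs[[assign[r]]]
      ft[r, setdiff(vars, keep)] <- NA_real_
    }
  } else if (is.numeric(missing_pattern) && length(missing_pattern) == 1 &&
    missing_pattern > 0 && missing_pattern < 1) {
    mask <- matrix(runif(n * length(vars)) < missing_pattern, n)
    # keep at least one observed variable per row
    allgone <- rowSums(!mask) == 0
    mask[cbind(which(allgone), sample.int(length(vars), sum(allgone), replace = TRUE))] <- FALSE
    M <- as.matrix(ft[vars])
    M[mask] <- NA_real_
    ft[vars] <- as_tibble(M)
  } else {
    abort("missing_pattern must be NULL, 'complete', 'pairs', or a probability in (0, 1)")
  }
  ft
}

#' Write a phased trio fixture (VCF, weights, phenotypes, pedigree)
#'
#' Exports the final simulated generation as (a) a phased trio VCF over the
#' observed loci, with the offspring's first haplotype paternal, (b) a PGS
#' weight table, (c) a phenotype TSV, and (d) a pedigree TSV, plus a JSON
#' sidecar recording the haplotypic-score centering constant so that scores
#' reconstructed by [haplotypic_scores()] round-trip exactly to the
#' simulator's internal values after subtracting the constant.
#'
#' @param pop a [simulate_population()] result (haplotypes of the final
#'   generation and its parents must be available, which is the default).
#' @param dir output directory (created if needed).
#' @param n_families optionally restrict to the first `n_families` couples.
#' @return Invisibly, a named list of the written file paths.
#' @export
export_fixture <- function(pop, dir, n_families = NULL) {
  stopifnot(inherits(pop, "pop_sequence"))
  if (is.null(pop$haplotypes)) {
    abort("final-generation haplotypes were not retained")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- pop$config$n_generations
  tbl <- pop$generations[[gen + 1L]]
  par <- pop$generations[[gen]]
  off <- which(tbl$sex == 1L)
  if (!is.null(n_families)) off <- off[seq_len(n_families)]
  fam <- seq_along(off)

  hp <- pop$haplotypes$parents
  ho <- pop$haplotypes$offspring
  obs <- pop$obs_loci
  fa <- tbl$father[off]
  mo <- tbl$mother[off]

  # genotype strings: REF = other_allele (G), ALT = effect_allele (A);
  # haplotype value 1 = carries the effect allele = ALT
  gt_str <- function(a1, a2) paste0(a1, "|", a2)
  samples <- c(
    sprintf("FAM%04d_father", fam),
    sprintf("FAM%04d_mother", fam),
    sprintf("FAM%04d_offspring", fam)
  )
  gt_block <- function(hap, idx) {
    vapply(
      idx,
      function(i) gt_str(hap$h1[i, obs], hap$h2[i, obs]),
      character(length(obs))
    )
  }
  gt <- cbind(gt_block(hp, fa), gt_block(hp, mo), gt_block(ho, off))
  w <- pop$weights
  fixed <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT",
    w$chromosome, w$position, w$variant_id, w$other_allele, w$effect_allele
  )
  vcf_path <- file.path(dir, "trios.vcf")
  con <- file(vcf_path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pgsnurture_simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  ), con)
  writeLines(paste(fixed, apply(gt, 1, paste, collapse = "\t"), sep = "\t"), con)
  close(con)

  weights_path <- file.path(dir, "weights.tsv")
  readr::write_tsv(w[c(
    "variant_id", "chromosome", "position", "effect_allele",
    "other_allele", "weight"
  )], weights_path)

  ped_path <- file.path(dir, "pedigree.tsv")
  readr::write_tsv(tibble(
    family_id = sprintf("FAM%04d", fam),
    father_id = sprintf("FAM%04d_father", fam),
    mother_id = sprintf("FAM%04d_mother", fam),
    offspring_id = sprintf("FAM%04d_offspring", fam)
  ), ped_path)

  pheno_path <- file.path(dir, "phenotypes.tsv")
  readr::write_tsv(tibble(
    family_id = sprintf("FAM%04d", fam),
    Y_o = tbl$Y[off], Y_p = par$Y[fa], Y_m = par$Y[mo]
  ), pheno_path)

  meta_path <- file.path(dir, "fixture.json")
  jsonlite::write_json(
    list(
      score_center = pop$centers$obs,
      offspring_hap1 = "paternal",
      n_families = length(fam),
      generation = gen
    ),
    meta_path,
    auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    vcf = vcf_path, weights = weights_path, pedigree = ped_path,
    phenotypes = pheno_path, meta = meta_path
  ))
}
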