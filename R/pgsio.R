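#' Read and write PGS weight tables
#'
#' The weight table follows the common PGS scoring-file layout: one row per
#' biallelic variant with the per-allele effect weight.
#'
#' @param path TSV file with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `weight`.
#' @return A tibble with those columns.
#' @export
read_weights <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(
      variant_id = "c", chromosome = "c", position = "i",
      effect_allele = "c", other_allele = "c", weight = "d"
    )
  )
  need <- c(
    "variant_id", "chromosome", "position",
    "effect_allele", "other_allele", "weight"
  )
  missing_cols <- setdiff(need, names(w))
  if (length(missing_cols)) {
    abort(paste("weight table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(w$variant_id)) abort("duplicate variant_id in weight table")
  if (any(w$effect_allele == w$other_allele)) abort("effect and other allele must differ")
  if (any(!is.finite(w$weight))) abort("non-finite weights")
  w[need]
}

#' Read trio genotypes from a VCF plus a pedigree table
#'
#' Loads a (phased or unphased) VCF via \pkg{vcfR} and organizes the genotype
#' calls by trio according to a pedigree table. Multi-allelic sites are
#' excluded and counted.
#'
#' @param vcf_path path to a VCF file.
#' @param ped_path path to a pedigree TSV with columns `family_id`,
#'   `father_id`, `mother_id`, `offspring_id` naming VCF sample columns.
#' @param phased treat genotypes as phased? When `TRUE`, the offspring's
#'   first haplotype is taken as `offspring_hap1` (paternal by convention).
#' @param offspring_hap1 which parent the offspring's first haplotype comes
#'   from in phased data: `"paternal"` (default) or `"maternal"`.
#' @return A `trio_genotypes` object: variant table, per-sample allele
#'   matrices, the pedigree, and QC counts.
#' @export
read_trios <- function(vcf_path, ped_path, phased = TRUE,
                       offspring_hap1 = c("paternal", "maternal")) {
  offspring_hap1 <- match.arg(offspring_hap1)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_multi <- sum(multi)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]

  # split GT strings into two allele matrices (NA for missing)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  a1[a1 == "."] <- NA
  a2[a2 == "."] <- NA
  mode(a1) <- "integer"
  mode(a2) <- "integer"
  dim(a1) <- dim(gt); dimnames(a1) <- dimnames(gt)
  dim(a2) <- dim(gt); dimnames(a2) <- dimnames(gt)

  ped <- readr::read_tsv(ped_path, show_col_types = FALSE)
  need <- c("family_id", "father_id", "mother_id", "offspring_id")
  if (!all(need %in% names(ped))) {
    abort(paste("pedigree lacks columns:", paste(setdiff(need, names(ped)), collapse = ", ")))
  }
  absent <- setdiff(
    c(ped$father_id, ped$mother_id, ped$offspring_id),
    colnames(gt)
  )
  if (length(absent)) {
    abort(paste("pedigree samples absent from VCF:", paste(utils::head(absent, 5), collapse = ", ")))
  }

  structure(
    list(
      variants = tibble(
        variant_id = fix$ID,
        chromosome = fix$CHROM,
        position = as.integer(fix$POS),
        ref = fix$REF,
        alt = fix$ALT
      ),
      a1 = a1, a2 = a2,
      ped = ped,
      phased = phased,
      offspring_hap1 = offspring_hap1,
      n_multiallelic = n_multi
    ),
    class = "trio_genotypes"
  )
}

#' @export
print.trio_genotypes <- function(x, ...) {
  cat(sprintf(
    "<trio_genotypes> %d variants x %d families (%s; %d multi-allelic sites excluded)\n",
    nrow(x$variants), nrow(x$ped),
    if (x$phased) "phased" else "unphased", x$n_multiallelic
  ))
  invisible(x)
}

#' Resolve which parental alleles were transmitted (unphased trios)
#'
#' For unphased biallelic genotypes, Mendelian deduction identifies the
#' transmitted allele of each parent at most sites. The assignment is
#' ambiguous if and only if father, mother, and offspring are all
#' heterozygous; it is a Mendelian error when no assignment of one allele
#' from each parent reproduces the offspring genotype.
#'
#' @param father,mother,offspring integer dosage vectors (0/1/2 copies of
#'   the alternate allele), recycled to a common length.
#' @return Tibble with columns `t_p`, `t_m` (transmitted alternate-allele
#'   dosage of each parent, `NA` when unresolved) and `status`
#'   (`"ok"`, `"ambiguous"`, `"mendelian_error"`, `"missing"`).
#' @examples
#' resolve_transmission(2, 0, 1) # father transmits alt, mother ref
#' resolve_transmission(1, 1, 1) # triple heterozygote: ambiguous
#' resolve_transmission(2, 2, 1) # impossible: Mendelian error
#' @export
resolve_transmission <- function(father, mother, offspring) {
  n <- max(length(father), length(mother), length(offspring))
  fd <- rep_len(as.integer(father), n)
  md <- rep_len(as.integer(mother), n)
  od <- rep_len(as.integer(offspring), n)

  t_p <- rep(NA_integer_, n)
  t_m <- rep(NA_integer_, n)
  status <- rep("missing", n)

  ok_in <- !is.na(fd) & !is.na(md) & !is.na(od)
  idx <- which(ok_in)
  if (length(idx)) {
    # enumerate candidate transmissions: tp in father's alleles, tm in
    # mother's, tp + tm = offspring dosage
    f <- fd[idx]; m <- md[idx]; o <- od[idx]
    can <- function(par, al) (al == 0 & par < 2) | (al == 1 & par > 0)
    n_sol <- matrix(0L, length(idx), 1)
    sol_tp <- rep(NA_integer_, length(idx))
    sol_tm <- rep(NA_integer_, length(idx))
    for (tp in 0:1) {
      for (tm in 0:1) {
        hit <- can(f, tp) & can(m, tm) & (tp + tm == o)
        n_sol[hit] <- n_sol[hit] + 1L
        sol_tp[hit] <- tp
        sol_tm[hit] <- tm
      }
    }
    st <- ifelse(n_sol == 0, "mendelian_error",
      ifelse(n_sol > 1, "ambiguous", "ok")
    )
    status[idx] <- st
    good <- st == "ok"
    t_p[idx[good]] <- sol_tp[good]
    t_m[idx[good]] <- sol_tm[good]
  }
  tibble(t_p = t_p, t_m = t_m, status = status)
}

#' Construct the four haplotypic PGSs from trio genotypes
#'
#' Resolves each parent's transmitted and nontransmitted allele at every
#' scored site (directly from the offspring haplotypes in phased mode;
#' by Mendelian deduction otherwise) and sums `weight x effect-allele
#' dosage` into the transmitted scores `T_p`, `T_m`, with the complements in
#' `NT_p`, `NT_m`. Sites whose alleles do not match the weight table (by
#' allele identity; no strand inference) are dropped and counted; Mendelian
#' errors are excluded per family and counted.
#'
#' @param trios a [read_trios()] object.
#' @param weights a weight table (see [read_weights()]).
#' @param ambiguity_policy `"split"` (default): an ambiguous (triple
#'   heterozygous) site contributes half the parent's genotype score to each
#'   of that parent's T and NT — unbiased for the score sums, slightly
#'   attenuating the T/NT contrast; `"drop"`: the site is excluded for that
#'   family.
#' @return Tibble with `family_id`, `T_p`, `NT_p`, `T_m`, `NT_m`,
#'   `n_sites_used`, `n_ambiguous`, `n_mendelian_errors`, plus attribute
#'   `"qc"` (site-level counts).
#' @export
haplotypic_scores <- function(trios, weights,
                              ambiguity_policy = c("split", "drop")) {
  stopifnot(inherits(trios, "trio_genotypes"))
  ambiguity_policy <- match.arg(ambiguity_policy)

  v <- trios$variants
  key_v <- paste(v$chromosome, v$position)
  key_w <- paste(weights$chromosome, weights$position)
  shared <- intersect(key_v, key_w)
  if (!length(shared)) abort("no overlapping variants between trios and weights")
  iv <- match(shared, key_v)
  iw <- match(shared, key_w)

  # allele matching: effect allele must be REF or ALT at the site
  eff <- weights$effect_allele[iw]
  oth <- weights$other_allele[iw]
  ok_alt <- eff == v$alt[iv] & oth == v$ref[iv]
  ok_ref <- eff == v$ref[iv] & oth == v$alt[iv]
  usable <- ok_alt | ok_ref
  n_mismatch <- sum(!usable)
  iv <- iv[usable]; iw <- iw[usable]
  flip <- ok_ref[usable] # TRUE: effect allele is REF, dosage = 1 - alt dosage
  wgt <- weights$weight[iw]
  if (!length(iv)) abort("no allele-consistent variants between trios and weights")

  ped <- trios$ped
  n_fam <- nrow(ped)
  m <- length(iv)

  # allele matrices restricted to scored sites, oriented to the effect allele
  orient <- function(x) {
    x <- x[iv, , drop = FALSE]
    x[flip, ] <- 1L - x[flip, , drop = FALSE]
    x
  }
  a1 <- orient(trios$a1)
  a2 <- orient(trios$a2)

  fa1 <- a1[, ped$father_id, drop = FALSE]
  fa2 <- a2[, ped$father_id, drop = FALSE]
  ma1 <- a1[, ped$mother_id, drop = FALSE]
  ma2 <- a2[, ped$mother_id, drop = FALSE]
  oa1 <- a1[, ped$offspring_id, drop = FALSE]
  oa2 <- a2[, ped$offspring_id, drop = FALSE]
  fd <- fa1 + fa2
  md <- ma1 + ma2
  od <- oa1 + oa2

  if (trios$phased) {
    tp <- if (trios$offspring_hap1 == "paternal") oa1 else oa2
    tm <- if (trios$offspring_hap1 == "paternal") oa2 else oa1
    ok <- !is.na(fd) & !is.na(md) & !is.na(tp) & !is.na(tm)
    # Mendelian check: transmitted allele must exist in the parent
    mend_ok <- ok & (tp == fa1 | tp == fa2) & (tm == ma1 | tm == ma2)
    amb <- ok & FALSE
    status_ok <- mend_ok
    err <- ok & !mend_ok
  } else {
    res <- resolve_transmission(as.vector(fd), as.vector(md), as.vector(od))
    st <- matrix(res$status, m, n_fam)
    tp <- matrix(res$t_p, m, n_fam)
    tm <- matrix(res$t_m, m, n_fam)
    status_ok <- st == "ok"
    amb <- st == "ambiguous"
    err <- st == "mendelian_error"
  }

  zero <- function(x) {
    x[is.na(x)] <- 0L
    x
  }
  use_amb <- ambiguity_policy == "split" & amb
  used <- status_ok | use_amb

  # resolved sites: transmitted dosage and complement; ambiguous under
  # "split": half the parental genotype dosage on each side
  tp_c <- ifelse(status_ok, tp, ifelse(use_amb, fd / 2, 0))
  ntp_c <- ifelse(status_ok, fd - tp, ifelse(use_amb, fd / 2, 0))
  tm_c <- ifelse(status_ok, tm, ifelse(use_amb, md / 2, 0))
  ntm_c <- ifelse(status_ok, md - tm, ifelse(use_amb, md / 2, 0))

  out <- tibble(
    family_id = ped$family_id,
    T_p = unname(colSums(wgt * zero(tp_c) * used)),
    NT_p = unname(colSums(wgt * zero(ntp_c) * used)),
    T_m = unname(colSums(wgt * zero(tm_c) * used)),
    NT_m = unname(colSums(wgt * zero(ntm_c) * used)),
    n_sites_used = unname(colSums(used)),
    n_ambiguous = unname(colSums(amb)),
    n_mendelian_errors = unname(colSums(err))
  )
  amb_rate <- mean(out$n_ambiguous / m)
  if (!trios$phased && amb_rate > 0.2) {
    warn(sprintf(
      "%.0f%% of sites are ambiguous (triple heterozygotes) under unphased resolution",
      100 * amb_rate
    ))
  }
  attr(out, "qc") <- list(
    n_sites_scored = m,
    n_allele_mismatch = n_mismatch,
    n_multiallelic = trios$n_multiallelic,
    ambiguity_rate = amb_rate,
    ambiguity_policy = ambiguity_policy,
    phased = trios$phased
  )
  out
}

#' Standardize haplotypic scores and report the matching k
#'
#' Centers the four haplotypic score columns and applies a scaling
#' convention, returning the family table on the chosen scale with the
#' base-population constant `k` the estimators must use attached as
#' attribute `"k"` (see [base_constants()] for the conventions).
#'
#' @param table a tibble with columns `T_p`, `NT_p`, `T_m`, `NT_m` (other
#'   columns are passed through).
#' @param convention scaling convention; for `"base_standardized"` the base
#'   generation variance must be supplied via `k_base` (it cannot be
#'   estimated from current-generation data).
#' @param k_base known base-population haplotypic variance (simulated data).
#' @return The table with centered, rescaled scores and attributes `k` and
#'   `scaling`.
#' @export
standardize_scores <- function(table,
                               convention = c(
                                 "full_pgs_standardized_now",
                                 "haplotypic_half_now",
                                 "base_standardized"
                               ),
                               k_base = NULL) {
  convention <- match.arg(convention)
  score_cols <- c("T_p", "NT_p", "T_m", "NT_m")
  stopifnot(all(score_cols %in% names(table)))
  cc <- stats::complete.cases(table[score_cols])
  if (sum(cc) < 2) abort("need at least 2 families with complete scores")
  X <- as.matrix(table[score_cols])
  X <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  table[score_cols] <- as_tibble(X)
  if (convention == "base_standardized") {
    if (is.null(k_base)) {
      abort("base_standardized scaling needs the known base-generation variance (k_base)")
    }
    attr(table, "k") <- k_base
    attr(table, "scaling") <- convention
    return(table)
  }
  resc <- rescale_scores(table, convention)
  table <- resc$table
  attr(table, "k") <- resc$k
  attr(table, "scaling") <- convention
  table
}
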