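#' Standardize traits to mean zero and unit SD
#'
#' Each trait column is centred and scaled over its non-missing families
#' (sample SD); missing values are preserved. Standardization is idempotent.
#'
#' @param phenotypes Long phenotype tibble (`family_id`, `trait_id`, `value`).
#' @return The same tibble with standardized values and attribute
#'   `standardized = TRUE`.
#' @export
standardize_phenotypes <- function(phenotypes) {
  out <- phenotypes |>
    group_by(.data$trait_id) |>
    group_modify(function(d, key) {
      v <- d$value[!is.na(d$value)]
      if (length(v) < 2)
        abort(paste0("trait ", key$trait_id, " has fewer than 2 non-missing values"))
      s <- sd(v)
      if (s < 1e-12)
        abort(paste0("trait ", key$trait_id, " has zero standard deviation"))
      d$value <- (d$value - mean(v)) / s
      d
    }) |>
    ungroup()
  attr(out, "standardized") <- TRUE
  out
}

#' Filter markers by minor allele frequency
#'
#' Retains markers whose minor genotype-class frequency (computed over
#' non-missing calls) is at least `maf_min`. Mirrors the exclusion of markers
#' with strong segregation distortion before variance/covariance scans.
#'
#' @param genotypes Genotype tibble.
#' @param maf_min Minimum minor allele frequency (default 0.33).
#' @return The filtered genotype tibble; excluded markers are logged.
#' @export
filter_maf <- function(genotypes, maf_min = 0.33) {
  af <- allele_freqs(genotypes)
  drop <- af$marker[is.na(af$maf) | af$maf < maf_min]
  if (length(drop) == length(af$marker))
    warn("all markers fail the MAF filter; returning an empty matrix")
  vc_inform("filter_maf: ", nrow(af) - length(drop), "/", nrow(af),
            " markers retained (maf_min = ", maf_min, ")",
            if (length(drop) > 0) paste0("; excluded: ", paste(drop, collapse = ", ")))
  genotypes[c("family_id", setdiff(af$marker, drop))]
}

#' Brown-Forsythe two-group variance test statistic
#'
#' The Levene statistic computed on absolute deviations from the group
#' medians, for two groups: with `z_ij = |y_ij - median(group i)|`,
#' `F = (N - 2) * sum_i n_i (zbar_i - zbar)^2 / sum_ij (z_ij - zbar_i)^2`.
#' Location shifts of either group leave the statistic unchanged.
#'
#' @param group_CO,group_MT Numeric vectors of trait values for the two
#'   homozygote classes (each of length >= 2).
#' @return The F statistic (1 and N-2 df).
#' @export
brown_forsythe <- function(group_CO, group_MT) {
  g0 <- group_CO[!is.na(group_CO)]
  g1 <- group_MT[!is.na(group_MT)]
  if (length(g0) < 2 || length(g1) < 2)
    abort("each genotype class needs at least 2 values")
  z0 <- abs(g0 - median(g0))
  z1 <- abs(g1 - median(g1))
  n0 <- length(z0); n1 <- length(z1); N <- n0 + n1
  zb0 <- mean(z0); zb1 <- mean(z1)
  zb <- (n0 * zb0 + n1 * zb1) / N
  den <- sum((z0 - zb0)^2) + sum((z1 - zb1)^2)
  if (den <= 0) abort("within-group deviations are all zero; statistic undefined")
  (N - 2) * (n0 * (zb0 - zb)^2 + n1 * (zb1 - zb)^2) / den
}

#' Genome-wide variance-QTL scan
#'
#' Computes the Brown-Forsythe statistic contrasting the two homozygote
#' classes at every marker and assigns genome-wide permutation p-values by the
#' maximum-statistic method: trait values are shuffled against the genotype
#' matrix as whole family vectors (the per-family genotype vector and trait
#' value are never altered internally), the genome-wide maximum statistic of
#' each permuted dataset forms the null distribution, and
#' `perm_p = #(maxima >= observed) / n_perm`. With `correction = TRUE` the
#' estimate `(# + 1) / (n_perm + 1)` is reported instead (never zero).
#'
#' Markers failing the MAF filter are absent from the result; markers where a
#' genotype class has fewer than 2 non-missing families are skipped with a
#' warning (NA statistic).
#'
#' @param genotypes Genotype tibble.
#' @param phenotypes Long phenotype tibble.
#' @param trait Trait id to scan.
#' @param map Optional genetic map; adds `linkage_group` and `cM` columns.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for the permutation stream.
#' @param maf_min Minor-allele-frequency threshold applied before the scan
#'   (set to 0 to disable).
#' @param correction Use the add-one permutation p-value estimate.
#' @return A `vcqtl_scan` tibble: `marker`, (`linkage_group`, `cM`,)
#'   `statistic`, `perm_p`, `n_CO`, `n_MT`.
#' @export
scan_variance <- function(genotypes, phenotypes, trait, map = NULL,
                          n_perm = 1000, seed = NULL, maf_min = 0.33,
                          correction = FALSE) {
  if (maf_min > 0) genotypes <- filter_maf(genotypes, maf_min)
  y_tbl <- phenotypes |>
    filter(.data$trait_id == trait) |>
    inner_join(genotypes["family_id"], by = "family_id") |>
    filter(!is.na(.data$value))
  if (nrow(y_tbl) < 4) abort("too few families with genotype and trait data")
  geno <- geno_int_matrix(genotypes[match(y_tbl$family_id, genotypes$family_id), ])
  if (!is.null(seed)) withr::local_seed(seed)
  vc_inform("scan_variance: trait ", trait, ", ", nrow(geno), " families x ",
            ncol(geno), " markers, ", n_perm, " permutations",
            if (!is.null(seed)) paste0(", seed ", seed))
  perms <- perm_matrix(nrow(geno), n_perm)
  res <- cpp_scan_bf(y_tbl$value, geno, perms)
  finish_scan(res, colnames(geno), map, n_perm, correction,
              method = "brown_forsythe", trait = trait)
}

# Shared post-processing: permutation p-values and output assembly.
finish_scan <- function(res, markers, map, n_perm, correction, method, trait) {
  pm <- res$perm_max[!is.na(res$perm_max)]
  pp <- vapply(res$statistic, function(s) {
    if (is.na(s) || length(pm) == 0) return(NA_real_)
    k <- sum(pm >= s)
    if (correction) (k + 1) / (length(pm) + 1) else k / length(pm)
  }, numeric(1))
  out <- tibble(marker = markers, statistic = res$statistic, perm_p = pp,
                n_CO = res$n_CO, n_MT = res$n_MT)
  if (any(is.na(out$statistic)))
    warn(paste0("marker(s) skipped (degenerate genotype classes): ",
                paste(out$marker[is.na(out$statistic)], collapse = ", ")))
  if (!is.null(map))
    out <- out |>
      left_join(map, by = "marker") |>
      select("marker", "linkage_group", "cM", everything())
  attr(out, "method") <- method
  attr(out, "trait") <- trait
  attr(out, "n_perm") <- n_perm
  class(out) <- c("vcqtl_scan", class(out))
  out
}

#' Decompose marker-associated trait variance
#'
#' Splits the pooled two-class phenotypic variance at a biallelic homozygous
#' locus into the part explained by the difference in class means (`Vm`), the
#' part explained by the difference in class standard deviations (`Vv`), and a
#' residual:
#' `Vp = p*q*(mu_CO - mu_MT)^2 + p*q*(sd_CO - sd_MT)^2 + (p*sd_CO + q*sd_MT)^2`
#' with `p`, `q` the class frequencies. The identity is exact, so
#' `Vm_over_Vp + Vv_over_Vp <= 1`, `Vm = 0` iff the means are equal and
#' `Vv = 0` iff the SDs are equal.
#'
#' @param group_CO,group_MT Trait values for the two classes (each >= 2).
#' @return A one-row tibble: `p`, `q`, `mu_CO`, `mu_MT`, `sigma_CO`,
#'   `sigma_MT`, `Vp`, `Vm_over_Vp`, `Vv_over_Vp`.
#' @export
decompose_variance <- function(group_CO, group_MT) {
  g0 <- group_CO[!is.na(group_CO)]
  g1 <- group_MT[!is.na(group_MT)]
  if (length(g0) < 2 || length(g1) < 2)
    abort("each genotype class needs at least 2 values")
  p <- length(g0) / (length(g0) + length(g1)); q <- 1 - p
  mu0 <- mean(g0); mu1 <- mean(g1)
  s0 <- sd(g0); s1 <- sd(g1)
  vm <- p * q * (mu0 - mu1)^2
  vv <- p * q * (s0 - s1)^2
  vr <- (p * s0 + q * s1)^2
  vp <- vm + vv + vr
  tibble(p = p, q = q, mu_CO = mu0, mu_MT = mu1, sigma_CO = s0, sigma_MT = s1,
         Vp = vp, Vm_over_Vp = vm / vp, Vv_over_Vp = vv / vp)
}

#' Pairwise epistasis scan around a focal marker
#'
#' For each partner marker, fits the two-way fixed-effects ANOVA
#' `trait ~ focal * partner` on family means (families with a missing call at
#' either marker dropped) and reports the interaction F and p-value. Partners
#' with any empty genotype cell (including partners perfectly confounded with
#' the focal marker) are skipped with a warning.
#'
#' @param genotypes Genotype tibble.
#' @param phenotypes Long phenotype tibble.
#' @param trait Trait id.
#' @param focal_marker Focal marker id.
#' @param partner_markers Character vector of partner marker ids (default: all
#'   other markers).
#' @return A tibble: `partner`, `interaction_F`, `interaction_p`, `n`.
#' @export
pairwise_epistasis <- function(genotypes, phenotypes, trait, focal_marker,
                               partner_markers = NULL) {
  if (!focal_marker %in% names(genotypes)) abort("focal marker not in genotype matrix")
  partner_markers <- partner_markers %||% setdiff(marker_names(genotypes), focal_marker)
  y_tbl <- phenotypes |>
    filter(.data$trait_id == trait, !is.na(.data$value))
  dat0 <- genotypes |>
    select("family_id", all_of(c(focal_marker, partner_markers))) |>
    inner_join(y_tbl[c("family_id", "value")], by = "family_id")
  skipped <- character(0)
  rows <- purrr::map_dfr(partner_markers, function(mk) {
    d <- tibble(y = dat0$value,
                f = factor(dat0[[focal_marker]], levels = c("CO", "MT")),
                g = factor(dat0[[mk]], levels = c("CO", "MT"))) |>
      filter(!is.na(.data$f), !is.na(.data$g))
    cells <- table(d$f, d$g)
    if (any(cells == 0) || nrow(d) < 8) {
      skipped <<- c(skipped, mk)
      return(tibble(partner = mk, interaction_F = NA_real_,
                    interaction_p = NA_real_, n = nrow(d)))
    }
    a <- anova(lm(y ~ f * g, data = d))
    tibble(partner = mk, interaction_F = a["f:g", "F value"],
           interaction_p = a["f:g", "Pr(>F)"], n = nrow(d))
  })
  if (length(skipped) > 0)
    warn(paste0("partner marker(s) skipped (empty genotype cells): ",
                paste(skipped, collapse = ", ")))
  rows
}

#' Sequential Bonferroni (Holm) adjustment
#'
#' Convenience wrapper around `stats::p.adjust(method = "holm")` for the small
#' sets of univariate tests reported alongside the mixed-model ANOVAs.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) p.adjust(p, method = "holm")
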