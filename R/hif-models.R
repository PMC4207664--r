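#' Delta-Ct from paired qPCR cycle thresholds
#'
#' `delta_Ct = Ct(reference) - Ct(target)`. When the target amplifies later
#' than the reference (the usual regime for a lowly expressed target), the
#' value is negative, and a larger (less negative) delta-Ct means higher
#' target expression. The relative signal is `2^delta_Ct`; the delta-Ct itself
#' (proportional to the log signal) is the recommended analysis response.
#'
#' @param ct_reference Ct values of the reference gene (e.g. ACT2).
#' @param ct_target Ct values of the target gene (e.g. FT).
#' @return Numeric vector of delta-Ct values.
#' @export
delta_ct <- function(ct_reference, ct_target) {
  if (any(!is.finite(ct_reference)) || any(!is.finite(ct_target)))
    abort("Ct values must be finite")
  ct_reference - ct_target
}

#' Relative expression from delta-Ct
#' @param dct Delta-Ct values.
#' @return `2^dct`.
#' @export
relative_expression <- function(dct) 2^dct

# Containment denominator df. A fixed term is tested in the family stratum
# when all of its factors are among `family_contains` (the factors the family
# random term is treated as nested within); otherwise in the residual stratum.
# family-stratum df = n_families - n observed (genotype x HIF) cells;
# residual df = N - n_families - n_blocks - 1 (n_blocks = 0 without a block term).
containment_df <- function(term, data, family_contains, has_block) {
  n <- nrow(data)
  n_fam <- nlevels(droplevels(data$Family))
  n_cells <- nrow(distinct(data, .data$nFT_genotype, .data$HIF))
  n_block <- if (has_block) nlevels(droplevels(data$Block)) else 0L
  parts <- strsplit(term, ":")[[1]]
  if (length(parts) > 0 && all(parts %in% family_contains))
    n_fam - n_cells
  else
    n - n_fam - n_block - 1
}

fit_lmm <- function(formula, data) {
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      formula, data = data, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) abort(paste0("mixed model failed to converge: ",
                                     conditionMessage(e))))
  fit
}

# REML likelihood-ratio test for dropping one random intercept. Boundary
# estimates give chi2 = 0 (p = 1); the 1-df chi-square reference is used
# without boundary correction.
random_lrt <- function(full_fit, formula_reduced, data) {
  ll_full <- as.numeric(logLik(full_fit))
  red_terms <- lme4::findbars(formula_reduced)
  ll_red <- if (length(red_terms) == 0) {
    as.numeric(logLik(lm(lme4::nobars(formula_reduced), data = data), REML = TRUE))
  } else {
    as.numeric(logLik(fit_lmm(formula_reduced, data)))
  }
  chi2 <- max(0, 2 * (ll_full - ll_red))
  c(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

build_anova_table <- function(fit, data, formula, response, fixed_terms,
                              random_terms, family_contains, has_block, ddf) {
  a3 <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  rows <- purrr::map_dfr(fixed_terms, function(tm) {
    stopifnot(tm %in% rownames(a3))
    den <- if (ddf == "containment")
      containment_df(tm, data, family_contains, has_block)
    else a3[tm, "DenDF"]
    Fv <- a3[tm, "F value"]
    tibble(term = tm, type = "fixed", statistic = Fv,
           num_df = a3[tm, "NumDF"], den_df = den,
           p_value = pf(Fv, a3[tm, "NumDF"], den, lower.tail = FALSE))
  })
  rand_rows <- purrr::map_dfr(random_terms, function(tm) {
    reduced <- drop_random_term(formula, tm)
    lrt <- random_lrt(fit, reduced, data)
    tibble(term = tm, type = "random", statistic = lrt[["chi2"]],
           num_df = 1, den_df = NA_real_, p_value = lrt[["p"]])
  })
  structure(list(table = bind_rows(rows, rand_rows), fit = fit,
                 response = response, n_obs = nrow(data),
                 ddf = ddf),
            class = "vcqtl_anova")
}

drop_random_term <- function(formula, term) {
  rhs <- paste(deparse(formula[[3]]), collapse = " ")
  rhs_new <- gsub(paste0("\\+\\s*\\(1\\s*\\|\\s*", term, "\\)"), "", rhs)
  as.formula(paste(deparse(formula[[2]]), "~", rhs_new))
}

#' Mixed-model ANOVA for a HIF phenotype experiment
#'
#' REML fit of `response ~ nFT_genotype * HIF + (1|Family) + (1|Block)` with
#' marginal (Type III) F tests for the fixed terms and REML likelihood-ratio
#' chi-squared tests (1 df) for the random intercepts. Family is the sibling
#' group nested within a genotype-by-background cell; Block is the greenhouse
#' block (omitted automatically when the data have at most one block level).
#'
#' Denominator degrees of freedom use the containment method by default:
#' terms composed entirely of between-lineage factors (`family_contains`,
#' default `"HIF"`) are tested at the family stratum
#' (`n_families - n_cells`), all other fixed terms at the residual stratum
#' (`N - n_families - n_blocks - 1`). `ddf = "satterthwaite"` is available as
#' an alternative. Variance components estimated at the boundary (zero) are
#' reported, not errors.
#'
#' @param data A HIF tibble (see [read_hif_table()] / [sim_hif()]).
#' @param response Name of the response column (e.g. `"Flowering_time"`).
#' @param family_contains Factors whose terms are tested at the family
#'   stratum under containment.
#' @param ddf `"containment"` (default) or `"satterthwaite"`.
#' @return A `vcqtl_anova` object; `tidy()` returns the test table.
#' @export
fit_hif_mixed_model <- function(data, response, family_contains = "HIF",
                                ddf = c("containment", "satterthwaite")) {
  ddf <- match.arg(ddf)
  stopifnot(response %in% names(data))
  data <- droplevels(as_tibble(data))
  if (nlevels(data$HIF) < 2) abort("at least 2 HIFs are required")
  has_block <- "Block" %in% names(data) && nlevels(droplevels(factor(data$Block))) > 1
  rhs <- "nFT_genotype * HIF + (1 | Family)"
  if (has_block) rhs <- paste(rhs, "+ (1 | Block)")
  formula <- as.formula(paste(response, "~", rhs))
  fit <- fit_lmm(formula, data)
  build_anova_table(fit, data, formula, response,
                    fixed_terms = c("nFT_genotype", "HIF", "nFT_genotype:HIF"),
                    random_terms = c("Family", if (has_block) "Block"),
                    family_contains = family_contains, has_block = has_block,
                    ddf = ddf)
}

#' Mixed-model ANOVA for a HIF expression experiment
#'
#' Same contract as [fit_hif_mixed_model()] on the delta-Ct response, without
#' a block term (a single-block design), and with all design factors tested at
#' the family stratum under containment — the family (sibling group) is the
#' unit of biological replication for genotype and background in the small
#' expression design.
#'
#' @param data An expression tibble (see [read_expression_table()] /
#'   [sim_expression()]).
#' @param ddf `"containment"` (default) or `"satterthwaite"`.
#' @return A `vcqtl_anova` object.
#' @export
fit_expression_model <- function(data, ddf = c("containment", "satterthwaite")) {
  ddf <- match.arg(ddf)
  data <- droplevels(as_tibble(data))
  if (nlevels(data$HIF) < 2) abort("at least 2 HIFs are required")
  formula <- delta_Ct ~ nFT_genotype * HIF + (1 | Family)
  fit <- fit_lmm(formula, data)
  build_anova_table(fit, data, formula, "delta_Ct",
                    fixed_terms = c("nFT_genotype", "HIF", "nFT_genotype:HIF"),
                    random_terms = "Family",
                    family_contains = c("nFT_genotype", "HIF"),
                    has_block = FALSE, ddf = ddf)
}

#' Association between visible buds and expression
#'
#' Mixed model `delta_Ct ~ Visible_bud + (1 | Family)`: does the phenological
#' state (visible flowering buds at tissue collection) predict focal-gene
#' expression? F for the bud term with containment residual df
#' (`N - n_families - 1`). A constant delta-Ct gives a zero F by definition.
#'
#' @param data An expression tibble with both bud states present.
#' @return A `vcqtl_anova` object with the `Visible_bud` fixed term and the
#'   `Family` random term.
#' @export
test_bud_association <- function(data) {
  data <- droplevels(as_tibble(data))
  if (length(unique(data$Visible_bud)) < 2)
    abort("both bud states must be present")
  n <- nrow(data)
  n_fam <- nlevels(data$Family)
  den <- n - n_fam - 1
  if (sd(data$delta_Ct) < 1e-12) {
    tab <- tibble(term = c("Visible_bud", "Family"),
                  type = c("fixed", "random"),
                  statistic = c(0, 0), num_df = c(1, 1),
                  den_df = c(den, NA_real_), p_value = c(1, 1))
    return(structure(list(table = tab, fit = NULL, response = "delta_Ct",
                          n_obs = n, ddf = "containment"),
                     class = "vcqtl_anova"))
  }
  formula <- delta_Ct ~ Visible_bud + (1 | Family)
  fit <- fit_lmm(formula, data)
  a3 <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  Fv <- a3["Visible_bud", "F value"]
  lrt <- random_lrt(fit, delta_Ct ~ Visible_bud, data)
  tab <- bind_rows(
    tibble(term = "Visible_bud", type = "fixed", statistic = Fv,
           num_df = a3["Visible_bud", "NumDF"], den_df = den,
           p_value = pf(Fv, a3["Visible_bud", "NumDF"], den, lower.tail = FALSE)),
    tibble(term = "Family", type = "random", statistic = lrt[["chi2"]],
           num_df = 1, den_df = NA_real_, p_value = lrt[["p"]]))
  structure(list(table = tab, fit = fit, response = "delta_Ct", n_obs = n,
                 ddf = "containment"),
            class = "vcqtl_anova")
}
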