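test_that("delta-Ct arithmetic and relative expression", {
  expect_equal(delta_ct(20, 25), -5)
  expect_equal(relative_expression(delta_ct(20, 25)), 1 / 32)
  expect_equal(delta_ct(20, 20), 0)
  expect_true(all(delta_ct(c(18, 20), c(24, 27)) < 0))
  expect_error(delta_ct(NA, 20), "finite")
})

test_that("mixed model reduces to two-way fixed ANOVA when variance components vanish", {
  skip_if_not_installed("car")
  d <- sim_hif(backgrounds = c(a = 5.2, b = 6.0), families_per_hif = 8,
               sibs_per_family = 4, n_blocks = 2,
               family_sd = 0, block_sd = 0, seed = 53)
  a <- fit_hif_mixed_model(d, "Flowering_time")
  vc <- glance(a)
  expect_lt(vc$sigma_Family, 1e-8)   # estimates sit on the boundary
  expect_lt(vc$sigma_Block, 1e-8)
  ref <- car::Anova(lm(Flowering_time ~ nFT_genotype * HIF, data = d,
                       contrasts = list(nFT_genotype = "contr.sum",
                                        HIF = "contr.sum")), type = 3)
  tab <- tidy(a)
  expect_equal(tab$statistic[tab$term == "nFT_genotype"],
               ref["nFT_genotype", "F value"], tolerance = 1e-6)
  expect_equal(tab$statistic[tab$term == "HIF"], ref["HIF", "F value"],
               tolerance = 1e-6)
  expect_equal(tab$statistic[tab$term == "nFT_genotype:HIF"],
               ref["nFT_genotype:HIF", "F value"], tolerance = 1e-6)
})

test_that("REML variance components match an independent restricted-likelihood maximizer", {
  e <- sim_expression(backgrounds = c(a = 5.5, b = 6.5), families_per_class = 4,
                      plants_per_family = 4, family_sd = 0.8, resid_sd = 0.5,
                      seed = 52)
  a <- fit_expression_model(e)
  vc <- glance(a)

  # independent REML deviance: profile over (sigma2_family, sigma2_resid)
  X <- model.matrix(~ nFT_genotype * HIF, data = e)
  Zf <- model.matrix(~ 0 + Family, data = e)
  y <- e$delta_Ct
  restricted_ll <- function(s2f, s2e) {
    V <- s2f * tcrossprod(Zf) + s2e * diag(length(y))
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              t(y) %*% P %*% y)[1]
  }
  # coarse grid then local refinement
  grid <- expand.grid(s2f = seq(0.01, 2, length.out = 15),
                      s2e = seq(0.05, 1.5, length.out = 15))
  ll <- mapply(restricted_ll, grid$s2f, grid$s2e)
  start <- grid[which.max(ll), ]
  opt <- optim(log(as.numeric(start)),
               function(p) -restricted_ll(exp(p[1]), exp(p[2])))
  oracle <- exp(opt$par)
  expect_equal(vc$sigma_Family^2, oracle[1], tolerance = 0.01)
  expect_equal(vc$sigma_residual^2, oracle[2], tolerance = 0.01)
})

test_that("planted interactions are recovered and saturated backgrounds give none", {
  # backgrounds straddling one threshold: strong genotype-by-background signal
  d <- sim_hif(backgrounds = c(mid = 3.0, hi = 5.2), families_per_hif = 8,
               sibs_per_family = 4, n_blocks = 2, seed = 53)
  tab <- tidy(fit_hif_mixed_model(d, "Flowering_time"))
  expect_lt(tab$p_value[tab$term == "nFT_genotype:HIF"], 0.01)

  # both backgrounds above the high threshold: no interaction in expectation
  d0 <- sim_hif(backgrounds = c(hi1 = 7.5, hi2 = 8.5), families_per_hif = 8,
                sibs_per_family = 4, n_blocks = 2, seed = 55)
  tab0 <- tidy(fit_hif_mixed_model(d0, "Flowering_time"))
  expect_gt(tab0$p_value[tab0$term == "nFT_genotype:HIF"], 0.05)
})

test_that("interaction recovery rate across seeds matches the designed power", {
  hits <- purrr::map_lgl(1:100, function(s) {
    d <- sim_hif(backgrounds = c(mid = 3.0, hi = 5.2), families_per_hif = 6,
                 sibs_per_family = 3, n_blocks = 3, seed = 1000 + s)
    tab <- tidy(fit_hif_mixed_model(d, "Flowering_time"))
    tab$p_value[tab$term == "nFT_genotype:HIF"] < 0.05
  })
  expect_gte(mean(hits), 0.90)
})

test_that("REML estimates are unbiased and the null interaction is calibrated", {
  true_fam <- 3; true_block <- 2
  res <- purrr::map_dfr(1:200, function(s) {
    d <- sim_hif(backgrounds = c(a = 7.5, b = 8.5), families_per_hif = 6,
                 sibs_per_family = 4, n_blocks = 4,
                 family_sd = true_fam, block_sd = true_block, seed = 2000 + s)
    a <- fit_hif_mixed_model(d, "Flowering_time")
    vc <- glance(a)
    tab <- tidy(a)
    tibble::tibble(s2_fam = vc$sigma_Family^2,
                   s2_res = vc$sigma_residual^2,
                   p_int = tab$p_value[tab$term == "nFT_genotype:HIF"])
  })
  # residual variance under saturation: season1_sd^2 + (slope_c * noise_sd)^2
  m <- threshold_model()
  true_res <- m$season1_sd^2 + (m$slope_c * m$noise_sd)^2
  expect_lt(abs(mean(res$s2_fam) - true_fam^2), 0.2 * true_fam^2)
  expect_lt(abs(mean(res$s2_res) - true_res), 0.1 * true_res)
  # no true interaction above saturation: ~5% rejections at alpha = 0.05
  expect_lt(abs(mean(res$p_int < 0.05) - 0.05), 0.04)
})

test_that("containment denominator df follow the design strata", {
  d <- sim_hif(families_per_hif = 5, sibs_per_family = 3, n_blocks = 3, seed = 55)
  tab <- tidy(fit_hif_mixed_model(d, "Flowering_time"))
  n <- nrow(d); n_fam <- nlevels(droplevels(d$Family)); n_block <- 3
  expect_equal(tab$den_df[tab$term == "HIF"], n_fam - 4 * 2)
  expect_equal(tab$den_df[tab$term == "nFT_genotype"], n - n_fam - n_block - 1)
  expect_equal(tab$den_df[tab$term == "nFT_genotype:HIF"], n - n_fam - n_block - 1)

  e <- sim_expression(seed = 56)
  tabe <- tidy(fit_expression_model(e))
  n_fam_e <- nlevels(droplevels(e$Family))
  expect_true(all(tabe$den_df[tabe$type == "fixed"] == n_fam_e - 4))
})

test_that("fixed-effect F statistics are invariant to factor relabeling", {
  d <- sim_hif(families_per_hif = 6, sibs_per_family = 3, n_blocks = 2, seed = 57)
  tab <- tidy(fit_hif_mixed_model(d, "Flowering_time"))
  d2 <- d
  levels(d2$HIF) <- rev(paste0("Z", seq_len(nlevels(d$HIF))))
  d2$nFT_genotype <- factor(ifelse(d$nFT_genotype == "CO", "MT", "CO"),
                            levels = c("CO", "MT"))
  tab2 <- tidy(fit_hif_mixed_model(d2, "Flowering_time"))
  expect_equal(tab2$statistic[tab2$type == "fixed"],
               tab$statistic[tab$type == "fixed"], tolerance = 1e-4)
})

test_that("random-effect LRT sits at the boundary when a component is absent", {
  e <- sim_expression(backgrounds = c(a = 5.5, b = 6.5), family_sd = 0,
                      families_per_class = 5, plants_per_family = 3, seed = 58)
  tab <- tidy(fit_expression_model(e))
  expect_lt(tab$statistic[tab$term == "Family"], 1)
})

test_that("bud association: detects coupling, rejects degenerate input, zero F on constant data", {
  e <- sim_expression(backgrounds = c(low = 0.5, mid = 3.0),
                      families_per_class = 6, plants_per_family = 3, seed = 59)
  tab <- tidy(test_bud_association(e))
  expect_lt(tab$p_value[tab$term == "Visible_bud"], 0.01)
  expect_equal(tab$den_df[tab$term == "Visible_bud"],
               nrow(e) - nlevels(droplevels(e$Family)) - 1)

  e_one <- dplyr::mutate(e, Visible_bud = TRUE)
  expect_error(test_bud_association(e_one), "both bud states")

  e_const <- dplyr::mutate(e, delta_Ct = -5)
  tabc <- tidy(test_bud_association(e_const))
  expect_equal(tabc$statistic[tabc$term == "Visible_bud"], 0)
})

test_that("null bud association p-values are roughly uniform", {
  rej <- purrr::map_lgl(1:60, function(s) {
    withr::local_seed(3000 + s)
    e <- sim_expression(backgrounds = c(a = 3.0, b = 3.0),
                        families_per_class = 6, plants_per_family = 3)
    e$Visible_bud <- sample(rep(c(TRUE, FALSE), length.out = nrow(e)))
    tidy(test_bud_association(e))$p_value[1] < 0.05
  })
  expect_lt(mean(rej), 0.15)
})

test_that("holm adjustment applies the sequential Bonferroni schedule", {
  # sorted p (0.01, 0.03, 0.04) scale by (3, 2, 1) with running maximum
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
})
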