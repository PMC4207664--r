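#' Simulate a genetic map
#'
#' Evenly spaced markers over a given number of linkage groups, mirroring a
#' typical biparental RIL linkage map (default: 164 markers on 7 linkage
#' groups at 5.5 cM spacing).
#'
#' @param n_markers Total number of markers.
#' @param n_linkage_groups Number of linkage groups.
#' @param spacing Marker spacing in centimorgans.
#' @return A genetic-map tibble (`marker`, `linkage_group`, `cM`).
#' @export
sim_genetic_map <- function(n_markers = 164, n_linkage_groups = 7, spacing = 5.5) {
  stopifnot(n_markers >= n_linkage_groups, spacing >= 0)
  sizes <- rep(n_markers %/% n_linkage_groups, n_linkage_groups)
  extra <- n_markers %% n_linkage_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  purrr::map2_dfr(seq_len(n_linkage_groups), sizes, function(lg, k) {
    tibble(marker = sprintf("m%02d_%03d", lg, seq_len(k)),
           linkage_group = as.integer(lg),
           cM = spacing * (seq_len(k) - 1))
  })
}

#' Simulate RIL genotypes by repeated selfing
#'
#' Simulates diploid descent from a fully heterozygous F1 through
#' `selfing_generations` rounds of self-pollination with single-seed descent.
#' Crossovers are drawn independently each meiosis under the Haldane map
#' function (no interference); markers on different linkage groups segregate
#' independently. The final call is `CO` or `MT` where the line is homozygous
#' and `NA` where residual heterozygosity remains (expected fraction
#' `2^-selfing_generations`, about 3.1% for the default five generations,
#' i.e. ~96.9% homozygous calls).
#'
#' @param map Genetic-map tibble.
#' @param n_families Number of RIL families (default 178).
#' @param selfing_generations Number of selfing rounds after the F1
#'   (default 5, an F6 population).
#' @param seed Optional integer seed.
#' @return A genotype tibble (`family_id` + one column per marker).
#' @export
sim_ril_genotypes <- function(map, n_families = 178, selfing_generations = 5,
                              seed = NULL) {
  if (nrow(map) == 0) abort("empty genetic map")
  stopifnot(n_families > 0, selfing_generations >= 1)
  if (!is.null(seed)) withr::local_seed(seed)

  m <- nrow(map)
  # Recombination fraction between adjacent markers; 0.5 across linkage groups.
  r <- if (m > 1) {
    d <- diff(map$cM)
    same_lg <- diff(map$linkage_group) == 0
    ifelse(same_lg, 0.5 * (1 - exp(-2 * d / 100)), 0.5)
  } else numeric(0)

  gamete <- function(h1, h2) {
    n <- nrow(h1)
    pick <- matrix(FALSE, n, m)
    pick[, 1] <- runif(n) < 0.5
    if (m > 1) {
      sw <- matrix(runif(n * (m - 1)) < rep(r, each = n), n, m - 1)
      for (j in 2:m) pick[, j] <- xor(pick[, j - 1], sw[, j - 1])
    }
    ifelse(pick, h2, h1)
  }

  h1 <- matrix(0L, n_families, m)  # CO haplotype
  h2 <- matrix(1L, n_families, m)  # MT haplotype
  for (gen in seq_len(selfing_generations)) {
    g1 <- gamete(h1, h2)
    g2 <- gamete(h1, h2)
    h1 <- g1; h2 <- g2
  }

  calls <- matrix(NA_character_, n_families, m)
  calls[h1 == 0L & h2 == 0L] <- "CO"
  calls[h1 == 1L & h2 == 1L] <- "MT"
  res <- as_tibble(calls, .name_repair = "minimal")
  names(res) <- map$marker
  bind_cols(tibble(family_id = sprintf("RIL%03d", seq_len(n_families))), res)
}

#' Sigmoid expression response
#'
#' Probability that the floral integrator is activated given input signal `x`,
#' steepness `a` and genotype-specific threshold `b`:
#' `y = 1 / (1 + exp(a * (-x + b)))`. As `a` grows the curve converges to a
#' hard threshold at `b`.
#'
#' @param x Input signal (genomic background + environment).
#' @param a Sigmoid steepness (> 0).
#' @param b Activation threshold in signal units.
#' @return Activation probability in (0, 1).
#' @export
sigmoid_response <- function(x, a, b) {
  stopifnot(a > 0)
  plogis(a * (x - b))
}

#' Default threshold flowering model
#'
#' Parameters of the threshold/sigmoid flowering-time integrator used by the
#' phenotype simulators. Twelve background loci (two per non-focal linkage
#' group) contribute equal signal; each environment adds a fixed offset; the
#' focal locus responds through a sigmoid whose threshold depends on its
#' genotype (`b_MT < b_CO`: the MT genotype flowers at lower signal).
#' Individuals that activate flower in season 1 at `season1_base -
#' slope_c * x` days (truncated below 180); the rest flower in season 2
#' around `season2_base` days (truncated above 180). Leaf number at flowering
#' is coupled to flowering time.
#'
#' The six default environment offsets are a packaged calibration chosen so
#' the simulated grand-mean flowering times fall in the three regimes
#' (promoting, slightly inhibiting, strongly inhibiting) that motivate the
#' scans; see the methods vignette for the calibration and its limits.
#'
#' @param map Genetic-map tibble used to place the focal and background loci.
#' @param focal_marker Marker acting as the threshold locus; default the
#'   middle marker of linkage group 1.
#' @param n_background Number of background loci (spread over non-focal
#'   linkage groups).
#' @param beta Signal contribution of each background MT allele.
#' @return An object of class `threshold_model` (a named list).
#' @export
threshold_model <- function(map = sim_genetic_map(),
                            focal_marker = NULL,
                            n_background = 12,
                            beta = 0.5) {
  stopifnot(nrow(map) > 0)
  lgs <- sort(unique(map$linkage_group))
  if (is.null(focal_marker)) {
    lg1 <- map$marker[map$linkage_group == lgs[1]]
    focal_marker <- lg1[ceiling(length(lg1) / 2)]
  }
  if (!focal_marker %in% map$marker) abort("focal marker not in map")
  focal_lg <- map$linkage_group[map$marker == focal_marker]
  other_lgs <- setdiff(lgs, focal_lg)
  per_lg <- ceiling(n_background / length(other_lgs))
  bg <- character(0)
  for (lg in other_lgs) {
    mk <- map$marker[map$linkage_group == lg]
    at <- unique(pmax(1, round(length(mk) * seq_len(per_lg) / (per_lg + 1))))
    bg <- c(bg, mk[at])
  }
  bg <- utils::head(unique(bg), n_background)
  structure(list(
    a = 4,
    b_CO = 4.2,
    b_MT = 1.8,
    focal_marker = focal_marker,
    background_effects = setNames(rep(beta, length(bg)), bg),
    env_offsets = c("16h18C4w" = 4.6, "16h18C6w" = 8.9,
                    "12h18C4w" = 2.1, "12h18C6w" = 2.5,
                    "16h25C4w" = -1.5, "16h25C6w" = -0.6),
    noise_sd = 0.4,
    season1_base = 175, season1_sd = 4,
    season2_base = 244, season2_sd = 10,
    slope_c = 4.5,
    leaf_coupling = 0.3, leaf_sd = 3
  ), class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Threshold flowering model\n")
  cat("  sigmoid: a =", x$a, ", thresholds b_CO =", x$b_CO, ", b_MT =", x$b_MT, "\n")
  cat("  focal locus:", x$focal_marker, "|", length(x$background_effects),
      "background loci (beta =", unname(x$background_effects[1]), ")\n")
  cat("  environments:", paste(names(x$env_offsets), collapse = ", "), "\n")
  invisible(x)
}

validate_threshold_model <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  if (!(model$b_MT < model$b_CO))
    abort("threshold model requires b_MT < b_CO (the MT genotype has the lower threshold)")
  invisible(model)
}

# Individual-level generative rules shared by the RIL and HIF simulators.
# x: input signal; b: per-individual threshold. Returns days to flowering and
# a season-1 indicator; season-1 times are truncated below 180 days and
# season-2 times above 180 days.
draw_flowering <- function(x, b, model) {
  y <- sigmoid_response(x, model$a, b)
  s1 <- rbinom(length(x), 1, y) == 1
  t1 <- pmin(model$season1_base - model$slope_c * x +
               rnorm(length(x), 0, model$season1_sd), 179.5)
  t2 <- pmax(model$season2_base + rnorm(length(x), 0, model$season2_sd), 180.5)
  list(time = ifelse(s1, t1, t2), season1 = s1)
}

#' Simulate family-mean phenotypes under the threshold model
#'
#' For each individual, the input signal is the sum of background-locus
#' contributions (MT alleles add `beta` each; missing calls contribute half),
#' the environment offset, and Gaussian noise. The focal-locus genotype sets
#' the sigmoid threshold; activated individuals flower in season 1, the rest
#' in season 2. Family means over `n_reps` individuals are returned for
#' flowering time and leaf number in each requested environment.
#'
#' Families with a missing call at the focal marker are assigned a random
#' homozygous threshold (they remain in the phenotype table but carry no
#' focal-class information in scans).
#'
#' @param genotypes Genotype tibble containing the focal and background markers.
#' @param model A [threshold_model()].
#' @param environments Character vector of environment ids (default: all in
#'   the model).
#' @param n_reps Individuals per family per environment (default 5).
#' @param seed Optional integer seed.
#' @return A long phenotype tibble with trait ids
#'   `flowering_time@<env>` and `leaf_number@<env>`.
#' @export
sim_threshold_phenotypes <- function(genotypes, model = threshold_model(),
                                     environments = names(model$env_offsets),
                                     n_reps = 5, seed = NULL) {
  validate_threshold_model(model)
  if (!model$focal_marker %in% names(genotypes))
    abort(paste0("focal marker ", model$focal_marker, " missing from genotype matrix"))
  bad_env <- setdiff(environments, names(model$env_offsets))
  if (length(bad_env) > 0)
    abort(paste0("unknown environment(s): ", paste(bad_env, collapse = ", ")))
  if (!is.null(seed)) withr::local_seed(seed)

  bg <- names(model$background_effects)
  missing_bg <- setdiff(bg, names(genotypes))
  if (length(missing_bg) > 0)
    abort(paste0("background marker(s) missing from genotype matrix: ",
                 paste(missing_bg, collapse = ", ")))

  n <- nrow(genotypes)
  z <- vapply(bg, function(mk) {
    calls <- genotypes[[mk]]
    ifelse(is.na(calls), 0.5, as.numeric(calls == "MT"))
  }, numeric(n))
  base_signal <- as.numeric(z %*% model$background_effects)

  focal <- genotypes[[model$focal_marker]]
  focal_resolved <- ifelse(is.na(focal),
                           ifelse(runif(n) < 0.5, "CO", "MT"), focal)
  b_fam <- ifelse(focal_resolved == "MT", model$b_MT, model$b_CO)

  out <- purrr::map_dfr(environments, function(env) {
    e <- model$env_offsets[[env]]
    x <- rep(base_signal + e, each = n_reps) +
      rnorm(n * n_reps, 0, model$noise_sd)
    fl <- draw_flowering(x, rep(b_fam, each = n_reps), model)
    leaf <- model$leaf_coupling * fl$time + rnorm(n * n_reps, 0, model$leaf_sd)
    fam <- rep(genotypes$family_id, each = n_reps)
    tibble(family_id = fam, env = env, ft = fl$time, ln = leaf) |>
      group_by(.data$family_id) |>
      summarise(ft = mean(.data$ft), ln = mean(.data$ln), .groups = "drop") |>
      tidyr::pivot_longer(c("ft", "ln"), names_to = "tr", values_to = "value") |>
      mutate(trait_id = paste0(ifelse(.data$tr == "ft", "flowering_time", "leaf_number"),
                               "@", env)) |>
      select("family_id", "trait_id", "value")
  })
  arrange(out, .data$trait_id, match(.data$family_id, genotypes$family_id))
}

#' Simulate a heterogeneous inbred family (HIF) experiment
#'
#' Each HIF is a sibling group nearly identical in genomic background but
#' segregating for the two focal-locus homozygotes. The background signal is
#' fixed within a HIF (supplied per HIF); trait values follow the same
#' threshold generative rules as [sim_threshold_phenotypes()] with additional
#' family and block random intercepts. A true focal-by-background interaction
#' exists exactly when the background levels straddle one of the two
#' thresholds.
#'
#' @param model A [threshold_model()].
#' @param backgrounds Named or unnamed numeric vector of per-HIF background
#'   signal levels; `length(backgrounds)` is the number of HIFs (>= 2).
#' @param families_per_hif Homozygous families per HIF (split evenly between
#'   the CO and MT classes).
#' @param sibs_per_family Full siblings phenotyped per family (> 0).
#' @param n_blocks Number of greenhouse blocks; siblings are assigned
#'   cyclically so the design is balanced.
#' @param family_sd,block_sd SD (days) of family and block random intercepts.
#' @param seed Optional integer seed.
#' @return A HIF tibble with the standard columns (see [read_hif_table()]).
#' @export
sim_hif <- function(model = threshold_model(),
                    backgrounds = c(`3A` = 5.0, `89A` = 3.0, `98A` = 2.5, `105A` = 1.0),
                    families_per_hif = 20, sibs_per_family = 9, n_blocks = 9,
                    family_sd = 3, block_sd = 2, seed = NULL) {
  validate_threshold_model(model)
  if (length(backgrounds) < 2)
    abort("at least 2 HIFs are required (the interaction is untestable otherwise)")
  if (sibs_per_family <= 0) abort("sibs_per_family must be positive")
  stopifnot(families_per_hif >= 2, n_blocks >= 1)
  if (!is.null(seed)) withr::local_seed(seed)

  hif_ids <- names(backgrounds) %||% paste0("HIF", seq_along(backgrounds))
  if (is.null(names(backgrounds))) names(backgrounds) <- hif_ids

  block_dev <- rnorm(n_blocks, 0, block_sd)
  n_co <- ceiling(families_per_hif / 2)

  rows <- purrr::map_dfr(hif_ids, function(h) {
    purrr::map_dfr(seq_len(families_per_hif), function(f) {
      geno <- if (f <= n_co) "CO" else "MT"
      fam_id <- paste0(h, "_F", sprintf("%02d", f))
      fam_dev <- rnorm(1, 0, family_sd)
      blocks <- rep(seq_len(n_blocks), length.out = sibs_per_family)
      x <- backgrounds[[h]] + rnorm(sibs_per_family, 0, model$noise_sd)
      b <- if (geno == "MT") model$b_MT else model$b_CO
      fl <- draw_flowering(x, rep(b, sibs_per_family), model)
      ft <- fl$time + fam_dev + block_dev[blocks]
      leaf <- model$leaf_coupling * ft + rnorm(sibs_per_family, 0, model$leaf_sd)
      height <- 20 + 0.05 * ft + ifelse(geno == "MT", -2, 0) +
        0.5 * fam_dev + 0.3 * block_dev[blocks] +
        rnorm(sibs_per_family, 0, 2)
      tibble(Block = paste0("B", blocks),
             Flowering_time = ft,
             Leaf_number_at_flowering = leaf,
             Height_at_flowering = height,
             nFT_genotype = geno, HIF = h, Family = fam_id)
    })
  })
  rows |>
    mutate(Block = factor(.data$Block),
           nFT_genotype = factor(.data$nFT_genotype, levels = c("CO", "MT")),
           HIF = factor(.data$HIF), Family = factor(.data$Family))
}

#' Simulate a HIF expression (delta-Ct) experiment
#'
#' Delta-Ct of the focal transcript relative to a reference gene, generated
#' from the same sigmoid activation rules: expression rises with the
#' activation probability of the individual's genotype at its HIF background
#' signal, so an interaction exists when backgrounds straddle one threshold.
#' Bud presence is drawn from the same activation probability, coupling
#' phenology to expression.
#'
#' @param model A [threshold_model()].
#' @param backgrounds Per-HIF background signal levels (>= 2 HIFs).
#' @param families_per_class Families per focal genotype per HIF.
#' @param plants_per_family Plants measured per family.
#' @param dct_base Delta-Ct at zero activation (Ct units, negative).
#' @param dct_range Delta-Ct increase from zero to full activation.
#' @param family_sd,resid_sd Family and residual SD in Ct units.
#' @param seed Optional integer seed.
#' @return An expression tibble (see [read_expression_table()]).
#' @export
sim_expression <- function(model = threshold_model(),
                           backgrounds = c(`89A` = 1.0, `98A` = 3.0),
                           families_per_class = 5, plants_per_family = 2,
                           dct_base = -9, dct_range = 5,
                           family_sd = 0.3, resid_sd = 0.6, seed = NULL) {
  validate_threshold_model(model)
  if (length(backgrounds) < 2) abort("at least 2 HIFs are required")
  stopifnot(families_per_class >= 1, plants_per_family >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  hif_ids <- names(backgrounds) %||% paste0("HIF", seq_along(backgrounds))
  if (is.null(names(backgrounds))) names(backgrounds) <- hif_ids

  rows <- purrr::map_dfr(hif_ids, function(h) {
    purrr::map_dfr(c("CO", "MT"), function(geno) {
      purrr::map_dfr(seq_len(families_per_class), function(f) {
        fam_id <- paste0(h, "_", geno, sprintf("%02d", f))
        fam_dev <- rnorm(1, 0, family_sd)
        b <- if (geno == "MT") model$b_MT else model$b_CO
        x <- backgrounds[[h]] + rnorm(plants_per_family, 0, model$noise_sd)
        y <- sigmoid_response(x, model$a, b)
        dct <- dct_base + dct_range * y + fam_dev +
          rnorm(plants_per_family, 0, resid_sd)
        tibble(Plant_ID = paste0(fam_id, "_P", seq_len(plants_per_family)),
               HIF = h, Family = fam_id, nFT_genotype = geno,
               Visible_bud = rbinom(plants_per_family, 1, y) == 1,
               delta_Ct = pmin(dct, -0.1))
      })
    })
  })
  rows |>
    mutate(HIF = factor(.data$HIF), Family = factor(.data$Family),
           nFT_genotype = factor(.data$nFT_genotype, levels = c("CO", "MT")))
}
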