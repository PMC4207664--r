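#' @export
print.vcqtl_anova <- function(x, ...) {
  cat("Mixed-model ANOVA (", x$response, ", ", x$n_obs, " observations, ",
      x$ddf, " df)\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    if (tab$type[i] == "fixed") {
      cat(sprintf("  %-22s F_%d,%g = %8.2f   p = %s\n", tab$term[i],
                  tab$num_df[i], round(tab$den_df[i], 1), tab$statistic[i],
                  format.pval(tab$p_value[i], digits = 3, eps = 1e-3)))
    } else {
      cat(sprintf("  %-22s chi2_1 = %7.1f   p = %s  (random)\n", tab$term[i],
                  tab$statistic[i],
                  format.pval(tab$p_value[i], digits = 3, eps = 1e-3)))
    }
  }
  invisible(x)
}

#' Tidy a mixed-model ANOVA
#'
#' @param x A `vcqtl_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `type`, `statistic`
#'   (F for fixed terms, LRT chi-squared for random terms), `num_df`,
#'   `den_df`, `p_value`.
#' @method tidy vcqtl_anova
#' @export
tidy.vcqtl_anova <- function(x, ...) x$table

#' One-row model summary of a mixed-model ANOVA
#'
#' @param x A `vcqtl_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: `response`, `n_obs`, `logLik` (REML), variance
#'   components where available.
#' @method glance vcqtl_anova
#' @export
glance.vcqtl_anova <- function(x, ...) {
  if (is.null(x$fit))
    return(tibble(response = x$response, n_obs = x$n_obs, logLik = NA_real_,
                  sigma_residual = 0))
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  out <- tibble(response = x$response, n_obs = x$n_obs,
                logLik = as.numeric(logLik(x$fit)),
                sigma_residual = vc$sdcor[vc$grp == "Residual"])
  for (g in setdiff(vc$grp, "Residual"))
    out[[paste0("sigma_", g)]] <- vc$sdcor[vc$grp == g]
  out
}

#' Tidy a scan result
#'
#' Scan results already are tibbles; `tidy()` strips the scan class.
#'
#' @param x A `vcqtl_scan` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy vcqtl_scan
#' @export
tidy.vcqtl_scan <- function(x, ...) {
  class(x) <- setdiff(class(x), "vcqtl_scan")
  as_tibble(x)
}

#' One-row summary of a scan
#'
#' @param x A `vcqtl_scan` tibble.
#' @param ... Unused.
#' @return A one-row tibble: scan `method`, `trait`, `n_markers`, `n_perm`,
#'   `top_marker` (largest statistic), `min_perm_p`.
#' @method glance vcqtl_scan
#' @export
glance.vcqtl_scan <- function(x, ...) {
  ok <- !is.na(x$statistic)
  top <- if (attr(x, "method") == "krzanowski")
    x$marker[ok][which.min(x$statistic[ok])]
  else x$marker[ok][which.max(x$statistic[ok])]
  tibble(method = attr(x, "method"), trait = attr(x, "trait"),
         n_markers = nrow(x), n_perm = attr(x, "n_perm"),
         top_marker = top, min_perm_p = min(x$perm_p, na.rm = TRUE))
}

#' Plot a genome scan
#'
#' Per-marker scan statistic along the genome, faceted by linkage group when
#' map positions are present, with genome-wide significance thresholds drawn
#' from the permutation null (the `alpha` quantiles of marker-level
#' significance are implicit in `perm_p`; markers at or below each alpha are
#' highlighted).
#'
#' @param object A `vcqtl_scan` tibble including `linkage_group` and `cM`.
#' @param alpha Significance levels to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vcqtl_scan
#' @export
autoplot.vcqtl_scan <- function(object, alpha = c(0.05, 0.01), ...) {
  if (!all(c("linkage_group", "cM") %in% names(object)))
    abort("autoplot needs a scan annotated with a genetic map")
  d <- as_tibble(object) |>
    filter(!is.na(.data$statistic)) |>
    mutate(sig = cut(.data$perm_p, breaks = c(-Inf, sort(alpha), Inf),
                     labels = c(paste0("p <= ", sort(alpha)), "ns")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cM, y = .data$statistic)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sig), size = 1.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$linkage_group),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)",
                  y = paste0(attr(object, "method"), " statistic"),
                  colour = "genome-wide", title = attr(object, "trait")) +
    ggplot2::theme_minimal()
}
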