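#' Estimate the pair of G matrices at a marker
#'
#' Sample covariance matrices of family-mean trait vectors within each
#' homozygote class at a marker. Families with a missing call at the marker or
#' a missing value for any trait in the set are dropped (complete case).
#'
#' @param genotypes Genotype tibble.
#' @param phenotypes Long phenotype tibble.
#' @param marker Marker id.
#' @param traits Ordered character vector of trait ids (>= 1).
#' @param min_class Minimum families per class (default 3).
#' @return An object of class `g_matrix_pair`: list with `G_CO`, `G_MT`,
#'   degrees of freedom `V_CO`, `V_MT`, `trait_ids` and `marker`.
#' @export
estimate_g_pair <- function(genotypes, phenotypes, marker, traits,
                            min_class = 3) {
  if (!marker %in% names(genotypes)) abort("marker not in genotype matrix")
  Y <- phenotype_matrix(phenotypes, traits, families = genotypes$family_id)
  keep <- complete.cases(Y) & !is.na(genotypes[[marker]])
  Y <- Y[keep, , drop = FALSE]
  cls <- genotypes[[marker]][keep]
  n0 <- sum(cls == "CO"); n1 <- sum(cls == "MT")
  if (n0 < min_class || n1 < min_class)
    abort(paste0("fewer than ", min_class, " complete-case families in a class at ",
                 marker, " (CO: ", n0, ", MT: ", n1, ")"))
  g_matrix_pair(cov(Y[cls == "CO", , drop = FALSE]),
                cov(Y[cls == "MT", , drop = FALSE]),
                V_CO = n0 - 1, V_MT = n1 - 1,
                trait_ids = traits, marker = marker)
}

#' Construct a G-matrix pair
#'
#' @param G_CO,G_MT Symmetric covariance matrices over the same ordered traits.
#' @param V_CO,V_MT Degrees of freedom (class size minus 1).
#' @param trait_ids Optional trait names.
#' @param marker Optional marker id.
#' @return A `g_matrix_pair` object.
#' @export
g_matrix_pair <- function(G_CO, G_MT, V_CO, V_MT, trait_ids = NULL, marker = NULL) {
  G_CO <- as.matrix(G_CO); G_MT <- as.matrix(G_MT)
  if (!all(dim(G_CO) == dim(G_MT))) abort("G matrices must have equal dimensions")
  if (max(abs(G_CO - t(G_CO))) > 1e-10 || max(abs(G_MT - t(G_MT))) > 1e-10)
    abort("G matrices must be symmetric")
  if (V_CO < 1 || V_MT < 1) abort("degrees of freedom must be >= 1")
  structure(list(G_CO = G_CO, G_MT = G_MT, V_CO = V_CO, V_MT = V_MT,
                 trait_ids = trait_ids %||% colnames(G_CO), marker = marker),
            class = "g_matrix_pair")
}

#' @export
print.g_matrix_pair <- function(x, ...) {
  cat("G-matrix pair", if (!is.null(x$marker)) paste0("at ", x$marker), "\n")
  cat("  traits:", paste(x$trait_ids, collapse = ", "), "\n")
  cat("  df: CO", x$V_CO, "| MT", x$V_MT, "\n")
  invisible(x)
}

#' Box's M statistic (trace form)
#'
#' Compares the overall size ("multivariate volume") of two covariance
#' matrices via their traces: with `S_i = trace(G_i)`, `V_i` the degrees of
#' freedom, `N = sum(V_i)` and pooled trace `S = sum(V_i S_i) / N`,
#' `M = N log(S) - sum(V_i log(S_i)) >= 0`, equal to zero iff the traces are
#' equal, and invariant to rescaling both matrices by the same constant.
#' `form = "determinant"` gives the classical log-determinant Box's M on the
#' pooled covariance matrix instead.
#'
#' @param pair A `g_matrix_pair`.
#' @param form `"trace"` (default) or `"determinant"`.
#' @return The statistic (non-negative scalar).
#' @export
boxs_m <- function(pair, form = c("trace", "determinant")) {
  form <- match.arg(form)
  stopifnot(inherits(pair, "g_matrix_pair"))
  V <- c(pair$V_CO, pair$V_MT); N <- sum(V)
  if (form == "trace") {
    S_i <- c(sum(diag(pair$G_CO)), sum(diag(pair$G_MT)))
    if (any(S_i <= 0)) abort("non-positive trace; statistic undefined")
    S <- sum(V * S_i) / N
    return(N * log(S) - sum(V * log(S_i)))
  }
  pooled <- (V[1] * pair$G_CO + V[2] * pair$G_MT) / N
  d_i <- c(det(pair$G_CO), det(pair$G_MT))
  if (any(d_i <= 0) || det(pooled) <= 0)
    abort("non-positive determinant; statistic undefined")
  N * log(det(pooled)) - sum(V * log(d_i))
}

# Leading eigenvectors in decreasing eigenvalue order, unit length, signed so
# the largest-magnitude component is positive (deterministic tie-break).
lead_eigenvectors <- function(G, k) {
  e <- eigen(G, symmetric = TRUE)
  A <- e$vectors[, seq_len(k), drop = FALSE]
  apply(A, 2, function(v) {
    v <- v / sqrt(sum(v * v))
    if (v[which.max(abs(v))] < 0) -v else v
  })
}

#' Angle between leading eigenvectors of two G matrices
#'
#' The radian angle between the first principal components (Gmax) of the two
#' matrices, `theta = acos(u . v / (|u||v|))`; because eigenvectors are
#' non-directional, angles above pi/2 are reflected to `pi - theta`, so the
#' result lies in `[0, pi/2]` and is invariant to eigenvector sign flips.
#'
#' @param pair A `g_matrix_pair`.
#' @return The angle in radians, in `[0, pi/2]`.
#' @export
gmax_angle <- function(pair) {
  stopifnot(inherits(pair, "g_matrix_pair"))
  if (sum(pair$G_CO^2) == 0 || sum(pair$G_MT^2) == 0)
    abort("zero matrix; Gmax undefined")
  u <- lead_eigenvectors(pair$G_CO, 1)[, 1]
  v <- lead_eigenvectors(pair$G_MT, 1)[, 1]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  theta <- acos(pmin(1, pmax(-1, ct)))
  if (theta > pi / 2) pi - theta else theta
}

#' Krzanowski common-subspace index
#'
#' Similarity between the k-dimensional principal subspaces of two covariance
#' matrices. The columns of `A` and `B` are the first `k` eigenvectors of each
#' matrix, each standardized by the square root of its self dot-product; the
#' index is the sum of eigenvalues of `S = t(A) B t(B) A`, ranging from 0
#' (orthogonal subspaces) to `k` (identical subspaces). `k` must not exceed
#' half the trait count.
#'
#' @param pair A `g_matrix_pair`.
#' @param k Subspace dimension; default `floor(p/2)`.
#' @return The index in `[0, k]`.
#' @export
krzanowski_index <- function(pair, k = NULL) {
  stopifnot(inherits(pair, "g_matrix_pair"))
  p <- nrow(pair$G_CO)
  k <- k %||% floor(p / 2)
  if (k < 1 || k > floor(p / 2))
    abort(paste0("k must be in 1..floor(p/2) = ", floor(p / 2)))
  A <- lead_eigenvectors(pair$G_CO, k)
  B <- lead_eigenvectors(pair$G_MT, k)
  S <- t(A) %*% B %*% t(B) %*% A
  sum(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
}

#' Genome-wide covariance-structure scan
#'
#' Per-marker comparison of the two homozygote-class G matrices over a trait
#' set, with genome-wide permutation p-values from the maximum-statistic
#' method. Whole family trait vectors are shuffled against the genotype
#' matrix, preserving inter-trait correlation. Methods: `boxm` (trace-form
#' Box's M: size), `gmax_angle` (orientation of the leading axis), and
#' `krzanowski` (subspace similarity; the scan statistic is the negative
#' index, i.e. dissimilarity, while the reported `statistic` column is the
#' index itself). With two traits the Gmax angle captures all orientation
#' difference and the Krzanowski method is disabled.
#'
#' @param genotypes Genotype tibble.
#' @param phenotypes Long phenotype tibble (standardized traits recommended).
#' @param traits Ordered trait ids (>= 2).
#' @param method `"boxm"`, `"gmax_angle"` or `"krzanowski"`.
#' @param k Subspace dimension for `krzanowski` (default `floor(p/2)`).
#' @param map Optional genetic map to annotate positions.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param maf_min MAF filter threshold (0 disables).
#' @param min_class Minimum complete-case families per class (default 3).
#' @param correction Use the add-one permutation p-value estimate.
#' @return A `vcqtl_scan` tibble: `marker`, (`linkage_group`, `cM`,) `method`,
#'   `statistic`, `perm_p`, `n_CO`, `n_MT`.
#' @export
scan_covariance <- function(genotypes, phenotypes, traits,
                            method = c("boxm", "gmax_angle", "krzanowski"),
                            k = NULL, map = NULL, n_perm = 1000, seed = NULL,
                            maf_min = 0.33, min_class = 3, correction = FALSE) {
  method <- match.arg(method)
  p <- length(traits)
  if (p < 2) abort("covariance scans need at least 2 traits")
  if (method == "krzanowski") {
    if (p == 2)
      abort("the Krzanowski method is disabled for two-trait sets; use gmax_angle")
    k <- k %||% floor(p / 2)
    if (k < 1 || k > floor(p / 2))
      abort(paste0("k must be in 1..floor(p/2) = ", floor(p / 2)))
  } else k <- 0L
  if (maf_min > 0) genotypes <- filter_maf(genotypes, maf_min)

  Y <- phenotype_matrix(phenotypes, traits, families = genotypes$family_id)
  keep <- complete.cases(Y)
  Y <- Y[keep, , drop = FALSE]
  geno <- geno_int_matrix(genotypes[keep, ])
  if (nrow(Y) < 2 * min_class) abort("too few complete-case families")
  if (!is.null(seed)) withr::local_seed(seed)
  vc_inform("scan_covariance (", method, "): ", p, " traits, ", nrow(Y),
            " complete-case families x ", ncol(geno), " markers, ", n_perm,
            " permutations", if (!is.null(seed)) paste0(", seed ", seed))
  perms <- perm_matrix(nrow(Y), n_perm)
  mcode <- match(method, c("boxm", "gmax_angle", "krzanowski")) - 1L
  res <- cpp_scan_cov(Y, geno, mcode, as.integer(k), as.integer(min_class), perms)
  out <- finish_scan(res, colnames(geno), map, n_perm, correction,
                     method = method, trait = paste(traits, collapse = "+"))
  # The engine maximizes dissimilarity (-index) for Krzanowski; report the
  # index itself, which lives in [0, k].
  if (method == "krzanowski") out$statistic <- -out$statistic
  out <- mutate(out, method = method, .after = if ("cM" %in% names(out)) "cM" else "marker")
  out
}

#' Confidence ellipse coordinates for a 2x2 covariance block
#'
#' Presentation utility: boundary points of the `level` confidence region of a
#' bivariate Gaussian with the given mean and covariance, using the
#' chi-squared quantile with 2 df. Used to draw per-genotype G-matrix ellipses.
#'
#' @param sigma 2x2 covariance matrix.
#' @param centre Length-2 mean vector.
#' @param level Confidence level (default 0.95).
#' @param n_points Number of boundary points.
#' @return A tibble with columns `x`, `y`.
#' @export
confidence_ellipse <- function(sigma, centre = c(0, 0), level = 0.95,
                               n_points = 100) {
  stopifnot(all(dim(sigma) == c(2, 2)))
  e <- eigen(sigma, symmetric = TRUE)
  r <- sqrt(qchisq(level, df = 2))
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(ang), sin(ang)) * r
  pts <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% circ
  tibble(x = centre[1] + pts[1, ], y = centre[2] + pts[2, ])
}

#' Plot per-genotype trait clouds with G-matrix ellipses
#'
#' Scatter of family means for two traits, split by homozygote class at a
#' marker, with 95% confidence ellipses of each class covariance matrix.
#'
#' @param genotypes Genotype tibble.
#' @param phenotypes Long phenotype tibble.
#' @param marker Marker id.
#' @param traits Exactly two trait ids.
#' @param level Ellipse confidence level.
#' @return A ggplot object.
#' @export
plot_g_ellipses <- function(genotypes, phenotypes, marker, traits, level = 0.95) {
  stopifnot(length(traits) == 2)
  Y <- phenotype_matrix(phenotypes, traits, families = genotypes$family_id)
  keep <- complete.cases(Y) & !is.na(genotypes[[marker]])
  d <- tibble(x = Y[keep, 1], y = Y[keep, 2],
              genotype = genotypes[[marker]][keep])
  ell <- d |>
    group_by(.data$genotype) |>
    group_modify(function(g, key) {
      confidence_ellipse(cov(cbind(g$x, g$y)), c(mean(g$x), mean(g$y)), level)
    }) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$genotype)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_path(data = ell, ggplot2::aes(group = .data$genotype)) +
    ggplot2::labs(x = traits[1], y = traits[2], colour = marker) +
    ggplot2::theme_minimal()
}
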