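# Shared fixtures and independent oracles, built in code at test time.

options(vcqtl.verbose = FALSE)

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_map <- function(n_per_lg = c(3, 3), spacing = 5.5) {
  purrr::map2_dfr(seq_along(n_per_lg), n_per_lg, function(lg, k) {
    tibble::tibble(marker = paste0("m", lg, "_", seq_len(k)),
                   linkage_group = as.integer(lg), cM = spacing * (seq_len(k) - 1))
  })
}

# Genotype tibble from a named list of call vectors.
toy_genotypes <- function(calls, family_ids = NULL) {
  n <- length(calls[[1]])
  out <- tibble::as_tibble(calls)
  dplyr::bind_cols(
    tibble::tibble(family_id = family_ids %||% sprintf("F%02d", seq_len(n))), out)
}

# Long phenotype tibble from a named list of numeric vectors (one per trait).
toy_phenotypes <- function(values, family_ids = NULL) {
  n <- length(values[[1]])
  ids <- family_ids %||% sprintf("F%02d", seq_len(n))
  purrr::imap_dfr(values, function(v, tr) {
    tibble::tibble(family_id = ids, trait_id = tr, value = v)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multivariate normal draws via Cholesky (kept independent of the package).
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% chol(sigma), 2, mu, `+`)
}

# Rotation matrix for 2-d rotation-only covariance perturbations.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Brute-force Krzanowski oracle: explicit projection matrices and the trace of
# their product (independent of the package's eigen-sum implementation).
krz_oracle <- function(G1, G2, k) {
  basis <- function(G) eigen(G, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  A <- basis(G1); B <- basis(G2)
  PA <- A %*% solve(t(A) %*% A) %*% t(A)
  PB <- B %*% solve(t(B) %*% B) %*% t(B)
  sum(diag(PA %*% PB))
}

# Random genotype tibble (iid markers) for null-calibration fixtures where
# linkage is irrelevant.
random_genotypes <- function(n_fam, n_mark, miss = 0.03) {
  calls <- purrr::map(seq_len(n_mark), function(j) {
    g <- sample(c("CO", "MT"), n_fam, replace = TRUE)
    g[runif(n_fam) < miss] <- NA
    g
  })
  names(calls) <- sprintf("mk%03d", seq_len(n_mark))
  toy_genotypes(calls)
}
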