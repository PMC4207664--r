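#' Read a genetic map
#'
#' Reads a delimited text file (tab or comma, auto-detected, header required)
#' with columns `marker`, `linkage_group` and `cM` into a genetic-map tibble.
#' Marker identifiers must be unique and positions must be non-negative and
#' non-decreasing within each linkage group; violations are reported with the
#' offending row.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `marker` (character), `linkage_group`
#'   (integer) and `cM` (double), in file order.
#' @export
read_genetic_map <- function(path) {
  df <- read_delim_sniff(path, c("marker", "linkage_group", "cM"))
  map <- tibble(
    marker = as.character(df$marker),
    linkage_group = parse_int_column(df$linkage_group, "linkage_group", path),
    cM = parse_num_column(df$cM, "cM", path)
  )
  validate_genetic_map(map)
  map
}

#' Write a genetic map
#'
#' @param map A genetic-map tibble as returned by [read_genetic_map()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  validate_genetic_map(map)
  readr::write_tsv(map, path)
  invisible(path)
}

validate_genetic_map <- function(map) {
  stopifnot(all(c("marker", "linkage_group", "cM") %in% names(map)))
  dup <- map$marker[duplicated(map$marker)]
  if (length(dup) > 0)
    abort(paste0("duplicated marker id(s) in map: ", paste(unique(dup), collapse = ", ")))
  if (any(map$cM < 0)) {
    i <- which(map$cM < 0)[1]
    abort(paste0("negative cM position at row ", i, " (marker ", map$marker[i], ")"))
  }
  bad <- map |>
    group_by(.data$linkage_group) |>
    summarise(ok = !is.unsorted(.data$cM), .groups = "drop")
  if (any(!bad$ok))
    abort(paste0("cM positions not non-decreasing within linkage group(s): ",
                 paste(bad$linkage_group[!bad$ok], collapse = ", ")))
  invisible(map)
}

#' Read a RIL genotype matrix
#'
#' Reads a families-by-markers table. Cell codes are configurable; the two
#' homozygote codes are mapped to the canonical internal labels `CO` and `MT`,
#' and both the heterozygote code and the missing code are stored as `NA`
#' (heterozygous calls are treated as missing data in these near-homozygous
#' RIL populations). The marker columns must match the map exactly.
#'
#' @param path Path to the genotype file. First column must be `family_id`.
#' @param map Genetic map tibble; defines the expected marker set.
#' @param codes Named character vector with entries `CO`, `MT`, `HET` and
#'   `missing` giving the codes used in the file.
#' @return A tibble with `family_id` plus one character column per map marker,
#'   values in `CO`/`MT`/`NA`.
#' @export
read_genotypes <- function(path, map,
                           codes = c(CO = "CO", MT = "MT", HET = "HET", missing = "NA")) {
  stopifnot(all(c("CO", "MT", "HET", "missing") %in% names(codes)))
  df <- read_delim_sniff(path, "family_id", col_types = readr::cols(.default = "c"))
  mk_file <- setdiff(names(df), "family_id")
  extra <- setdiff(mk_file, map$marker)
  if (length(extra) > 0)
    abort(paste0("marker(s) in genotype file absent from map: ",
                 paste(extra, collapse = ", ")))
  absent <- setdiff(map$marker, mk_file)
  if (length(absent) > 0)
    abort(paste0("map marker(s) missing from genotype file: ",
                 paste(absent, collapse = ", ")))
  g <- as.matrix(df[map$marker])
  out <- matrix(NA_character_, nrow(g), ncol(g))
  out[g == codes[["CO"]]] <- "CO"
  out[g == codes[["MT"]]] <- "MT"
  known <- is.na(g) | g %in% unname(codes)
  if (!all(known)) {
    bad <- unique(g[!known])
    abort(paste0("unknown genotype code(s): ", paste(bad, collapse = ", ")))
  }
  res <- as_tibble(out, .name_repair = "minimal")
  names(res) <- map$marker
  res <- bind_cols(tibble(family_id = as.character(df$family_id)), res)
  vc_inform("read_genotypes: ", nrow(res), " families x ", ncol(res) - 1L, " markers")
  res
}

#' Write a RIL genotype matrix
#'
#' Writes the canonical `CO`/`MT`/`NA` codes as tab-delimited text; a
#' subsequent [read_genotypes()] with default codes recovers the same tibble.
#'
#' @param genotypes Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, na = "NA")
  invisible(path)
}

#' Read a family-mean phenotype table
#'
#' Reads a wide table (one row per family, one column per trait-by-environment
#' combination) and returns the long phenotype tibble used throughout the
#' package. Missing values are kept; downstream operations drop them pairwise.
#'
#' @param path Path to the phenotype file; first column `family_id`.
#' @return A tibble with columns `family_id`, `trait_id`, `value`.
#' @export
read_phenotypes <- function(path) {
  df <- read_delim_sniff(path, "family_id")
  long <- df |>
    mutate(family_id = as.character(.data$family_id)) |>
    tidyr::pivot_longer(-"family_id", names_to = "trait_id", values_to = "value") |>
    mutate(value = as.numeric(.data$value))
  as_tibble(long)
}

#' Write a family-mean phenotype table
#'
#' @param phenotypes Long phenotype tibble (`family_id`, `trait_id`, `value`).
#' @param path Output path (tab-delimited, wide layout).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  wide <- tidyr::pivot_wider(phenotypes, id_cols = "family_id",
                             names_from = "trait_id", values_from = "value")
  readr::write_tsv(wide, path, na = "NA")
  invisible(path)
}

hif_columns <- c("Block", "Flowering_time", "Leaf_number_at_flowering",
                 "Height_at_flowering", "nFT_genotype", "HIF", "Family")

#' Read a heterogeneous-inbred-family (HIF) phenotype table
#'
#' Expects the exact column set `Block`, `Flowering_time`,
#' `Leaf_number_at_flowering`, `Height_at_flowering`, `nFT_genotype`, `HIF`,
#' `Family`. Genotypes must be `CO` or `MT`, and each family must nest within
#' a single (HIF, genotype) pair.
#'
#' @param path Path to the HIF table (tab- or comma-delimited).
#' @return A typed tibble with factor design columns and numeric responses.
#' @export
read_hif_table <- function(path) {
  df <- read_delim_sniff(path, hif_columns)
  out <- tibble(
    Block = factor(df$Block),
    Flowering_time = as.numeric(df$Flowering_time),
    Leaf_number_at_flowering = as.numeric(df$Leaf_number_at_flowering),
    Height_at_flowering = as.numeric(df$Height_at_flowering),
    nFT_genotype = factor(as.character(df$nFT_genotype), levels = c("CO", "MT")),
    HIF = factor(df$HIF),
    Family = factor(df$Family)
  )
  if (any(is.na(out$nFT_genotype)))
    abort("nFT_genotype must be coded CO or MT")
  check_family_nesting(out)
  out
}

#' Write a HIF phenotype table
#' @param data HIF tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hif_table <- function(data, path) {
  readr::write_tsv(data[hif_columns], path, na = "NA")
  invisible(path)
}

expression_columns <- c("Plant_ID", "HIF", "Family", "nFT_genotype",
                        "Visible_bud", "delta_Ct")

#' Read an expression (delta-Ct) table
#'
#' Expects the exact columns `Plant_ID`, `HIF`, `Family`, `nFT_genotype`,
#' `Visible_bud`, `delta_Ct`. `delta_Ct` is the reference-gene Ct minus the
#' target-gene Ct; in data where the target always amplifies later than the
#' reference it is negative, so non-negative values raise a warning (not an
#' error). Non-finite `delta_Ct` is an error.
#'
#' @param path Path to the expression table.
#' @return A typed tibble; `Visible_bud` is logical.
#' @export
read_expression_table <- function(path) {
  df <- read_delim_sniff(path, expression_columns)
  out <- tibble(
    Plant_ID = as.character(df$Plant_ID),
    HIF = factor(df$HIF),
    Family = factor(df$Family),
    nFT_genotype = factor(as.character(df$nFT_genotype), levels = c("CO", "MT")),
    Visible_bud = parse_logical_column(df$Visible_bud),
    delta_Ct = as.numeric(df$delta_Ct)
  )
  if (any(is.na(out$nFT_genotype)))
    abort("nFT_genotype must be coded CO or MT")
  if (any(!is.finite(out$delta_Ct)))
    abort("delta_Ct contains non-finite values")
  if (any(out$delta_Ct >= 0))
    warn(paste0(sum(out$delta_Ct >= 0),
                " delta_Ct value(s) are non-negative; expected negative when the ",
                "target gene amplifies later than the reference"))
  check_family_nesting(out)
  out
}

#' Write an expression table
#' @param data Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(data, path) {
  readr::write_tsv(data[expression_columns], path, na = "NA")
  invisible(path)
}

check_family_nesting <- function(data) {
  combos <- data |>
    distinct(.data$Family, .data$HIF, .data$nFT_genotype) |>
    count(.data$Family)
  bad <- combos$Family[combos$n > 1]
  if (length(bad) > 0)
    abort(paste0("family value(s) not nested within a single (HIF, nFT_genotype) pair: ",
                 paste(bad, collapse = ", ")))
  invisible(data)
}

# -- parsing helpers ---------------------------------------------------------

# Delimiter auto-detection: tab wins if present on the header line, else comma.
read_delim_sniff <- function(path, required_cols, col_types = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = col_types, progress = FALSE,
                          na = c("", "NA"))
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0)
    abort(paste0("missing required column(s) in ", basename(path), ": ",
                 paste(missing_cols, collapse = ", "),
                 " (expected header includes: ",
                 paste(required_cols, collapse = ", "), ")"))
  df
}

parse_num_column <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out) & !is.na(x))) {
    i <- which(is.na(out) & !is.na(x))[1]
    abort(paste0("non-numeric ", name, " at row ", i, " of ", basename(path),
                 ": '", x[i], "'"))
  }
  out
}

parse_int_column <- function(x, name, path) {
  num <- parse_num_column(x, name, path)
  if (any(!is.na(num) & num != round(num))) {
    i <- which(num != round(num))[1]
    abort(paste0("non-integer ", name, " at row ", i, " of ", basename(path)))
  }
  as.integer(num)
}

parse_logical_column <- function(x) {
  if (is.logical(x)) return(x)
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("TRUE", "T", "YES", "Y", "1")] <- TRUE
  out[s %in% c("FALSE", "F", "NO", "N", "0")] <- FALSE
  if (any(is.na(out) & !is.na(s)))
    abort("Visible_bud contains values not interpretable as logical")
  out
}

#' Allele frequencies per marker
#'
#' Frequencies of the two homozygote classes among non-missing calls.
#'
#' @param genotypes Genotype tibble.
#' @return A tibble with `marker`, `n_CO`, `n_MT`, `freq_CO`, `freq_MT`, `maf`.
#' @export
allele_freqs <- function(genotypes) {
  g <- geno_int_matrix(genotypes)
  n_co <- colSums(g == 0L, na.rm = TRUE)
  n_mt <- colSums(g == 1L, na.rm = TRUE)
  tot <- n_co + n_mt
  f_co <- ifelse(tot > 0, n_co / tot, NA_real_)
  tibble(marker = colnames(g), n_CO = as.integer(n_co), n_MT = as.integer(n_mt),
         freq_CO = f_co, freq_MT = 1 - f_co,
         maf = pmin(f_co, 1 - f_co))
}
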