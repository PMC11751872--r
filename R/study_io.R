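# Reading, validating and screening per-study genotype count tables.
#
# Input schema (one row per study x SNP): study_id, first_author, year,
# country, ethnicity, control_source, genotyping_method, snp_id, gene,
# case_11, case_12, case_22, ctrl_11, ctrl_12, ctrl_22, quality_total.
# Genotype "11" is the common homozygote, "22" the variant homozygote as
# declared by the data source; orientation is never inferred from frequency.

STUDY_COLUMNS <- c("study_id", "snp_id", "gene", "ethnicity", "control_source",
                   "genotyping_method", "case_11", "case_12", "case_22",
                   "ctrl_11", "ctrl_12", "ctrl_22")

ETHNICITY_LEVELS <- c("Asian", "Caucasian", "Other")
CONTROL_SOURCES <- c("population", "hospital", "unknown")
GENOTYPING_METHODS <- c("RFLP-PCR", "TaqMan", "Other")

map_to_levels <- function(x, levels, field) {
  idx <- match(tolower(trimws(x)), tolower(levels))
  out <- levels[idx]
  bad <- is.na(idx) | !nzchar(trimws(x))
  if (any(bad)) {
    warning(sprintf("%d value(s) of %s outside {%s} mapped to '%s': %s",
                    sum(bad), field, paste(levels[-length(levels)], collapse = ", "),
                    levels[length(levels)],
                    paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    out[bad] <- levels[length(levels)]
  }
  out
}

#' Read per-study genotype count tables from a delimited file
#'
#' Parses a CSV of case-control genotype counts (one row per study-SNP pair),
#' validates counts, and normalises the categorical metadata. Ethnicities
#' other than Asian/Caucasian, control sources other than
#' population/hospital, and genotyping methods other than RFLP-PCR/TaqMan are
#' mapped to "Other"/"unknown" with a warning.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping required column
#'   names to the names actually used in the file, e.g.
#'   `c(case_11 = "case_AA")`.
#' @return A `genotype_studies` data frame with the canonical columns plus
#'   any extra columns present (e.g. `quality_total`).
#' @seealso [write_studies()], [apply_inclusion_filters()]
#' @export
parse_studies <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw))
        stop("schema maps '", canon, "' to missing column '", schema[[canon]], "'")
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(STUDY_COLUMNS, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  as_genotype_studies(raw)
}

#' Validate a data frame of genotype studies
#'
#' Checks counts (non-negative integers, positive case and control totals),
#' normalises metadata levels, and classes the result. Rows failing count
#' validation raise an error naming the row and offending cell.
#'
#' @param df a data frame with the columns listed in [parse_studies()].
#' @return A `genotype_studies` data frame.
#' @export
as_genotype_studies <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  count_cols <- grep("^(case|ctrl)_(11|12|22)$", names(df), value = TRUE)
  for (cc in count_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("invalid count in column '%s', row %d: '%s'",
                   cc, bad[1], as.character(df[[cc]][bad[1]])))
    df[[cc]] <- as.integer(round(v))
  }
  case_tot <- df$case_11 + df$case_12 + df$case_22
  ctrl_tot <- df$ctrl_11 + df$ctrl_12 + df$ctrl_22
  if (any(case_tot < 1) || any(ctrl_tot < 1))
    stop("case and control totals must each be >= 1 (row ",
         which(case_tot < 1 | ctrl_tot < 1)[1], ")")
  df$ethnicity <- map_to_levels(df$ethnicity, ETHNICITY_LEVELS, "ethnicity")
  df$control_source <- map_to_levels(df$control_source, CONTROL_SOURCES,
                                     "control_source")
  df$genotyping_method <- map_to_levels(df$genotyping_method,
                                        GENOTYPING_METHODS, "genotyping_method")
  class(df) <- c("genotype_studies", "data.frame")
  df
}

#' Write genotype studies back to CSV
#'
#' Inverse of [parse_studies()]: `parse_studies(write_studies(x, f))` is the
#' identity on valid records.
#'
#' @param studies a `genotype_studies` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  utils::write.csv(as.data.frame(studies), path, row.names = FALSE)
  invisible(path)
}

#' Hardy-Weinberg equilibrium test on genotype counts
#'
#' Pearson chi-square goodness-of-fit (1 df) of observed genotype counts
#' against Hardy-Weinberg expectation at the estimated allele frequency.
#' Monomorphic samples (either allele absent) cannot deviate from HWE and
#' are flagged degenerate with `conforms = TRUE` by convention.
#'
#' @param counts integer triple (common-homozygote, heterozygote,
#'   variant-homozygote).
#' @param alpha significance level for the conformity flag (default 0.05).
#' @return List of class `hwe_result`: `chi2`, `p_value`, `conforms`,
#'   `degenerate`, `q` (variant allele frequency).
#' @examples
#' hwe_test(c(36, 48, 16))  # exact HWE at q = 0.4: chi2 = 0
#' hwe_test(c(50, 20, 30))  # strong deviation
#' @export
hwe_test <- function(counts, alpha = 0.05) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("control total must be > 0")
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  if (q == 0 || q == 1) {
    return(structure(list(chi2 = 0, p_value = 1, conforms = TRUE,
                          degenerate = TRUE, q = q), class = "hwe_result"))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(chi2 = chi2, p_value = p, conforms = p >= alpha,
                 degenerate = FALSE, q = q), class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (1 df), p = %.4g, q = %.4f -> %s%s\n",
              x$chi2, x$p_value, x$q,
              if (x$conforms) "conforms" else "deviates",
              if (x$degenerate) " (monomorphic, degenerate)" else ""))
  invisible(x)
}

#' Variant allele frequency from genotype counts
#'
#' Frequency of the declared variant allele, `(2 n22 + n12) / (2 n)`.
#' Reported on the full 0-1 scale: the declared variant allele need not be
#' the minor one.
#'
#' @param counts genotype triple as in [hwe_test()].
#' @return Frequency in \[0, 1\].
#' @examples
#' variant_allele_freq(c(36, 48, 16))  # 0.4
#' @export
variant_allele_freq <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("undefined for zero total")
  (2 * counts[3] + counts[2]) / (2 * n)
}

#' Classify a study quality score on the 15-point scale
#'
#' @param total_score integer 0-15 (sum over the seven assessment domains).
#' @return List `total_score`, `class` ("high" for scores >= 11, "medium"
#'   for 7-10, "excluded" below 7).
#' @export
quality_class <- function(total_score) {
  stopifnot(is.finite(total_score), total_score >= 0, total_score <= 15,
            total_score == round(total_score))
  cls <- if (total_score >= 11) "high" else if (total_score >= 7) "medium" else "excluded"
  list(total_score = as.integer(total_score), class = cls)
}

#' Apply the inclusion filters to a set of genotype studies
#'
#' A study is dropped when its controls deviate from Hardy-Weinberg
#' equilibrium, when the combined case + control sample is below the minimum
#' size, or when its quality score classifies as excluded (< 7). SNPs left
#' with fewer than two retained studies are flagged (they cannot enter
#' model-selection, which needs at least two studies).
#'
#' @param studies a `genotype_studies` data frame.
#' @param alpha_hwe HWE significance level (default 0.05).
#' @param min_n minimum combined sample size (default 300).
#' @param min_quality minimum quality score (default 7); rows lacking a
#'   `quality_total` column are not filtered on quality.
#' @return List of class `screening_report`: `kept` (genotype_studies with
#'   added `hwe_p`, `maf`, `quality_class`, `snp_underpowered` columns),
#'   `dropped` (data frame with a `reason` column), and the filter settings.
#' @export
apply_inclusion_filters <- function(studies, alpha_hwe = 0.05, min_n = 300,
                                    min_quality = 7) {
  studies <- as_genotype_studies(as.data.frame(studies))
  n <- nrow(studies)
  hwe_p <- maf <- numeric(n)
  qcls <- character(n)
  reason <- character(n)
  has_q <- "quality_total" %in% names(studies)
  for (i in seq_len(n)) {
    ctrl <- c(studies$ctrl_11[i], studies$ctrl_12[i], studies$ctrl_22[i])
    hw <- hwe_test(ctrl, alpha = alpha_hwe)
    hwe_p[i] <- hw$p_value
    maf[i] <- variant_allele_freq(ctrl)
    total <- sum(studies[i, c("case_11", "case_12", "case_22",
                              "ctrl_11", "ctrl_12", "ctrl_22")])
    qcls[i] <- if (has_q && is.finite(studies$quality_total[i]))
      quality_class(studies$quality_total[i])$class else NA_character_
    # order-independent: reasons accumulate, drop if any filter fires
    fired <- c(
      if (!hw$conforms) "HWE",
      if (total < min_n) "sample size",
      if (has_q && !is.na(qcls[i]) && studies$quality_total[i] < min_quality) "quality"
    )
    reason[i] <- paste(fired, collapse = "; ")
  }
  studies$hwe_p <- hwe_p
  studies$maf <- maf
  studies$quality_class <- qcls
  drop <- nzchar(reason)
  kept <- studies[!drop, , drop = FALSE]
  dropped <- as.data.frame(studies[drop, , drop = FALSE])
  dropped$reason <- reason[drop]
  snp_k <- table(kept$snp_id)
  kept$snp_underpowered <- snp_k[kept$snp_id] < 2
  class(kept) <- c("genotype_studies", "data.frame")
  structure(list(kept = kept, dropped = dropped,
                 settings = list(alpha_hwe = alpha_hwe, min_n = min_n,
                                 min_quality = min_quality)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening: %d kept, %d dropped (HWE alpha %.3g, min n %d, min quality %d)\n",
              nrow(x$kept), nrow(x$dropped), x$settings$alpha_hwe,
              x$settings$min_n, x$settings$min_quality))
  if (nrow(x$dropped))
    print(x$dropped[, c("study_id", "snp_id", "reason")], row.names = FALSE)
  invisible(x)
}

#' Write a screening report to CSV and JSON
#'
#' @param report a `screening_report` from [apply_inclusion_filters()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_screening_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kept_csv <- file.path(dir, "screening_kept.csv")
  drop_csv <- file.path(dir, "screening_dropped.csv")
  js <- file.path(dir, "screening.json")
  utils::write.csv(as.data.frame(report$kept), kept_csv, row.names = FALSE)
  utils::write.csv(report$dropped, drop_csv, row.names = FALSE)
  jsonlite::write_json(list(
    settings = report$settings,
    n_kept = nrow(report$kept), n_dropped = nrow(report$dropped),
    dropped = report$dropped[, intersect(c("study_id", "snp_id", "reason"),
                                         names(report$dropped))]
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(kept_csv, drop_csv, js))
}
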