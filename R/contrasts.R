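# Six genetic-model dichotomizations of a biallelic genotype triple and the
# Woolf log-OR machinery applied to the resulting 2x2 tables.

#' The six genetic models
#'
#' Names of the six dichotomizations of the genotype triple (11 = common
#' homozygote, 12 = heterozygote, 22 = variant homozygote):
#' \describe{
#'   \item{allelic}{variant allele vs common allele (allele counts, 2n)}
#'   \item{homozygote}{22 vs 11}
#'   \item{heterozygote}{12 vs 11}
#'   \item{dominant}{12 + 22 vs 11}
#'   \item{recessive}{22 vs 11 + 12}
#'   \item{overdominant}{12 vs 11 + 22}
#' }
#' The variant-bearing grouping is always the "exposed" group, so OR > 1
#' reads as hazardous and OR < 1 as protective for the variant.
#'
#' @return Character vector of the six model names.
#' @export
genetic_models <- function() {
  c("allelic", "homozygote", "heterozygote", "dominant", "recessive",
    "overdominant")
}

#' Build the 2x2 table of a genetic model from genotype counts
#'
#' @param study one row of a `genotype_studies` data frame, or a list with
#'   `case_11`, `case_12`, `case_22`, `ctrl_11`, `ctrl_12`, `ctrl_22`.
#' @param model one of [genetic_models()], or `"or3"` for the variant- vs
#'   heterozygote contrast (22 vs 12) used by Thakkinstian's algorithm.
#' @return List of class `two_by_two`: `a` (exposed cases), `b` (unexposed
#'   cases), `c` (exposed controls), `d` (unexposed controls),
#'   `continuity_added = FALSE`, `model`. For the allelic model the cells are
#'   allele counts (denominators are twice the subject counts); genotype
#'   contrasts (homozygote, heterozygote, or3) discard the excluded genotype.
#' @examples
#' s <- list(case_11 = 10, case_12 = 20, case_22 = 30,
#'           ctrl_11 = 40, ctrl_12 = 30, ctrl_22 = 10)
#' build_contrast(s, "recessive")  # (30, 30, 10, 70)
#' @export
build_contrast <- function(study, model) {
  model <- match.arg(model, c(genetic_models(), "or3"))
  ca <- as.numeric(c(study$case_11, study$case_12, study$case_22))
  co <- as.numeric(c(study$ctrl_11, study$ctrl_12, study$ctrl_22))
  stopifnot(length(ca) == 3, length(co) == 3, all(ca >= 0), all(co >= 0))
  cells <- switch(model,
    allelic = c(2 * ca[3] + ca[2], 2 * ca[1] + ca[2],
                2 * co[3] + co[2], 2 * co[1] + co[2]),
    homozygote = c(ca[3], ca[1], co[3], co[1]),
    heterozygote = c(ca[2], ca[1], co[2], co[1]),
    dominant = c(ca[2] + ca[3], ca[1], co[2] + co[3], co[1]),
    recessive = c(ca[3], ca[1] + ca[2], co[3], co[1] + co[2]),
    overdominant = c(ca[2], ca[1] + ca[3], co[2], co[1] + co[3]),
    or3 = c(ca[3], ca[2], co[3], co[2])
  )
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 continuity_added = FALSE, model = model),
            class = "two_by_two")
}

#' Odds ratio of a 2x2 table with Woolf standard error
#'
#' log-OR = log(ad/bc), SE = sqrt(1/a + 1/b + 1/c + 1/d). If any cell is
#' zero, 0.5 is added to all four cells (Haldane-Anscombe) and
#' `continuity_added` is set. Tables with an empty margin (two zero cells in
#' the same row or column) have no defined odds ratio and raise an error.
#'
#' @param table a `two_by_two` from [build_contrast()], or a list with
#'   numeric `a`, `b`, `c`, `d`.
#' @return An [effect_estimate()] with an added `continuity_added` flag.
#' @examples
#' estimate_or(list(a = 30, b = 30, c = 10, d = 70))  # OR = 7
#' @export
estimate_or <- function(table) {
  cells <- as.numeric(c(table$a, table$b, table$c, table$d))
  stopifnot(length(cells) == 4, all(cells >= 0))
  added <- FALSE
  if (any(cells == 0)) {
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0 ||
        cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0)
      stop("odds ratio undefined: empty margin in table (",
           paste(cells, collapse = ", "), ")")
    cells <- cells + 0.5
    added <- TRUE
  }
  est <- effect_estimate(log(cells[1] * cells[4] / (cells[2] * cells[3])),
                         sqrt(sum(1 / cells)))
  est$continuity_added <- added
  est$cells <- cells
  est
}

#' Per-study effects for one genetic model across a set of studies
#'
#' Convenience wrapper: [build_contrast()] + [estimate_or()] per row.
#'
#' @param studies a `genotype_studies` data frame.
#' @param model a genetic model name (or `"or3"`).
#' @return List of `effect_estimate`s, named by `study_id`.
#' @export
study_effects <- function(studies, model) {
  out <- lapply(seq_len(nrow(studies)), function(i)
    estimate_or(build_contrast(studies[i, ], model)))
  names(out) <- studies$study_id
  out
}

#' Export per-study contrasts in long format
#'
#' One row per (study, model): the 2x2 cells, OR, CI and p-value.
#'
#' @param studies a `genotype_studies` data frame.
#' @param models character vector of models (default all six).
#' @return A data frame.
#' @export
contrast_table <- function(studies, models = genetic_models()) {
  rows <- list()
  for (m in models) {
    for (i in seq_len(nrow(studies))) {
      tb <- build_contrast(studies[i, ], m)
      es <- estimate_or(tb)
      rows[[length(rows) + 1]] <- data.frame(
        study_id = studies$study_id[i], snp_id = studies$snp_id[i], model = m,
        a = tb$a, b = tb$b, c = tb$c, d = tb$d,
        or = es$or, ci_low = es$ci_low, ci_high = es$ci_high,
        p = es$p_value, continuity_added = es$continuity_added)
    }
  }
  do.call(rbind, rows)
}
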