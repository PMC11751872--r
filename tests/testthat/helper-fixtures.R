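# Shared fixtures and independent hand oracles used across test files.

make_study <- function(ca, co, study_id = "s1", snp_id = "rs0000001",
                       ethnicity = "Asian", quality = 12) {
  data.frame(study_id = study_id, first_author = "A", year = 2020L,
             country = "X", ethnicity = ethnicity,
             control_source = "population", genotyping_method = "TaqMan",
             snp_id = snp_id, gene = "g",
             case_11 = ca[1], case_12 = ca[2], case_22 = ca[3],
             ctrl_11 = co[1], ctrl_12 = co[2], ctrl_22 = co[3],
             quality_total = quality)
}

make_studies <- function(...) as_genotype_studies(do.call(rbind, list(...)))

make_effects <- function(yi, sei) {
  stopifnot(length(yi) == length(sei))
  lapply(seq_along(yi), function(i) effect_estimate(yi[i], sei[i]))
}

# independent inverse-variance oracle (brute-force weighted mean)
hand_fixed <- function(yi, sei) {
  w <- 1 / sei^2
  mu <- sum(w * yi) / sum(w)
  list(mu = mu, se = sqrt(1 / sum(w)), q = sum(w * (yi - mu)^2))
}

# independent DerSimonian-Laird oracle
hand_dl <- function(yi, sei) {
  w <- 1 / sei^2
  fx <- hand_fixed(yi, sei)
  tau2 <- max(0, (fx$q - (length(yi) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (sei^2 + tau2)
  list(mu = sum(ws * yi) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}
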