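#' @keywords internal
#' @import stats
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

# z quantile for two-sided 95% intervals; kept symbolic so the CI invariants
# (ci = exp(log_or +/- 1.96 se)) hold exactly as documented
Z95 <- qnorm(0.975)

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so simulation helpers do not perturb the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct an effect estimate from a log odds ratio and its standard error
#'
#' The canonical effect container used throughout the package, for per-study
#' and pooled effects alike: log-OR, SE, a 95% Wald CI on the OR scale, and
#' the two-sided normal p-value.
#'
#' @param log_or log odds ratio.
#' @param se positive standard error of the log odds ratio.
#' @return An object of class `effect_estimate`: list with `log_or`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p_value`.
#' @examples
#' effect_estimate(log(2), 0.2)
#' @export
effect_estimate <- function(log_or, se) {
  stopifnot(is.finite(log_or), is.finite(se), se > 0)
  structure(list(
    log_or = log_or,
    se = se,
    or = exp(log_or),
    ci_low = exp(log_or - Z95 * se),
    ci_high = exp(log_or + Z95 * se),
    p_value = 2 * pnorm(-abs(log_or / se))
  ), class = "effect_estimate")
}

#' Recover an effect estimate from a printed OR and 95% CI
#'
#' Inverts the Wald interval: SE = (log(ci_high) - log(ci_low)) / (2 * 1.96).
#' Useful when only the published OR and CI are available (e.g. feeding
#' reported pooled results into [fprp()]).
#'
#' @param or odds ratio.
#' @param ci_low,ci_high 95% confidence limits on the OR scale.
#' @return An `effect_estimate`.
#' @examples
#' effect_from_ci(0.69, 0.56, 0.85)
#' @export
effect_from_ci <- function(or, ci_low, ci_high) {
  stopifnot(or > 0, ci_low > 0, ci_high > ci_low)
  effect_estimate(log(or), (log(ci_high) - log(ci_low)) / (2 * Z95))
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), log-OR %.4f (SE %.4f), p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$log_or, x$se, x$p_value))
  invisible(x)
}
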