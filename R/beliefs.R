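#' Classify belief change between prior and final plausibility ratings
#'
#' @param prior,final Integer codes in `1..C` (vectors of equal length,
#'   both non-missing; missing pairs should be excluded upstream).
#' @return Factor with levels `increased`, `decreased`, `unchanged`.
#' @export
classify_change <- function(prior, final) {
  stopifnot(length(prior) == length(final))
  if (anyNA(prior) || anyNA(final)) {
    stop("classify_change requires non-missing prior and final codes",
         call. = FALSE)
  }
  d <- sign(final - prior)
  factor(c("decreased", "unchanged", "increased")[d + 2],
         levels = c("increased", "decreased", "unchanged"))
}

#' Percentage of teams agreeing with a statement
#'
#' On the 4-point scale, agreement is a response in the top two
#' categories (codes 3 and 4, "yes, mostly" / "yes, definitely");
#' the rate is computed over non-missing responses and reported to two
#' decimals.
#'
#' @param responses Integer codes in `1..4`, `NA` allowed.
#' @return Percentage in `[0, 100]`, rounded to 2 decimals.
#' @export
agreement_rate <- function(responses) {
  x <- responses[!is.na(responses)]
  if (length(x) == 0L) {
    stop("agreement rate undefined: all responses missing", call. = FALSE)
  }
  round(100 * mean(x >= 3L), 2)
}

#' Summarize belief updating across teams
#'
#' Means are computed over all non-missing values at each time point;
#' change-class proportions only over teams with both responses.
#'
#' @param records A data.frame with columns `team_id`, `prior`, `final`
#'   (integer codes in `1..C`, `NA` allowed).
#' @return A `sees_beliefs` list: `mean_prior`, `mean_final`,
#'   `pct_agree_prior`, `pct_agree_final`, `change` (named proportions
#'   `increased`, `decreased`, `unchanged`), `n_complete`.
#' @export
summarize_beliefs <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("prior", "final") %in% names(records)))
  complete <- !is.na(records$prior) & !is.na(records$final)
  if (!any(complete)) {
    stop("need at least one team with both prior and final response",
         call. = FALSE)
  }
  cls <- classify_change(records$prior[complete], records$final[complete])
  structure(
    list(mean_prior = mean(records$prior, na.rm = TRUE),
         mean_final = mean(records$final, na.rm = TRUE),
         pct_agree_prior = agreement_rate(records$prior),
         pct_agree_final = agreement_rate(records$final),
         change = prop.table(table(cls)),
         n_complete = sum(complete)),
    class = "sees_beliefs"
  )
}

#' @export
print.sees_beliefs <- function(x, ...) {
  cat(sprintf("<sees_beliefs> %d complete pairs\n", x$n_complete))
  cat(sprintf("  mean plausibility %.2f -> %.2f; agreement %.2f%% -> %.2f%%\n",
              x$mean_prior, x$mean_final, x$pct_agree_prior,
              x$pct_agree_final))
  cat(sprintf("  increased %.0f%%, decreased %.0f%%, unchanged %.0f%%\n",
              100 * x$change[["increased"]], 100 * x$change[["decreased"]],
              100 * x$change[["unchanged"]]))
  invisible(x)
}

#' Robust and classical descriptives of a numeric vector
#'
#' Reports median, unscaled median absolute deviation
#' (`median(|x - median(x)|)`, no consistency constant), mean and sample
#' standard deviation (`n - 1` denominator). With a single value the SD
#' is undefined and reported as 0 with `sd_defined = FALSE`.
#'
#' @param values Numeric vector (non-finite values dropped).
#' @return List: `median`, `mad`, `mean`, `sd`, `n`, `sd_defined`.
#' @export
group_descriptives <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) == 0L) stop("no finite values", call. = FALSE)
  med <- stats::median(x)
  list(median = med,
       mad = stats::median(abs(x - med)),
       mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else 0,
       n = length(x),
       sd_defined = length(x) > 1L)
}

#' Survey response rate
#'
#' @param n_responded Number of responding teams.
#' @param n_invited Number of invited teams.
#' @return Percentage responding, to 2 decimals.
#' @export
response_rate <- function(n_responded, n_invited) {
  stopifnot(n_invited > 0, n_responded >= 0, n_responded <= n_invited)
  round(100 * n_responded / n_invited, 2)
}
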