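#' Delphi item-screening rule
#'
#' Applies the preregistered inclusion criterion used during instrument
#' development: an item is eligible for inclusion when its expert
#' recommendation ratings (9-point scale, 1 = definitely not include,
#' 9 = definitely include) have a median of 6 or higher and an
#' interquartile range of 2 or smaller (indicating consensus). Items
#' that meet the median criterion but lack consensus are flagged
#' `high_support_flag` when at least `high_support_cutoff` percent of
#' experts strongly endorse them (rating 7-9); the flag is advisory for
#' a discussion round, never an automatic include. All other items are
#' excluded.
#'
#' Quantiles use linear interpolation (R's default type 7); the
#' convention is recorded in the output attributes because boundary
#' decisions (IQR exactly 2) depend on it.
#'
#' @param ratings Matrix or data.frame, experts in rows, items in
#'   columns; integer ratings in `1..9`.
#' @param high_support_cutoff Percent of ratings in `[7, 9]` needed for
#'   the advisory flag (default 70).
#' @return A data.frame (`item_id`, `median`, `iqr`, `pct_high`,
#'   `decision`) with attribute `quantile_type = 7`.
#' @examples
#' r <- cbind(a = c(7, 8, 8, 9), b = c(2, 5, 8, 9))
#' delphi_screen(r)
#' @export
delphi_screen <- function(ratings, high_support_cutoff = 70) {
  m <- as.matrix(ratings)
  if (nrow(m) < 2L) stop("need ratings from >= 2 experts", call. = FALSE)
  if (anyNA(m) || any(m != round(m)) || any(m < 1 | m > 9)) {
    stop("validation error: ratings must be integers in 1..9", call. = FALSE)
  }
  item_ids <- colnames(m) %||% paste0("item_", seq_len(ncol(m)))
  med <- apply(m, 2, stats::median)
  iqr <- apply(m, 2, stats::IQR, type = 7)
  pct_high <- 100 * colMeans(m >= 7)
  decision <- ifelse(med >= 6 & iqr <= 2, "include",
              ifelse(med >= 6 & pct_high >= high_support_cutoff,
                     "high_support_flag", "exclude"))
  out <- data.frame(item_id = item_ids, median = med, iqr = iqr,
                    pct_high = pct_high, decision = decision,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "quantile_type") <- 7L
  attr(out, "high_support_cutoff") <- high_support_cutoff
  out
}
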