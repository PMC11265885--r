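#' Summarize a fitted consensus model
#'
#' Produces the item-level and subscale-level quantities used to report a
#' consensus analysis: per-item posterior medians and central 95%
#' credible intervals of the consensus locations, the overall consensus
#' (posterior median and 95% CI of the per-draw mean of the subscale's
#' item locations), the standard deviation across item-level posterior
#' medians, posterior medians of the category thresholds, per-team
#' scepticism medians, and per-item difficulty medians. Each item is also
#' assigned the response-category label whose threshold interval contains
#' its consensus median.
#'
#' @param fit A `sees_fit` from [fit_consensus()].
#' @param instrument The `sees_instrument` the responses were coded with.
#' @return A `sees_summary`: list with `items` (data.frame: `item_id`,
#'   `label`, `median`, `lower`, `upper`, `difficulty`,
#'   `consensus_label`), `overall` (named vector `median`, `lower`,
#'   `upper`), `sd_across_items`, `thresholds`, `scepticism` (data.frame
#'   per team) and `subscale`.
#' @export
summarize_consensus <- function(fit, instrument) {
  stopifnot(inherits(fit, "sees_fit"),
            inherits(instrument, "sees_instrument"))
  if (length(fit$draws$mu) < 100L) {
    stop("need >= 100 post-warmup draws to summarize", call. = FALSE)
  }
  q <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
  Tq <- apply(fit$draws$T, 2, q)
  items <- data.frame(
    item_id = fit$item_ids,
    median = Tq[1, ], lower = Tq[2, ], upper = Tq[3, ],
    difficulty = apply(fit$draws$lam, 2, stats::median),
    stringsAsFactors = FALSE, row.names = NULL
  )
  idx <- match(items$item_id, instrument$items$id)
  items$label <- instrument$items$label[idx]
  overall_draws <- rowMeans(fit$draws$T)
  overall <- q(overall_draws)
  names(overall) <- c("median", "lower", "upper")
  thresholds <- apply(fit$draws$gamma, 2, stats::median)
  out <- structure(
    list(items = items,
         overall = overall,
         sd_across_items = if (nrow(items) > 1L) stats::sd(items$median) else 0,
         thresholds = thresholds,
         scepticism = data.frame(
           team_id = fit$team_ids,
           median = apply(fit$draws$beta, 2, stats::median),
           stringsAsFactors = FALSE, row.names = NULL),
         subscale = fit$subscale, C = fit$C),
    class = "sees_summary"
  )
  out$items$consensus_label <- label_consensus(out, instrument)
  out
}

#' Map consensus medians to response-category labels
#'
#' An item's consensus location is interpretable only relative to the
#' category thresholds: the assigned label is the category whose
#' threshold interval (using posterior threshold medians) contains the
#' item's consensus median. A median exactly on a threshold is assigned
#' to the higher category.
#'
#' @param summary A `sees_summary`.
#' @param instrument The matching `sees_instrument`.
#' @return Character vector of per-item category labels.
#' @export
label_consensus <- function(summary, instrument) {
  stopifnot(inherits(summary, "sees_summary"))
  g <- summary$thresholds
  vapply(seq_len(nrow(summary$items)), function(i) {
    cat_idx <- 1L + sum(summary$items$median[i] >= g)
    it <- instrument$items[match(summary$items$item_id[i],
                                 instrument$items$id), ]
    it$response_labels[[1]][cat_idx]
  }, "")
}

#' Forest plot of a consensus summary
#'
#' Items on the vertical axis, consensus posterior medians with 95%
#' credible intervals on the latent scale, threshold positions as dashed
#' vertical lines, and the overall subscale consensus as a separate
#' bottom row.
#'
#' @param summary A `sees_summary`.
#' @return A ggplot object.
#' @export
plot_consensus <- function(summary) {
  stopifnot(inherits(summary, "sees_summary"))
  it <- summary$items
  rows <- rbind(
    data.frame(name = paste0(it$item_id, " [", it$label, "]"),
               median = it$median, lower = it$lower, upper = it$upper,
               overall = FALSE, stringsAsFactors = FALSE),
    data.frame(name = "Overall", median = summary$overall[["median"]],
               lower = summary$overall[["lower"]],
               upper = summary$overall[["upper"]],
               overall = TRUE, stringsAsFactors = FALSE)
  )
  rows$name <- factor(rows$name, levels = rev(rows$name))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$median, y = .data$name)) +
    ggplot2::geom_vline(xintercept = summary$thresholds,
                        linetype = "dashed", colour = "grey55") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$overall), size = 2.5,
                        fill = "white") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 21),
                                guide = "none") +
    ggplot2::labs(x = "Latent consensus", y = NULL,
                  title = paste("Consensus:", summary$subscale)) +
    ggplot2::theme_minimal()
}

#' @export
print.sees_summary <- function(x, ...) {
  cat(sprintf("<sees_summary> subscale '%s'\n", x$subscale))
  cat(sprintf("  overall consensus %.2f [%.2f, %.2f], item-SD %.2f\n",
              x$overall[["median"]], x$overall[["lower"]],
              x$overall[["upper"]], x$sd_across_items))
  cat("  thresholds:", paste(sprintf("%.2f", x$thresholds), collapse = ", "),
      "\n")
  df <- x$items[, c("item_id", "median", "lower", "upper", "consensus_label")]
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}
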