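#' Run a full consensus fit from files
#'
#' Pipeline entry point: loads an instrument, reads and recodes a raw
#' response CSV, fits the consensus model per subscale, and writes the
#' recode/validation report, item summaries, posterior draws, forest
#' plots and a run log (with seed, configuration and package version)
#' into `out_dir`.
#'
#' @param responses_path CSV of raw responses (see [read_responses()]).
#' @param out_dir Output directory (created if needed).
#' @param instrument_path Optional instrument definition; default is the
#'   packaged SEES.
#' @param subscales Subscales to fit.
#' @param config A [model_config()].
#' @param make_plots Write forest plots as PNG (default `TRUE`).
#' @return (Invisibly) named list of written file paths.
#' @export
run_fit <- function(responses_path, out_dir, instrument_path = NULL,
                    subscales = c("subjective_evidence",
                                  "methodological_appropriateness"),
                    config = model_config(), make_plots = TRUE) {
  instrument <- load_instrument(instrument_path)
  raw <- read_responses(responses_path)
  table <- recode_responses(raw, instrument)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  report <- validate_responses(table, instrument)
  p <- file.path(out_dir, "recode_report.json")
  jsonlite::write_json(
    list(teams = length(table$team_ids), items = length(table$item_ids),
         na_counts = as.list(table$na_counts),
         na_fraction = as.list(round(report$na_fraction, 4)),
         high_na_items = report$high_na_items,
         violations = report$violations),
    p, auto_unbox = TRUE, pretty = TRUE)
  files["recode_report"] <- p

  for (s in subscales) {
    fit <- fit_consensus(table, instrument, s, config)
    summ <- summarize_consensus(fit, instrument)
    p <- file.path(out_dir, paste0("summary_", s, ".csv"))
    utils::write.csv(summ$items, p, row.names = FALSE)
    files[paste0("summary_", s)] <- p
    p <- file.path(out_dir, paste0("overall_", s, ".json"))
    jsonlite::write_json(
      list(subscale = s,
           overall = as.list(summ$overall),
           sd_across_items = summ$sd_across_items,
           thresholds = summ$thresholds,
           scepticism = summ$scepticism),
      p, auto_unbox = TRUE, pretty = TRUE, digits = 6)
    files[paste0("overall_", s)] <- p
    p <- file.path(out_dir, paste0("draws_", s, ".csv"))
    dr <- cbind(chain = fit$chain, fit$draws$T, fit$draws$gamma,
                mu = fit$draws$mu, sigma = fit$draws$sigma,
                sigma_beta = fit$draws$sigma_beta)
    colnames(dr) <- c("chain", paste0("T_", fit$item_ids),
                      paste0("gamma_", seq_len(ncol(fit$draws$gamma))),
                      "mu", "sigma", "sigma_beta")
    utils::write.csv(dr, p, row.names = FALSE)
    files[paste0("draws_", s)] <- p
    if (make_plots) {
      p <- file.path(out_dir, paste0("forest_", s, ".png"))
      ggplot2::ggsave(p, plot_consensus(summ), width = 7,
                      height = 1 + 0.45 * nrow(summ$items), dpi = 150)
      files[paste0("forest_", s)] <- p
    }
  }

  p <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(
    list(timestamp = format(Sys.time(), tz = "UTC"),
         r_version = R.version.string,
         package_version = as.character(utils::packageVersion("sees")),
         seed = config$seed,
         config = unclass(config),
         config_hash = .config_hash(config),
         responses = responses_path),
    p, auto_unbox = TRUE, pretty = TRUE)
  files["run_log"] <- p
  invisible(files)
}

#' Assemble a Markdown report from fit outputs
#'
#' Combines consensus summaries written by [run_fit()] with optional
#' belief-updating and effect-size correlation inputs into one
#' self-contained Markdown report. Sections whose inputs are missing are
#' marked unavailable rather than dropped.
#'
#' @param out_dir Directory holding [run_fit()] outputs; the report is
#'   written there as `report.md`.
#' @param beliefs_path Optional CSV with columns `team_id`, `prior`,
#'   `final` (codes 1..4).
#' @param effects_path Optional CSV with columns `team_id`,
#'   `effect_size`; when both inputs are present, Bayesian correlations
#'   of effect sizes with prior and final beliefs are included.
#' @param seed Seed for the stochastic Spearman Bayes factors.
#' @return (Invisibly) the report path.
#' @export
run_report <- function(out_dir, beliefs_path = NULL, effects_path = NULL,
                       seed = 1L) {
  lines <- c("# SEES analysis report", "")

  lines <- c(lines, "## Consensus", "")
  summaries <- sort(list.files(out_dir, pattern = "^summary_.*\\.csv$",
                               full.names = TRUE))
  if (length(summaries) == 0L) {
    lines <- c(lines, "_Section unavailable: no consensus summaries found._",
               "")
  } else {
    for (p in summaries) {
      s <- sub("^summary_(.*)\\.csv$", "\\1", basename(p))
      df <- utils::read.csv(p)
      lines <- c(lines, paste0("### ", s), "",
                 "| item | median | 95% CI | label |",
                 "|---|---|---|---|",
                 sprintf("| %s | %.2f | [%.2f, %.2f] | %s |",
                         df$item_id, df$median, df$lower, df$upper,
                         df$consensus_label),
                 "")
      op <- file.path(out_dir, paste0("overall_", s, ".json"))
      if (file.exists(op)) {
        ov <- jsonlite::read_json(op, simplifyVector = TRUE)
        lines <- c(lines, sprintf(
          "Overall consensus %.2f [%.2f, %.2f]; SD across items %.2f.",
          ov$overall$median, ov$overall$lower, ov$overall$upper,
          ov$sd_across_items), "")
      }
    }
  }

  lines <- c(lines, "## Belief updating", "")
  beliefs <- NULL
  if (!is.null(beliefs_path) && file.exists(beliefs_path)) {
    beliefs <- utils::read.csv(beliefs_path)
    b <- summarize_beliefs(beliefs)
    lines <- c(lines, sprintf(
      paste0("Mean plausibility %.2f before and %.2f after analysis; ",
             "%.2f%% of teams agreed before, %.2f%% after. ",
             "Among %d complete pairs: %.0f%% increased, %.0f%% decreased, ",
             "%.0f%% unchanged."),
      b$mean_prior, b$mean_final, b$pct_agree_prior, b$pct_agree_final,
      b$n_complete, 100 * b$change[["increased"]],
      100 * b$change[["decreased"]], 100 * b$change[["unchanged"]]), "")
  } else {
    lines <- c(lines, "_Section unavailable: no beliefs input._", "")
  }

  lines <- c(lines, "## Correlations with reported effect sizes", "")
  if (!is.null(beliefs) && !is.null(effects_path) &&
      file.exists(effects_path)) {
    eff <- utils::read.csv(effects_path)
    m <- merge(beliefs, eff, by = "team_id")
    rows <- character(0)
    for (var in c("prior", "final")) {
      ok <- is.finite(m[[var]]) & is.finite(m$effect_size)
      res <- spearman_bf(m[[var]][ok], m$effect_size[ok], seed = seed)
      rows <- c(rows, sprintf(
        "| %s beliefs vs effect size | spearman | %.2f [%.2f, %.2f] | %.2f | %.2f |",
        var, res$estimate, res$ci95[1], res$ci95[2], res$bf_plus0,
        res$bf_0plus))
    }
    lines <- c(lines, "| pair | method | estimate [95% CI] | BF+0 | BF0+ |",
               "|---|---|---|---|---|", rows, "")
  } else {
    lines <- c(lines,
               "_Section unavailable: needs both beliefs and effects inputs._",
               "")
  }

  lines <- c(lines, sprintf("_Generated %s._",
                            format(Sys.time(), tz = "UTC")))
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

# small stable hash (FNV-1a over the deparsed object) used to stamp
# outputs with the configuration they came from
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
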