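#' Read a raw survey response table
#'
#' Reads a wide CSV: first column the team identifier, remaining columns
#' one per item id. Cells may hold response labels, the
#' not-applicable label, empty strings, or integer codes.
#'
#' @param path CSV file path.
#' @return A data.frame with character columns, first column `team_id`.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) {
    stop("response file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character())
  if (ncol(raw) < 2L) {
    stop("response table must have a team-id column plus item columns",
         call. = FALSE)
  }
  names(raw)[1] <- "team_id"
  raw
}

#' Recode raw responses against an instrument
#'
#' Maps response labels (or raw integer codes) to ordinal codes `1..C`
#' where `C` is the most favourable category. Counter-indicative items
#' are reverse-coded (`x -> C + 1 - x`) exactly once, so that higher
#' codes always mean stronger belief / fewer concerns. The
#' not-applicable label and empty cells become missing values and are
#' tallied per item.
#'
#' Label matching is case-insensitive and punctuation/whitespace
#' normalized. Integer input is interpreted on the raw presentation
#' scale (ascending endorsement before reverse coding).
#'
#' @param raw A data.frame as returned by [read_responses()], or a
#'   matrix of labels/codes with team ids as row names.
#' @param instrument A `sees_instrument`.
#' @return A `sees_responses` object: list with `team_ids`, `item_ids`,
#'   `values` (integer matrix, teams x items, `NA` for missing),
#'   `na_counts` (per item), `C`, and `reversed = TRUE` recording that
#'   reverse coding has been applied.
#' @export
recode_responses <- function(raw, instrument) {
  stopifnot(inherits(instrument, "sees_instrument"))
  if (is.matrix(raw)) {
    team_ids <- rownames(raw) %||% as.character(seq_len(nrow(raw)))
    tab <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    team_ids <- as.character(raw[[1]])
    tab <- raw[, -1, drop = FALSE]
  }
  item_ids <- colnames(tab)
  known <- instrument$items$id
  unknown <- setdiff(item_ids, known)
  if (length(unknown)) {
    stop("recode error: response columns not in instrument: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  C <- instrument$C
  na_norm <- .normalize_label(instrument$na_label)
  # accept either half of the combined sentinel as well
  na_alts <- unique(c(na_norm, .normalize_label(
    strsplit(instrument$na_label, "/", fixed = TRUE)[[1]]), "na", ""))
  values <- matrix(NA_integer_, nrow(tab), length(item_ids),
                   dimnames = list(team_ids, item_ids))
  for (j in seq_along(item_ids)) {
    it <- instrument$items[match(item_ids[j], known), ]
    coded_labels <- .normalize_label(it$response_labels[[1]])
    col <- as.character(tab[[j]])
    norm <- .normalize_label(col)
    is_na <- norm %in% na_alts | is.na(col)
    code <- match(norm, coded_labels)
    # integer input: raw ascending-endorsement codes, reverse if needed
    num <- suppressWarnings(as.numeric(col))
    int_ok <- !is.na(num) & num == round(num) & num >= 1 & num <= C
    code[int_ok] <- if (it$reverse_coded) C + 1L - num[int_ok] else num[int_ok]
    bad <- which(is.na(code) & !is_na)
    if (length(bad)) {
      stop(sprintf(
        "recode error: unrecognized label '%s' (row %d / team %s, column %s)",
        col[bad[1]], bad[1], team_ids[bad[1]], item_ids[j]), call. = FALSE)
    }
    code[is_na] <- NA_integer_
    values[, j] <- as.integer(code)
  }
  structure(
    list(team_ids = team_ids, item_ids = item_ids, values = values,
         na_counts = colSums(is.na(values)), C = C, reversed = TRUE),
    class = "sees_responses"
  )
}

#' Construct a response table from an already-coded matrix
#'
#' For programmatic use (e.g. the synthetic generator): values must be
#' integers in `1..C` or `NA`, with reverse coding already applied.
#'
#' @param values Integer matrix, teams x items.
#' @param C Number of categories.
#' @param team_ids,item_ids Optional identifiers; defaults from dimnames.
#' @return A `sees_responses` object.
#' @export
as_sees_responses <- function(values, C = 4L, team_ids = NULL,
                              item_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  ok <- is.na(values) | (values >= 1L & values <= C)
  if (!all(ok)) {
    stop("response values must be integers in 1..", C, " or NA",
         call. = FALSE)
  }
  team_ids <- team_ids %||% rownames(values) %||%
    paste0("team_", seq_len(nrow(values)))
  item_ids <- item_ids %||% colnames(values) %||%
    paste0("item_", seq_len(ncol(values)))
  dimnames(values) <- list(team_ids, item_ids)
  structure(
    list(team_ids = team_ids, item_ids = item_ids, values = values,
         na_counts = colSums(is.na(values)), C = as.integer(C),
         reversed = TRUE),
    class = "sees_responses"
  )
}

#' Validate a coded response table
#'
#' Report-only checks: out-of-range codes, teams or items with no data at
#' all, and per-item not-applicable/missing fractions (items with more
#' than `na_flag_threshold` missing are flagged; their consensus will be
#' estimated with wide uncertainty).
#'
#' @param table A `sees_responses`.
#' @param instrument A `sees_instrument`.
#' @param na_flag_threshold Fraction above which an item is flagged
#'   (default 0.5).
#' @return A list with `violations` (data.frame of out-of-range cells),
#'   `all_missing_teams`, `all_missing_items`, `na_fraction` (named
#'   vector) and `high_na_items`.
#' @export
validate_responses <- function(table, instrument,
                               na_flag_threshold = 0.5) {
  stopifnot(inherits(table, "sees_responses"),
            inherits(instrument, "sees_instrument"))
  v <- table$values
  C <- instrument$C
  bad <- which(!is.na(v) & (v < 1L | v > C), arr.ind = TRUE)
  violations <- data.frame(
    team_id = table$team_ids[bad[, 1]],
    item_id = table$item_ids[bad[, 2]],
    value = v[bad],
    stringsAsFactors = FALSE
  )
  na_fraction <- colMeans(is.na(v))
  names(na_fraction) <- table$item_ids
  list(
    violations = violations,
    all_missing_teams = table$team_ids[rowSums(!is.na(v)) == 0L],
    all_missing_items = table$item_ids[colSums(!is.na(v)) == 0L],
    na_fraction = na_fraction,
    high_na_items = table$item_ids[na_fraction > na_flag_threshold]
  )
}

#' @export
print.sees_responses <- function(x, ...) {
  cat(sprintf("<sees_responses>: %d teams x %d items, C = %d, %d missing cells\n",
              length(x$team_ids), length(x$item_ids), x$C,
              sum(is.na(x$values))))
  invisible(x)
}

# subset the columns of a response table belonging to one subscale
.subscale_values <- function(table, instrument, subscale) {
  ids <- subscale_items(instrument, subscale)$id
  keep <- intersect(ids, table$item_ids)
  if (length(keep) < 1L) {
    stop("no items of subscale '", subscale, "' present in response table",
         call. = FALSE)
  }
  table$values[, keep, drop = FALSE]
}
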