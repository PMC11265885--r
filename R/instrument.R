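#' Load a survey instrument definition
#'
#' Reads an instrument schema (YAML or JSON) and returns a validated
#' `sees_instrument` object. With no arguments the packaged SEES
#' (Subjective Evidence Evaluation Survey) definition is loaded: one
#' prior-belief item plus 18 scored items split over the
#' `subjective_evidence` (8 items) and `methodological_appropriateness`
#' (10 items) subscales, each answered on a 4-point Likert scale with a
#' "not applicable/I do not know" option.
#'
#' Item `response_labels` are stored low-to-high on the *coded* scale, so
#' that code `C` always denotes the most favourable response (strongest
#' belief in the hypothesis, or fewest methodological concerns). For
#' counter-indicative items (`reverse_coded = TRUE`; SE_4 to SE_7 in the
#' packaged SEES) the stored label order is therefore the inverse of the
#' presentation order.
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON instrument
#'   definition. `NULL` (default) loads the packaged SEES.
#' @return A `sees_instrument`: a list with elements `name`, `C` (number
#'   of response categories), `na_label`, and `items` (a data.frame with
#'   columns `id`, `subscale`, `label`, `text`, `example`,
#'   `reverse_coded`, `allows_na`, plus a list-column `response_labels`).
#' @examples
#' inst <- load_instrument()
#' nrow(subscale_items(inst, "subjective_evidence"))
#' @export
load_instrument <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sees_instrument.yaml", package = "sees")
  }
  if (!file.exists(path)) {
    stop("instrument definition file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  as_sees_instrument(raw)
}

.valid_subscales <- c("prior", "subjective_evidence",
                      "methodological_appropriateness")

#' @rdname load_instrument
#' @param x A list with fields `C`, `na_label` and `items` as produced by
#'   parsing an instrument definition file.
#' @export
as_sees_instrument <- function(x) {
  if (is.null(x$items) || length(x$items) == 0L) {
    stop("instrument schema error: no items defined", call. = FALSE)
  }
  C <- as.integer(x$C %||% 4L)
  if (C < 2L) stop("instrument schema error: C must be >= 2", call. = FALSE)
  items <- lapply(x$items, function(it) {
    for (f in c("id", "subscale", "text")) {
      if (is.null(it[[f]])) {
        stop("instrument schema error: item missing field '", f, "'",
             call. = FALSE)
      }
    }
    if (!it$subscale %in% .valid_subscales) {
      stop("instrument schema error: unknown subscale '", it$subscale,
           "' for item ", it$id, call. = FALSE)
    }
    labs <- unlist(it$response_labels)
    if (length(labs) != C) {
      stop("instrument schema error: item ", it$id, " has ", length(labs),
           " response labels, expected ", C, call. = FALSE)
    }
    list(id = as.character(it$id),
         subscale = it$subscale,
         label = as.character(it$label %||% it$id),
         text = as.character(it$text),
         example = as.character(it$example %||% ""),
         reverse_coded = isTRUE(it$reverse_coded),
         allows_na = isTRUE(it$allows_na),
         response_labels = labs)
  })
  ids <- vapply(items, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("instrument schema error: duplicate item id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  # subscale membership must be consistent with the id prefix convention
  pref <- sub("_.*$", "", ids)
  sub <- vapply(items, `[[`, "", "subscale")
  expect <- c(PRIOR = "prior", SE = "subjective_evidence",
              MA = "methodological_appropriateness")
  bad <- which(pref %in% names(expect) & expect[pref] != sub)
  if (length(bad)) {
    stop("instrument schema error: item ", ids[bad[1]],
         " is assigned to subscale '", sub[bad[1]], "'", call. = FALSE)
  }
  df <- data.frame(
    id = ids,
    subscale = sub,
    label = vapply(items, `[[`, "", "label"),
    text = vapply(items, `[[`, "", "text"),
    example = vapply(items, `[[`, "", "example"),
    reverse_coded = vapply(items, `[[`, NA, "reverse_coded"),
    allows_na = vapply(items, `[[`, NA, "allows_na"),
    stringsAsFactors = FALSE
  )
  df$response_labels <- lapply(items, `[[`, "response_labels")
  out <- structure(
    list(name = x$name %||% "instrument", C = C,
         na_label = x$na_label %||% "not applicable/I do not know",
         items = df),
    class = "sees_instrument"
  )
  out
}

#' Scored items of an instrument
#'
#' Scored items are all items outside the `prior` subscale; the
#' prior-belief item is administered before the analysis and is not part
#' of either subscale nor of the consensus model.
#'
#' @param instrument A `sees_instrument`.
#' @return A data.frame of items (same columns as `instrument$items`).
#' @export
scored_items <- function(instrument) {
  stopifnot(inherits(instrument, "sees_instrument"))
  instrument$items[instrument$items$subscale != "prior", , drop = FALSE]
}

#' @rdname scored_items
#' @param subscale Subscale identifier, e.g. `"subjective_evidence"`.
#' @export
subscale_items <- function(instrument, subscale) {
  stopifnot(inherits(instrument, "sees_instrument"))
  subscale <- match.arg(subscale, .valid_subscales)
  instrument$items[instrument$items$subscale == subscale, , drop = FALSE]
}

#' Reverse-code ordinal responses
#'
#' Maps a response code `x` on a `C`-category scale to `C + 1 - x`, the
#' standard recoding for counter-indicative items. The map is an
#' involution: applying it twice restores the input.
#'
#' @param x Integer codes in `1..C` (`NA` allowed).
#' @param C Number of response categories.
#' @return Recoded integer vector.
#' @export
reverse_code <- function(x, C = 4L) {
  stopifnot(C >= 2L)
  as.integer(C + 1L - x)
}

#' @export
print.sees_instrument <- function(x, ...) {
  it <- x$items
  cat(sprintf("<sees_instrument '%s'>: %d items (%d scored), C = %d\n",
              x$name, nrow(it), sum(it$subscale != "prior"), x$C))
  for (s in unique(it$subscale)) {
    cat(sprintf("  %-32s %d item(s)\n", s, sum(it$subscale == s)))
  }
  rc <- it$id[it$reverse_coded]
  if (length(rc)) cat("  reverse-coded:", paste(rc, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize a response label for matching: case, punctuation and
# whitespace dialects across survey exports should not matter
.normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9 ]+", " ", x)
  gsub(" +", " ", trimws(x))
}
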