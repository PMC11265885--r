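test_that("packaged instrument has the published structure", {
  inst <- load_instrument()
  expect_s3_class(inst, "sees_instrument")
  expect_equal(inst$C, 4L)
  expect_equal(nrow(scored_items(inst)), 18L)
  expect_equal(nrow(subscale_items(inst, "subjective_evidence")), 8L)
  expect_equal(nrow(subscale_items(inst, "methodological_appropriateness")),
               10L)
  expect_equal(nrow(subscale_items(inst, "prior")), 1L)
  expect_setequal(inst$items$id[inst$items$reverse_coded],
                  c("SE_4", "SE_5", "SE_6", "SE_7"))
  expect_true(all(scored_items(inst)$allows_na))
  expect_true(all(lengths(inst$items$response_labels) == 4L))
})

test_that("schema violations are reported with the offending item", {
  base <- list(C = 4, items = list(
    list(id = "SE_1", subscale = "subjective_evidence", text = "t",
         response_labels = as.list(letters[1:4])),
    list(id = "SE_2", subscale = "subjective_evidence", text = "t",
         response_labels = as.list(letters[1:4]))))
  expect_s3_class(as_sees_instrument(base), "sees_instrument")

  dup <- base; dup$items[[2]]$id <- "SE_1"
  expect_error(as_sees_instrument(dup), "duplicate.*SE_1")

  short <- base; short$items[[2]]$response_labels <- as.list(letters[1:3])
  expect_error(as_sees_instrument(short), "SE_2.*3 response labels")

  odd <- base; odd$items[[2]]$subscale <- "mystery"
  expect_error(as_sees_instrument(odd), "unknown subscale")

  mismatch <- base; mismatch$items[[2]]$id <- "MA_1"
  expect_error(as_sees_instrument(mismatch), "MA_1")
})

test_that("reverse coding is an involution and matches C+1-x", {
  for (C in 2:6) {
    x <- seq_len(C)
    expect_equal(reverse_code(x, C), rev(x))
    expect_equal(reverse_code(reverse_code(x, C), C), x)
  }
})

test_that("labels are recoded to the favourable-high convention", {
  inst <- load_instrument()
  raw <- data.frame(
    team_id = c("t1", "t2"),
    SE_1 = c("yes, definitely", "no, mostly not"),
    SE_4 = c("yes, definitely", "No, Definitely Not!"),
    MA_3 = c("not applicable/I do not know", "no concerns"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  tab <- recode_responses(raw, inst)
  expect_equal(tab$values["t1", "SE_1"], 4L) # top endorsement
  expect_equal(tab$values["t2", "SE_1"], 2L)
  expect_equal(tab$values["t1", "SE_4"], 1L) # counter-indicative: 5 - 4
  expect_equal(tab$values["t2", "SE_4"], 4L) # normalization tolerated
  expect_true(is.na(tab$values["t1", "MA_3"]))
  expect_equal(unname(tab$na_counts["MA_3"]), 1L)
  expect_equal(tab$values["t2", "MA_3"], 4L)
  expect_true(tab$reversed)
})

test_that("integer input is accepted and reverse-coded once", {
  inst <- load_instrument()
  raw <- data.frame(team_id = "t1", SE_1 = "4", SE_4 = "4",
                    check.names = FALSE)
  tab <- recode_responses(raw, inst)
  expect_equal(tab$values[1, "SE_1"], 4L)
  expect_equal(tab$values[1, "SE_4"], 1L)
})

test_that("recoding round-trips through each item's coded labels", {
  inst <- load_instrument()
  set.seed(42)
  ids <- scored_items(inst)$id
  # build a random label table, recode, then look codes back up
  raw_labels <- vapply(ids, function(id) {
    it <- inst$items[match(id, inst$items$id), ]
    sample(it$response_labels[[1]], 5, replace = TRUE)
  }, character(5))
  raw <- data.frame(team_id = paste0("t", 1:5), raw_labels,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab <- recode_responses(raw, inst)
  for (id in ids) {
    it <- inst$items[match(id, inst$items$id), ]
    expect_equal(it$response_labels[[1]][tab$values[, id]],
                 raw[[id]], info = id)
  }
})

test_that("unrecognized labels name the row and column", {
  inst <- load_instrument()
  raw <- data.frame(team_id = c("t1", "t2"),
                    SE_1 = c("yes, definitely", "absolutely"),
                    check.names = FALSE)
  expect_error(recode_responses(raw, inst), "absolutely.*row 2.*SE_1")
})

test_that("validation flags range violations and high-NA items", {
  inst <- load_instrument()
  v <- matrix(sample(1:4, 40, replace = TRUE), 10, 4,
              dimnames = list(paste0("t", 1:10),
                              c("SE_1", "SE_2", "SE_3", "SE_4")))
  tab <- as_sees_responses(v, C = 4)
  rep0 <- validate_responses(tab, inst)
  expect_equal(nrow(rep0$violations), 0L)
  expect_length(rep0$high_na_items, 0L)

  # out-of-range cell injected after construction
  tab_bad <- tab
  tab_bad$values[1, 1] <- 5L
  rep1 <- validate_responses(tab_bad, inst)
  expect_equal(nrow(rep1$violations), 1L)
  expect_equal(rep1$violations$item_id, "SE_1")

  # 6 of 10 teams missing on one item -> flagged above the 0.5 threshold
  v2 <- v
  v2[1:6, "SE_2"] <- NA_integer_
  rep2 <- validate_responses(as_sees_responses(v2, C = 4), inst)
  expect_equal(unname(rep2$na_fraction["SE_2"]), 0.6)
  expect_equal(rep2$high_na_items, "SE_2")
})
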