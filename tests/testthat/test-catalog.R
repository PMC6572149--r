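test_that("vocabulary defines 13 behavior classes and 6 working types, 4 key", {
  bc <- behavior_classes()
  expect_equal(nrow(bc), 13)
  expect_equal(anyDuplicated(bc$code), 0)
  wt <- working_types()
  expect_equal(nrow(wt), 6)
  expect_setequal(wt$id[wt$is_key], key_wts)
})

test_that("tabulation reproduces the case-study count structure", {
  fx <- study_fixture()
  tab <- tabulate_occurrences(fx$records)
  expect_equal(tab$n_accidents, 200)
  for (wt in key_wts) {
    tot <- sum(tab$counts$count[tab$counts$working_type == wt])
    expect_equal(tot, unname(frozen_type_totals[wt]))
  }
  # per-class ventilation counts sum to the type total
  vent <- c(OIW = 32, FSD = 19, UUD = 15, VDP = 6, RIW = 10)
  for (b in names(vent)) {
    i <- tab$counts$working_type == "ventilation" & tab$counts$behavior == b
    expect_equal(tab$counts$count[i], unname(vent[b]))
  }
  expect_equal(sum(vent), 82)
  # non-key types are represented but empty
  expect_equal(sum(tab$counts$count[tab$counts$working_type == "mining"]), 0)
})

test_that("occurrence probabilities and shares match the published table", {
  tab <- tabulate_occurrences(study_fixture()$records)
  expect_equal(occurrence_probability(tab, "ventilation", "OIW"), 0.16)
  expect_equal(occurrence_probability(tab, "blasting", "UUD"), 0.065)
  expect_equal(occurrence_probability(tab, "ventilation", "UA"), 0)
  for (wt in key_wts) {
    expect_equal(working_type_share(tab, wt), unname(frozen_type_shares[wt]))
  }
  expect_equal(sum(sapply(key_wts, working_type_share, table = tab)), 100)
})

test_that("empty record collections tabulate to an all-zero table", {
  empty <- data.frame(accident_id = character(0),
                      working_type = character(0),
                      behavior_code = character(0))
  tab <- tabulate_occurrences(empty)
  expect_equal(tab$n_accidents, 0)
  expect_true(all(tab$counts$count == 0))
  expect_error(occurrence_probability(tab, "ventilation", "OIW"),
               "undefined")
  expect_error(working_type_share(tab, "ventilation"), "undefined")
})

test_that("unknown tokens are rejected naming the token and row", {
  recs <- data.frame(accident_id = c("A1", "A2"),
                     working_type = c("ventilation", "plumbing"),
                     behavior_code = c("OIW", "OIW"))
  expect_error(tabulate_occurrences(recs), "'plumbing' in row 2")
  recs2 <- data.frame(accident_id = "A1", working_type = "blasting",
                      behavior_code = "XYZ")
  expect_error(tabulate_occurrences(recs2), "'XYZ' in row 1")
})

test_that("tabulation is invariant under row order and CSV round-trips", {
  fx <- study_fixture()
  tab <- tabulate_occurrences(fx$records)
  shuffled <- fx$records[withr::with_seed(7, sample(nrow(fx$records))), ]
  expect_equal(tabulate_occurrences(shuffled)$counts, tab$counts)

  path <- withr::local_tempfile(fileext = ".csv")
  write_accident_records(fx$records, path)
  tab2 <- tabulate_occurrences(read_accident_records(path))
  expect_identical(tab2$counts, tab$counts)
  expect_identical(tab2$n_accidents, tab$n_accidents)
})

test_that("cell probabilities sum to citations over accidents", {
  fx <- study_fixture()
  tab <- tabulate_occurrences(fx$records)
  probs <- mapply(function(w, b) occurrence_probability(tab, w, b),
                  tab$counts$working_type, tab$counts$behavior)
  expect_equal(sum(probs), sum(tab$counts$count) / tab$n_accidents)
})
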