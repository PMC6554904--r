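test_that("category registries match the published measure structure", {
  ch <- category_registry("charlson")
  em <- category_registry("elixhauser")
  expect_equal(nrow(ch), 17)
  expect_equal(nrow(em), 31)
  expect_true(all(ch$weight_original %in% c(1, 2, 3, 6)))
  expect_true(all(ch$weight_quan %in% c(0, 1, 2, 4, 6)))
  # the Quan modification keeps exactly 12 contributing categories
  expect_equal(sum(ch$weight_quan > 0), 12)
  expect_false(anyDuplicated(ch$category) > 0)
  expect_false(anyDuplicated(em$category) > 0)
})

test_that("loading collapses duplicate (code, category) pairs only", {
  rows <- tiny_charlson_rows()
  rows <- rbind(rows, rows[2, ])             # exact duplicate pair
  path <- write_codelist_csv(rows)
  expect_message(cl <- load_codelist(path, "charlson"), "collapsed 1")
  expect_equal(nrow(cl$entries), 6)
  # same code in two different categories is retained
  rows2 <- tiny_charlson_rows()
  rows2$category[5] <- "cancer"
  rows2 <- rbind(rows2, data.frame(code = "B58..", term = "Secondary ca",
                                   category = "mets"))
  cl2 <- load_codelist(write_codelist_csv(rows2), "charlson")
  expect_equal(nrow(cl2$entries), 7)
  expect_setequal(lookup(cl2, "B58.."), c("cancer", "mets"))
})

test_that("loader rejects bad files with informative errors", {
  expect_error(load_codelist(tempfile(), "charlson"), "not found")
  rows <- tiny_charlson_rows()
  no_col <- rows[, c("code", "term")]
  expect_error(load_codelist(write_codelist_csv(no_col), "charlson"),
               "mandatory column")
  bad_cat <- rows
  bad_cat$category[3] <- "asthma"   # not a charlson category
  expect_error(load_codelist(write_codelist_csv(bad_cat), "charlson"),
               "row 3.*asthma")
  empty <- rows
  empty$code[2] <- "  "
  expect_error(load_codelist(write_codelist_csv(empty), "charlson"),
               "empty code")
})

test_that("codes are matched verbatim and case-sensitively", {
  cl <- load_codelist(write_codelist_csv(tiny_charlson_rows()), "charlson")
  expect_equal(lookup(cl, "H33.."), "copd")
  expect_equal(lookup(cl, "h33.."), character(0))   # case matters
  expect_equal(lookup(cl, " H33.. "), "copd")       # trimmed
  expect_equal(lookup(cl, "XYZ"), character(0))
  # every lookup result lies inside the measure's category set
  for (cd in cl$entries$code) {
    expect_true(all(lookup(cl, cd) %in% category_registry("charlson")$category))
  }
})

test_that("validation report enumerates the right facts", {
  cl <- load_codelist(write_codelist_csv(tiny_charlson_rows()), "charlson")
  rep <- validate_codelist(cl)
  expect_equal(nrow(rep$duplicate_pairs), 0)
  expect_length(rep$unknown_categories, 0)
  expect_equal(rep$empty_codes, 0)
  expect_equal(rep$entry_count, 6)
  # per-category counts partition the entries
  expect_equal(sum(rep$per_category_counts), rep$entry_count)
  # a code sitting in two categories is informational, not a duplicate
  rows <- rbind(tiny_charlson_rows(),
                data.frame(code = "B58..", term = "x", category = "cancer"))
  rep2 <- validate_codelist(load_codelist(write_codelist_csv(rows),
                                          "charlson"))
  expect_equal(rep2$cross_category_codes, "B58..")
  expect_equal(nrow(rep2$duplicate_pairs), 0)
})

test_that("write/load round trip is lossless", {
  cl <- load_codelist(write_codelist_csv(tiny_charlson_rows()), "charlson")
  path <- tempfile(fileext = ".csv")
  write_codelist(cl, path)
  expect_identical(load_codelist(path, "charlson"), cl)
})

test_that("merge is a set union with subset-membership discrepancies", {
  mk <- function(codes, category = "chf") {
    readmorbid:::new_codelist(
      data.frame(code = codes, term = codes, category = category), "charlson")
  }
  l1 <- mk(c("a", "b")); l2 <- mk(c("b", "c"))
  m <- merge_codelists(l1, l2)
  expect_setequal(m$merged$entries$code, c("a", "b", "c"))
  expect_setequal(m$discrepancies$code, c("a", "c"))
  expect_true(all(m$discrepancies$n_lists == 1))
  # idempotence
  mi <- merge_codelists(l1, l1)
  expect_identical(mi$merged$entries, l1$entries)
  expect_equal(nrow(mi$discrepancies), 0)
  # mixed measures refuse
  em <- readmorbid:::new_codelist(
    data.frame(code = "a", term = "a", category = "chf"), "elixhauser")
  expect_error(merge_codelists(l1, em), "different measures")
})

test_that("merge is commutative and associative on random lists", {
  set.seed(11)
  key <- function(cl) sort(paste(cl$entries$code, cl$entries$category))
  for (i in 1:20) {
    ls <- replicate(3, random_codelist(n = sample(3:10, 1)),
                    simplify = FALSE)
    m123 <- merge_codelists(ls)$merged
    m321 <- merge_codelists(ls[c(3, 2, 1)])$merged
    pair <- merge_codelists(
      merge_codelists(ls[[1]], ls[[2]])$merged, ls[[3]])$merged
    expect_identical(key(m123), key(m321))
    expect_identical(key(m123), key(pair))
  }
})
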