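make_events <- function(days_before_index, codes,
                        index = as.Date("2005-06-15")) {
  data.frame(patient_id = rep("P1", length(codes)),
             event_date = index - days_before_index,
             code = codes, stringsAsFactors = FALSE)
}

test_that("look-back windows bound event ascertainment half-open", {
  cl <- load_codelist(write_codelist_csv(tiny_charlson_rows()), "charlson")
  index <- as.Date("2005-06-15")
  ev <- make_events(400, "H33..", index)
  expect_false(flag_comorbidities(ev, cl, index, "one_year")[["copd"]])
  expect_true(flag_comorbidities(ev, cl, index, "five_year")[["copd"]])
  # events on/after the index date never count
  ev0 <- make_events(c(0, -5), c("H33..", "G58.."), index)
  f <- flag_comorbidities(ev0, cl, index, "complete_record")
  expect_false(any(f))
  # boundary: exactly 365 days before index is inside the 1-year window
  ev365 <- make_events(365, "H33..", index)
  expect_true(flag_comorbidities(ev365, cl, index, "one_year")[["copd"]])
  # no events at all
  f0 <- flag_comorbidities(make_events(integer(), character(), index),
                           cl, index, "one_year")
  expect_false(any(f0))
  expect_equal(charlson_index(f0), 0L)
})

test_that("unknown codes are ignored silently", {
  cl <- load_codelist(write_codelist_csv(tiny_charlson_rows()), "charlson")
  index <- as.Date("2005-06-15")
  ev <- make_events(c(10, 20), c("ZZZZ.", "G58.."), index)
  f <- flag_comorbidities(ev, cl, index, "complete_record")
  expect_equal(names(f)[f], "chf")
})

test_that("window monotonicity holds against a brute-force re-scan", {
  coh <- small_cohort(n_cases = 150, seed = 31)
  kinds <- c("one_year", "five_year", "complete_record")
  profs <- lapply(kinds, function(w)
    comorbidity_profiles(coh, window = w, hierarchy = FALSE))
  names(profs) <- kinds
  for (i in 1:2) {
    narrow <- profs[[kinds[i]]]
    wide <- profs[[kinds[i + 1]]]
    for (measure in c("charlson", "elixhauser")) {
      fn <- profile_flags(narrow, measure)
      fw <- profile_flags(wide, measure)
      expect_true(all(fw[fn]),
                  label = paste("flags(", kinds[i], ") subset of flags(",
                                kinds[i + 1], "),", measure))
    }
    expect_true(all(narrow$cci_original <= wide$cci_original))
    expect_true(all(narrow$em_count <= wide$em_count))
  }
  # spot-check a sample of patients against the single-patient scan
  idx <- seq(1, nrow(coh$patients), by = 37)
  for (i in idx) {
    pid <- coh$patients$patient_id[i]
    ev <- coh$events[coh$events$patient_id == pid, ]
    for (w in kinds) {
      direct <- flag_comorbidities(ev, coh$codelists$charlson,
                                   coh$patients$index_date[i], w)
      vect <- profile_flags(profs[[w]], "charlson")[pid, ]
      expect_equal(unname(vect), unname(direct == TRUE))
    }
  }
})

test_that("severity hierarchy clears superseded categories idempotently", {
  f <- flag_vector("charlson", c("diab", "diab_comp", "mild_liver"))
  out <- apply_hierarchy(f, default_hierarchy("charlson"))
  expect_true(out[["diab_comp"]] && !out[["diab"]])
  expect_true(out[["mild_liver"]])   # severe counterpart absent
  expect_identical(apply_hierarchy(out, default_hierarchy("charlson")), out)
  # empty rule set is the identity
  expect_identical(apply_hierarchy(f, NULL), f)
  expect_identical(apply_hierarchy(f, default_hierarchy("charlson")[0, ]), f)
  # elixhauser defaults
  g <- flag_vector("elixhauser", c("htn_unc", "htn_comp", "mets",
                                   "solid_tumour"))
  out2 <- apply_hierarchy(g, default_hierarchy("elixhauser"))
  expect_false(out2[["htn_unc"]])
  expect_false(out2[["solid_tumour"]])
  expect_true(out2[["htn_comp"]] && out2[["mets"]])
})

test_that("charlson index equals brute-force weight summation", {
  reg <- category_registry("charlson")
  expect_equal(charlson_index(flag_vector("charlson", "pvd")), 1L)
  expect_equal(charlson_index(flag_vector("charlson", "mets")), 6L)
  expect_equal(charlson_index(flag_vector("charlson")), 0L)
  expect_equal(charlson_index(stats::setNames(rep(TRUE, 17), reg$category)),
               sum(reg$weight_original))
  set.seed(17)
  for (i in 1:200) {
    on <- sample(reg$category, sample(0:17, 1))
    f <- flag_vector("charlson", on)
    expect_equal(charlson_index(f, "original"),
                 sum(reg$weight_original[reg$category %in% on]))
    expect_equal(charlson_index(f, "quan"),
                 sum(reg$weight_quan[reg$category %in% on]))
  }
})

test_that("elixhauser profile is an ordered binary vector with popcount", {
  f <- flag_vector("elixhauser")
  expect_equal(elixhauser_profile(f)$count, 0)
  expect_equal(sum(elixhauser_profile(f)$vector), 0)
  f[] <- TRUE
  expect_equal(elixhauser_profile(f)$count, 31)
  # count invariant under reordering of the input names
  g <- flag_vector("elixhauser", c("chf", "obesity", "depression"))
  shuffled <- g[sample(names(g))]
  expect_equal(elixhauser_profile(shuffled)$count, 3)
  expect_equal(names(elixhauser_profile(shuffled)$vector),
               category_registry("elixhauser")$category)
})

test_that("engine recovers the generator's latent flags exactly", {
  coh <- small_cohort(n_cases = 250, seed = 77)
  pr <- comorbidity_profiles(coh, window = "complete_record",
                             hierarchy = FALSE)
  for (measure in c("charlson", "elixhauser")) {
    truth <- coh$flags[, grep(paste0("^", measure, ":"),
                              colnames(coh$flags))]
    colnames(truth) <- sub(".*:", "", colnames(truth))
    got <- profile_flags(pr, measure)[rownames(truth), colnames(truth)]
    expect_identical(unname(got), unname(truth))
  }
})

test_that("count distribution bins as the descriptive table does", {
  coh <- small_cohort(n_cases = 120, seed = 13)
  pr <- comorbidity_profiles(coh)
  tab <- count_distribution(pr, coh, "elixhauser")
  expect_equal(rownames(tab), c("0", "1", "2", "3", "4", "5", ">6"))
  expect_equal(unname(colSums(tab)), c(1, 1), tolerance = 1e-12)
  # counts of exactly 6 land in the terminal bin by default
  pr6 <- pr[1, ]
  pr6$em_count <- 6L
  pats <- coh$patients[coh$patients$patient_id == pr6$patient_id, ]
  attr(pr6, "window") <- attr(pr, "window")
  tab6 <- count_distribution(pr6, pats, "elixhauser")
  expect_equal(unname(tab6[">6", 1]), 1)
  # all-zero cohort: everything in bin 0
  pr0 <- pr
  pr0$em_count <- 0L
  tab0 <- count_distribution(pr0, coh, "elixhauser")
  expect_equal(unname(tab0["0", ]), c(1, 1))
  expect_error(count_distribution(pr[0, ], coh, "charlson"), "empty")
})

test_that("scoring is deterministic", {
  coh <- small_cohort(n_cases = 60, seed = 5)
  a <- comorbidity_profiles(coh, window = "five_year")
  b <- comorbidity_profiles(coh, window = "five_year")
  expect_identical(a, b)
})
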