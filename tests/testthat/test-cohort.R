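test_that("generator config validates its inputs", {
  expect_error(generator_config(female_fraction = 1.2), "probability")
  expect_error(generator_config(control_ratio = 0))
  expect_error(generator_config(recent_fraction = -0.1), "probability")
  expect_error(generator_config(
    prevalence_charlson = stats::setNames(rep(0.1, 3), c("mi", "chf", "pvd"))),
    "named over all 17")
  cfg <- generator_config()
  expect_true(all(unlist(cfg$prevalence) >= 0 & unlist(cfg$prevalence) <= 1))
})

test_that("zero cases give an empty cohort", {
  coh <- simulate_cohort(generator_config(n_cases = 0), seed = 1)
  expect_equal(nrow(coh$patients), 0)
  expect_equal(nrow(coh$events), 0)
})

test_that("case demographics hit the configured calibration targets", {
  cases <- generate_cases(generator_config(n_cases = 10000), seed = 3)
  expect_lt(abs(mean(cases$sex) - 0.751), 0.02)
  expect_lt(abs(stats::median(cases$age_at_index) - 82), 1)
  iqr <- stats::quantile(cases$age_at_index, c(0.25, 0.75))
  expect_lt(abs(iqr[[1]] - 75), 2)
  expect_lt(abs(iqr[[2]] - 87), 2)
})

test_that("constructive record invariants hold for every patient", {
  set.seed(99)
  for (rep in 1:3) {
    cfg <- generator_config(
      n_cases = 150,
      control_ratio = sample(1:3, 1),
      female_fraction = runif(1, 0.4, 0.9),
      events_per_flag = runif(1, 1, 4))
    coh <- simulate_cohort(cfg, seed = sample.int(10000, 1))
    p <- coh$patients
    expect_true(all(p$registration_start < p$registration_end))
    # >= 3 years up-to-standard registration before index
    expect_true(all(as.numeric(p$index_date - p$registration_start) >=
                      3 * 365))
    cases <- p[p$role == "case", ]
    expect_true(all(cases$index_date >= as.Date("1999-01-01") &
                      cases$index_date <= as.Date("2013-10-09")))
    expect_true(all(is.na(p$death_date) | p$death_date >= p$index_date))
    expect_equal(p$year_of_birth,
                 as.integer(format(p$index_date, "%Y")) - p$age_at_index)
    # events live inside the registration window and before death
    ev <- merge(coh$events, p, by = "patient_id")
    expect_true(all(ev$event_date >= ev$registration_start))
    expect_true(all(ev$event_date < ev$index_date))
    expect_true(all(is.na(ev$death_date) | ev$event_date <= ev$death_date))
  }
})

test_that("controls are an exact ratio-fold copy of the case strata", {
  cfg <- generator_config(n_cases = 100)
  cases <- generate_cases(cfg, seed = 5)
  controls <- match_controls(cases, cfg, seed = 5)
  expect_equal(nrow(controls), 200)
  expect_true(all(!is.na(controls$matched_case_id)))
  m <- match(controls$matched_case_id, cases$patient_id)
  expect_equal(controls$sex, cases$sex[m])
  expect_equal(controls$age_at_index, cases$age_at_index[m])
  expect_equal(controls$index_date, cases$index_date[m])
  # multiset identity: (sex, age) of controls = 2 copies of cases'
  key <- function(d) sort(paste(d$sex, d$age_at_index))
  expect_equal(key(controls), rep(key(cases), each = 2))
  # ratio 1 gives equal counts
  cfg1 <- generator_config(n_cases = 50, control_ratio = 1)
  expect_equal(nrow(match_controls(generate_cases(cfg1, 1), cfg1, 1)), 50)
})

test_that("latent flag frequencies match configured prevalences", {
  p0 <- stats::setNames(rep(0, 17), category_registry("charlson")$category)
  pe <- stats::setNames(rep(0, 31), category_registry("elixhauser")$category)
  p0["pvd"] <- 0.3
  cfg <- generator_config(n_cases = 10000, control_ratio = 1,
                          prevalence_charlson = p0,
                          prevalence_elixhauser = pe)
  cases <- generate_cases(cfg, seed = 8)
  gen <- generate_comorbidity_events(cases, synthetic_codelists(), cfg,
                                     seed = 8)
  freq <- mean(gen$flags[, "charlson:pvd"])
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))  # 3-sigma binomial
  expect_equal(sum(gen$flags[, colnames(gen$flags) != "charlson:pvd"]), 0)
  # every event's code maps back to the flagged category
  cats <- lookup(synthetic_codelists()$charlson, unique(gen$events$code))
  expect_true(all(unlist(cats) == "pvd"))
})

test_that("zero prevalence means no events; empty category list errors", {
  p0 <- stats::setNames(rep(0, 17), category_registry("charlson")$category)
  pe <- stats::setNames(rep(0, 31), category_registry("elixhauser")$category)
  cfg <- generator_config(n_cases = 20, prevalence_charlson = p0,
                          prevalence_elixhauser = pe)
  coh <- simulate_cohort(cfg, seed = 2)
  expect_equal(nrow(coh$events), 0)
  # nonzero prevalence on a category with no codes must error
  p0["hiv"] <- 0.5
  cfg2 <- generator_config(n_cases = 20, prevalence_charlson = p0,
                           prevalence_elixhauser = pe)
  cl <- synthetic_codelists()
  cl$charlson$entries <- cl$charlson$entries[
    cl$charlson$entries$category != "hiv", ]
  cases <- generate_cases(cfg2, seed = 2)
  expect_error(generate_comorbidity_events(cases, cl, cfg2, seed = 2),
               "empty code list")
})

test_that("mortality respects degenerate and calibrated configurations", {
  # impossible death
  cfg0 <- generator_config(n_cases = 200, intercept_30d = -Inf,
                           intercept_365d = -Inf)
  coh0 <- simulate_cohort(cfg0, seed = 4)
  expect_true(all(is.na(coh0$patients$death_date)))
  # certain 30-day death
  cfg1 <- generator_config(n_cases = 200, intercept_30d = Inf)
  coh1 <- simulate_cohort(cfg1, seed = 4)
  days <- as.numeric(coh1$patients$death_date - coh1$patients$index_date)
  expect_true(all(!is.na(days) & days >= 0 & days <= 30))
})

test_that("empirical 30-day death rate matches the analytic model mean", {
  cfg <- generator_config(n_cases = 25000, control_ratio = 1)
  coh <- simulate_cohort(cfg, seed = 12)
  lp <- attr(coh$patients, "linear_predictors")$lp_30d
  p_mean <- mean(stats::plogis(lp))
  days <- as.numeric(coh$patients$death_date - coh$patients$index_date)
  rate <- mean(!is.na(days) & days <= 30)
  n <- nrow(coh$patients)
  expect_lt(abs(rate - p_mean), 3 * sqrt(p_mean * (1 - p_mean) / n))
})

test_that("same seed reproduces the cohort bit-identically, new seeds differ", {
  cfg <- generator_config(n_cases = 100)
  a <- simulate_cohort(cfg, seed = 21)
  b <- simulate_cohort(cfg, seed = 21)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  expect_identical(a$flags, b$flags)
  c <- simulate_cohort(cfg, seed = 22)
  expect_false(identical(a$events, c$events))
})

test_that("cohort tables round-trip through CSV losslessly", {
  coh <- small_cohort(n_cases = 40)
  dir <- tempfile()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  p <- coh$patients
  attr(p, "linear_predictors") <- NULL
  expect_equal(back$patients, p)
  expect_equal(back$events, coh$events)
  expect_equal(back$flags, coh$flags)
  # death_date must be an empty field, not a sentinel
  raw <- utils::read.csv(file.path(dir, "patients.csv"),
                         colClasses = "character")
  expect_true(any(raw$death_date == ""))
  # malformed dates are reported with their location
  raw$death_date[3] <- "13/01/2001"
  utils::write.csv(raw, file.path(dir, "patients.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "patients.csv.*death_date.*row 3")
  # empty cohort round-trips too
  coh0 <- simulate_cohort(generator_config(n_cases = 0), seed = 1)
  dir0 <- tempfile()
  write_cohort(coh0, dir0)
  expect_equal(nrow(read_cohort(dir0)$patients), 0)
})
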