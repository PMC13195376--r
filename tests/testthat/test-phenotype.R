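empty_cond <- tibble::tibble(
  identity_hash = character(), condition = character(),
  condition_date = as.Date(character())
)
empty_bp <- tibble::tibble(
  identity_hash = character(), measurement_date = as.Date(character()),
  sbp = numeric(), dbp = numeric(), outpatient = logical()
)
empty_a1c <- tibble::tibble(
  identity_hash = character(), measurement_date = as.Date(character()),
  a1c = numeric()
)

bp_row <- function(date, sbp = NA, dbp = NA, outpatient = TRUE) {
  tibble::tibble(
    identity_hash = "h1", measurement_date = as.Date(date),
    sbp = as.numeric(sbp), dbp = as.numeric(dbp), outpatient = outpatient
  )
}
dx_row <- function(condition, date) {
  tibble::tibble(
    identity_hash = "h1", condition = condition, condition_date = as.Date(date)
  )
}
a1c_row <- function(date, value) {
  tibble::tibble(
    identity_hash = "h1", measurement_date = as.Date(date), a1c = value
  )
}
htn <- function(conds, bp, year = 2020) {
  nrow(flag_hypertension(conds, bp, year)) == 1
}
dm <- function(conds, a1c, year = 2022) {
  nrow(flag_diabetes(conds, a1c, year)) == 1
}

test_that("hypertension phenotype: code disjunct and distinct-day BP rule", {
  # one dx code, no BP rows -> positive
  expect_true(htn(dx_row("hypertension", "2018-03-01"), empty_bp))
  # a diabetes code never triggers hypertension
  expect_false(htn(dx_row("diabetes", "2019-03-01"), empty_bp))
  # SBP 145 twice on the same date: only one distinct day -> negative
  expect_false(htn(
    empty_cond,
    dplyr::bind_rows(bp_row("2020-05-01", 145), bp_row("2020-05-01", 150))
  ))
  # two distinct days -> positive
  expect_true(htn(
    empty_cond,
    dplyr::bind_rows(bp_row("2020-05-01", 145), bp_row("2020-06-01", 141))
  ))
  # DBP exactly 90 on two dates, but one inpatient -> only one outpatient day
  expect_false(htn(
    empty_cond,
    dplyr::bind_rows(
      bp_row("2020-05-01", dbp = 90),
      bp_row("2020-06-01", dbp = 90, outpatient = FALSE)
    )
  ))
  # the same two days, both outpatient: inclusive threshold qualifies
  expect_true(htn(
    empty_cond,
    dplyr::bind_rows(
      bp_row("2020-05-01", dbp = 90), bp_row("2020-06-01", dbp = 90)
    )
  ))
  # missing components are non-qualifying, not errors
  expect_false(htn(
    empty_cond,
    dplyr::bind_rows(bp_row("2020-05-01"), bp_row("2020-06-01"))
  ))
})

test_that("lookbacks are whole calendar years ending December 31", {
  # hypertension dx window for 2020 is 2016-2020
  expect_true(htn(dx_row("hypertension", "2016-01-01"), empty_bp))
  expect_false(htn(dx_row("hypertension", "2015-12-31"), empty_bp))
  # BP window for 2020 is 2018-2020
  expect_false(htn(
    empty_cond,
    dplyr::bind_rows(bp_row("2017-12-31", 160), bp_row("2020-06-01", 160))
  ))
  # diabetes in 2022: codes 2018-2022, labs 2020-2022
  expect_true(dm(dx_row("diabetes", "2018-01-01"), empty_a1c))
  expect_false(dm(dx_row("diabetes", "2017-12-31"), empty_a1c))
  expect_true(dm(empty_cond, a1c_row("2020-01-01", 7.2)))
  expect_false(dm(empty_cond, a1c_row("2019-12-31", 7.2)))
})

test_that("diabetes phenotype: inclusive HbA1c threshold, single result suffices", {
  expect_true(dm(empty_cond, a1c_row("2022-02-01", 6.5)))
  expect_false(dm(empty_cond, a1c_row("2022-02-01", 6.49)))
  expect_false(dm(empty_cond, a1c_row("2022-02-01", NA)))
})

test_that("eligibility: inclusive age boundary, 3-calendar-year encounters, all-ages option", {
  assigned <- tibble::tibble(
    identity_hash = "h1", assigned_system = "A", n_encounter_days = 1L,
    birth_date = as.Date("2002-12-31"), # turns 18 on Dec 31, 2020
    sex = "female", race_ethnicity = "white",
    tract_id = "T0001", zip_code = "55001"
  )
  enc <- tibble::tibble(
    identity_hash = "h1", system_id = "A",
    encounter_date = as.Date("2018-01-01")
  )
  e <- apply_eligibility(assigned, enc, 2020, min_age = 18)
  expect_true(e$eligible)

  # encounter only in index_year - 3 -> outside window
  enc_old <- dplyr::mutate(enc, encounter_date = as.Date("2017-12-31"))
  expect_false(apply_eligibility(assigned, enc_old, 2020, 18)$eligible)

  # all-ages rule keeps a 5-year-old
  young <- dplyr::mutate(assigned, birth_date = as.Date("2015-06-01"))
  expect_false(apply_eligibility(young, enc, 2020, min_age = 18)$eligible)
  expect_true(apply_eligibility(young, enc, 2020, min_age = NULL)$eligible)

  # encounter at a non-assigned system does not count
  enc_b <- dplyr::mutate(enc, system_id = "B")
  expect_false(apply_eligibility(assigned, enc_b, 2020, 18)$eligible)
})

test_that("deaths and missing birth dates exclude with logged reasons", {
  assigned <- tibble::tibble(
    identity_hash = c("h1", "h2"), assigned_system = "A",
    n_encounter_days = 1L,
    birth_date = as.Date(c("1950-01-01", NA)),
    death_date = as.Date(c("2020-12-31", NA)),
    sex = "female", race_ethnicity = "white",
    tract_id = "T0001", zip_code = "55001"
  )
  enc <- tibble::tibble(
    identity_hash = c("h1", "h2"), system_id = "A",
    encounter_date = as.Date("2020-01-01")
  )
  expect_message(
    e <- apply_eligibility(assigned, enc, 2020, min_age = 18),
    "missing birth date"
  )
  expect_equal(e$eligible, c(FALSE, FALSE))
  expect_equal(e$exclusion_reason, c("deceased", "missing_birth_date"))
  # dying after Dec 31 of the index year does not exclude
  assigned$death_date[1] <- as.Date("2021-01-01")
  expect_message(e2 <- apply_eligibility(assigned, enc, 2020, 18))
  expect_true(e2$eligible[1])
})

test_that("phenotypes match a brute-force oracle on random short histories", {
  withr::with_seed(99, {
    for (i in 1:250) {
      h <- random_history(2020)
      expect_equal(
        htn(h$conditions, h$bp, 2020),
        oracle_hypertension(h$conditions, h$bp, 2020),
        info = paste("history", i)
      )
      expect_equal(
        dm(h$conditions, h$a1c, 2020),
        oracle_diabetes(h$conditions, h$a1c, 2020),
        info = paste("history", i)
      )
    }
  })
})

test_that("adding events never unsets a phenotype; removing never sets one", {
  withr::with_seed(123, {
    for (i in 1:40) {
      h <- random_history(2020)
      base_htn <- htn(h$conditions, h$bp, 2020)
      base_dm <- dm(h$conditions, h$a1c, 2020)
      extra <- random_history(2020)
      expect_true(
        htn(
          dplyr::bind_rows(h$conditions, extra$conditions),
          dplyr::bind_rows(h$bp, extra$bp), 2020
        ) >= base_htn
      )
      expect_true(
        dm(
          dplyr::bind_rows(h$conditions, extra$conditions),
          dplyr::bind_rows(h$a1c, extra$a1c), 2020
        ) >= base_dm
      )
      # random subsets of the history
      sub_bp <- h$bp[sample(nrow(h$bp), floor(nrow(h$bp) / 2)), ]
      sub_cond <- h$conditions[
        sample(nrow(h$conditions), floor(nrow(h$conditions) / 2)),
      ]
      expect_true(htn(sub_cond, sub_bp, 2020) <= base_htn)
    }
  })
})
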