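test_that("read/write round-trips a valid dataset field-for-field", {
  ds <- simulate_dataset(sim_config(n_individuals = 12, seed = 7,
                                    n_sibling_pairs = 3))
  bp <- tempfile(fileext = ".csv")
  ip <- tempfile(fileext = ".csv")
  write_dataset(ds, bp, ip)
  ds2 <- read_dataset(bp, ip)
  expect_equal(ds2$bouts, ds$bouts)
  expect_equal(ds2$individuals, ds$individuals)

  # optional fields are written as empty cells, not "NA" literals
  raw <- readLines(bp)
  expect_false(any(grepl(",NA,|,NA$", raw)))

  # round-trip applies to the fixture too, preserving category counts
  fx <- table1_fixture()
  write_dataset(fx, bp, ip)
  fx2 <- read_dataset(bp, ip)
  expect_equal(table(fx2$bouts$category), table(fx$bouts$category))
  expect_equal(fx2$individuals, fx$individuals)
})

test_that("an empty bout table with a valid header is a valid dataset", {
  ds <- simulate_dataset(sim_config(n_individuals = 5, seed = 1,
                                    n_sibling_pairs = 0))
  bp <- tempfile(fileext = ".csv"); ip <- tempfile(fileext = ".csv")
  write_dataset(ds, bp, ip)
  writeLines(readLines(bp)[1], bp)   # header only
  ds2 <- read_dataset(bp, ip)
  expect_equal(nrow(ds2$bouts), 0)
  expect_equal(ds2$individuals, ds$individuals)
})

test_that("validation rejects schema, integrity, coding and domain violations", {
  bouts <- toy_bout("b1", "A", 2.0)
  inds <- toy_individual("A")

  # missing column named in the error
  expect_error(explor_dataset(bouts[, -3], inds), "age_at_bout",
               class = "explor_schema_error")
  # unknown individual cited with its row
  b2 <- toy_bout("b2", "ZZ", 1.0)
  expect_error(explor_dataset(rbind(bouts, b2), inds), "ZZ",
               class = "explor_integrity_error")
  expect_error(explor_dataset(rbind(bouts, b2), inds), "row")
  # atypical bout lacking its mode
  b3 <- toy_bout("b3", "A", 1.0, typicality = "atypical")
  expect_error(explor_dataset(rbind(bouts, b3), inds),
               class = "explor_coding_error")
  # typical bout carrying a mode is equally miscoded
  b4 <- toy_bout("b4", "A", 1.0, atypical_mode = "commission")
  expect_error(explor_dataset(rbind(bouts, b4), inds),
               class = "explor_coding_error")
  # the seven-category ethogram is closed
  b5 <- toy_bout("b5", "A", 1.0, category = "grooming")
  expect_error(explor_dataset(rbind(bouts, b5), inds),
               class = "explor_schema_error")
  # nonpositive observation hours
  expect_error(explor_dataset(bouts, toy_individual("A", observation_hours = 0)),
               class = "explor_domain_error")
  # duplicate bout ids
  expect_error(explor_dataset(rbind(bouts, bouts), inds),
               class = "explor_integrity_error")
  # enums are parsed case-insensitively rather than rejected
  b6 <- toy_bout("b6", "A", 1.0, typicality = "Atypical",
                 atypical_mode = "Commission")
  ds <- explor_dataset(rbind(bouts, b6), inds)
  expect_equal(ds$bouts$typicality, c("typical", "atypical"))
})

test_that("the fixture reproduces the published accounting and is deterministic", {
  ds <- table1_fixture()
  expect_equal(nrow(ds$bouts), 67)
  expect_equal(nrow(ds$individuals), 36)

  cnt <- table(ds$bouts$category)
  expect_equal(cnt[["tool"]], 28)
  expect_equal(cnt[["doll"]], 2)
  expect_equal(cnt[["aggression"]], 7)
  expect_equal(cnt[["game"]], 11)
  expect_equal(cnt[["locomotion_aid"]], 2)
  expect_equal(cnt[["physical_stimulation"]], 8)
  expect_equal(cnt[["play_nest"]], 9)

  sub <- table(ds$bouts$subcategory)
  expect_equal(sub[["leaf_clipping"]], 1)
  expect_equal(sub[["leaf_grooming"]], 8)
  expect_equal(sub[["leaf_napkin"]], 1)
  expect_equal(sub[["sponge"]], 12)
  expect_equal(sub[["stick_honey"]], 2)
  expect_equal(sub[["stick_insect"]], 2)
  expect_equal(sub[["stick_water"]], 2)
  # subcategory totals partition their categories
  expect_equal(sum(sub[c("leaf_clipping", "leaf_grooming", "leaf_napkin",
                         "sponge", "stick_honey", "stick_insect",
                         "stick_water")]), 28)
  expect_equal(sum(sub[c("branch_shake", "stick_throw")]), 7)
  expect_equal(sum(sub[c("scratch_body", "masturbate")]), 8)

  expect_equal(sum(ds$bouts$typicality == "typical"), 34)
  expect_equal(sum(ds$bouts$typicality == "atypical"), 33)
  expect_equal(sum(ds$bouts$atypical_mode == "omission", na.rm = TRUE), 2)
  expect_equal(sum(ds$bouts$atypical_mode == "commission", na.rm = TRUE), 31)

  per_ind <- table(ds$bouts$individual_id)
  expect_true(all(per_ind >= 1 & per_ind <= 5))
  expect_equal(length(per_ind), 36)

  # observation effort honors the published total and range
  expect_equal(sum(ds$individuals$observation_hours), 569.58)
  expect_equal(range(ds$individuals$observation_hours), c(2.72, 37.24))
  # seven maternal sibling pairs
  expect_equal(sum(table(ds$individuals$maternal_id) == 2), 7)

  expect_identical(table1_fixture(), ds)
})
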