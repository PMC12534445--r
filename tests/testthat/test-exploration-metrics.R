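test_that("z_transform standardizes to mean 0, sample SD 1, with degenerate conventions", {
  expect_equal(z_transform(c(0, 2)), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(z_transform(c(5, 5, 5, 5)), rep(0, 4))
  expect_error(z_transform(3), class = "explor_domain_error")
  for (seed in 1:5) {
    set.seed(seed)
    z <- z_transform(rnorm(36, 10, 3))
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  }
  # population-SD variant scales by sqrt((n-1)/n)
  x <- c(1, 4, 9, 2)
  expect_equal(z_transform(x, "population"),
               (x - mean(x)) / (sd(x) * sqrt(3 / 4)))
})

test_that("compute_metrics derives the five metrics per individual", {
  ds <- explor_dataset(toy_bout("b1", "A", 2.4), toy_individual("A"))
  # 1 bout, 1 category, no atypical use, 1/10 bouts per hour, 1 age point
  prof <- compute_metrics(ds)
  expect_equal(prof$total_bouts, 1L)
  expect_equal(prof$category_diversity, 1L)
  expect_equal(prof$atypical_proportion, 0)
  expect_equal(prof$bout_rate, 0.1)
  expect_equal(prof$age_diversity, 1L)
  expect_equal(prof$central_age, 2.4)

  # age diversity counts distinct integer age points (floor of decimal age)
  b <- rbind(toy_bout("b1", "A", 1.2), toy_bout("b2", "A", 1.9),
             toy_bout("b3", "A", 3.0))
  prof <- compute_metrics(explor_dataset(b, toy_individual("A")))
  expect_equal(prof$age_diversity, 2L)
})

test_that("fixture metrics match an independent brute-force recount", {
  ds <- table1_fixture()
  prof <- compute_metrics(ds)
  expect_equal(round(mean(prof$total_bouts), 2), 1.86)
  expect_equal(round(sd(prof$total_bouts), 2), 1.13)
  for (i in seq_len(nrow(prof))) {
    id <- prof$individual_id[i]
    rows <- ds$bouts[ds$bouts$individual_id == id, ]
    hrs <- ds$individuals$observation_hours[
      ds$individuals$individual_id == id]
    expect_equal(prof$total_bouts[i], nrow(rows))
    expect_equal(prof$category_diversity[i], length(unique(rows$category)))
    expect_equal(prof$atypical_proportion[i],
                 sum(rows$typicality == "atypical") / nrow(rows))
    expect_equal(prof$bout_rate[i], nrow(rows) / hrs)
    expect_equal(prof$age_diversity[i],
                 length(unique(floor(rows$age_at_bout))))
  }
})

test_that("Exploration Indexes sum to zero and equal a from-scratch recomputation", {
  ds <- simulate_dataset(sim_config(seed = 11))
  prof <- exploration_profiles(ds)
  expect_lt(abs(sum(prof$exploration_index)), 1e-9)
  expect_equal(prof$exploration_index,
               rowSums(prof[, paste0("z_", c("total_bouts",
                                             "category_diversity",
                                             "atypical_proportion",
                                             "bout_rate", "age_diversity"))]),
               tolerance = 1e-12)
  # independent recomputation from the raw metrics
  zs <- function(x) (x - mean(x)) / sd(x)
  manual <- zs(prof$total_bouts) + zs(prof$category_diversity) +
    zs(prof$atypical_proportion) + zs(prof$bout_rate) + zs(prof$age_diversity)
  expect_equal(prof$exploration_index, manual, tolerance = 1e-12)

  # two identical individuals: all z-scores, hence both indexes, are 0
  b <- rbind(toy_bout("b1", "A", 2.0), toy_bout("b2", "B", 2.0))
  ii <- rbind(toy_individual("A"), toy_individual("B"))
  expect_equal(exploration_profiles(explor_dataset(b, ii))$exploration_index,
               c(0, 0))
})

test_that("the index is invariant to affine rescaling of a raw metric", {
  ds <- simulate_dataset(sim_config(seed = 4))
  prof1 <- exploration_profiles(ds)
  ds$individuals$observation_hours <- ds$individuals$observation_hours * 60
  prof2 <- exploration_profiles(ds)   # hours in minutes
  expect_equal(prof2$exploration_index, prof1$exploration_index,
               tolerance = 1e-9)
})

test_that("permuting individual order permutes outputs identically", {
  ds <- simulate_dataset(sim_config(n_individuals = 15, seed = 9,
                                    n_sibling_pairs = 4))
  prof1 <- exploration_profiles(ds)
  set.seed(1)
  ds2 <- ds
  ds2$bouts <- ds2$bouts[sample(nrow(ds2$bouts)), ]
  ds2$individuals <- ds2$individuals[sample(nrow(ds2$individuals)), ]
  prof2 <- exploration_profiles(explor_dataset(ds2$bouts, ds2$individuals))
  m <- match(prof1$individual_id, prof2$individual_id)
  expect_equal(prof2$exploration_index[m], prof1$exploration_index,
               tolerance = 1e-12)
})

test_that("the metric4 switch swaps bout rate for raw observation hours", {
  ds <- simulate_dataset(sim_config(n_individuals = 10, seed = 2,
                                    n_sibling_pairs = 0))
  prof <- exploration_index(compute_metrics(ds), metric4 = "hours")
  zs <- function(x) (x - mean(x)) / sd(x)
  expect_equal(prof$z_observation_hours, zs(prof$observation_hours),
               tolerance = 1e-12)
  expect_false("z_bout_rate" %in% names(prof))
})
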