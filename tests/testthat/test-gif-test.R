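# end-to-end behaviour of the resampling tests on simulated cohorts

sim_cohort <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  assign_phenotypes(simulate_genealogy(cfg), cfg)
}

test_that("gif_test is bitwise reproducible for fixed inputs and seed", {
  g <- sim_cohort(301)
  pool <- eligible_pool(g, sex = "male")
  set.seed(1); cases <- sample(pool, 10)
  a <- gif_test(g, cases, pool, R = 1, seed = 5)
  b <- gif_test(g, cases, pool, R = 1, seed = 5)
  a$call <- b$call <- NULL
  expect_identical(a, b)
  r <- gif_test(g, cases, pool, R = 25, seed = 5)
  s <- gif_test(g, cases, pool, R = 25, seed = 5)
  expect_identical(r$control_gifs, s$control_gifs)
  expect_identical(r$by_distance, s$by_distance)
})

test_that("the result object is internally consistent", {
  g <- sim_cohort(302)
  pool <- eligible_pool(g, sex = "male")
  set.seed(2); cases <- sample(pool, 12)
  r <- gif_test(g, cases, pool, R = 30, seed = 9)
  expect_s3_class(r, "gif_test")
  expect_equal(r$n_cases, 12)
  expect_length(r$control_gifs, 30)
  expect_equal(r$mean_control_gif, mean(r$control_gifs))
  expect_equal(r$p, sum(r$control_gifs >= r$case_gif) / 30)
  # decomposition conserves the totals for cases and mean controls
  expect_equal(sum(r$by_distance$case), r$case_gif,
               tolerance = 1e-9 * max(1, r$case_gif))
  expect_equal(sum(r$by_distance$control), r$mean_control_gif,
               tolerance = 1e-9 * max(1, r$mean_control_gif))
  expect_output(print(r), "GIF test")
})

test_that("subset GIF leaves the subset's own statistic unchanged", {
  g <- sim_cohort(303)
  pool <- eligible_pool(g, sex = "male")
  cases <- case_ids(g, within = pool)
  expect_gte(length(cases), 8)
  sub <- cases[seq_len(4)]
  r_pop <- gif_test(g, sub, pool, R = 10, seed = 3, by_distance = FALSE)
  r_sub <- subset_gif_test(g, sub, cases, R = 10, seed = 3,
                           by_distance = FALSE)
  expect_identical(r_pop$case_gif, r_sub$case_gif)
  expect_identical(r_sub$test, "subset")
})

test_that("a subset must be contained in the case cohort", {
  g <- sim_cohort(304)
  pool <- eligible_pool(g, sex = "male")
  cases <- case_ids(g, within = pool)
  expect_error(subset_gif_test(g, c(cases[1], "I1"), cases[-1], R = 2,
                               seed = 1), "contained in the case cohort")
})

test_that("case controls are more related than population controls on clustered cohorts", {
  # carriers cluster in pedigrees, so random draws of cases are on average
  # more related than random matched draws from the population; asserted on
  # the mean across cohorts because any single small cohort is noisy
  sub_means <- pop_means <- numeric()
  for (seed in 311:320) {
    g <- sim_cohort(seed, n_founder_couples = 40,
                    variant_founder_freq = 0.02,
                    penetrance_carrier = 0.9)
    pool <- eligible_pool(g, sex = "male")
    cases <- case_ids(g, within = pool)
    if (length(cases) < 10) next
    sub <- cases[seq_len(5)]
    r_pop <- gif_test(g, sub, pool, R = 40, seed = 7, by_distance = FALSE)
    r_sub <- subset_gif_test(g, sub, cases, R = 40, seed = 7,
                             by_distance = FALSE)
    pop_means <- c(pop_means, r_pop$mean_control_gif)
    sub_means <- c(sub_means, r_sub$mean_control_gif)
  }
  expect_gte(length(sub_means), 3)
  expect_gt(mean(sub_means), mean(pop_means))
})

test_that("degenerate subset equal to all cases behaves like a permutation draw", {
  g <- sim_cohort(309)
  pool <- eligible_pool(g, sex = "male")
  cases <- case_ids(g, within = pool)
  expect_gte(length(cases), 5)
  ps <- vapply(1:12, function(s)
    subset_gif_test(g, cases, cases, R = 20, seed = s,
                    by_distance = FALSE)$p, 0)
  # every control set is the case set itself up to permutation: p = 1 always
  expect_true(all(ps == 1))
})

test_that("fewer than two cases is a domain error", {
  g <- sim_cohort(306)
  pool <- eligible_pool(g, sex = "male")
  expect_error(gif_test(g, pool[1], pool, R = 2, seed = 1), "at least 2")
  expect_error(gif_test(g, pool[1:2], pool, R = 0, seed = 1), "at least 1")
})
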