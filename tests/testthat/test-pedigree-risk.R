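rate_cohort <- function() {
  n <- 120
  ids <- paste0("r", seq_len(n))
  ped <- data.frame(id = ids, father = "0", mother = "0",
                    sex = rep(c(1, 2), length.out = n))
  attrs <- data.frame(id = ids,
                      birth_year = rep(c(1900, 1900, 1920, 1920),
                                       length.out = n),
                      birth_in_state = TRUE)
  genealogy(ped, attrs)
}

test_that("stratum rates are case fractions and recover overall prevalence", {
  # 100 males of one cohort, 10 of them cases
  ids <- paste0("p", 1:100)
  g <- genealogy(data.frame(id = ids, father = "0", mother = "0", sex = 1),
                 data.frame(id = ids, birth_year = 1940))
  rt <- cohort_rates(g, ids[1:10], ids)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$rate, 0.10)

  g2 <- rate_cohort()
  pop <- g2$ind$id
  set.seed(4)
  cases <- sample(pop, 18)
  rt2 <- cohort_rates(g2, cases, pop)
  # a stratum with no cases carries rate zero
  expect_true(all(rt2$rate >= 0))
  # rates weighted by stratum size sum back to overall prevalence
  expect_equal(sum(rt2$rate * rt2$n) / sum(rt2$n), length(cases) / length(pop))
})

test_that("expected counts accumulate stratum rates over descendants", {
  # founder with 50 male descendants in a 0.10-rate stratum
  ids <- c("F0", "W0", paste0("d", 1:50), paste0("u", 1:50))
  ped <- data.frame(id = ids,
                    father = c("0", "0", rep("F0", 50), rep("0", 50)),
                    mother = c("0", "0", rep("W0", 50), rep("0", 50)),
                    sex = 1)
  ped$sex[2] <- 2
  attrs <- data.frame(id = ids, birth_year = c(1890, 1890, rep(1920, 100)))
  g <- genealogy(ped, attrs)
  eligible <- c(paste0("d", 1:50), paste0("u", 1:50))
  # make the male/1920 stratum rate exactly 0.10: 10 cases of 100
  rates <- cohort_rates(g, paste0("u", 1:10), eligible)
  ec <- expected_cases(g, "F0", rates, eligible)
  expect_setequal(ec$descendants, paste0("d", 1:50))
  expect_equal(ec$expected, 5.0)
  # childless founder
  ec0 <- expected_cases(g, "u1", rates, eligible)
  expect_identical(ec0$descendants, character(0))
  expect_equal(ec0$expected, 0)
})

test_that("excess probability is an exact upper Poisson tail", {
  expect_equal(excess_p(0, 5), 1.0)
  expect_equal(excess_p(3, 2), ppois(2, 2, lower.tail = FALSE))
  expect_error(excess_p(3, 0), "positive")
  expect_error(excess_p(2.5, 1), "integer")
  # strictly decreasing in observed, increasing in expected (excess regime)
  obs <- 40:60
  p_obs <- vapply(obs, excess_p, 0, expected = 36)
  expect_true(all(diff(p_obs) < 0))
  exps <- seq(30, 50, by = 2.5)
  p_exp <- vapply(exps, function(e) excess_p(56, e), 0)
  expect_true(all(diff(p_exp) > 0))
})

test_that("Poisson tail and continuity-corrected normal agree within an order of magnitude", {
  for (cs in list(c(56, 36), c(173, 131), c(76, 51.5), c(50, 30))) {
    p_pois <- excess_p(cs[1], cs[2])
    p_norm <- pnorm((cs[1] - 0.5 - cs[2]) / sqrt(cs[2]), lower.tail = FALSE)
    expect_lt(abs(log10(p_pois) - log10(p_norm)), 1)
  }
})

test_that("an enriched founder is ranked first by the excess test", {
  # two founder families: one with concentrated cases
  mk_fam <- function(tag, n_desc) {
    ids <- c(paste0(tag, "F"), paste0(tag, "M"), paste0(tag, "d", 1:n_desc))
    data.frame(id = ids,
               father = c("0", "0", rep(paste0(tag, "F"), n_desc)),
               mother = c("0", "0", rep(paste0(tag, "M"), n_desc)),
               sex = c(1, 2, rep(1, n_desc)))
  }
  ped <- rbind(mk_fam("a", 30), mk_fam("b", 30))
  attrs <- data.frame(id = ped$id, birth_year = 1930)
  g <- genealogy(ped, attrs)
  eligible <- ped$id[grepl("d", ped$id)]
  cases <- c(paste0("ad", 1:12), "bd1")      # 12 cases in family a, 1 in b
  res <- pedigree_excess_test(g, cases, eligible)
  expect_s3_class(res, "pedigree_risk")
  expect_identical(res$founder[1], "aF")
  arow <- res[res$founder == "aF", ]
  expect_equal(arow$observed, 12)
  expect_equal(arow$expected, 30 * 13 / 60)   # internal male/1930 rate
  expect_equal(arow$p, excess_p(12, 6.5))
  expect_true(all(res$observed <= res$n_descendants))
  expect_true(all(res$p > 0 & res$p <= 1))
})
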