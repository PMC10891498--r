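test_that("signed rank test matches exact enumeration and R's approximation", {
  # perfectly antisymmetric sample: statistic at its null mean
  expect_equal(wilcoxon_signed_rank(c(-3, -1, 1, 3))$p_value, 1)

  # fixed n = 8 vector against the 2^8 enumeration oracle
  d8 <- c(1.2, -0.4, 2.1, 3.3, -1.8, 0.9, 2.6, 1.1)
  expect_lt(
    abs(wilcoxon_signed_rank(d8)$p_value - exact_signed_rank_p(d8)), 0.1
  )

  # all-positive n = 20: exact p would be 2 * 2^-20
  expect_lt(wilcoxon_signed_rank(rnorm(20) + 10)$p_value, 0.001)

  # agreement with the independent normal-approximation implementation,
  # including ties, and with exact enumeration across random small samples
  set.seed(5)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.3, 1), 1)
    d <- d[d != 0]
    if (length(d) < 3) next
    ours <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = FALSE)
    )
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    # documented discreteness bound: 0.1 from n = 8, 0.2 down to n = 5
    expect_lt(
      abs(ours$p_value - exact_signed_rank_p(d)),
      if (length(d) >= 8) 0.1 else 0.2
    )
  }

  # all-zero differences warn and return 1
  expect_warning(res <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(res$p_value, 1)
})

test_that("mcnemar uses discordant pairs with an exact small-sample branch", {
  mk <- function(b, c, concordant = 5) {
    list(
      a = c(rep(TRUE, b), rep(FALSE, c), rep(TRUE, concordant)),
      b = c(rep(FALSE, b), rep(TRUE, c), rep(TRUE, concordant))
    )
  }
  # symmetric discordance: statistic 0, p = 1
  v <- mk(5, 5)
  res <- mcnemar(v$a, v$b)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # b = 10, c = 2: chi-squared 16/3, closed-form tail
  v <- mk(10, 2)
  res <- mcnemar(v$a, v$b)
  expect_equal(res$statistic, 64 / 12)
  expect_equal(res$p_value, pchisq(64 / 12, 1, lower.tail = FALSE))
  ref <- stats::mcnemar.test(table(v$a, v$b), correct = FALSE)
  expect_equal(res$p_value, ref$p.value)

  # one discordant pair: exact binomial, two-sided p = 1
  v <- mk(1, 0)
  res <- mcnemar(v$a, v$b)
  expect_equal(res$method, "exact_binomial")
  expect_equal(res$p_value, 1)

  # no discordance warns
  v <- mk(0, 0)
  expect_warning(res <- mcnemar(v$a, v$b), "discordant")
  expect_equal(res$p_value, 1)
})

test_that("spearman correlation is tie-aware rank-then-pearson", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  # 6-point fixture with one tie, frozen from hand ranking
  # (ranks of x: 1, 2.5, 2.5, 4, 5, 6)
  xt <- c(1, 2, 2, 3, 4, 5)
  yt <- c(2, 1, 3, 5, 4, 6)
  expect_equal(spearman_rho(xt, yt), 0.8406680017, tolerance = 1e-9)
  expect_equal(spearman_rho(xt, yt), cor(xt, yt, method = "spearman"))
  expect_warning(res <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res))
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("limits of agreement follow mean plus/minus 1.96 sample SD", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(
    unlist(tidy(ident)[c("mean_difference", "sd_difference", "loa_low", "loa_high")]),
    c(mean_difference = 0, sd_difference = 0, loa_low = 0, loa_high = 0)
  )
  ba <- bland_altman(c(0, 1, 2), c(1, 1, 1)) # differences -1, 0, 1
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 1)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))
  # translation equivariance
  set.seed(8)
  x <- rnorm(50, 100, 10)
  y <- rnorm(50, 100, 10)
  b0 <- bland_altman(x, y)
  b1 <- bland_altman(x + 7, y)
  expect_equal(b1$mean_difference, b0$mean_difference + 7)
  expect_equal(
    b1$loa_high - b1$loa_low, b0$loa_high - b0$loa_low
  )
  expect_error(bland_altman(1, 2), "2 pairs")
})

test_that("relevance flags combine significance with the >10% rule", {
  # published examples: fruit flagged low, cheese too small, vegetables n.s.
  expect_equal(
    relevance_flag(83, 130, 0.005),
    tibble::tibble(relevant = TRUE, direction = "method_a_lower")
  )
  expect_equal(relevance_flag(30, 31, 0.006)$relevant, FALSE)
  expect_equal(relevance_flag(117, 130, 0.13)$relevant, FALSE)
  # zero reference median is not evaluable
  expect_true(is.na(relevance_flag(5, 0, 0.001)$relevant))
  # boundary: p exactly .05 is not significant under the strict rule
  expect_equal(relevance_flag(0, 15, 0.05)$relevant, FALSE)
  expect_equal(relevance_flag(20, 15, 0.01)$direction, "method_a_higher")
})

test_that("median of correlations and SUS scoring behave as defined", {
  expect_equal(median_of_correlations(0.5), 0.5)
  expect_equal(median_of_correlations(c(0.2, NA, 0.8)), 0.5)
  expect_error(median_of_correlations(NA_real_), "no correlation")

  resp <- function(odd, even, id = "p1") {
    tibble::tibble(
      participant_id = id, item = 1:10,
      response = rep(c(odd, even), 5)
    )
  }
  expect_equal(sus_score(resp(5, 1))$by_person$sus_score, 100)
  expect_equal(sus_score(resp(3, 3))$by_person$sus_score, 50)
  expect_equal(sus_score(resp(1, 5))$by_person$sus_score, 0)
  # missing item excludes the participant from the total, not item means
  partial <- dplyr::bind_rows(resp(3, 3), resp(5, 1, "p2")[1:9, ])
  s <- sus_score(partial)
  expect_equal(s$by_person$participant_id, "p1")
  expect_equal(nrow(s$item_means), 10)
  expect_equal(s$n_scored, 1)
})

test_that("comparison tables filter, flag, and ignore participant order", {
  set.seed(19)
  n <- 40
  groups <- wheel_of_five_groups()
  daily_b <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n), day_index = 1L
  )
  for (g in groups) daily_b[[g]] <- 0
  daily_b$fruit <- rlnorm(n, log(150), 0.4)
  daily_b$bread <- rlnorm(n, log(130), 0.3)
  daily_b$sauces <- rbinom(n, 1, 0.6) * rlnorm(n, log(40), 0.5)
  daily_b$energy_kcal <- rnorm(n, 2000, 300)
  daily_a <- daily_b
  daily_a$fruit <- daily_a$fruit * 0.5 # large, consistent deficit
  daily_a$energy_kcal <- daily_a$energy_kcal + rnorm(n, 0, 50)

  cmp <- compare_tables(
    daily_a, daily_b,
    variables = c(groups, "energy_kcal")
  )
  # groups with zero 75th percentile under both methods are filtered out,
  # but stay in the consumer table
  expect_false("eggs" %in% cmp$paired$variable)
  expect_true("eggs" %in% cmp$consumers$variable)
  fruit <- cmp$paired[cmp$paired$variable == "fruit", ]
  expect_true(fruit$relevant_difference)
  expect_equal(fruit$direction, "method_a_lower")
  bread <- cmp$paired[cmp$paired$variable == "bread", ]
  expect_false(bread$relevant_difference)
  expect_equal(bread$spearman_rho, 1)

  # identical methods: p-values 1 (or missing), correlations 1, no flags
  same <- suppressWarnings(
    compare_tables(daily_b, daily_b, variables = c("fruit", "bread"))
  )
  expect_true(all(same$paired$wilcoxon_p == 1))
  expect_equal(same$paired$spearman_rho, rep(1, nrow(same$paired)))
  expect_false(any(same$paired$relevant_difference, na.rm = TRUE))

  # invariance to participant ordering
  shuffled <- daily_a[sample(n), ]
  cmp2 <- compare_tables(shuffled, daily_b, variables = c(groups, "energy_kcal"))
  expect_equal(cmp2$paired, cmp$paired)

  # consumer counts and the mcnemar discordance direction
  omit <- daily_a
  omit$sauces[omit$sauces > 0][1:5] <- 0
  cc <- compare_tables(omit, daily_b)$consumers
  sr <- cc[cc$variable == "sauces", ]
  expect_equal(sr$consumers_b - sr$consumers_a, 5)
  expect_true(sr$consumers_a <= n && sr$consumers_b <= n)
})

test_that("stratified comparisons suppress tiny strata with a warning", {
  set.seed(23)
  n <- 30
  roster <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    gender = "woman", age_years = 30L, height_m = 1.7,
    weight_kg = c(rep(60, 29), 95), # one obese participant -> tiny stratum
    education = rep(c("low", "middle", "high"), each = 10)
  )
  daily_b <- tibble::tibble(
    participant_id = roster$participant_id, day_index = 1L,
    fruit = rlnorm(n, log(150), 0.4)
  )
  daily_a <- daily_b
  daily_a$fruit <- daily_a$fruit * exp(rnorm(n, 0, 0.1))
  expect_warning(
    cmp <- compare_tables(
      daily_a, daily_b,
      variables = "fruit", roster = roster, strata = c("education", "bmi")
    ),
    "n < 2"
  )
  expect_true(all(
    paste0("education:", c("low", "middle", "high")) %in% names(cmp$strata)
  ))
  expect_false("bmi:30_plus" %in% names(cmp$strata))
  expect_equal(cmp$strata[["education:low"]]$n, 10)
})
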