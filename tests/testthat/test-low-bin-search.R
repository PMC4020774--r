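test_that("build_histogram assigns every value to exactly one bin", {
  h <- build_histogram(c(1, 1, 1, 9, 9), k = 2)
  expect_equal(h$counts, c(3, 2))
  expect_equal(h$width, 4)
  expect_equal(h$centers, c(3, 7))

  set.seed(1)
  for (rep in 1:3) {
    x <- rlnorm(500, 7, 0.8)
    k <- sample(c(7, 37, 80), 1)
    h <- build_histogram(x, k)
    expect_equal(sum(h$counts), length(x))
    expect_equal(h$counts, oracle_bin_counts(x, k))
    expect_lt(max(abs(diff(h$edges)) - h$width), 1e-9 * h$width)
  }
  expect_error(build_histogram(rep(3, 10), 5), "zero range")
  expect_error(build_histogram(1:10, 1), "k must be")
})

test_that("find_cutoff_bin implements the two occupancy criteria", {
  mk <- function(counts) {
    k <- length(counts)
    structure(list(edges = 0:k, centers = (1:k) - 0.5, counts = counts,
                   width = 1, total = sum(counts)),
              class = "receptor_histogram")
  }
  cfg <- low_bin_config()
  # hand-checked: index 4 (0-based) = 5 (1-based); bin 4 fails on left neighbor 40
  expect_equal(find_cutoff_bin(mk(c(10, 500, 40, 3, 2, 1)), cfg), 5L)
  # no bin below threshold
  expect_true(is.na(find_cutoff_bin(mk(c(100, 90, 80)), cfg)))
  # largest bin 500 => threshold "fewer than 5": a 5-cell bin never qualifies
  expect_true(is.na(find_cutoff_bin(mk(c(500, 10, 5, 5, 5)), cfg)))
  expect_equal(find_cutoff_bin(mk(c(500, 10, 4, 4, 4)), cfg), 4L)
  # last bin: missing right neighbor counts as zero cells
  expect_equal(find_cutoff_bin(mk(c(500, 0, 2)), cfg), 3L)
})

test_that("find_cutoff_bin agrees with the exhaustive scan oracle", {
  set.seed(61)
  cfg <- low_bin_config()
  for (rep in 1:200) {
    h <- random_histogram(sample(5:80, 1))
    got <- find_cutoff_bin(h, cfg)
    want <- oracle_cutoff(h$counts, cfg$eligibility_fraction)
    expect_identical(got, want)
  }
})

test_that("optimal_bin_number matches the exhaustive argmin oracle", {
  cfg <- low_bin_config(k_min = 5, k_max = 60)
  for (seed in 1:5) {
    s <- generate_population(population_spec(n_cells = 3000, seed = seed))
    fit <- fit_mle(s, "lognormal")
    opt <- optimal_bin_number(s, "lognormal", cfg, fit = fit)
    brute <- vapply(cfg$k_min:cfg$k_max,
                    function(k) compute_sse(build_histogram(s, k), fit),
                    numeric(1))
    expect_equal(opt$k_star, (cfg$k_min:cfg$k_max)[which.min(brute)])
    expect_equal(unname(opt$sse_by_k), brute)
    expect_gte(opt$k_star, cfg$k_min)
    expect_lte(opt$k_star, cfg$k_max)
  }
})

test_that("low_bin_search removes a planted right-tail cluster", {
  hits <- 0
  for (seed in 1:5) {
    s <- generate_population(population_spec(
      n_cells = 20000, contamination_fraction = 0.003,
      contamination_location = 10, seed = seed))
    res <- low_bin_search(s)
    planted_removed <- sum(s$component == 1 & !res$kept_mask) /
      sum(s$component == 1)
    clean_removed <- sum(s$component == 0 & !res$kept_mask) /
      sum(s$component == 0)
    if (planted_removed >= 0.9 && clean_removed <= 0.01) hits <- hits + 1
    # conservation and right-side-only contract
    expect_equal(sum(res$kept_mask) + res$removed_count, s$n)
    expect_equal(min(res$kept$values), min(s$values))
  }
  expect_gte(hits, 4)
})

test_that("low_bin_search is deterministic and leaves clean data intact", {
  s <- generate_population(population_spec(n_cells = 5000, seed = 8))
  r1 <- low_bin_search(s)
  r2 <- low_bin_search(s)
  expect_identical(r1$kept_mask, r2$kept_mask)
  expect_identical(r1$k_star, r2$k_star)
  # narrow uniform sample: dense everywhere, no sparse right tail
  set.seed(9)
  u <- runif(5000, 1000, 2000)
  ru <- low_bin_search(u)
  expect_true(is.na(ru$cutoff_bin))
  expect_equal(ru$removed_count, 0)
  expect_error(low_bin_search(runif(50, 1, 2)), "at least 100")
})

test_that("lower eligibility fraction never removes more cells", {
  for (seed in 1:3) {
    s <- generate_population(population_spec(
      n_cells = 10000, contamination_fraction = 0.005, seed = seed))
    r1 <- low_bin_search(s, low_bin_config(eligibility_fraction = 0.01))
    r2 <- low_bin_search(s, low_bin_config(eligibility_fraction = 0.005))
    expect_lte(r2$removed_count, r1$removed_count)
  }
})

test_that("three_sd_outliers matches a direct threshold oracle", {
  set.seed(71)
  x <- c(rnorm(1000, 100, 10), 100 + 4 * 10)
  mask <- three_sd_outliers(x)
  expect_identical(mask, x <= mean(x) + 3 * sd(x))
  expect_false(mask[length(x)])
  expect_true(all(three_sd_outliers(rep(7, 10))))
})

test_that("baseline bin-count rules evaluate their formulas", {
  expect_equal(baseline_bin_rules(29584, "matlab_sqrt"), 172L)
  expect_equal(baseline_bin_rules(1, "matlab_sqrt"), 1L)
  expect_equal(baseline_bin_rules(20000, "palisade"), as.integer(floor(20000^(1 / 3))))
  expect_equal(baseline_bin_rules(20000, "palisade", exponent = 0.25),
               as.integer(floor(20000^0.25)))
  expect_error(baseline_bin_rules(100, "sturges"))
})

test_that("subsample bootstrap reduces to the full-data result at size n", {
  s <- generate_population(population_spec(n_cells = 2000,
                                           contamination_fraction = 0.005,
                                           seed = 5))
  full <- low_bin_search(s)
  b <- bootstrap_subsample(s, sizes = s$n, trials = 1, seed = 1)
  expect_equal(b$trials$geometric_mean, exp(mean(log(full$kept$values))))
  expect_error(bootstrap_subsample(s, sizes = s$n + 1, trials = 1, seed = 1),
               "exceeds")
  # reproducibility
  b2 <- bootstrap_subsample(s, sizes = 500, trials = 3, seed = 4)
  b3 <- bootstrap_subsample(s, sizes = 500, trials = 3, seed = 4)
  expect_identical(b2$trials, b3$trials)
})

test_that("perturbation bootstrap bounds the geometric-mean inflation", {
  s <- generate_population(population_spec(n_cells = 5000,
                                           contamination_fraction = 0.003,
                                           seed = 6))
  full_gm <- exp(mean(log(low_bin_search(s)$kept$values)))
  # size 0: identical to the unperturbed run
  b0 <- bootstrap_perturb(s, sizes = 0, trials = 1, seed = 2)
  expect_equal(b0$trials$geometric_mean, full_gm)
  # scaling a subset by 1.2 can raise the GM by at most factor 1.2
  b <- bootstrap_perturb(s, sizes = c(1000, 5000), trials = 2, seed = 3)
  expect_true(all(b$trials$geometric_mean <= 1.2 * full_gm + 1e-9))
})
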