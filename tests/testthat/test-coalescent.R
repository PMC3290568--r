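test_that("simulator matches coalescent closed forms at constant size", {
  set.seed(41)
  th <- 15.83e-4 * 9209
  p <- sim_params(40, 9209, 15.83e-4, 0.94e-4, reps = 4000)
  st <- simulate_stats(p)
  k <- tajima_constants(40)

  se_S <- sqrt(th * k$a1 + th^2 * k$a2) / sqrt(nrow(st))
  expect_lt(abs(mean(st$S) - th * k$a1), 3 * se_S)

  var_pi <- k$b1 * th + k$b2 * th^2
  se_pi <- sqrt(var_pi) / sqrt(nrow(st))
  expect_lt(abs(mean(st$pi_total) - th), 3 * se_pi)
})

test_that("Var(S) matches Watterson's closed form without recombination", {
  set.seed(42)
  th <- 15.83e-4 * 9209
  p <- sim_params(40, 9209, 15.83e-4, 0, conv_ratio_f = 0, reps = 10000)
  st <- simulate_stats(p)
  k <- tajima_constants(40)
  v_expect <- th * k$a1 + th^2 * k$a2
  # SE of the sample variance from the observed fourth moment
  m4 <- mean((st$S - mean(st$S))^4)
  se_v <- sqrt((m4 - var(st$S)^2) / nrow(st))
  expect_lt(abs(var(st$S) - v_expect), 3 * se_v)
})

test_that("recombination monotonically shrinks the variance of pi", {
  set.seed(43)
  vars <- vapply(c(0, 10e-4, 100e-4), function(r) {
    p <- sim_params(40, 9209, 15.83e-4, r, conv_ratio_f = 0, reps = 3000)
    var(simulate_stats(p)$pi_total)
  }, numeric(1))
  expect_true(vars[1] > vars[2] && vars[2] > vars[3])
})

test_that("identical seeds reproduce the replicate stream bitwise", {
  p <- sim_params(20, 1e4, 1e-3, 1e-4, reps = 50)
  set.seed(7); a <- simulate_stats(p)
  set.seed(7); b <- simulate_stats(p)
  expect_identical(a, b)

  set.seed(8); h1 <- simulate_sample(p)
  set.seed(8); h2 <- simulate_sample(p)
  expect_identical(h1$haplotypes, h2$haplotypes)
  expect_identical(h1$positions, h2$positions)
})

test_that("fixed-S conditioning yields exactly S sites per replicate", {
  set.seed(44)
  p <- sim_params(40, 9209, 15.83e-4, 0.94e-4, reps = 200)
  st <- simulate_stats(p, mutation_model = "fixed_s", s_fixed = 62)
  expect_true(all(st$S == 62))
})

test_that("site-frequency spectrum is proportional to 1/i", {
  set.seed(45)
  th <- 2e-3 * 2e4
  p <- sim_params(20, 2e4, 2e-3, 0, conv_ratio_f = 0, reps = 1500)
  reps <- simulate_counts(p)
  # per-replicate category counts; E[xi_i] = theta / i exactly, and the
  # coalescent makes counts overdispersed relative to Poisson, so the
  # standard error comes from the replicate spread, not sqrt(mean)
  per_rep <- t(vapply(reps, function(cnt)
    tabulate(cnt[cnt > 0 & cnt < 20], nbins = 19), integer(19)))
  tstat <- vapply(1:19, function(i) {
    (mean(per_rep[, i]) - th / i) /
      (sd(per_rep[, i]) / sqrt(nrow(per_rep)))
  }, numeric(1))
  expect_lt(max(abs(tstat)), 4)
  expect_gt(stats::cor(colMeans(per_rep), th / (1:19)), 0.999)
})

test_that("null distributions respect their length and exclusion contract", {
  set.seed(46)
  p <- sim_params(10, 500, 2e-4, 0, conv_ratio_f = 0, reps = 400)
  nd <- null_distribution(p, statistic = "tajima_d")
  expect_s3_class(nd, "null_distribution")
  expect_equal(length(nd$values), nd$reps - nd$excluded)
  expect_gt(nd$excluded, 0)  # tiny theta: some replicates have S = 0

  nd_s <- null_distribution(p, statistic = "S")
  expect_equal(length(nd_s$values), nd_s$reps)
  expect_false(is.unsorted(nd$values))
})

test_that("ms-format export writes one well-formed block per sample", {
  set.seed(49)
  p <- sim_params(6, 1000, 5e-3, 0, conv_ratio_f = 0, reps = 1)
  samples <- list(simulate_sample(p), simulate_sample(p))
  f <- withr::local_tempfile()
  write_ms(samples, f, L = 1000)
  lines <- readLines(f)
  expect_equal(sum(lines == "//"), 2)
  seg <- as.integer(sub("segsites: ", "", grep("^segsites:", lines,
                                               value = TRUE)))
  expect_equal(seg, vapply(samples, n_site, integer(1)))
  hap_lines <- grep("^[01]+$", lines, value = TRUE)
  expect_equal(length(hap_lines), 12)
  expect_equal(nchar(hap_lines[1]), n_site(samples[[1]]))
  pos <- as.numeric(strsplit(sub("positions: ", "",
                                 grep("^positions:", lines,
                                      value = TRUE)[1]), " ")[[1]])
  expect_true(all(pos >= 0 & pos < 1))
  expect_false(is.unsorted(pos))
})

test_that("percentile uses the linear-interpolation convention", {
  nd <- structure(list(statistic = "S", values = as.numeric(1:100),
                       reps = 100, excluded = 0, params_digest = ""),
                  class = "null_distribution")
  expect_equal(percentile(nd, 97.5), 97.525)
  sym <- structure(list(statistic = "S", values = as.numeric(1:9),
                        reps = 9, excluded = 0, params_digest = ""),
                   class = "null_distribution")
  expect_equal(percentile(sym, 50), 5)

  set.seed(47)
  for (k in 1:5) {
    v <- sort(rnorm(50))
    nd2 <- structure(list(statistic = "S", values = v, reps = 50,
                          excluded = 0, params_digest = ""),
                     class = "null_distribution")
    q <- 97.5 / 100
    idx <- (50 - 1) * q + 1
    oracle <- v[floor(idx)] + (idx - floor(idx)) *
      (v[ceiling(idx)] - v[floor(idx)])
    expect_equal(percentile(nd2, 97.5), oracle)
  }
  expect_error(percentile(nd, 0), "in \\(0, 100\\)")
})

test_that("the empirical neutrality test follows its p-value contract", {
  nd <- structure(list(statistic = "tajima_d",
                       values = sort(rnorm(999)), reps = 999, excluded = 0,
                       params_digest = ""), class = "null_distribution")
  top <- neutrality_test(100, nd)
  expect_equal(top$p_value, 1 / 1000)
  expect_true(top$significant)

  med <- neutrality_test(median(nd$values), nd)
  expect_equal(med$p_value, 0.5, tolerance = 0.01)

  at975 <- percentile(nd, 97.5)
  expect_true(neutrality_test(at975 + 1e-9, nd)$significant)
  expect_false(neutrality_test(at975 - 1e-9, nd)$significant)
  expect_error(neutrality_test(1, nd, statistic = "pi_e4"),
               "does not match")
})

test_that("demographic models shift the statistics in the expected direction", {
  set.seed(48)
  p <- sim_params(30, 9209, 15.83e-4, 0.94e-4, reps = 800)
  d_const <- mean(simulate_stats(p)$tajima_d, na.rm = TRUE)
  d_exp <- mean(simulate_stats(
    p, demographic_model("recent_expansion", N0 = 1e4, N1 = 1e7,
                         t = 1000))$tajima_d, na.rm = TRUE)
  d_bot <- mean(simulate_stats(
    p, demographic_model("bottleneck", b = 0.1, t0 = 1600,
                         t1 = 1200))$tajima_d, na.rm = TRUE)
  expect_lt(d_exp, d_const)   # expansions push D negative
  expect_gt(d_bot, d_exp)
})
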