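# a small matrix with a controllable EHH decay: core at column 2,
# one upstream and two downstream sites
ehh_fixture <- function() {
  #          up  core d1  d2
  g <- rbind(c(0, 1, 0, 0),   # carriers (derived at core): rows 1-3
             c(0, 1, 0, 1),
             c(0, 1, 1, 1),
             c(1, 0, 0, 0),   # ancestral class: rows 4-6
             c(1, 0, 0, 1),
             c(0, 0, 1, 0))
  hap_matrix(g, c(500, 1500, 2500, 4000))
}

test_that("EHH is 1 at the core and follows pair enumeration", {
  h <- ehh_fixture()
  cv <- ehh(h, 2, "derived")
  expect_equal(cv$ehh[cv$distance == 0], 1)
  # 3 carriers; at the first downstream site alleles are (0,0,1):
  # one identical pair of C(3,2) = 3
  expect_equal(cv$ehh[cv$distance == 1000], 1 / 3)
  # beyond it carriers are (00, 01, 11): all distinct
  expect_equal(cv$ehh[cv$distance == 2500], 0)
  # upstream site alleles (0,0,0): all still identical
  expect_equal(cv$ehh[cv$distance == -1000], 1)
})

test_that("EHH is non-increasing with distance on random matrices", {
  set.seed(51)
  for (k in 1:6) {
    h <- random_hap(n = 14, m = 10)
    core <- 5
    cnt <- sum(h$haplotypes[, core])
    if (cnt < 2 || cnt > 12) next
    cv <- ehh(h, core, "derived")
    down <- cv$ehh[cv$distance >= 0]
    up <- rev(cv$ehh[cv$distance <= 0])
    expect_true(all(diff(down) <= 1e-12))
    expect_true(all(diff(up) <= 1e-12))
  }
})

test_that("iHH integrates by trapezoids and flags data edges", {
  # constant EHH = 1 out to d gives exactly d
  g <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(0, 0, 0))
  h <- hap_matrix(g, c(1000, 2000, 3000))
  cv <- ehh(h, 1, "derived")
  out <- ihh(cv)
  expect_equal(out$value, 2000)
  expect_true(out$edge)  # never reached the truncation level

  # EHH dropping 1 -> 0.5 over 1000 bp: trapezoid 750
  g2 <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 0), c(0, 0))
  h2 <- hap_matrix(g2, c(1000, 2000))
  cv2 <- ehh(h2, 1, "derived")
  expect_equal(cv2$ehh, c(1, 0.5))
  expect_equal(ihh(cv2)$value, 750)

  # crossing the truncation level: integrate to the interpolated crossing
  # on both sides (core in the middle, EHH 1 -> 1/3 at each flank)
  h3 <- hap_matrix(cbind(c(1, 0, 0, 0, 0), c(1, 1, 1, 0, 0),
                         c(1, 0, 0, 0, 0)),
                   c(1000, 3000, 5000))
  cv3 <- ehh(h3, 2, "derived")
  expect_equal(cv3$ehh, c(1 / 3, 1, 1 / 3))
  val <- ihh(cv3, truncation = 0.5)
  dcross <- 2000 * (1 - 0.5) / (1 - 1 / 3)
  expect_equal(val$value, 2 * (1 + 0.5) / 2 * dcross)
  expect_false(val$edge)

  # a core at the data boundary carries the edge flag even if the other
  # side crosses the truncation level
  h4 <- hap_matrix(cbind(c(1, 1, 1, 0, 0), c(1, 0, 0, 0, 0)),
                   c(1000, 3000))
  expect_true(ihh(ehh(h4, 1, "derived"), truncation = 0.5)$edge)
})

test_that("early-stopped curves leave iHH unchanged", {
  set.seed(52)
  p <- sim_params(24, 1e5, 8e-4, 2e-4, reps = 1)
  h <- simulate_sample(p)
  core <- which.min(abs(colSums(h$haplotypes) - 12))
  full <- ihh(ehh(h, core, "derived"), 0.05)
  stopped <- ihh(ehh(h, core, "derived", stop_below = 0.05), 0.05)
  expect_equal(stopped$value, full$value)
  expect_equal(stopped$edge, full$edge)
})

test_that("unstandardised iHS is zero for mirror-symmetric classes", {
  # both allele classes carry identical flanking structure
  flank <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  g <- cbind(rbind(flank, flank)[, 1], c(rep(1, 4), rep(0, 4)),
             rbind(flank, flank)[, 2])
  h <- hap_matrix(g, c(100, 200, 300))
  r <- ihs_unstandardized(h, 2)
  expect_equal(r$ihs_unstd, 0)
  expect_equal(r$daf, 0.5)
})

test_that("a planted sweep on the derived allele gives a negative score", {
  set.seed(53)
  p <- sim_params(40, 2e5, 8e-4, 2e-4, reps = 1)
  h <- simulate_sample(p)
  sw <- inject_sweep(h, sweep_scenario(0.5, 50))
  tr <- attr(sw, "truth")
  r <- ihs_unstandardized(sw, tr$core_site)
  expect_lt(r$ihs_unstd, 0)

  # invariant to haplotype order
  perm <- sample(n_hap(sw))
  sw2 <- hap_matrix(sw$haplotypes[perm, ], sw$positions)
  r2 <- ihs_unstandardized(sw2, tr$core_site)
  expect_equal(r2$ihs_unstd, r$ihs_unstd)
})

test_that("standardisation centres and scales every occupied bin", {
  set.seed(54)
  scores <- rnorm(400)
  dafs <- runif(400, 0.05, 0.95)
  std <- standardize_ihs(scores, dafs, n_bins = 10)
  by_bin <- split(std$ihs_std, std$bin)
  for (v in by_bin) {
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
  # a planted extreme outlier keeps an extreme rank after standardisation
  scores[1] <- 10
  dafs[1] <- 0.5
  std2 <- standardize_ihs(scores, dafs)
  expect_equal(which.max(abs(std2$ihs_std)), 1L)
  # singleton bins are flagged missing
  std3 <- standardize_ihs(c(1, 2, 3), c(0.06, 0.5, 0.51), n_bins = 20)
  expect_true(is.na(std3$ihs_std[1]))
})

test_that("significant sites cluster by gap threshold", {
  none <- tibble::tibble(position = c(1, 2, 3) * 1e3,
                         significant = FALSE)
  expect_equal(nrow(cluster_significant(none, 1e4)), 0)

  scan <- tibble::tibble(
    position = c(1e3, 2e3, 3e3, 5e4, 51e3, 90e3),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  cl <- cluster_significant(scan, max_gap = 5e3)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$n_sites, c(2L, 2L, 1L))

  # brute-force scan oracle
  set.seed(55)
  pos <- sort(sample(1e6, 60))
  sig <- rbinom(60, 1, 0.3) == 1
  sc <- tibble::tibble(position = pos, significant = sig)
  cl2 <- cluster_significant(sc, max_gap = 3e4)
  spos <- pos[sig]
  if (length(spos) > 0) {
    runs <- 1 + sum(diff(spos) > 3e4)
    expect_equal(nrow(cl2), runs)
    expect_equal(sum(cl2$n_sites), length(spos))
  }
})

test_that("gene enrichment p follows the empirical-rank contract", {
  bg <- seq(0.01, 0.2, length.out = 99)
  expect_equal(gene_enrichment_p(0.5, bg), 1 / 100)
  med <- gene_enrichment_p(median(bg), bg)
  expect_equal(med, 0.51, tolerance = 0.02)
  # rank agreement with an explicit sort
  set.seed(56)
  bg2 <- runif(49)
  obs <- runif(1)
  expect_equal(gene_enrichment_p(obs, bg2),
               (1 + sum(sort(bg2) >= obs)) / 50)
  expect_error(gene_enrichment_p(0.1, numeric()), "empty")
})
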