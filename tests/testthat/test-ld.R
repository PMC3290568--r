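test_that("two-site counts form an exact 2x2 table", {
  g <- rbind(matrix(1L, 7, 2), matrix(0L, 3, 2))
  h <- toy_hap(g)
  c2 <- two_site_counts(h, 1, 2)
  expect_equal(c2, list(n11 = 7L, n10 = 0L, n01 = 0L, n00 = 3L))

  set.seed(31)
  for (k in 1:8) {
    h <- random_hap(n = 11, m = 4)
    segs <- which(colSums(h$haplotypes) %in% 1:10)
    if (length(segs) < 2) next
    c2 <- two_site_counts(h, segs[1], segs[2])
    expect_equal(c2$n11 + c2$n10 + c2$n01 + c2$n00, 11L)
    # brute-force row enumeration
    a <- h$haplotypes[, segs[1]]; b <- h$haplotypes[, segs[2]]
    expect_equal(c2$n11, sum(a & b))
    expect_equal(c2$n00, sum(!a & !b))
  }
  hm <- toy_hap(cbind(rep(0L, 4), c(0L, 1L, 0L, 1L)))
  expect_error(two_site_counts(hm, 1, 2), "monomorphic")
})

test_that("|D'| and r2 match hand-derived values", {
  perfect <- list(n11 = 7, n10 = 0, n01 = 0, n00 = 3)
  expect_equal(ld_dprime(perfect), 1)
  expect_equal(ld_r_squared(perfect), 1)

  # (4,2,2,2): p1 = q1 = 0.6, p11 = 0.4, D = 0.04, Dmax = 0.24
  mid <- list(n11 = 4, n10 = 2, n01 = 2, n00 = 2)
  expect_equal(ld_dprime(mid), 0.04 / 0.24, tolerance = 1e-12)
  expect_equal(ld_r_squared(mid), 0.04^2 / (0.6 * 0.4 * 0.6 * 0.4),
               tolerance = 1e-12)

  # D = 0 at linkage equilibrium
  eq <- list(n11 = 9, n10 = 3, n01 = 3, n00 = 1)  # p11 = p1*q1 = 0.5625
  expect_equal(ld_dprime(eq), 0)
  expect_equal(ld_r_squared(eq), 0)
})

test_that("r2 <= |D'| <= 1 and symmetries hold on random tables", {
  set.seed(32)
  for (k in 1:40) {
    cnt <- as.list(rmultinom(1, 24, runif(4, 0.05, 1))[, 1])
    names(cnt) <- c("n11", "n10", "n01", "n00")
    dp <- ld_dprime(cnt)
    r2 <- ld_r_squared(cnt)
    if (is.na(dp)) next
    expect_lte(r2, dp + 1e-12)
    expect_lte(dp, 1 + 1e-12)
    # swapping the two sites
    swap <- list(n11 = cnt$n11, n10 = cnt$n01, n01 = cnt$n10,
                 n00 = cnt$n00)
    expect_equal(ld_dprime(swap), dp, tolerance = 1e-12)
    expect_equal(ld_r_squared(swap), r2, tolerance = 1e-12)
    # relabeling alleles at both sites leaves r2 unchanged
    rel <- list(n11 = cnt$n00, n10 = cnt$n01, n01 = cnt$n10,
                n00 = cnt$n11)
    expect_equal(ld_r_squared(rel), r2, tolerance = 1e-12)
    # relabeling at one site leaves |D'| unchanged
    one <- list(n11 = cnt$n10, n10 = cnt$n11, n01 = cnt$n00,
                n00 = cnt$n01)
    expect_equal(ld_dprime(one), dp, tolerance = 1e-12)
  }
})

test_that("ld_matrix covers all MAF-passing pairs consistently", {
  set.seed(33)
  g <- cbind(c(1, 1, 1, 0, 0, 0, 1, 0), c(1, 1, 0, 0, 1, 0, 1, 0),
             c(0, 1, 1, 0, 0, 1, 1, 0))
  h <- toy_hap(g)
  m <- ld_matrix(h, min_maf = 0.05)
  expect_equal(nrow(m), 3)
  for (k in seq_len(nrow(m))) {
    c2 <- two_site_counts(h, m$i[k], m$j[k])
    expect_equal(m$dprime[k], ld_dprime(c2))
    expect_equal(m$r2[k], ld_r_squared(c2))
  }
})

test_that("planted perfectly linked sites are recovered as one group", {
  set.seed(34)
  base <- rbinom(20, 1, 0.4)
  noise <- matrix(rbinom(20 * 3, 1, 0.5), 20)
  g <- cbind(base, noise[, 1], base, noise[, 2], base, noise[, 3])
  h <- toy_hap(g)
  m <- ld_matrix(h)
  grp <- complete_ld_groups(m, dprime_min = 1, r2_min = 0.99)
  planted <- h$positions[c(1, 3, 5)]
  expect_true(any(vapply(split(grp$position, grp$group),
                         function(v) setequal(v, planted), logical(1))))
})

test_that("transitive closure equals a union-find oracle", {
  set.seed(35)
  for (k in 1:5) {
    h <- random_hap(n = 16, m = 7)
    m <- ld_matrix(h, min_maf = 0.01)
    if (nrow(m) == 0) next
    thr_d <- 0.8; thr_r <- 0.5
    grp <- complete_ld_groups(m, dprime_min = thr_d, r2_min = thr_r)
    edges <- m[!is.na(m$dprime) & m$dprime >= thr_d - 1e-9 &
                 m$r2 >= thr_r, ]
    if (nrow(edges) == 0) {
      expect_equal(nrow(grp), 0)
      next
    }
    nodes <- as.character(sort(unique(c(edges$pos_i, edges$pos_j))))
    oracle <- brute_groups(edges, nodes)
    mine <- split(as.character(grp$position), grp$group)
    norm <- function(l) sort(vapply(l, function(v)
      paste(sort(as.numeric(v)), collapse = ","), character(1)))
    expect_equal(unname(norm(mine)), unname(norm(oracle)))
  }
})

test_that("jointly swept sites reach complete LD in synthetic sweeps", {
  set.seed(36)
  p <- sim_params(30, 5e4, 4e-4, 1e-4, reps = 1)
  h <- simulate_sample(p)
  sw <- inject_sweep(h, sweep_scenario(0.5, 1e-6))  # young: no scars
  tr <- attr(sw, "truth")
  core <- tr$core_site
  # a site carried only by the swept haplotypes is in complete LD with core
  carried <- which(colSums(sw$haplotypes[tr$carriers, , drop = FALSE]) ==
                     length(tr$carriers) &
                   colSums(sw$haplotypes[-tr$carriers, , drop = FALSE]) == 0)
  carried <- setdiff(carried, core)
  if (length(carried) > 0) {
    c2 <- two_site_counts(sw, core, carried[1])
    expect_equal(ld_dprime(c2), 1)
  } else {
    succeed("no co-carried site in this draw")
  }
})
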