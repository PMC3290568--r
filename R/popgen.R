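#' Tajima variance constants
#'
#' The sample-size constants entering the variance normalisation of Tajima's
#' D: `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param n number of sampled chromosomes, `>= 2`.
#' @return A named list with `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
#' @examples
#' tajima_constants(40)$a1
tajima_constants <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("n must be a single sample size >= 2", call. = FALSE)
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Number of segregating sites
#'
#' Counts the sites at which both alleles are present in the sample.
#'
#' @param h a [hap_matrix()].
#' @return Integer count.
#' @export
segregating_sites <- function(h) {
  stopifnot(inherits(h, "hap_matrix"))
  if (n_site(h) == 0) return(0L)
  cnt <- colSums(h$haplotypes)
  sum(cnt > 0 & cnt < n_hap(h))
}

#' Nucleotide diversity per base pair
#'
#' Mean number of pairwise differences over all `choose(n, 2)` haplotype
#' pairs, divided by the surveyed length `L`. Computed with the unbiased
#' frequency form `sum(2 p (1-p)) * n/(n-1) / L`, which is algebraically
#' identical to pairwise enumeration.
#'
#' @param h a [hap_matrix()].
#' @param L surveyed length in bp (`> 0`); not inferred from positions.
#' @return Per-bp diversity (unscaled; multiply by `1e4` for reporting).
#' @export
nucleotide_diversity <- function(h, L) {
  stopifnot(inherits(h, "hap_matrix"))
  if (!is.numeric(L) || L <= 0) stop("L must be positive", call. = FALSE)
  n <- n_hap(h)
  if (n < 2) stop("need at least 2 haplotypes", call. = FALSE)
  if (n_site(h) == 0) return(0)
  p <- colSums(h$haplotypes) / n
  sum(2 * p * (1 - p)) * n / (n - 1) / L
}

#' Watterson's estimator of theta per base pair
#'
#' `S / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites.
#' @param n number of chromosomes.
#' @param L surveyed length in bp.
#' @return Per-bp estimate of `4 Ne mu` (unscaled).
#' @export
#' @examples
#' watterson_theta(S = 62, n = 40, L = 9209) * 1e4
watterson_theta <- function(S, n, L) {
  if (!is.numeric(L) || L <= 0) stop("L must be positive", call. = FALSE)
  S / (tajima_constants(n)$a1 * L)
}

#' Tajima's D
#'
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1))`, where `pi_total` is
#' the total (not per-bp) mean pairwise difference. Undefined at `S = 0`:
#' returns `NA_real_` (never 0) with a message.
#'
#' @param S segregating sites.
#' @param pi_total total mean pairwise differences (per-bp value times `L`).
#' @param n number of chromosomes, `>= 4`.
#' @return The D statistic, or `NA_real_` when `S == 0`.
#' @export
tajima_d <- function(S, pi_total, n) {
  if (n < 4) stop("n must be >= 4 for Tajima's D", call. = FALSE)
  if (S == 0) {
    return(NA_real_)
  }
  k <- tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Summary statistics for a region
#'
#' Bundles N, L, S, per-bp pi and Watterson's theta (both reported `x 1e4`)
#' and Tajima's D for the sites of `h` falling in `region`, using the
#' region's surveyed length as `L`.
#'
#' @param h a [hap_matrix()].
#' @param region a [region_spec()]; its `L_surveyed` is the denominator.
#' @return A one-row tibble: `region, n, L, S, pi_e4, theta_w_e4, tajima_d`.
#' @export
summarize_region <- function(h, region) {
  hr <- restrict_to_region(h, region)
  n <- n_hap(hr)
  L <- region$L_surveyed
  S <- segregating_sites(hr)
  pi_bp <- nucleotide_diversity(hr, L)
  tibble(
    region = region$label,
    n = n,
    L = L,
    S = as.integer(S),
    pi_e4 = pi_bp * 1e4,
    theta_w_e4 = watterson_theta(S, n, L) * 1e4,
    tajima_d = tajima_d(S, pi_bp * L, n)
  )
}

#' Folded-free derived site frequency spectrum
#'
#' @param h a [hap_matrix()].
#' @return Tibble with `derived_count` (1..n-1) and `sites`.
#' @export
site_frequency_spectrum <- function(h) {
  stopifnot(inherits(h, "hap_matrix"))
  n <- n_hap(h)
  cnt <- colSums(h$haplotypes)
  cnt <- cnt[cnt > 0 & cnt < n]
  tibble(derived_count = seq_len(n - 1),
         sites = as.integer(tabulate(cnt, nbins = n - 1)))
}
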