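#' Two-site haplotype counts
#'
#' Exact 2x2 table of derived/ancestral combinations at two segregating
#' sites: `n11` counts haplotypes derived at both.
#'
#' @param h a [hap_matrix()].
#' @param i,j column indices of two distinct sites, both segregating.
#' @return Named list `n11, n10, n01, n00` summing to `n_hap(h)`.
#' @export
two_site_counts <- function(h, i, j) {
  stopifnot(inherits(h, "hap_matrix"))
  if (i == j) stop("sites must be distinct", call. = FALSE)
  a <- h$haplotypes[, i]
  b <- h$haplotypes[, j]
  for (v in list(a, b)) {
    if (all(v == 0) || all(v == 1)) {
      stop("monomorphic site in pair", call. = FALSE)
    }
  }
  list(n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
       n01 = sum(a == 0 & b == 1), n00 = sum(a == 0 & b == 0))
}

ld_from_counts <- function(c2) {
  n <- c2$n11 + c2$n10 + c2$n01 + c2$n00
  p1 <- (c2$n11 + c2$n10) / n   # derived freq at first site
  q1 <- (c2$n11 + c2$n01) / n   # derived freq at second site
  if (p1 %in% c(0, 1) || q1 %in% c(0, 1)) {
    return(list(D = NA_real_, dprime = NA_real_, r2 = NA_real_))
  }
  p11 <- c2$n11 / n
  D <- p11 - p1 * q1
  dmax <- if (D >= 0) min(p1 * (1 - q1), (1 - p1) * q1)
          else min(p1 * q1, (1 - p1) * (1 - q1))
  dprime <- if (D == 0) 0 else abs(D) / dmax
  r2 <- D^2 / (p1 * (1 - p1) * q1 * (1 - q1))
  list(D = D, dprime = dprime, r2 = r2)
}

#' Normalised linkage disequilibrium for a site pair
#'
#' `D = p11 - p1 q1`; `|D'| = |D| / Dmax` with `Dmax` the usual
#' frequency-bound; `r^2 = D^2 / (p1(1-p1) q1(1-q1))`. Reported `|D'|` is
#' absolute; the signed `D` is returned alongside.
#'
#' @param counts result of [two_site_counts()].
#' @return For `ld_dprime`/`ld_r_squared`, a single number (`NA` and a
#'   warning if an allele is fixed).
#' @export
#' @examples
#' ld_dprime(list(n11 = 7, n10 = 0, n01 = 0, n00 = 3))  # complete LD
ld_dprime <- function(counts) ld_from_counts(counts)$dprime

#' @rdname ld_dprime
#' @export
ld_r_squared <- function(counts) ld_from_counts(counts)$r2

#' Pairwise LD matrix in long format
#'
#' All site pairs passing a minor-allele-frequency filter, as a long tibble.
#'
#' @param h a [hap_matrix()].
#' @param min_maf minor allele frequency floor (default 0.05).
#' @return Tibble of class `ld_matrix`: `pos_i, pos_j, i, j, D, dprime, r2`.
#' @export
ld_matrix <- function(h, min_maf = 0.05) {
  stopifnot(inherits(h, "hap_matrix"))
  n <- n_hap(h)
  p <- colSums(h$haplotypes) / n
  keep <- which(pmin(p, 1 - p) >= min_maf & p > 0 & p < 1)
  pairs <- if (length(keep) >= 2) utils::combn(keep, 2) else
    matrix(integer(), nrow = 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ld <- ld_from_counts(two_site_counts(h, i, j))
    tibble(i = i, j = j, pos_i = h$positions[i], pos_j = h$positions[j],
           D = ld$D, dprime = ld$dprime, r2 = ld$r2)
  })
  if (nrow(res) == 0) {
    res <- tibble(i = integer(), j = integer(), pos_i = numeric(),
                  pos_j = numeric(), D = numeric(), dprime = numeric(),
                  r2 = numeric())
  }
  class(res) <- c("ld_matrix", class(res))
  res
}

#' Group sites in complete (or near-complete) LD
#'
#' Transitive closure of pairs with `|D'| >= dprime_min` and `r2 >= r2_min`.
#' The default `r2_min = 0.90` mirrors the near-complete criterion used to
#' bundle tightly linked functional alleles.
#'
#' @param m an [ld_matrix()] tibble.
#' @param dprime_min threshold on `|D'|` (default 1, allowing a small
#'   numerical tolerance).
#' @param r2_min threshold on `r^2`.
#' @param tol numerical tolerance applied to `dprime_min`.
#' @return Tibble `position, group` (group ids over grouped sites only).
#' @export
complete_ld_groups <- function(m, dprime_min = 1, r2_min = 0.90,
                               tol = 1e-9) {
  stopifnot(all(c("pos_i", "pos_j", "dprime", "r2") %in% names(m)))
  stopifnot(dprime_min >= 0, dprime_min <= 1, r2_min >= 0, r2_min <= 1)
  sel <- !is.na(m$dprime) & m$dprime >= dprime_min - tol & m$r2 >= r2_min
  edges <- m[sel, c("pos_i", "pos_j")]
  if (nrow(edges) == 0) {
    return(tibble(position = numeric(), group = integer()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$pos_i),
               to = as.character(edges$pos_j)),
    directed = FALSE)
  comp <- igraph::components(g)
  tibble(position = as.numeric(names(comp$membership)),
         group = as.integer(comp$membership)) |>
    arrange(.data$group, .data$position)
}

#' @export
autoplot.ld_matrix <- function(object, statistic = c("dprime", "r2"), ...) {
  statistic <- match.arg(statistic)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$pos_i), y = factor(.data$pos_j),
                               fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "position", y = "position",
                  fill = if (statistic == "dprime") "|D'|" else
                    expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
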