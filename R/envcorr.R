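#' Pathogen presence/absence matrix
#'
#' @param presence binary matrix, pathogens in rows, countries in columns;
#'   dimnames required and unique.
#' @param pathogen_class class per pathogen: `"virus"`, `"bacteria"` or
#'   `"protozoa"`.
#' @return A `pathogen_matrix` object.
#' @export
pathogen_matrix <- function(presence, pathogen_class) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    stop("presence needs pathogen rownames and country colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence))) {
    stop("duplicate pathogen or country labels", call. = FALSE)
  }
  if (!all(presence %in% c(0, 1))) stop("entries must be 0/1", call. = FALSE)
  classes <- c("virus", "bacteria", "protozoa")
  if (length(pathogen_class) != nrow(presence) ||
      !all(pathogen_class %in% classes)) {
    stop("pathogen_class must be one of virus/bacteria/protozoa per pathogen",
         call. = FALSE)
  }
  structure(list(presence = presence, pathogen_class = pathogen_class),
            class = "pathogen_matrix")
}

#' Pathogen richness per country
#'
#' Number of distinct pathogens of the selected classes recorded present in
#' each country (column sums of the presence matrix restricted to the
#' classes).
#'
#' @param m a [pathogen_matrix()].
#' @param classes subset of `c("virus", "bacteria", "protozoa")`; default all
#'   (the intracellular-pathogen set).
#' @return Named integer vector, one count per country.
#' @export
pathogen_richness <- function(m, classes = c("virus", "bacteria",
                                             "protozoa")) {
  stopifnot(inherits(m, "pathogen_matrix"))
  if (length(classes) == 0) stop("empty class subset", call. = FALSE)
  if (!all(classes %in% c("virus", "bacteria", "protozoa"))) {
    stop("unknown pathogen class", call. = FALSE)
  }
  keep <- m$pathogen_class %in% classes
  colSums(m$presence[keep, , drop = FALSE])
}

# tau-b and the tie-corrected normal approximation used by the classical
# Kendall test; C and D counted over all pairs
kendall_core <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    p <- dx * dy
    C <- C + sum(p > 0)
    D <- D + sum(p < 0)
  }
  S <- C - D
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  # tie-corrected variance of S (Kendall 1970)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  list(S = S, tau = tau, varS = varS, C = C, D = D)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall coefficient
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` with a two-sided p-value by
#' exact permutation enumeration for `n <= 10`, a normal approximation with
#' continuity correction for larger samples, or random permutations.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param method `"auto"` (exact below `exact_limit`, else normal),
#'   `"exact"`, `"normal_approx"` or `"permutation"`.
#' @param n_perm random permutations for `method = "permutation"`.
#' @param exact_limit largest n for exact enumeration (default 10).
#' @return Tibble of class `kendall_result`: `tau, p_value, n, method`.
#' @export
#' @examples
#' kendall_tau(1:4, c(1, 3, 2, 4))  # tau = 2/3
kendall_tau <- function(x, y, method = c("auto", "exact", "normal_approx",
                                         "permutation"),
                        n_perm = 2000, exact_limit = 10) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("need equal-length vectors with at least 3 complete pairs",
         call. = FALSE)
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: tau undefined", call. = FALSE)
    out <- tibble(tau = NA_real_, p_value = NA_real_, n = n,
                  method = "undefined")
    class(out) <- c("kendall_result", class(out))
    return(out)
  }
  k <- kendall_core(x, y)
  used <- method
  if (method == "auto") used <- if (n <= exact_limit) "exact" else
    "normal_approx"
  p <- switch(used,
    exact = {
      if (n > 10) stop("exact enumeration limited to n <= 10", call. = FALSE)
      kendall_exact_p_cpp(x, y)
    },
    normal_approx = {
      z <- (abs(k$S) - 1) / sqrt(k$varS)  # continuity correction
      2 * pnorm(max(z, 0), lower.tail = FALSE)
    },
    permutation = {
      hits <- sum(purrr::map_lgl(seq_len(n_perm), function(b) {
        abs(kendall_core(x, sample(y))$S) >= abs(k$S)
      }))
      (1 + hits) / (n_perm + 1)
    })
  out <- tibble(tau = k$tau, p_value = min(p, 1), n = n, method = used)
  class(out) <- c("kendall_result", class(out))
  out
}

#' Correlate variant frequencies with per-country richness
#'
#' Joins a population frequency table to country-level pathogen richness and
#' computes one Kendall correlation per allele/haplotype. Populations
#' sharing a country share a richness value; the resulting ties are handled
#' by tau-b. Set `average_by_country = TRUE` to average population
#' frequencies within each country first.
#'
#' @param freqs tibble with columns `population`, `country`,
#'   `allele_or_haplotype`, `frequency` (in `[0, 1]`).
#' @param richness named vector of per-country counts
#'   (see [pathogen_richness()]).
#' @param method,n_perm passed to [kendall_tau()].
#' @param average_by_country collapse populations to country means first.
#' @return Tibble: `allele_or_haplotype, tau, p_value, n, method`.
#' @export
correlate_frequencies <- function(freqs, richness,
                                  method = c("auto", "exact", "normal_approx",
                                             "permutation"),
                                  n_perm = 2000,
                                  average_by_country = FALSE) {
  method <- match.arg(method)
  need <- c("population", "country", "allele_or_haplotype", "frequency")
  if (!all(need %in% names(freqs))) {
    stop("freqs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(freqs$frequency < 0 | freqs$frequency > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  unmapped <- setdiff(unique(freqs$country), names(richness))
  if (length(unmapped) > 0) {
    stop("populations in countries with no richness value: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  df <- freqs
  if (average_by_country) {
    df <- df |>
      group_by(.data$country, .data$allele_or_haplotype) |>
      summarise(frequency = mean(.data$frequency), .groups = "drop") |>
      mutate(population = .data$country)
  }
  df$richness <- unname(richness[df$country])
  df |>
    group_by(.data$allele_or_haplotype) |>
    dplyr::group_modify(function(g, key) {
      kendall_tau(g$richness, g$frequency, method = method, n_perm = n_perm)
    }) |>
    ungroup()
}

#' Haplotype frequency by exact match at named sites
#'
#' Frequency of chromosomes carrying a given allele configuration at a set
#' of sites (e.g. the derived state at each of several functional SNPs).
#'
#' @param h a [hap_matrix()].
#' @param positions bp positions of the defining sites.
#' @param alleles 0/1 allele per site (default all derived).
#' @return Frequency in `[0, 1]`.
#' @export
haplotype_frequency <- function(h, positions,
                                alleles = rep(1L, length(positions))) {
  stopifnot(inherits(h, "hap_matrix"))
  idx <- match(positions, h$positions)
  if (anyNA(idx)) {
    stop("positions not present: ",
         paste(positions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  hit <- apply(h$haplotypes[, idx, drop = FALSE], 1,
               function(r) all(r == alleles))
  mean(hit)
}
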