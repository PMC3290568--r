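#' Mutation rate calibrated from interspecies divergence
#'
#' `mu = dxy / (2 * split_years / gen_years)`: the per-site divergence
#' accumulated along both lineages since the species split, converted to a
#' per-site per-generation rate.
#'
#' @param dxy average nucleotide substitutions per site between the two
#'   species.
#' @param split_years split time in years (default 5.4e6, the
#'   human-chimpanzee calibration).
#' @param gen_years generation time in years (default 25).
#' @return Mutation rate per site per generation.
#' @export
#' @examples
#' mutation_rate_from_divergence(0.01296)  # 3e-8
mutation_rate_from_divergence <- function(dxy, split_years = 5.4e6,
                                          gen_years = 25) {
  if (any(c(dxy, split_years, gen_years) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  dxy / (2 * split_years / gen_years)
}

#' Convert generations to years
#'
#' @param g generations (`>= 0`).
#' @param gen_time years per generation (default 25).
#' @return Years.
#' @export
#' @examples
#' generations_to_years(660)  # 16,500
generations_to_years <- function(g, gen_time = 25) {
  if (any(g < 0)) stop("g must be >= 0", call. = FALSE)
  g * gen_time
}

#' Allele age from the decay of haplotype sharing
#'
#' Recombination erodes the ancestral haplotype around a focal allele at a
#' rate proportional to its age: on each side of the core, the genetic
#' distance from the core to the first marker at which a carrier departs
#' from the ancestral haplotype is approximately exponential with rate `g`
#' (the age in generations) per Morgan, plus a mutation hazard of
#' `mu_per_marker * g` per marker scanned. The censored-exponential maximum
#' likelihood estimate is
#' `g_hat = n_uncensored / sum(d_i + mu_per_marker * m_i)`,
#' with `d_i` the sharing distance (Morgans, censored at the map edge) and
#' `m_i` the markers scanned. The decay statistic is `tau = 1 / g_hat`, so
#' the age is `1 / tau` generations. This is a deliberately transparent
#' estimator of the haplotype-sharing decay, not a port of any fine-mapping
#' likelihood machinery; see the methods vignette.
#'
#' @param cases a [hap_matrix()] restricted to the carrier haplotypes.
#' @param core core site index within `cases`.
#' @param map cumulative genetic positions in Morgans, one per site of
#'   `cases`; if `NULL`, a uniform `cm_per_mb` map over the physical
#'   positions is used.
#' @param ancestral_haplotype optional 0/1 vector (one per site) giving the
#'   ancestral core haplotype; default is the majority allele among carriers
#'   at each marker, ties broken toward the ancestral (0) allele.
#' @param mu_per_marker per-marker mutation rate (default 2.5e-8).
#' @param cm_per_mb uniform map rate when `map` is absent (default 1).
#' @param gen_time years per generation (default 25).
#' @param n_boot bootstrap replicates over carriers for the confidence
#'   interval (default 200; 0 to skip).
#' @return A `dhs_estimate` object: `tau`, `generations`, `years`,
#'   `n_cases`, `censored`, `ci_generations`.
#' @export
dhs_tau <- function(cases, core, map = NULL, ancestral_haplotype = NULL,
                    mu_per_marker = 2.5e-8, cm_per_mb = 1, gen_time = 25,
                    n_boot = 200) {
  stopifnot(inherits(cases, "hap_matrix"))
  nc <- n_hap(cases)
  if (nc < 2) stop("need at least 2 carrier haplotypes", call. = FALSE)
  if (is.null(map)) {
    map <- (cases$positions - cases$positions[1]) * cm_per_mb / 100 / 1e6
  }
  if (length(map) != n_site(cases)) {
    stop("map must have one entry per site", call. = FALSE)
  }
  if (is.null(ancestral_haplotype)) {
    cnt <- colSums(cases$haplotypes)
    ancestral_haplotype <- as.integer(cnt > nc / 2)  # ties -> ancestral (0)
  }

  sides <- list(up = rev(seq_len(core - 1)),
                down = seq_len(n_site(cases))[-seq_len(core)])
  obs <- purrr::map_dfr(seq_len(nc), function(i) {
    purrr::map_dfr(names(sides), function(sd) {
      cols <- sides[[sd]]
      if (length(cols) == 0) return(NULL)
      mism <- which(cases$haplotypes[i, cols] != ancestral_haplotype[cols])
      if (length(mism) == 0) {
        tibble(carrier = i, side = sd,
               d = abs(map[cols[length(cols)]] - map[core]),
               markers = length(cols), censored = TRUE)
      } else {
        k <- mism[1]
        tibble(carrier = i, side = sd, d = abs(map[cols[k]] - map[core]),
               markers = k, censored = FALSE)
      }
    })
  })

  estimate <- function(o) {
    k <- sum(!o$censored)
    if (k == 0) return(NA_real_)
    denom <- sum(o$d + mu_per_marker * o$markers)
    if (denom <= 0) return(NA_real_)
    k / denom
  }
  g_hat <- estimate(obs)
  if (is.na(g_hat)) {
    stop("no decay observed; age unresolved (all observations censored)",
         call. = FALSE)
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- purrr::map_dbl(seq_len(n_boot), function(b) {
      pick <- sample.int(nc, nc, replace = TRUE)
      estimate(bind_rows(lapply(pick, function(i) obs[obs$carrier == i, ])))
    })
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 20) {
      ci <- unname(quantile(boots, c(0.025, 0.975)))
    }
  }

  structure(list(tau = 1 / g_hat, generations = g_hat,
                 years = generations_to_years(g_hat, gen_time),
                 n_cases = nc, censored = sum(obs$censored),
                 n_obs = nrow(obs), ci_generations = ci,
                 gen_time = gen_time),
            class = "dhs_estimate")
}

#' @export
print.dhs_estimate <- function(x, ...) {
  cat(sprintf(
    "<dhs_estimate> age %.0f generations (%.0f years at %g y/gen)\n",
    x$generations, x$years, x$gen_time))
  cat(sprintf("  %d carriers, %d/%d side-observations censored\n",
              x$n_cases, x$censored, x$n_obs))
  if (!anyNA(x$ci_generations)) {
    cat(sprintf("  bootstrap 95%% CI: %.0f-%.0f generations\n",
                x$ci_generations[1], x$ci_generations[2]))
  }
  invisible(x)
}

#' @export
tidy.dhs_estimate <- function(x, ...) {
  tibble(tau = x$tau, generations = x$generations, years = x$years,
         ci_low_gen = x$ci_generations[1], ci_high_gen = x$ci_generations[2])
}

#' @export
glance.dhs_estimate <- function(x, ...) {
  tibble(n_cases = x$n_cases, n_obs = x$n_obs, censored = x$censored,
         generations = x$generations, years = x$years)
}
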