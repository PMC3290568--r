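#' Generate a neutral haplotype sample
#'
#' Thin wrapper over [simulate_sample()]: one neutral coalescent sample
#' under the given parameters and demographic model.
#'
#' @inheritParams simulate_sample
#' @return A [hap_matrix()].
#' @export
generate_neutral <- function(params, model = demographic_model("constant"),
                             mutation_model = c("poisson_theta", "fixed_s"),
                             s_fixed = NULL) {
  simulate_sample(params, model, mutation_model, s_fixed)
}

#' Sweep scenario for haplotype injection
#'
#' @param core_frequency target derived frequency of the core allele, in
#'   `(0, 1)`.
#' @param sweep_age_generations age of the swept haplotype in generations.
#' @param mutation_noise per-bp mutation probability overlaid on swept
#'   haplotype copies (default 0).
#' @param cm_per_mb genetic-map rate used to convert physical to genetic
#'   distance for the recombination scars (default 1).
#' @return A `sweep_scenario` object.
#' @export
sweep_scenario <- function(core_frequency, sweep_age_generations,
                           mutation_noise = 0, cm_per_mb = 1) {
  stopifnot(core_frequency > 0, core_frequency < 1,
            sweep_age_generations > 0, mutation_noise >= 0)
  structure(list(core_frequency = core_frequency,
                 sweep_age_generations = sweep_age_generations,
                 mutation_noise = mutation_noise, cm_per_mb = cm_per_mb),
            class = "sweep_scenario")
}

#' Inject a partial sweep into a neutral haplotype sample
#'
#' Emulates the haplotype structure left by recent positive selection on a
#' core allele: a fraction `core_frequency` of haplotypes is replaced by
#' copies of one template haplotype carrying a derived core allele. Each
#' copy is truncated on each side of the core at an
#' `Exponential(rate = age)` genetic distance (a recombination scar), beyond
#' which the recipient's own alleles are retained, and optionally overlaid
#' with Poisson mutation noise. The returned truth record makes recovery
#' tests independent of the construction details.
#'
#' @param h a neutral [hap_matrix()].
#' @param scenario a [sweep_scenario()].
#' @param core_site optional core column index; default is the middle site.
#' @return A [hap_matrix()] with attribute `truth`: list with `core_site`,
#'   `core_position`, `carriers`, `age_generations`.
#' @export
inject_sweep <- function(h, scenario, core_site = NULL) {
  stopifnot(inherits(h, "hap_matrix"), inherits(scenario, "sweep_scenario"))
  n <- n_hap(h); m <- n_site(h)
  if (m < 3) stop("need at least 3 sites", call. = FALSE)
  core <- core_site %||% ceiling(m / 2)
  ncar <- round(scenario$core_frequency * n)
  if (ncar < 2 || ncar >= n) {
    stop("requested core frequency unreachable at this sample size",
         call. = FALSE)
  }
  map <- (h$positions - h$positions[1]) * scenario$cm_per_mb / 100 / 1e6

  geno <- h$haplotypes
  # the founder haplotype is taken from a non-carrier row so that every
  # carrier (including the first) genuinely decays away from it
  template <- geno[n, ]
  template[core] <- 1L
  carriers <- seq_len(ncar)
  g <- scenario$sweep_age_generations
  for (i in carriers) {
    recipient <- geno[i, ]
    hap <- recipient
    # genetic distance to the recombination scar on each side
    d_up <- rexp(1, rate = g); d_down <- rexp(1, rate = g)
    within <- abs(map - map[core])
    take <- (map <= map[core] & within <= d_up) |
      (map >= map[core] & within <= d_down)
    hap[take] <- template[take]
    hap[core] <- 1L
    if (scenario$mutation_noise > 0) {
      span <- diff(range(h$positions))
      nmut <- rpois(1, scenario$mutation_noise * span)
      if (nmut > 0) {
        flip <- sample.int(m, min(nmut, m))
        hap[flip] <- 1L - hap[flip]
        hap[core] <- 1L
      }
    }
    geno[i, ] <- hap
  }
  geno[-carriers, core] <- 0L
  out <- hap_matrix(geno, h$positions, site_ids = h$site_ids,
                    sample_ids = h$sample_ids)
  attr(out, "truth") <- list(core_site = core,
                             core_position = h$positions[core],
                             carriers = carriers,
                             age_generations = g,
                             template = template)
  out
}

#' Environmental-effect scenario
#'
#' @param n_populations number of sampled populations.
#' @param n_countries number of countries the populations map onto.
#' @param effect_tau target Kendall correlation between richness and
#'   frequency, in `[-1, 1]`.
#' @param noise_sd standard deviation of frequency noise on the latent
#'   scale (default chosen so that `effect_tau` is achieved approximately).
#' @return An `env_effect_scenario` object.
#' @export
env_effect_scenario <- function(n_populations = 50, n_countries = 21,
                                effect_tau = 0.4, noise_sd = NULL) {
  stopifnot(abs(effect_tau) <= 1, n_populations >= 3, n_countries >= 2)
  structure(list(n_populations = n_populations, n_countries = n_countries,
                 effect_tau = effect_tau, noise_sd = noise_sd),
            class = "env_effect_scenario")
}

#' Generate a frequency table and pathogen matrix with a planted effect
#'
#' Country richness comes from a synthetic pathogen presence/absence matrix
#' with uniform presence probabilities. Population frequencies are a
#' monotone function of the country's richness plus Gaussian noise on a
#' latent scale, calibrated through the Greiner relation
#' `tau = 2 asin(rho) / pi` so that the realised Kendall correlation is
#' approximately `effect_tau`.
#'
#' @param scenario an [env_effect_scenario()].
#' @param n_pathogens pathogens in the synthetic matrix (default 60).
#' @param variant label for the allele/haplotype column.
#' @return List with `freqs` (population frequency tibble), `pathogens`
#'   (a [pathogen_matrix()]), and `truth` (effect sign and strength).
#' @export
generate_env_table <- function(scenario, n_pathogens = 60,
                               variant = "variant1") {
  stopifnot(inherits(scenario, "env_effect_scenario"))
  ncty <- scenario$n_countries
  npop <- scenario$n_populations
  countries <- sprintf("country%02d", seq_len(ncty))
  classes <- sample(c("virus", "bacteria", "protozoa"), n_pathogens,
                    replace = TRUE)
  # heterogeneous per-country presence probabilities induce a richness
  # gradient
  pcountry <- runif(ncty, 0.2, 0.8)
  presence <- matrix(rbinom(n_pathogens * ncty, 1,
                            rep(pcountry, each = n_pathogens)),
                     nrow = n_pathogens,
                     dimnames = list(sprintf("path%03d", seq_len(n_pathogens)),
                                     countries))
  pm <- pathogen_matrix(presence, classes)
  rich <- pathogen_richness(pm)

  pop_country <- countries[((seq_len(npop) - 1) %% ncty) + 1]
  x <- as.numeric(scale(rich[pop_country]))
  if (all(!is.finite(x))) x <- rep(0, npop)
  rho <- sin(pi * scenario$effect_tau / 2)
  z <- rho * x + sqrt(max(0, 1 - rho^2)) * rnorm(npop)
  if (!is.null(scenario$noise_sd)) z <- z + rnorm(npop, 0, scenario$noise_sd)
  freqs <- tibble(
    population = sprintf("pop%03d", seq_len(npop)),
    country = pop_country,
    allele_or_haplotype = variant,
    frequency = pnorm(z))
  list(freqs = freqs, pathogens = pm,
       truth = list(effect_tau = scenario$effect_tau,
                    sign = sign(scenario$effect_tau)))
}

#' Evolve a codon alignment at a known dN/dS
#'
#' Evolves `n_codons` sense codons along a fixed 3-taxon star tree (one
#' focal taxon, two outgroups) under a simple continuous-time codon model:
#' all single-base changes are proposed at equal rates, changes to stop
#' codons are forbidden, and nonsynonymous changes are accepted at relative
#' rate `omega`. Branch lengths are expected numbers of synonymous-scale
#' events per codon.
#'
#' @param n_codons number of codons.
#' @param tree_scale branch length from the root to each tip (expected
#'   substitution opportunities per codon; default 0.3).
#' @param omega true nonsynonymous/synonymous rate ratio (`>= 0`).
#' @return List with `alignment` (a [codon_alignment()] of taxa `focal`,
#'   `out1`, `out2`) and `truth` (`omega`, `tree_scale`).
#' @export
generate_codon_alignment <- function(n_codons, tree_scale = 0.3, omega = 1) {
  stopifnot(n_codons >= 1, omega >= 0, tree_scale >= 0)
  sense <- names(GENCODE)[GENCODE != "*"]
  root <- sample(sense, n_codons, replace = TRUE)
  nbt <- codon_neighbour_table()
  tally <- c(syn = 0L, nonsyn = 0L)

  evolve <- function(codons, t) {
    vapply(codons, function(cod) {
      time <- 0
      repeat {
        # per-codon event rates: syn neighbours at 1, nonsyn at omega
        nb <- nbt[[cod]]
        rates <- ifelse(nb$syn, 1, omega)
        tot <- sum(rates) / 9  # normalise to per-proposal scale
        if (tot <= 0) break
        time <- time + rexp(1, rate = tot)
        if (time > t) break
        pick <- if (length(nb$codon) == 1) 1L else
          sample.int(length(nb$codon), 1, prob = rates)
        tally[if (nb$syn[pick]) "syn" else "nonsyn"] <<-
          tally[if (nb$syn[pick]) "syn" else "nonsyn"] + 1L
        cod <- nb$codon[pick]
      }
      cod
    }, character(1), USE.NAMES = FALSE)
  }

  al <- codon_alignment(c(
    focal = paste(evolve(root, tree_scale), collapse = ""),
    out1 = paste(evolve(root, tree_scale), collapse = ""),
    out2 = paste(evolve(root, tree_scale), collapse = "")))
  list(alignment = al,
       truth = list(omega = omega, tree_scale = tree_scale,
                    n_syn_events = unname(tally["syn"]),
                    n_nonsyn_events = unname(tally["nonsyn"])))
}
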