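#' Simulation parameters for the coalescent engine
#'
#' Mutation and recombination are scaled per bp: `theta_per_bp = 4 Ne mu`,
#' `rho_per_bp = 4 Ne r` (crossover). Gene conversion initiates at
#' `conv_ratio_f * rho_per_bp` per bp with geometric tract lengths of mean
#' `tract_mean` bp.
#'
#' @param n sampled chromosomes (2..64).
#' @param L locus length in bp.
#' @param theta_per_bp population mutation rate per bp.
#' @param rho_per_bp population crossover rate per bp.
#' @param conv_ratio_f conversion-to-crossover ratio (default 2).
#' @param tract_mean mean conversion tract length in bp (default 500).
#' @param reps number of replicates.
#' @return A `sim_params` object.
#' @export
#' @examples
#' sim_params(n = 40, L = 9209, theta_per_bp = 15.83e-4, rho_per_bp = 0.94e-4)
sim_params <- function(n, L, theta_per_bp, rho_per_bp,
                       conv_ratio_f = 2, tract_mean = 500, reps = 1000) {
  stopifnot(n >= 2, n <= 64, L >= 1, reps >= 1, tract_mean >= 1)
  if (any(!is.finite(c(theta_per_bp, rho_per_bp, conv_ratio_f))) ||
      theta_per_bp < 0 || rho_per_bp < 0 || conv_ratio_f < 0) {
    stop("rates must be finite and non-negative", call. = FALSE)
  }
  structure(list(n = as.integer(n), L = L, theta_per_bp = theta_per_bp,
                 rho_per_bp = rho_per_bp, conv_ratio_f = conv_ratio_f,
                 tract_mean = tract_mean, reps = as.integer(reps)),
            class = "sim_params")
}

#' Demographic models for the coalescent null
#'
#' Encodings (time in generations before present, sizes in individuals;
#' internally rescaled to coalescent units of `4 N0` generations, with `N0`
#' the reference size that anchors theta and rho):
#' \describe{
#'   \item{constant}{size `N0` forever.}
#'   \item{recent_expansion}{instantaneous growth from ancestral `N0` to
#'     present `N1` at `t` generations ago; reference is the ancestral `N0`.}
#'   \item{twofold_growth}{exponential growth reaching `2 N0` at present over
#'     the last `t` generations (set `growth = "instant"` to switch);
#'     reference is the ancestral `N0`.}
#'   \item{bottleneck}{size `b * N0` between `t1` and `t0` generations ago
#'     (`t1 <= t0`), `N0` otherwise.}
#'   \item{structure}{`npop` islands of size `N0` each with symmetric scaled
#'     migration `m` (per-lineage rate in units of `4 N0` generations),
#'     sample split evenly.}
#'   \item{best_fit}{a calibrated-African-style preset: instantaneous growth
#'     from `N0 = 12500` to `25000` at 17000 generations ago. A simplified
#'     named preset; see the methods vignette.}
#' }
#'
#' @param name model name (see Details).
#' @param N0 reference effective size.
#' @param N1 post-expansion size (recent_expansion).
#' @param t event time in generations (expansion/growth).
#' @param t0,t1 bottleneck bounds in generations, `t1 <= t0`.
#' @param b bottleneck intensity in `(0, 1]` (size ratio during bottleneck).
#' @param npop number of demes.
#' @param m scaled symmetric migration rate.
#' @param growth `"exponential"` or `"instant"` for twofold_growth.
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(name = c("constant", "recent_expansion",
                                       "twofold_growth", "bottleneck",
                                       "structure", "best_fit"),
                              N0 = 1e4, N1 = 1e7, t = 1000,
                              t0 = 1600, t1 = 1200, b = 0.1,
                              npop = 2, m = 1.0,
                              growth = c("exponential", "instant")) {
  name <- match.arg(name)
  growth <- match.arg(growth)
  stopifnot(N0 > 0, N1 > 0, t >= 0, t0 >= 0, t1 >= 0, t1 <= t0,
            b > 0, b <= 1, npop >= 1, m >= 0)
  structure(list(name = name, N0 = N0, N1 = N1, t = t, t0 = t0, t1 = t1,
                 b = b, npop = as.integer(npop), m = m, growth = growth),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %s\n", x$name))
  invisible(x)
}

# piecewise-constant epochs in 4*N0 units (start times, relative sizes)
model_epochs <- function(model) {
  N0 <- model$N0
  u <- function(g) g / (4 * N0)
  switch(model$name,
    constant = list(start = 0, size = 1),
    recent_expansion = list(start = c(0, u(model$t)),
                            size = c(model$N1 / N0, 1)),
    twofold_growth = {
      if (model$growth == "instant") {
        list(start = c(0, u(model$t)), size = c(2, 1))
      } else {
        # discretise N(tau) = 2 * 2^(-tau/t) into 32 steps
        ns <- 32
        edges <- seq(0, model$t, length.out = ns + 1)
        mid <- (edges[-1] + edges[-(ns + 1)]) / 2
        list(start = c(u(edges[-(ns + 1)]), u(model$t)),
             size = c(2 * 2^(-mid / model$t), 1))
      }
    },
    bottleneck = list(start = c(0, u(model$t1), u(model$t0)),
                      size = c(1, model$b, 1)),
    structure = list(start = 0, size = 1),
    best_fit = list(start = c(0, 17000 / (4 * 12500)), size = c(2, 1))
  )
}

model_reference_N0 <- function(model) {
  if (model$name == "best_fit") 12500 else model$N0
}

run_engine <- function(params, model, fixed_s, return_sets, reps) {
  ep <- model_epochs(model)
  npop <- if (model$name == "structure") model$npop else 1L
  mig <- if (model$name == "structure") model$m else 0
  simulate_coalescent_cpp(
    n = params$n, reps = as.integer(reps),
    theta = params$theta_per_bp * params$L,
    rho = params$rho_per_bp * params$L,
    conv_ratio = params$conv_ratio_f,
    tract_mean_bp = params$tract_mean, L_bp = params$L,
    fixed_s = if (is.null(fixed_s)) -1L else as.integer(fixed_s),
    epoch_start = as.numeric(ep$start), epoch_size = as.numeric(ep$size),
    npop = as.integer(npop), mig = mig, return_sets = return_sets)
}

# map continuous fractions to strictly increasing integer bp in 1..L
fractions_to_bp <- function(frac, L) {
  pos <- floor(frac * L) + 1
  if (length(pos) > 1) {
    for (k in 2:length(pos)) {
      if (pos[k] <= pos[k - 1]) pos[k] <- pos[k - 1] + 1
    }
  }
  pos
}

#' Simulate one neutral sample of phased haplotypes
#'
#' Draws a sample from the ancestral recombination graph under the given
#' demographic model, with crossover, gene conversion and infinite-sites
#' mutation (positions mapped uniformly onto `1..L`).
#'
#' @param params a [sim_params()].
#' @param model a [demographic_model()] (default constant size).
#' @param mutation_model `"poisson_theta"` drops `Poisson(theta)` mutations
#'   on branches; `"fixed_s"` conditions each replicate on exactly `s_fixed`
#'   segregating sites, placed proportionally to branch length.
#' @param s_fixed segregating-site count for `mutation_model = "fixed_s"`.
#' @return A [hap_matrix()] (segregating sites only).
#' @export
simulate_sample <- function(params, model = demographic_model("constant"),
                            mutation_model = c("poisson_theta", "fixed_s"),
                            s_fixed = NULL) {
  mutation_model <- match.arg(mutation_model)
  fixed_s <- if (mutation_model == "fixed_s") {
    if (is.null(s_fixed)) stop("s_fixed required for fixed_s", call. = FALSE)
    s_fixed
  } else NULL
  rep1 <- run_engine(params, model, fixed_s, return_sets = TRUE, reps = 1)[[1]]
  if (length(rep1$positions) == 0) {
    return(hap_matrix(matrix(integer(), nrow = params$n, ncol = 0), numeric()))
  }
  hap_matrix(rep1$genotypes, fractions_to_bp(rep1$positions, params$L))
}

#' Per-replicate derived-allele counts from coalescent simulations
#'
#' Lower-level access to the simulator output: for each replicate, the
#' derived-allele count of every segregating site (the sufficient statistic
#' for frequency-spectrum summaries).
#'
#' @inheritParams simulate_sample
#' @return List of integer vectors, one per replicate.
#' @export
simulate_counts <- function(params, model = demographic_model("constant"),
                            mutation_model = c("poisson_theta", "fixed_s"),
                            s_fixed = NULL) {
  mutation_model <- match.arg(mutation_model)
  fixed_s <- if (mutation_model == "fixed_s") {
    if (is.null(s_fixed)) stop("s_fixed required for fixed_s", call. = FALSE)
    s_fixed
  } else NULL
  sims <- run_engine(params, model, fixed_s, return_sets = FALSE,
                     reps = params$reps)
  lapply(sims, function(x) as.integer(x$counts))
}

#' Per-replicate summary statistics from coalescent simulations
#'
#' Runs `params$reps` replicates and returns S, total and per-bp pi, and
#' Tajima's D for each (D is `NA` where `S = 0`).
#'
#' @inheritParams simulate_sample
#' @return Tibble with `rep, S, pi_total, pi_e4, tajima_d`.
#' @export
simulate_stats <- function(params, model = demographic_model("constant"),
                           mutation_model = c("poisson_theta", "fixed_s"),
                           s_fixed = NULL) {
  mutation_model <- match.arg(mutation_model)
  fixed_s <- if (mutation_model == "fixed_s") {
    if (is.null(s_fixed)) stop("s_fixed required for fixed_s", call. = FALSE)
    s_fixed
  } else NULL
  sims <- run_engine(params, model, fixed_s, return_sets = FALSE,
                     reps = params$reps)
  n <- params$n
  k <- tajima_constants(n)
  res <- purrr::map_dfr(seq_along(sims), function(r) {
    cnt <- sims[[r]]$counts
    cnt <- cnt[cnt > 0 & cnt < n]
    S <- length(cnt)
    pi_total <- sum(2 * cnt * (n - cnt)) / (n * (n - 1))
    D <- if (S == 0) NA_real_ else
      (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    tibble(rep = r, S = S, pi_total = pi_total, tajima_d = D)
  })
  res$pi_e4 <- res$pi_total / params$L * 1e4
  res[, c("rep", "S", "pi_total", "pi_e4", "tajima_d")]
}

#' Null distribution of a summary statistic
#'
#' Simulates replicates under a demographic model and collects one statistic
#' per replicate, sorted ascending. Replicates with `S = 0` contribute no
#' Tajima's D and are excluded from that distribution (count reported).
#'
#' @inheritParams simulate_sample
#' @param statistic `"pi_e4"` (per-bp diversity x 1e4), `"tajima_d"` or `"S"`.
#' @return A `null_distribution` object: sorted `values`, `reps`, `excluded`,
#'   `statistic`, and a parameter digest.
#' @export
null_distribution <- function(params, model = demographic_model("constant"),
                              statistic = c("pi_e4", "tajima_d", "S"),
                              mutation_model = c("poisson_theta", "fixed_s"),
                              s_fixed = NULL) {
  statistic <- match.arg(statistic)
  mutation_model <- match.arg(mutation_model)
  if (params$reps < 100) stop("use at least 100 replicates", call. = FALSE)
  st <- simulate_stats(params, model, mutation_model, s_fixed)
  vals <- st[[statistic]]
  excluded <- sum(is.na(vals))
  vals <- sort(vals[!is.na(vals)])
  if (length(vals) == 0) stop("all replicates uninformative (S = 0)",
                              call. = FALSE)
  structure(list(statistic = statistic, values = vals,
                 reps = params$reps, excluded = excluded,
                 params_digest = paste0(
                   "n=", params$n, ";L=", params$L,
                   ";theta=", signif(params$theta_per_bp, 6),
                   ";rho=", signif(params$rho_per_bp, 6),
                   ";f=", params$conv_ratio_f, ";tract=", params$tract_mean,
                   ";model=", model$name, ";mut=", mutation_model,
                   if (!is.null(s_fixed)) paste0(";S=", s_fixed) else "")),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: %d values (%d excluded)\n  %s\n",
              x$statistic, length(x$values), x$excluded, x$params_digest))
  invisible(x)
}

#' Linear-interpolation percentile of a null distribution
#'
#' @param nd a [null_distribution()].
#' @param q percentile in (0, 100); default 97.5.
#' @return The interpolated quantile.
#' @export
percentile <- function(nd, q = 97.5) {
  stopifnot(inherits(nd, "null_distribution"))
  if (q <= 0 || q >= 100) stop("q must be in (0, 100)", call. = FALSE)
  if (length(nd$values) == 0) stop("empty distribution", call. = FALSE)
  unname(quantile(nd$values, q / 100, type = 7))
}

#' One-sided empirical neutrality test
#'
#' `p = (1 + #\{sim >= obs\}) / (reps + 1)`; the significance flag is whether
#' the observed statistic exceeds the 97.5th percentile of the null.
#'
#' @param observed observed statistic value.
#' @param nd a [null_distribution()].
#' @param statistic name of the observed statistic; must match `nd`.
#' @return Tibble `statistic, observed, p_value, percentile_97_5, significant`.
#' @export
neutrality_test <- function(observed, nd, statistic = nd$statistic) {
  stopifnot(inherits(nd, "null_distribution"))
  if (!identical(statistic, nd$statistic)) {
    stop("statistic name does not match the null distribution", call. = FALSE)
  }
  usable <- length(nd$values)
  p <- (1 + sum(nd$values >= observed)) / (usable + 1)
  p975 <- percentile(nd, 97.5)
  tibble(statistic = statistic, observed = observed, p_value = p,
         percentile_97_5 = p975, significant = observed > p975)
}

#' Write simulated samples as ms-compatible text
#'
#' One `//` block per sample with `segsites:` and `positions:` lines
#' (positions as fractions of the locus) followed by one 0/1 string per
#' haplotype — the text format of the classical coalescent simulators,
#' readable by their downstream tooling.
#'
#' @param samples a [hap_matrix()] or list of them.
#' @param path output file.
#' @param L locus length in bp used to scale positions to `[0, 1)`.
#' @return `path`, invisibly.
#' @export
write_ms <- function(samples, path, L) {
  if (inherits(samples, "hap_matrix")) samples <- list(samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("standscan %d %d", n_hap(samples[[1]]),
                     length(samples)), con)
  writeLines("", con)
  for (h in samples) {
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", n_site(h)), con)
    if (n_site(h) > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", (h$positions - 1) / L),
                             collapse = " ")), con)
      apply(h$haplotypes, 1, function(r)
        writeLines(paste(r, collapse = ""), con))
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(statistic = x$statistic, value = x$values)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble(statistic = x$statistic, reps = x$reps, excluded = x$excluded,
         mean = mean(x$values), sd = stats::sd(x$values),
         p2_5 = unname(quantile(x$values, 0.025)),
         p97_5 = unname(quantile(x$values, 0.975)))
}

#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = percentile(object, 97.5),
                        linetype = "dashed") +
    ggplot2::labs(x = object$statistic, y = "replicates",
                  title = "Coalescent null distribution",
                  subtitle = "dashed: 97.5th percentile") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red3")
  }
  p
}
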