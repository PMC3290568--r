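default_config <- function() {
  list(
    seed = 1L,
    stages = c("synth", "stats", "null", "ld", "ihs", "age", "envcorr",
               "dnds"),
    sim = list(n = 40, L = 9209, theta_per_bp = 15.83e-4,
               rho_per_bp = 0.94e-4, conv_ratio_f = 2, tract_mean = 500,
               reps = 300),
    model = list(name = "constant", N0 = 1e4),
    regions = list(list(label = "full", start = 1, end = 9210,
                        L_surveyed = 9209)),
    ihs = list(min_maf = 0.05, truncation = 0.05, max_gap = 20000),
    age = list(gen_time = 25, mu_per_marker = 2.5e-8, cm_per_mb = 1),
    sweep = list(core_frequency = 0.4, age_generations = 400),
    env = list(n_populations = 42, n_countries = 21, effect_tau = 0.4),
    dnds = list(n_codons = 120, tree_scale = 0.3, omega = 0.5)
  )
}

#' Build or load an analysis configuration
#'
#' Starts from the package defaults and merges overrides from a YAML file
#' and/or a named list (list overrides win over file overrides).
#'
#' @param path optional YAML file.
#' @param overrides optional named list of overrides.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  merge_in <- function(base, extra) {
    for (nm in names(extra)) {
      if (is.list(extra[[nm]]) && is.list(base[[nm]]) &&
          !is.null(names(extra[[nm]]))) {
        base[[nm]] <- merge_in(base[[nm]], extra[[nm]])
      } else {
        base[[nm]] <- extra[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  structure(cfg, class = "analysis_config")
}

#' Validate an analysis configuration
#'
#' Checks constants and referenced paths; errors are returned as a character
#' vector, not raised.
#'
#' @param cfg an [analysis_config()].
#' @return Character vector of problems (length 0 when valid).
#' @export
validate_config <- function(cfg) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  s <- cfg$sim
  if (is.null(s$theta_per_bp) || !is.finite(s$theta_per_bp) ||
      s$theta_per_bp < 0) add("sim.theta_per_bp must be non-negative")
  if (is.null(s$rho_per_bp) || !is.finite(s$rho_per_bp) || s$rho_per_bp < 0)
    add("sim.rho_per_bp must be non-negative")
  if (is.null(s$n) || s$n < 2 || s$n > 64) add("sim.n must be in 2..64")
  if (is.null(s$reps) || s$reps < 1) add("sim.reps must be >= 1")
  for (r in cfg$regions) {
    if (!(r$start < r$end)) add(sprintf("region %s: start must be < end",
                                        r$label))
    if (r$L_surveyed <= 0 || r$L_surveyed > r$end - r$start)
      add(sprintf("region %s: bad L_surveyed", r$label))
  }
  if (!is.null(cfg$input_haplotypes) && !file.exists(cfg$input_haplotypes))
    add(sprintf("missing file: %s", cfg$input_haplotypes))
  if (cfg$age$gen_time <= 0) add("age.gen_time must be positive")
  if (cfg$sweep$core_frequency <= 0 || cfg$sweep$core_frequency >= 1)
    add("sweep.core_frequency must be in (0, 1)")
  unknown <- setdiff(cfg$stages,
                     c("synth", "stats", "null", "ld", "ihs", "age",
                       "envcorr", "dnds"))
  if (length(unknown) > 0) add(paste("unknown stages:",
                                     paste(unknown, collapse = ", ")))
  errs
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order from one
#' configuration, writing each stage's results as TSV files under
#' `out_dir` so every stage is independently re-runnable. A stage failure
#' halts execution and returns the partial report. With no input haplotype
#' file configured, the `synth` stage generates all inputs.
#'
#' @param cfg an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @return A `run_report` tibble: one row per executed stage with its
#'   outputs and timing.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("standscan_run_")) {
  stopifnot(inherits(cfg, "analysis_config"))
  errs <- validate_config(cfg)
  if (length(errs) > 0) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  params <- sim_params(cfg$sim$n, cfg$sim$L, cfg$sim$theta_per_bp,
                       cfg$sim$rho_per_bp, cfg$sim$conv_ratio_f,
                       cfg$sim$tract_mean, cfg$sim$reps)
  model <- do.call(demographic_model, cfg$model)
  report <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    files <- fun()
    report[[name]] <<- tibble(
      stage = name, outputs = paste(basename(files), collapse = ";"),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }

  out <- function(...) file.path(out_dir, paste0(...))

  res <- tryCatch({
    run_stage("synth", function() {
      if (!is.null(cfg$input_haplotypes)) {
        state$h <- read_phased_haplotypes(cfg$input_haplotypes,
                                          cfg$ancestral_map)
      } else {
        state$h <- simulate_sample(params, model)
      }
      f <- out("haplotypes.tsv")
      write_phased_haplotypes(state$h, f)
      sw <- sweep_scenario(cfg$sweep$core_frequency,
                           cfg$sweep$age_generations)
      state$swept <- inject_sweep(state$h, sw)
      f2 <- out("haplotypes_swept.tsv")
      write_phased_haplotypes(state$swept, f2)
      c(f, f2)
    })
    if (is.null(state$h)) {
      state$h <- if (!is.null(cfg$input_haplotypes))
        read_phased_haplotypes(cfg$input_haplotypes, cfg$ancestral_map)
      else simulate_sample(params, model)
    }
    regions <- lapply(cfg$regions, function(r)
      region_spec(r$label, r$start, r$end, r$L_surveyed))

    run_stage("stats", function() {
      tab <- bind_rows(lapply(regions, function(r)
        summarize_region(state$h, r)))
      state$stats <- tab
      f <- out("summary_stats.tsv")
      readr::write_tsv(tab, f)
      f
    })
    run_stage("null", function() {
      nd <- null_distribution(params, model, "tajima_d")
      obs <- if (!is.null(state$stats)) state$stats$tajima_d[1] else
        summarize_region(state$h, regions[[1]])$tajima_d
      tst <- neutrality_test(obs, nd)
      f <- out("neutrality_test.tsv")
      readr::write_tsv(tst, f)
      f
    })
    run_stage("ld", function() {
      m <- ld_matrix(state$h, min_maf = 0.05)
      f <- out("ld_pairs.tsv")
      readr::write_tsv(as_tibble(m), f)
      g <- complete_ld_groups(m)
      f2 <- out("ld_groups.tsv")
      readr::write_tsv(g, f2)
      c(f, f2)
    })
    run_stage("ihs", function() {
      scan <- ihs_scan(state$h, min_maf = cfg$ihs$min_maf,
                       truncation = cfg$ihs$truncation)
      f <- out("ihs_scan.tsv")
      readr::write_tsv(as_tibble(scan), f)
      cl <- cluster_significant(scan, cfg$ihs$max_gap)
      f2 <- out("ihs_clusters.tsv")
      readr::write_tsv(cl, f2)
      c(f, f2)
    })
    run_stage("age", function() {
      swept <- state$swept
      if (is.null(swept)) {
        sw <- sweep_scenario(cfg$sweep$core_frequency,
                             cfg$sweep$age_generations)
        swept <- inject_sweep(state$h, sw)
      }
      tr <- attr(swept, "truth")
      cases <- hap_matrix(
        swept$haplotypes[tr$carriers, , drop = FALSE], swept$positions)
      est <- dhs_tau(cases, tr$core_site,
                     mu_per_marker = cfg$age$mu_per_marker,
                     cm_per_mb = cfg$age$cm_per_mb,
                     gen_time = cfg$age$gen_time, n_boot = 100)
      f <- out("allele_age.tsv")
      readr::write_tsv(tidy(est), f)
      f
    })
    run_stage("envcorr", function() {
      sc <- env_effect_scenario(cfg$env$n_populations, cfg$env$n_countries,
                                cfg$env$effect_tau)
      ev <- generate_env_table(sc)
      rich <- pathogen_richness(ev$pathogens)
      tab <- correlate_frequencies(ev$freqs, rich)
      f <- out("env_correlation.tsv")
      readr::write_tsv(tab, f)
      f
    })
    run_stage("dnds", function() {
      ca <- generate_codon_alignment(cfg$dnds$n_codons, cfg$dnds$tree_scale,
                                     cfg$dnds$omega)
      seqs <- vapply(ca$alignment$codons, paste, character(1),
                     collapse = "")
      dd <- pairwise_dnds(seqs[["focal"]], seqs[["out1"]])
      lc <- lineage_changes(ca$alignment, "focal", c("out1", "out2"))
      f <- out("dnds.tsv")
      readr::write_tsv(dd, f)
      f2 <- out("lineage_changes.tsv")
      readr::write_tsv(lc, f2)
      c(f, f2)
    })
    NULL
  }, error = function(e) e)

  rep_tbl <- bind_rows(report)
  if (nrow(rep_tbl) > 0) {
    rep_tbl$seed <- cfg$seed
    rep_tbl$out_dir <- out_dir
  }
  class(rep_tbl) <- c("run_report", class(rep_tbl))
  if (inherits(res, "error")) {
    warning("pipeline halted: ", conditionMessage(res), call. = FALSE)
    attr(rep_tbl, "error") <- conditionMessage(res)
  }
  rep_tbl
}
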