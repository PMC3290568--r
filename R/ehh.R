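#' Extended haplotype homozygosity around a core site
#'
#' For the carriers of one allele at the core site, EHH at a flanking site is
#' the probability that two randomly drawn carrier haplotypes are identical
#' at every site from the core out to that site:
#' `EHH = sum_g choose(c_g, 2) / choose(c, 2)` over groups `g` of carriers
#' with identical prefixes. EHH is 1 at the core and non-increasing with
#' distance.
#'
#' @param h a [hap_matrix()].
#' @param core column index of the core site (must be segregating).
#' @param allele `"derived"` (carriers have 1) or `"ancestral"`.
#' @param direction `"both"`, `"upstream"` (negative distances) or
#'   `"downstream"`.
#' @param stop_below optional floor: a side's curve is not extended past the
#'   first site where EHH drops below this value (default 0, full curve).
#'   Scan code sets it to the integration truncation level, which leaves
#'   [ihh()] results unchanged while skipping unused flank.
#' @return An `ehh_curve` tibble: `distance` (bp offset from the core,
#'   negative upstream), `position`, `ehh`; attributes `core_position`,
#'   `allele`, `n_carriers`.
#' @export
ehh <- function(h, core, allele = c("derived", "ancestral"),
                direction = c("both", "upstream", "downstream"),
                stop_below = 0) {
  stopifnot(inherits(h, "hap_matrix"))
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  target <- if (allele == "derived") 1L else 0L
  carriers <- which(h$haplotypes[, core] == target)
  cc <- length(carriers)
  if (cc < 2) stop("fewer than 2 carrier haplotypes", call. = FALSE)
  if (cc == n_hap(h)) stop("core site is monomorphic", call. = FALSE)

  side <- function(cols, sign) {
    if (length(cols) == 0) return(tibble(distance = numeric(),
                                         position = numeric(),
                                         ehh = numeric()))
    grp <- rep(1L, cc)
    vals <- numeric(length(cols))
    used <- length(cols)
    for (k in seq_along(cols)) {
      a <- h$haplotypes[carriers, cols[k]]
      grp <- as.integer(factor(grp * 2L + a))
      tab <- tabulate(grp)
      vals[k] <- sum(tab * (tab - 1) / 2) / (cc * (cc - 1) / 2)
      if (vals[k] < stop_below) { used <- k; break }
    }
    cols <- cols[seq_len(used)]
    tibble(distance = sign * abs(h$positions[cols] - h$positions[core]),
           position = h$positions[cols], ehh = vals[seq_len(used)])
  }

  up <- if (direction %in% c("both", "upstream"))
    side(rev(seq_len(core - 1)), -1) else NULL
  down <- if (direction %in% c("both", "downstream"))
    side(seq_len(n_site(h))[-seq_len(core)], 1) else NULL
  out <- bind_rows(
    if (!is.null(up)) arrange(up, .data$distance),
    tibble(distance = 0, position = h$positions[core], ehh = 1),
    down
  )
  attr(out, "core_position") <- h$positions[core]
  attr(out, "allele") <- allele
  attr(out, "n_carriers") <- cc
  class(out) <- c("ehh_curve", class(out))
  out
}

# integrate one side (distances >= 0, ehh starting at 1) by trapezoids,
# stopping at the interpolated crossing of the truncation level
integrate_side <- function(dist, val, truncation) {
  dist <- c(0, dist); val <- c(1, val)
  total <- 0
  edge <- TRUE
  for (k in seq_len(length(dist) - 1)) {
    d0 <- dist[k]; d1 <- dist[k + 1]
    v0 <- val[k]; v1 <- val[k + 1]
    if (v1 < truncation) {
      dcross <- d0 + (d1 - d0) * (v0 - truncation) / (v0 - v1)
      total <- total + (v0 + truncation) / 2 * (dcross - d0)
      edge <- FALSE
      break
    }
    total <- total + (v0 + v1) / 2 * (d1 - d0)
  }
  list(value = total, edge = edge)
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of an EHH curve over physical distance on each side
#' of the core, truncated where EHH first falls below `truncation`
#' (interpolated crossing); sides are summed. If a side reaches the edge of
#' the data before the truncation level, the value carries an edge flag.
#'
#' @param curve an [ehh()] curve.
#' @param truncation EHH floor (default 0.05).
#' @return List with `value` (bp) and `edge` (logical).
#' @export
ihh <- function(curve, truncation = 0.05) {
  stopifnot(inherits(curve, "ehh_curve"))
  up <- curve[curve$distance < 0, ]
  down <- curve[curve$distance > 0, ]
  u <- integrate_side(abs(rev(up$distance)), rev(up$ehh), truncation)
  d <- integrate_side(down$distance, down$ehh, truncation)
  # reversed upstream rows are ordered nearest-first after rev()
  list(value = u$value + d$value, edge = u$edge || d$edge)
}

#' Unstandardised iHS at one site
#'
#' `ln(iHH_ancestral / iHH_derived)`: negative scores mean unusually long
#' shared haplotypes around the derived allele, the hallmark of a recent
#' partial sweep.
#'
#' @param h a [hap_matrix()].
#' @param core core site index.
#' @param truncation EHH floor passed to [ihh()].
#' @param min_carriers minimum carriers per allele class (default 2).
#' @return List with `ihs_unstd`, `ihh_a`, `ihh_d`, `daf`, `edge`; values are
#'   `NA` when an allele class is degenerate.
#' @export
ihs_unstandardized <- function(h, core, truncation = 0.05, min_carriers = 2) {
  cnt <- sum(h$haplotypes[, core])
  n <- n_hap(h)
  daf <- cnt / n
  if (cnt < min_carriers || (n - cnt) < min_carriers) {
    return(list(ihs_unstd = NA_real_, ihh_a = NA_real_, ihh_d = NA_real_,
                daf = daf, edge = NA))
  }
  ia <- ihh(ehh(h, core, "ancestral", stop_below = truncation), truncation)
  id <- ihh(ehh(h, core, "derived", stop_below = truncation), truncation)
  if (ia$value <= 0 || id$value <= 0) {
    return(list(ihs_unstd = NA_real_, ihh_a = ia$value, ihh_d = id$value,
                daf = daf, edge = ia$edge || id$edge))
  }
  list(ihs_unstd = log(ia$value / id$value), ihh_a = ia$value,
       ihh_d = id$value, daf = daf, edge = ia$edge || id$edge)
}

#' iHS scan over all eligible sites
#'
#' Computes the unstandardised iHS at every site passing the minor-allele
#' frequency floor, then optionally standardises within derived-allele
#' frequency bins.
#'
#' @param h a [hap_matrix()].
#' @param min_maf minor allele frequency floor (default 0.05).
#' @param truncation EHH floor (default 0.05).
#' @param standardize if `TRUE` (default), apply [standardize_ihs()].
#' @param n_bins DAF bins for standardisation.
#' @return An `ihs_scan` tibble: `site, position, daf, ihh_a, ihh_d,
#'   ihs_unstd, edge` and, when standardised, `ihs_std, significant`.
#' @export
ihs_scan <- function(h, min_maf = 0.05, truncation = 0.05,
                     standardize = TRUE, n_bins = 20) {
  stopifnot(inherits(h, "hap_matrix"))
  n <- n_hap(h)
  p <- colSums(h$haplotypes) / n
  eligible <- which(pmin(p, 1 - p) >= min_maf & p > 0 & p < 1)
  res <- purrr::map_dfr(eligible, function(s) {
    r <- ihs_unstandardized(h, s, truncation)
    tibble(site = s, position = h$positions[s], daf = r$daf,
           ihh_a = r$ihh_a, ihh_d = r$ihh_d, ihs_unstd = r$ihs_unstd,
           edge = isTRUE(r$edge))
  })
  if (nrow(res) == 0) {
    res <- tibble(site = integer(), position = numeric(), daf = numeric(),
                  ihh_a = numeric(), ihh_d = numeric(),
                  ihs_unstd = numeric(), edge = logical())
  }
  if (standardize && nrow(res) > 0) {
    std <- standardize_ihs(res$ihs_unstd, res$daf, n_bins = n_bins,
                           exclude = res$edge)
    res$ihs_std <- std$ihs_std
    res$significant <- std$significant
  }
  class(res) <- c("ihs_scan", class(res))
  res
}

#' Standardise iHS scores within derived-allele-frequency bins
#'
#' Within each of `n_bins` equal-width DAF bins, subtracts the bin mean and
#' divides by the bin standard deviation, so that standardised scores are
#' comparable across frequencies. Sites in bins with fewer than two usable
#' scores, excluded sites, and missing scores get `NA`.
#'
#' @param scores unstandardised iHS values.
#' @param dafs derived allele frequencies, same length.
#' @param n_bins number of equal-width bins over `[0.05, 0.95]` (default 20);
#'   frequencies outside the range fall into the end bins.
#' @param exclude logical vector: sites to exclude from bin moments and to
#'   leave unstandardised (e.g. edge-truncated curves).
#' @param threshold significance threshold on `|ihs_std|` (default 2, the
#'   genome-wide top-5 percent convention).
#' @return Tibble `ihs_std, bin, significant`.
#' @export
standardize_ihs <- function(scores, dafs, n_bins = 20,
                            exclude = rep(FALSE, length(scores)),
                            threshold = 2) {
  stopifnot(length(scores) == length(dafs))
  breaks <- seq(0.05, 0.95, length.out = n_bins + 1)
  bin <- findInterval(dafs, breaks, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  bin[bin > n_bins] <- n_bins
  usable <- !exclude & !is.na(scores)
  out <- rep(NA_real_, length(scores))
  for (b in unique(bin)) {
    inb <- usable & bin == b
    if (sum(inb) < 2) next
    mu <- mean(scores[inb])
    sdv <- stats::sd(scores[inb])
    if (sdv == 0) next
    out[inb] <- (scores[inb] - mu) / sdv
  }
  tibble(ihs_std = out, bin = bin,
         significant = !is.na(out) & abs(out) > threshold)
}

#' Cluster significant iHS sites along the chromosome
#'
#' Maximal runs of significant sites in which consecutive significant sites
#' are separated by at most `max_gap` bp.
#'
#' @param scan an [ihs_scan()] tibble with `position` and `significant`.
#' @param max_gap maximum inter-site gap in bp within a cluster.
#' @return Tibble `cluster, start, end, n_sites`.
#' @export
cluster_significant <- function(scan, max_gap) {
  stopifnot(all(c("position", "significant") %in% names(scan)))
  pos <- sort(scan$position[which(scan$significant)])
  if (length(pos) == 0) {
    return(tibble(cluster = integer(), start = numeric(), end = numeric(),
                  n_sites = integer()))
  }
  brk <- c(0, cumsum(diff(pos) > max_gap))
  tibble(position = pos, cluster = as.integer(brk) + 1L) |>
    group_by(.data$cluster) |>
    summarise(start = min(.data$position), end = max(.data$position),
              n_sites = dplyr::n(), .groups = "drop")
}

#' Empirical gene-level enrichment p-value
#'
#' Compares the observed fraction of significant SNPs in a gene with the
#' fractions observed in comparable background units:
#' `p = (1 + #\{background >= observed\}) / (length(background) + 1)`.
#'
#' @param observed_fraction observed significant fraction.
#' @param background numeric vector of background fractions.
#' @return Empirical p-value.
#' @export
gene_enrichment_p <- function(observed_fraction, background) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  (1 + sum(background >= observed_fraction)) / (length(background) + 1)
}

#' @export
autoplot.ehh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$ehh)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from core (bp)", y = "EHH",
                  title = sprintf("EHH decay (%s allele, %d carriers)",
                                  attr(object, "allele"),
                                  attr(object, "n_carriers"))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ihs_scan <- function(object, threshold = 2, ...) {
  if (!"ihs_std" %in% names(object)) {
    stop("scan is not standardised; rerun with standardize = TRUE",
         call. = FALSE)
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$ihs_std,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "position (bp)", y = "standardised iHS") +
    ggplot2::theme_minimal()
}
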