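#' Phased haplotype matrix
#'
#' The carrier object passed between all pipeline stages: an `n_hap x n_site`
#' 0/1 matrix of phased haplotypes over biallelic SNPs, where 0 is the
#' ancestral and 1 the derived allele (polarised against an outgroup), with
#' strictly increasing 1-based chromosomal positions.
#'
#' @param haplotypes integer/numeric matrix with entries in `{0, 1}`; rows are
#'   chromosomes, columns are sites.
#' @param positions integer vector of 1-based bp coordinates, strictly
#'   increasing, one per column.
#' @param site_ids optional character vector of site identifiers (e.g. rsIDs).
#' @param sample_ids optional character vector of chromosome labels.
#'
#' @return An object of class `hap_matrix`.
#' @export
#' @examples
#' h <- hap_matrix(rbind(c(0, 1), c(1, 1), c(0, 0), c(0, 1)),
#'                 positions = c(120, 340))
#' n_hap(h)
#' segregating_sites(h)
hap_matrix <- function(haplotypes, positions, site_ids = NULL,
                       sample_ids = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(haplotypes) != length(positions)) {
    stop("number of columns must equal length(positions)", call. = FALSE)
  }
  if (length(positions) > 0 && any(!is.finite(positions))) {
    stop("positions must be finite", call. = FALSE)
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype entries must all be 0 (ancestral) or 1 (derived)",
         call. = FALSE)
  }
  if (!is.null(site_ids) && length(site_ids) != length(positions)) {
    stop("site_ids must match the number of sites", call. = FALSE)
  }
  if (!is.null(sample_ids) && length(sample_ids) != nrow(haplotypes)) {
    stop("sample_ids must match the number of haplotypes", call. = FALSE)
  }
  structure(
    list(haplotypes = haplotypes, positions = positions,
         site_ids = site_ids, sample_ids = sample_ids),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d haplotypes x %d sites", n_hap(x), n_site(x)))
  if (n_site(x) > 0) {
    cat(sprintf(", positions %s-%s", format(min(x$positions), big.mark = ","),
                format(max(x$positions), big.mark = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Dimensions of a haplotype matrix
#' @param h a [hap_matrix()].
#' @return integer scalar.
#' @export
n_hap <- function(h) nrow(h$haplotypes)

#' @rdname n_hap
#' @export
n_site <- function(h) ncol(h$haplotypes)

#' Tidy per-site summary of a haplotype matrix
#'
#' @param x a [hap_matrix()].
#' @param ... unused.
#' @return A tibble with one row per site: `position`, `site_id`,
#'   `derived_count`, `derived_freq`.
#' @export
tidy.hap_matrix <- function(x, ...) {
  cnt <- colSums(x$haplotypes)
  tibble(
    position = x$positions,
    site_id = x$site_ids %||% NA_character_,
    derived_count = as.integer(cnt),
    derived_freq = cnt / n_hap(x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Region of a surveyed locus
#'
#' Regions are half-open `[start, end)` intervals in 1-based chromosomal
#' coordinates. `L_surveyed` is the number of base pairs actually sequenced
#' within the region; per-bp statistics divide by it, never by the region
#' span, so it must be supplied explicitly.
#'
#' @param label region name.
#' @param start,end region bounds in bp, `start < end`; `end` exclusive.
#' @param L_surveyed surveyed length in bp, `<= end - start`.
#' @return A `region_spec` object.
#' @export
#' @examples
#' region_spec("Region I", 100, 8000, L_surveyed = 7675)
region_spec <- function(label, start, end, L_surveyed = end - start) {
  stopifnot(is.character(label), length(label) == 1)
  if (!(start < end)) stop("start must be < end", call. = FALSE)
  if (L_surveyed > end - start || L_surveyed <= 0) {
    stop("L_surveyed must be positive and at most end - start", call. = FALSE)
  }
  structure(list(label = label, start = start, end = end,
                 L_surveyed = L_surveyed),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s [%s, %s), L_surveyed = %s bp\n", x$label,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$L_surveyed, big.mark = ",")))
  invisible(x)
}

#' Restrict a haplotype matrix to a region
#'
#' Keeps the sites with `start <= position < end`, preserving order.
#'
#' @param h a [hap_matrix()].
#' @param region a [region_spec()].
#' @return A [hap_matrix()] over the retained sites.
#' @export
restrict_to_region <- function(h, region) {
  stopifnot(inherits(h, "hap_matrix"), inherits(region, "region_spec"))
  keep <- h$positions >= region$start & h$positions < region$end
  if (!any(keep)) {
    stop(sprintf("no sites in region '%s'", region$label), call. = FALSE)
  }
  hap_matrix(h$haplotypes[, keep, drop = FALSE], h$positions[keep],
             site_ids = h$site_ids[keep], sample_ids = h$sample_ids)
}

#' Per-site functional annotations
#'
#' @param position bp coordinates.
#' @param functional_class one of `"nonsynonymous"`, `"synonymous"`,
#'   `"noncoding"`, `"nonsense"` per site.
#' @param ancestral_allele,derived_allele single bases; must differ per site.
#' @param ihs_significant optional logical flag per site.
#' @return A tibble of class `site_annotation`.
#' @export
site_annotation <- function(position, functional_class,
                            ancestral_allele, derived_allele,
                            ihs_significant = FALSE) {
  classes <- c("nonsynonymous", "synonymous", "noncoding", "nonsense")
  if (!all(functional_class %in% classes)) {
    stop("functional_class must be one of: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (any(toupper(ancestral_allele) == toupper(derived_allele))) {
    stop("ancestral and derived alleles must differ", call. = FALSE)
  }
  out <- tibble(
    position = as.numeric(position),
    functional_class = functional_class,
    ancestral_allele = toupper(ancestral_allele),
    derived_allele = toupper(derived_allele),
    ihs_significant = rep_len(ihs_significant, length(position))
  )
  class(out) <- c("site_annotation", class(out))
  out
}
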