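GENCODE <- NULL  # standard genetic code, filled at load

.onLoad <- function(libname, pkgname) {
  GENCODE <<- as.character(Biostrings::GENETIC_CODE)
  names(GENCODE) <<- names(Biostrings::GENETIC_CODE)
}

translate_codon <- function(codon) unname(GENCODE[codon])

is_stop <- function(codon) !is.na(GENCODE[codon]) && GENCODE[codon] == "*"

# sense-codon single-base neighbour lists (stops excluded), built once
.codon_cache <- new.env(parent = emptyenv())

codon_neighbour_table <- function() {
  if (!is.null(.codon_cache$nbt)) return(.codon_cache$nbt)
  sense <- names(GENCODE)[GENCODE != "*"]
  nbt <- lapply(sense, function(cod) {
    aa <- translate_codon(cod)
    nb <- character(0); syn <- logical(0)
    for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"),
                                       substr(cod, p, p))) {
      mut <- cod
      substr(mut, p, p) <- alt
      if (is_stop(mut)) next
      nb <- c(nb, mut)
      syn <- c(syn, translate_codon(mut) == aa)
    }
    list(codon = nb, syn = syn)
  })
  names(nbt) <- sense
  .codon_cache$nbt <- nbt
  nbt
}

#' Codon alignment
#'
#' Equal-length in-frame coding sequences over ACGT. Codon columns that
#' contain a non-ACGT character (gap, ambiguity) in any taxon are dropped
#' and counted in the `dropped_codons` attribute.
#'
#' @param seqs named character vector of aligned coding sequences, lengths
#'   equal and divisible by 3.
#' @return A `codon_alignment` object (list of per-taxon codon vectors).
#' @export
codon_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences must be aligned to equal length",
                                      call. = FALSE)
  if (lens[1] %% 3 != 0) stop("alignment length must be divisible by 3",
                              call. = FALSE)
  ncod <- lens[1] / 3
  codons <- lapply(seqs, function(s) {
    substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  })
  clean <- Reduce(`&`, lapply(codons, function(cv) grepl("^[ACGT]{3}$", cv)))
  dropped <- sum(!clean)
  codons <- lapply(codons, function(cv) cv[clean])
  structure(list(taxa = names(seqs), codons = codons,
                 n_codons = sum(clean)),
            class = "codon_alignment", dropped_codons = dropped)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codons\n",
              length(x$taxa), x$n_codons))
  invisible(x)
}

#' Expected synonymous and nonsynonymous sites of a codon (NG86)
#'
#' For each codon position, the synonymous fraction is the proportion of
#' single-base changes to sense codons that preserve the amino acid; changes
#' to stop codons are excluded from the denominator. Site counts sum the
#' fractions over the three positions, so `n_sites + s_sites = 3`.
#'
#' @param codon a 3-letter ACGT string; must be a sense codon.
#' @return List `n_sites, s_sites`.
#' @export
#' @examples
#' count_sites_ng86("TTT")  # s_sites = 1/3
count_sites_ng86 <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("not an ACGT codon", call. = FALSE)
  if (is_stop(codon)) stop("stop codon: excluded from site counting",
                           call. = FALSE)
  aa <- translate_codon(codon)
  s <- 0
  for (p in 1:3) {
    base <- substr(codon, p, p)
    syn <- 0; valid <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (is_stop(mut)) next
      valid <- valid + 1
      if (translate_codon(mut) == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  list(n_sites = 3 - s, s_sites = s)
}

# enumerate minimal mutational pathways between two codons, discarding any
# passing through a stop; returns average (syn, nonsyn) step counts
codon_path_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1) list(pos) else {
    idx <- if (k == 2) list(1:2, 2:1) else
      list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
           c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(o) pos[o])
  }
  acc <- c(syn = 0, nonsyn = 0)
  nok <- 0
  for (order in perms) {
    cur <- a
    steps <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (is_stop(nxt)) { ok <- FALSE; break }
      if (translate_codon(nxt) == translate_codon(cur)) {
        steps["syn"] <- steps["syn"] + 1
      } else {
        steps["nonsyn"] <- steps["nonsyn"] + 1
      }
      cur <- nxt
    }
    if (ok) { acc <- acc + steps; nok <- nok + 1 }
  }
  if (nok == 0) return(c(syn = NA_real_, nonsyn = NA_real_))
  acc / nok
}

#' Pairwise counting-based dN/dS (NG86)
#'
#' Expected sites are averaged over the two sequences; observed synonymous
#' and nonsynonymous differences average over all minimal mutational
#' pathways through sense codons; proportions receive the Jukes-Cantor
#' correction `d = -3/4 log(1 - 4p/3)`. Codons containing a stop in either
#' sequence, or connected only through stop codons, are excluded and
#' reported in `flagged_codons` (they carry a pseudogenisation signal, not a
#' rate).
#'
#' @param a,b equal-length in-frame ACGT coding sequences.
#' @return A `dnds_result` one-row tibble: `n_codons, N_sites, S_sites, Nd,
#'   Sd, pN, pS, dN, dS, omega, flagged_codons` plus an `omega_defined`
#'   logical (`FALSE` when `dS = 0` or a correction is undefined).
#' @export
pairwise_dnds <- function(a, b) {
  al <- codon_alignment(c(seq_a = a, seq_b = b))
  ca <- al$codons[[1]]; cb <- al$codons[[2]]
  flagged <- which(vapply(ca, is_stop, logical(1)) |
                     vapply(cb, is_stop, logical(1)))
  keep <- setdiff(seq_along(ca), flagged)
  Nsum <- 0; Ssum <- 0; Nd <- 0; Sd <- 0
  path_flagged <- integer()
  for (i in keep) {
    sa <- count_sites_ng86(ca[i]); sb <- count_sites_ng86(cb[i])
    dd <- codon_path_diffs(ca[i], cb[i])
    if (anyNA(dd)) { path_flagged <- c(path_flagged, i); next }
    Nsum <- Nsum + (sa$n_sites + sb$n_sites) / 2
    Ssum <- Ssum + (sa$s_sites + sb$s_sites) / 2
    Nd <- Nd + dd["nonsyn"]; Sd <- Sd + dd["syn"]
  }
  pN <- if (Nsum > 0) Nd / Nsum else NA_real_
  pS <- if (Ssum > 0) Sd / Ssum else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)  # correction undefined
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN); dS <- jc(pS)
  omega_defined <- !is.na(dN) && !is.na(dS) && dS > 0
  out <- tibble(
    n_codons = length(keep) - length(path_flagged),
    N_sites = unname(Nsum), S_sites = unname(Ssum),
    Nd = unname(Nd), Sd = unname(Sd), pN = unname(pN), pS = unname(pS),
    dN = unname(dN), dS = unname(dS),
    omega = if (omega_defined) dN / dS else NA_real_,
    omega_defined = omega_defined,
    flagged_codons = length(flagged) + length(path_flagged))
  class(out) <- c("dnds_result", class(out))
  out
}

#' Assign codon changes to a focal lineage by strict-consensus parsimony
#'
#' For each codon: if at least two outgroups are informative and all agree,
#' their shared codon is the inferred ancestral state; a differing focal
#' codon is then a change on the focal lineage. Disagreeing outgroups leave
#' the codon `ambiguous`; fewer than two informative outgroups leave it
#' `unassigned`.
#'
#' @param alignment a [codon_alignment()].
#' @param focal focal taxon name.
#' @param outgroups two or more outgroup taxon names.
#' @return Tibble: `codon, ancestral, focal, n_steps, aa_ancestral,
#'   aa_focal, status` (`"change"`, `"no_change"`, `"ambiguous"`,
#'   `"unassigned"`).
#' @export
lineage_changes <- function(alignment, focal, outgroups) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (length(outgroups) < 2) stop("need at least 2 outgroups", call. = FALSE)
  if (!all(c(focal, outgroups) %in% alignment$taxa)) {
    stop("taxa not in alignment", call. = FALSE)
  }
  fc <- alignment$codons[[focal]]
  oc <- do.call(rbind, alignment$codons[outgroups])
  purrr::map_dfr(seq_along(fc), function(i) {
    og <- oc[, i]
    og <- og[grepl("^[ACGT]{3}$", og)]
    if (length(og) < 2) {
      status <- "unassigned"; anc <- NA_character_; steps <- NA_integer_
    } else if (length(unique(og)) > 1) {
      status <- "ambiguous"; anc <- NA_character_; steps <- NA_integer_
    } else {
      anc <- unname(og[1])
      if (anc == fc[i]) {
        status <- "no_change"; steps <- 0L
      } else {
        status <- "change"
        steps <- sum(strsplit(anc, "")[[1]] != strsplit(fc[i], "")[[1]])
      }
    }
    tibble(codon = i, ancestral = anc, focal = fc[i],
           n_steps = steps,
           aa_ancestral = if (!is.na(anc)) translate_codon(anc) else
             NA_character_,
           aa_focal = translate_codon(fc[i]), status = status)
  })
}

#' Classify an omega (dN/dS) value
#'
#' Values below `1 - band` indicate purifying selection, above `1 + band`
#' positive selection, within the band (approximately) neutral evolution;
#' missing values propagate as `"undefined"`.
#'
#' @param omega dN/dS value(s).
#' @param band half-width of the neutrality band around 1 (default 0).
#' @return Character vector in
#'   `{"purifying", "neutral", "positive", "undefined"}`.
#' @export
#' @examples
#' classify_omega(c(0.36, 1, 47.8, NA))
classify_omega <- function(omega, band = 0) {
  vapply(omega, function(w) {
    if (is.na(w)) "undefined"
    else if (w < 1 - band) "purifying"
    else if (w > 1 + band) "positive"
    else "neutral"
  }, character(1))
}
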