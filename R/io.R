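#' Read phased haplotypes from a text table
#'
#' Supports two dialects. The phased dialect has two header lines (tab
#' separated): site identifiers, then bp positions; each following line is one
#' chromosome, `sample_id` then one base per site. The 0/1 dialect has a
#' single header of positions and rows of 0/1 codes (already polarised), with
#' an optional leading `sample_id` column.
#'
#' For the phased dialect, alleles are recoded so that 0 is the ancestral
#' allele given in `ancestral_map`. Sites whose map entry is missing, or whose
#' ancestral base matches neither observed allele, are dropped; the dropped
#' positions are recorded in the `"dropped_sites"` attribute. Monomorphic
#' sites are retained (they are excluded per-statistic downstream).
#'
#' @param path file path.
#' @param ancestral_map named character vector, `position -> ancestral base`
#'   (names are bp positions). Required for the phased dialect.
#' @return A [hap_matrix()] with attribute `dropped_sites` (tibble of
#'   position and reason).
#' @export
read_phased_haplotypes <- function(path, ancestral_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("file too short", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(fields)

  first <- fields[[1]]
  is_base_dialect <- suppressWarnings(all(is.na(as.numeric(first))))
  # phased dialect: line 1 rsIDs, line 2 positions, rows of bases
  if (is_base_dialect) {
    site_ids <- first
    positions <- suppressWarnings(as.numeric(fields[[2]]))
    if (anyNA(positions)) stop("second header line must be positions",
                               call. = FALSE)
    body <- fields[-(1:2)]
    if (any(lengths(body) != length(positions) + 1)) {
      stop("format error: unequal row lengths", call. = FALSE)
    }
    sample_ids <- vapply(body, `[[`, character(1), 1)
    alle <- toupper(do.call(rbind, lapply(body, function(f) f[-1])))
    if (is.null(ancestral_map)) {
      stop("ancestral_map is required for the phased base dialect",
           call. = FALSE)
    }
    anc <- toupper(unname(ancestral_map[as.character(positions)]))
    keep <- logical(length(positions))
    reason <- character(length(positions))
    code <- matrix(0L, nrow(alle), ncol(alle))
    for (j in seq_along(positions)) {
      obs <- unique(alle[, j])
      if (is.na(anc[j])) {
        reason[j] <- "no ancestral state in map"
      } else if (!(anc[j] %in% obs) && length(obs) > 1) {
        reason[j] <- "ancestral base matches neither allele"
      } else if (!(anc[j] %in% obs)) {
        reason[j] <- "ancestral base matches neither allele"
      } else {
        keep[j] <- TRUE
        code[, j] <- as.integer(alle[, j] != anc[j])
      }
    }
    dropped <- tibble(position = positions[!keep], reason = reason[!keep])
    if (nrow(dropped) > 0) {
      warning(sprintf("%d site(s) dropped during polarisation", nrow(dropped)),
              call. = FALSE)
    }
    h <- hap_matrix(code[, keep, drop = FALSE], positions[keep],
                    site_ids = site_ids[keep], sample_ids = sample_ids)
    attr(h, "dropped_sites") <- dropped
    return(h)
  }

  # 0/1 dialect: header of positions, rows of codes
  positions <- suppressWarnings(as.numeric(first))
  body <- fields[-1]
  has_label <- all(lengths(body) == length(positions) + 1)
  if (!has_label && any(lengths(body) != length(positions))) {
    stop("format error: unequal row lengths", call. = FALSE)
  }
  sample_ids <- NULL
  if (has_label) {
    sample_ids <- vapply(body, `[[`, character(1), 1)
    body <- lapply(body, function(f) f[-1])
  }
  code <- do.call(rbind, lapply(body, as.integer))
  h <- hap_matrix(code, positions, sample_ids = sample_ids)
  attr(h, "dropped_sites") <- tibble(position = numeric(), reason = character())
  h
}

#' Write a haplotype matrix in the 0/1 table dialect
#'
#' Round-trips with [read_phased_haplotypes()].
#'
#' @param h a [hap_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_haplotypes <- function(h, path) {
  stopifnot(inherits(h, "hap_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h$positions, collapse = "\t"), con)
  ids <- h$sample_ids %||% paste0("hap", seq_len(n_hap(h)))
  for (i in seq_len(n_hap(h))) {
    writeLines(paste(c(ids[i], h$haplotypes[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; labels are preserved. Duplicate labels are an
#' error.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  labs <- names(seqs)
  if (anyDuplicated(labs)) {
    stop("duplicate sequence labels in FASTA", call. = FALSE)
  }
  setNames(toupper(as.character(seqs)), labs)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), as.character(seqs[i])), con)
  }
  invisible(path)
}

#' Read phased biallelic SNPs from a minimal VCF
#'
#' Only biallelic SNP records with fully phased GT fields are used; indels
#' and multiallelic records are skipped and counted. An unphased genotype is
#' an error naming the offending record. Alleles are polarised against the
#' INFO ancestral-allele tag; records whose ancestral base matches neither
#' REF nor ALT (or lacks the tag) are dropped and counted.
#'
#' @param path VCF file (v4.x, GT-only is sufficient).
#' @param ancestral_tag INFO key holding the ancestral base (default `"AA"`).
#' @return A [hap_matrix()] with two rows per sample and attribute
#'   `dropped_sites`.
#' @export
read_vcf_minimal <- function(path, ancestral_tag = "AA") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF has no genotype columns",
                                        call. = FALSE)
  samples <- colnames(gt)[-1]

  ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
  pos <- as.numeric(fix$POS)
  is_snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)

  keep_idx <- which(is_snp)
  rows <- list(); positions <- numeric(); ids <- character()
  dropped <- list()
  for (k in keep_idx) {
    gts <- sub(":.*$", "", gt[k, -1])
    if (any(grepl("/", gts, fixed = TRUE))) {
      bad <- samples[grepl("/", gts, fixed = TRUE)][1]
      stop(sprintf("unphased genotype at %s:%s (sample %s)",
                   fix$CHROM[k], fix$POS[k], bad), call. = FALSE)
    }
    parts <- strsplit(gts, "|", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop(sprintf("genotype at %s:%s is not diploid phased",
                   fix$CHROM[k], fix$POS[k]), call. = FALSE)
    }
    alleles <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(alleles)) {
      dropped[[length(dropped) + 1]] <-
        tibble(position = pos[k], reason = "missing genotype call")
      next
    }
    aa <- NA_character_
    info <- fix$INFO[k]
    m <- regmatches(info, regexec(paste0("(?:^|;)", ancestral_tag, "=([ACGTacgt])"),
                                  info))[[1]]
    if (length(m) == 2) aa <- toupper(m[2])
    if (is.na(aa)) {
      dropped[[length(dropped) + 1]] <-
        tibble(position = pos[k], reason = "no ancestral state")
      next
    }
    if (aa == ref[k]) {
      code <- alleles
    } else if (aa == alt[k]) {
      code <- 1L - alleles
    } else {
      dropped[[length(dropped) + 1]] <-
        tibble(position = pos[k], reason = "ancestral base matches neither allele")
      next
    }
    rows[[length(rows) + 1]] <- code
    positions <- c(positions, pos[k])
    ids <- c(ids, if (!is.na(fix$ID[k]) && fix$ID[k] != ".") fix$ID[k]
             else paste0("site", pos[k]))
  }
  if (length(rows) == 0) stop("no usable biallelic phased SNPs", call. = FALSE)
  geno <- do.call(cbind, rows)  # (2*nsample) x nsite
  hap_ids <- as.vector(t(outer(samples, c("_A", "_B"), paste0)))
  ord <- order(positions)
  h <- hap_matrix(geno[, ord, drop = FALSE], positions[ord],
                  site_ids = ids[ord], sample_ids = hap_ids)
  dropped <- if (length(dropped)) bind_rows(dropped) else
    tibble(position = numeric(), reason = character())
  attr(h, "dropped_sites") <- dropped
  attr(h, "n_skipped_records") <- n_skipped
  h
}
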