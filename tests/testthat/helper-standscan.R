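# shared fixtures and independent brute-force oracles

toy_hap <- function(mat, pos = NULL) {
  mat <- as.matrix(mat)
  hap_matrix(mat, pos %||% (seq_len(ncol(mat)) * 10))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_hap <- function(n = 12, m = 8, pos = sort(sample(1e5, m))) {
  mat <- matrix(rbinom(n * m, 1, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                        each = n)]),
                nrow = n)
  hap_matrix(mat, pos)
}

# pi by explicit enumeration of all pairs
brute_pi <- function(h, L) {
  g <- h$haplotypes
  n <- nrow(g)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(g[i, ] != g[j, ])
  }
  tot / choose(n, 2) / L
}

# segregating sites by explicit column scan
brute_S <- function(h) {
  s <- 0
  for (j in seq_len(ncol(h$haplotypes))) {
    col <- h$haplotypes[, j]
    if (any(col == 0) && any(col == 1)) s <- s + 1
  }
  s
}

# union-find transitive closure over threshold edges
brute_groups <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(as.character(edges$pos_i[k]))
    b <- find(as.character(edges$pos_j[k]))
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# Kendall S statistic and exact permutation p by full R-side enumeration
brute_kendall_S <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  s
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

brute_kendall_exact_p <- function(x, y) {
  obs <- abs(brute_kendall_S(x, y))
  ps <- all_perms(y)
  mean(vapply(ps, function(p) abs(brute_kendall_S(x, p)) >= obs,
              logical(1)))
}

# independent NG86 per-codon site counts via the Biostrings code table
brute_ng86_sites <- function(codon) {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, p, p))
    muts <- vapply(alts, function(a) {
      x <- codon; substr(x, p, p) <- a; x
    }, character(1))
    keep <- code[muts] != "*"
    if (sum(keep) > 0) s <- s + mean(code[muts[keep]] == aa)
  }
  c(n = 3 - s, s = s)
}

# minimal-pathway syn/nonsyn step averaging, independent implementation
brute_path_diffs <- function(a, b) {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  paths <- all_perms(pos)
  tallies <- list()
  for (ord in paths) {
    cur <- a
    st <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      st[if (code[[nxt]] == code[[cur]]) "syn" else "nonsyn"] <-
        st[if (code[[nxt]] == code[[cur]]) "syn" else "nonsyn"] + 1
      cur <- nxt
    }
    if (ok) tallies[[length(tallies) + 1]] <- st
  }
  if (length(tallies) == 0) return(c(syn = NA_real_, nonsyn = NA_real_))
  Reduce(`+`, tallies) / length(tallies)
}

# write a minimal phased VCF for reader tests
write_toy_vcf <- function(path, records, samples = c("S1", "S2")) {
  head <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral\">",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(head, records), path)
  path
}
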