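test_that("NG86 site counts match enumeration on canonical codons", {
  # TTT (Phe): only TTT->TTC is synonymous, at position 3
  s <- count_sites_ng86("TTT")
  expect_equal(s$s_sites, 1 / 3)
  expect_equal(s$n_sites, 3 - 1 / 3)
  # ATG (Met): every single-base change is nonsynonymous
  expect_equal(count_sites_ng86("ATG")$s_sites, 0)
  # fourfold degenerate third position
  expect_equal(count_sites_ng86("GGG")$s_sites, 1)
  expect_error(count_sites_ng86("TAA"), "stop")
})

test_that("site counts agree with exhaustive enumeration for all 61 sense codons", {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  sense <- names(code)[code != "*"]
  expect_length(sense, 61)
  for (cod in sense) {
    mine <- count_sites_ng86(cod)
    oracle <- brute_ng86_sites(cod)
    expect_equal(mine$s_sites, unname(oracle["s"]), tolerance = 1e-12)
    expect_equal(mine$n_sites, unname(oracle["n"]), tolerance = 1e-12)
    expect_equal(mine$s_sites + mine$n_sites, 3, tolerance = 1e-12)
  }
})

test_that("pairwise dN/dS handles identity, single and multi differences", {
  a <- strrep("TTT", 10)
  same <- pairwise_dnds(a, a)
  expect_equal(same$Nd, 0)
  expect_equal(same$Sd, 0)
  expect_false(same$omega_defined)
  expect_true(is.na(same$omega))

  # one synonymous difference among ten codons
  b <- paste0("TTC", strrep("TTT", 9))
  r <- pairwise_dnds(a, b)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_equal(r$S_sites, 10 / 3, tolerance = 1e-12)
  pS <- 1 / (10 / 3)
  expect_equal(r$dS, -3 / 4 * log(1 - 4 * pS / 3), tolerance = 1e-12)
})

test_that("multi-difference pathway averaging matches brute enumeration", {
  set.seed(81)
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  sense <- names(code)[code != "*"]
  checked <- 0
  while (checked < 12) {
    pair <- sample(sense, 2)
    oracle <- brute_path_diffs(pair[1], pair[2])
    if (anyNA(oracle)) next
    r <- pairwise_dnds(pair[1], pair[2])
    expect_equal(r$Sd, unname(oracle["syn"]), tolerance = 1e-12)
    expect_equal(r$Nd, unname(oracle["nonsyn"]), tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("pairwise dN/dS is symmetric and flags stop codons", {
  set.seed(82)
  ca <- generate_codon_alignment(60, 0.4, 0.5)
  s <- vapply(ca$alignment$codons, paste, character(1), collapse = "")
  ab <- pairwise_dnds(s[["focal"]], s[["out1"]])
  ba <- pairwise_dnds(s[["out1"]], s[["focal"]])
  expect_equal(ab$omega, ba$omega)
  expect_equal(ab$Nd, ba$Nd)
  expect_equal(ab$Sd, ba$Sd)

  # a stop codon in one sequence is excluded and reported
  x <- paste0("TAA", strrep("TTT", 4))
  y <- paste0("TTA", strrep("TTT", 4))
  r <- pairwise_dnds(x, y)
  expect_equal(r$flagged_codons, 1)
  expect_equal(r$n_codons, 4)
  expect_equal(r$Nd + r$Sd, 0)
})

test_that("lineage assignment follows strict-consensus parsimony", {
  al <- codon_alignment(c(hum = "GAATTT", chimp = "TTATTT",
                          gor = "TTATTT", mac = "TTATTT"))
  lc <- lineage_changes(al, "hum", c("chimp", "gor", "mac"))
  expect_equal(lc$status, c("change", "no_change"))
  expect_equal(lc$ancestral[1], "TTA")
  expect_equal(lc$n_steps[1], 2L)       # TTA -> GAA touches two positions
  expect_equal(lc$aa_ancestral[1], "L")
  expect_equal(lc$aa_focal[1], "E")

  # disagreeing outgroups leave the codon ambiguous
  al2 <- codon_alignment(c(hum = "GAA", chimp = "TTA", gor = "CTA"))
  expect_error(lineage_changes(al2, "hum", "chimp"), "2 outgroups")
  lc2 <- lineage_changes(al2, "hum", c("chimp", "gor"))
  expect_equal(lc2$status, "ambiguous")
})

test_that("the stop-to-sense resurrection path is visible codon by codon", {
  # outgroups carry the Leu codon; two human states: stop and Glu
  al <- codon_alignment(c(active = "GAA", pseudo = "TAA",
                          chimp = "TTA", baboon = "TTA"))
  lc <- lineage_changes(al, "active", c("chimp", "baboon"))
  expect_equal(lc$status, "change")
  expect_equal(lc$aa_focal, "E")
  lcp <- lineage_changes(al, "pseudo", c("chimp", "baboon"))
  expect_equal(lcp$aa_focal, "*")
  expect_equal(lcp$n_steps, 1L)         # TTA -> TAA is one step
})

test_that("omega classification uses the fixed thresholds", {
  expect_equal(classify_omega(c(0.36, 1, 47.8, NA)),
               c("purifying", "neutral", "positive", "undefined"))
  expect_equal(classify_omega(0.95, band = 0.1), "neutral")
})

test_that("codon alignment drops incomplete codons and validates input", {
  al <- codon_alignment(c(a = "ATG-AATTT", b = "ATGGGATTT"))
  expect_equal(al$n_codons, 2)
  expect_equal(attr(al, "dropped_codons"), 1)
  expect_error(codon_alignment(c(a = "ATG", b = "ATGCCC")), "equal length")
  expect_error(codon_alignment(c(a = "ATGC", b = "ATGC")), "divisible")
  expect_error(codon_alignment(c("ATG", "ATG")), "unique")
})

test_that("a purely synonymous process yields only synonymous differences", {
  set.seed(83)
  ca <- generate_codon_alignment(120, 0.5, omega = 0)
  expect_equal(ca$truth$n_nonsyn_events, 0L)
  expect_gt(ca$truth$n_syn_events, 0L)
  s <- vapply(ca$alignment$codons, paste, character(1), collapse = "")
  r <- pairwise_dnds(s[["focal"]], s[["out1"]])
  # NG86 pathway averaging can assign small fractional nonsynonymous
  # counts to doubly hit codons even when every true event was synonymous
  expect_lt(r$Nd, 1.5)
  expect_gt(r$Sd, 0)
})
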