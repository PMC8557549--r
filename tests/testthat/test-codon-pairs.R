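test_that("codon pair counting slides a width-2 window within genes", {
  tab <- count_codon_pairs(list(c("ATG", "GCT", "GCT")))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n[tab$codon1 == "ATG" & tab$codon2 == "GCT"], 1L)
  expect_equal(tab$n[tab$codon1 == "GCT" & tab$codon2 == "GCT"], 1L)
  expect_equal(attr(tab, "n_pairs"), 2L)

  # single-codon genes contribute nothing; no cross-gene pairs
  tab2 <- count_codon_pairs(list("ATG", c("GCT", "GAA")))
  expect_equal(attr(tab2, "n_pairs"), 1L)

  # stop-containing pairs excluded
  tab3 <- count_codon_pairs(list(c("ATG", "GCT", "TAA")))
  expect_equal(attr(tab3, "n_pairs"), 1L)
  expect_false(any(tab3$codon2 == "TAA"))
})

test_that("pair counts equal a brute-force double loop on random corpora", {
  set.seed(51)
  code <- genetic_code()
  genes <- lapply(1:12, function(i) {
    c(sample(code$sense_codons, sample(2:30, 1), replace = TRUE),
      sample(code$stop_codons, 1))
  })
  tab <- count_codon_pairs(genes)
  oracle <- oracle_pair_counts(genes)
  expect_equal(attr(tab, "n_pairs"), sum(unlist(oracle)))
  for (i in seq_len(nrow(tab))) {
    key <- paste(tab$codon1[i], tab$codon2[i])
    expect_equal(tab$n[i], oracle[[key]])
  }
})

test_that("pair-count marginals over first and second codon nearly agree", {
  set.seed(52)
  genes <- lapply(1:10, function(i) {
    sample(genetic_code()$sense_codons, 40, replace = TRUE)
  })
  tab <- count_codon_pairs(genes)
  m1 <- tapply(tab$n, tab$codon1, sum)
  m2 <- tapply(tab$n, tab$codon2, sum)
  all_cod <- union(names(m1), names(m2))
  d <- abs(ifelse(is.na(m1[all_cod]), 0, m1[all_cod]) -
             ifelse(is.na(m2[all_cod]), 0, m2[all_cod]))
  expect_true(all(d <= length(genes))) # end effects bounded by gene count
})

test_that("preferred pairs take the per-amino-acid-pair argmax with lexicographic ties", {
  tokens <- list(rep(c("GGA", "GCT"), 10), rep(c("GGA", "GCA"), 4))
  pref <- preferred_pairs(count_codon_pairs(tokens))
  gly_ala <- pref[pref$aa1 == "Gly" & pref$aa2 == "Ala", ]
  expect_equal(paste0(gly_ala$codon1, gly_ala$codon2), "GGAGCT")

  # tie: two pair types equally frequent -> lexicographically first, flagged
  tokens2 <- list(c("CAT", "CAT"), c("CAC", "CAC"))
  pref2 <- preferred_pairs(count_codon_pairs(tokens2))
  expect_equal(paste0(pref2$codon1, pref2$codon2), "CACCAC")
  expect_true(pref2$tie)

  # brute-force argmax on a random table
  set.seed(53)
  genes <- lapply(1:8, function(i) {
    sample(genetic_code()$sense_codons, 60, replace = TRUE)
  })
  tab <- count_codon_pairs(genes)
  pref3 <- preferred_pairs(tab)
  code <- genetic_code()
  for (i in sample(nrow(pref3), 10)) {
    rows <- tab[code$aa3[code$codon_to_aa[tab$codon1]] == pref3$aa1[i] &
                  code$aa3[code$codon_to_aa[tab$codon2]] == pref3$aa2[i], ]
    expect_equal(pref3$n[i], max(rows$n))
  }
})

test_that("pair diffs report only amino-acid pairs whose argmax differs", {
  tokens_a <- list(rep(c("CAT", "CAT", "GCT", "GCC"), 5))
  tokens_b <- list(rep(c("CAC", "CAC", "GCT", "GCC"), 5))
  pref_a <- preferred_pairs(count_codon_pairs(tokens_a))
  pref_b <- preferred_pairs(count_codon_pairs(tokens_b))
  expect_equal(nrow(diff_preferred_pairs(pref_a, pref_a)), 0)
  d <- diff_preferred_pairs(pref_a, pref_b)
  his <- d[d$aa1 == "His" & d$aa2 == "His", ]
  expect_equal(nrow(his), 1)
  expect_equal(his$pair_a, "CATCAT")
  expect_equal(his$pair_b, "CACCAC")
  # RNA rendering
  d_rna <- diff_preferred_pairs(pref_a, pref_b, rna = TRUE)
  expect_equal(d_rna$pair_a[d_rna$aa1 == "His" & d_rna$aa2 == "His"], "CAUCAU")
})

test_that("pair-vs-optimal consistency flags homopairs without optimal codons", {
  tokens <- list(rep("GAT", 10), rep("AAC", 10))
  pref <- preferred_pairs(count_codon_pairs(tokens))
  rep <- pair_vs_optimal_consistency(pref, optimal_set = c("GAC", "AAC"))
  asp <- rep[rep$aa == "Asp", ]
  asn <- rep[rep$aa == "Asn", ]
  expect_false(asp$consistent) # preferred GATGAT but optimal is GAC
  expect_true(asn$consistent)  # preferred AACAAC and AAC is optimal
})
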