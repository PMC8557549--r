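test_that("RSCU matches the defining formula on hand examples", {
  # Phe TTT:3 TTC:1 -> 1.5 / 0.5
  r <- rscu(count_codons(c(rep("TTT", 3), "TTC")))
  expect_equal(r$rscu[r$codon == "TTT"], 1.5)
  expect_equal(r$rscu[r$codon == "TTC"], 0.5)
  # absent families are NA, not 0
  expect_true(is.na(r$rscu[r$codon == "GCA"]))

  # uniform usage in every family -> all RSCU = 1
  code <- genetic_code()
  r2 <- rscu(count_codons(rep(code$informative_codons, each = 2)))
  expect_true(all(r2$rscu == 1))
})

test_that("RSCU family sums equal family sizes and match a brute-force recount", {
  set.seed(31)
  code <- genetic_code()
  for (i in 1:25) {
    cods <- sample(code$sense_codons, sample(30:120, 1), replace = TRUE)
    r <- rscu(count_codons(cods))
    sums <- tapply(r$rscu, r$aa, function(x) sum(x))
    ks <- tapply(r$aa, r$aa, length)
    present <- !is.na(sums)
    expect_equal(as.numeric(sums[present]), as.numeric(ks[present]),
                 tolerance = 1e-9)
    oracle <- oracle_rscu(cods)
    for (cod in sample(names(oracle), 10)) {
      expect_equal(r$rscu[r$codon == cod], oracle[[cod]], tolerance = 1e-12)
    }
  }
})

test_that("pooled RSCU equals RSCU of pooled counts", {
  set.seed(32)
  cds <- make_cds(vapply(1:6, function(i) random_cds_string(60), character(1)))
  pooled <- colSums(codon_count_matrix(cds))
  r1 <- rscu(pooled)
  r2 <- rscu(count_codons(unlist(lapply(cds$sequence, tokenize_codons))))
  expect_equal(r1$rscu, r2$rscu)
})

test_that("ENc hits its analytic extremes", {
  code <- genetic_code()
  # one codon per degenerate amino acid, each 5 times -> exactly 20
  one_per <- vapply(code$family[names(which(code$degeneracy >= 2))], `[[`, "", 1)
  e20 <- enc(count_codons(rep(one_per, each = 5)))
  expect_identical(e20$enc, 20)
  expect_false(e20$capped)
  expect_equal(unlist(e20[, c("f2", "f3", "f4", "f6")]),
               c(f2 = 1, f3 = 1, f4 = 1, f6 = 1))

  # all 59 informative codons equally frequent -> raw > 61, capped
  e61 <- enc(count_codons(rep(code$informative_codons, each = 10)))
  expect_identical(e61$enc, 61)
  expect_true(e61$capped)
})

test_that("family homozygosities match the brute-force estimator", {
  # Lys AAA:4 AAG:0 -> Fhat = 1; Glu GAA:2 GAG:2 -> Fhat = 1/3
  cods <- c(rep("AAA", 4), rep("GAA", 2), rep("GAG", 2))
  m <- matrix(count_codons(cods), nrow = 1,
              dimnames = list("g", genetic_code()$codons))
  fhat <- codonscope:::family_homozygosity(m)
  expect_equal(unname(fhat[1, "K"]), 1)
  expect_equal(unname(fhat[1, "E"]), 1 / 3)
  expect_equal(unname(fhat[1, "K"]), oracle_fhat(cods, "K"))
  expect_equal(unname(fhat[1, "E"]), oracle_fhat(cods, "E"))
  # only two-fold families present -> 4-fold class absent -> ENc undefined
  expect_true(is.na(enc(count_codons(cods))$enc))

  set.seed(33)
  for (i in 1:10) {
    cods <- sample(genetic_code()$sense_codons, 80, replace = TRUE)
    m <- matrix(count_codons(cods), nrow = 1,
                dimnames = list("g", genetic_code()$codons))
    fhat <- codonscope:::family_homozygosity(m)
    for (aa in sample(colnames(fhat), 5)) {
      expect_equal(unname(fhat[1, aa]), oracle_fhat(cods, aa), tolerance = 1e-12)
    }
  }
})

test_that("ENc stays in [20, 61] and decreases with planted bias", {
  set.seed(34)
  encs <- vapply(c(0, 0.5, 1, 2, 4), function(b) {
    vals <- vapply(1:8, function(i) {
      enc(count_codons(sample_gene(400, b)))$enc
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(encs >= 20 & encs <= 61))
  expect_true(all(diff(encs) < 0))
})

test_that("expected-ENc curve matches independent evaluation on a grid", {
  g <- seq(0, 1, length.out = 101)
  independent <- pmin(2 + g + 29 / (g^2 + (1 - g)^2), 61)
  expect_equal(enc_expected(g), independent)
  expect_equal(enc_deviation(52.1, 0.5), (60.5 - 52.1) / 60.5)
  expect_equal(enc_deviation(61, 0.5), (60.5 - 61) / 60.5) # approx -0.00826
  expect_error(enc_expected(1.2), "\\[0, 1\\]")
})

test_that("CAI weights floor zero-count codons and give 1 for uniform references", {
  # Phe always TTC in the reference
  w <- build_cai_weights(count_codons(c(rep("TTC", 10), rep("GCT", 5), rep("GCC", 5))))
  expect_equal(w$w[w$codon == "TTC"], 1)
  expect_equal(w$w[w$codon == "TTT"], 0.01 / 2) # floored RSCU over family max 2
  expect_true(all(w$w > 0))
  expect_equal(max(w$w[w$aa == "Ala"]), 1)

  code <- genetic_code()
  w2 <- build_cai_weights(count_codons(rep(code$informative_codons, each = 3)))
  expect_true(all(w2$w == 1))
  expect_error(build_cai_weights(setNames(numeric(0), character(0))), "")
})

test_that("CAI is the geometric mean of weights, verified in the log domain", {
  code <- genetic_code()
  w_uniform <- build_cai_weights(count_codons(rep(code$informative_codons, each = 3)))
  # gene of family-maximal codons only -> CAI 1
  expect_equal(cai(count_codons(c("GCT", "GCC", "TTT")), w_uniform), 1)

  # half max-weight, half weight 0.5: CAI = sqrt(0.5)
  ref <- count_codons(c(rep("TTT", 20), rep("TTC", 10), rep("GAA", 20), rep("GAG", 10)))
  w <- build_cai_weights(ref)
  expect_equal(w$w[w$codon == "TTC"], 0.5)
  gene <- count_codons(c(rep("TTT", 5), rep("TTC", 5)))
  expect_equal(cai(gene, w), sqrt(0.5))

  set.seed(35)
  cods <- sample(code$sense_codons, 200, replace = TRUE)
  gene2 <- count_codons(cods)
  wv <- setNames(w_uniform$w, w_uniform$codon)
  keep <- cods[cods %in% names(wv)]
  log_oracle <- exp(mean(log(wv[keep])))
  expect_equal(cai(gene2, w_uniform), unname(log_oracle), tolerance = 1e-12)
})

test_that("Fop counts optimal codons over synonymous codons", {
  gene <- count_codons(c(rep("GCC", 7), rep("GCT", 13)))
  expect_equal(fop(gene, "GCC"), 0.35)
  expect_equal(fop(gene, c("GCC", "GCT")), 1)
  expect_equal(fop(gene, "TTT"), 0)
  # Met/Trp excluded from the denominator
  gene2 <- count_codons(c(rep("GCC", 5), rep("ATG", 5)))
  expect_equal(fop(gene2, "GCC"), 1)
})

test_that("CBI equals its closed form against a brute-force chance count", {
  # all-optimal gene
  expect_equal(cbi(count_codons(rep("GCC", 10)), "GCC"), 1)
  # exactly chance usage in a fourfold family -> 0
  chance <- count_codons(c("GCT", "GCC", "GCA", "GCG"))
  expect_equal(cbi(chance, "GCC"), 0)

  set.seed(36)
  code <- genetic_code()
  for (i in 1:5) {
    cods <- sample(code$sense_codons, 150, replace = TRUE)
    optimal <- c("GCC", "GAG", "TTC", "CGC")
    v <- count_codons(cods)
    # oracle: explicit family loop
    n_opt <- n_tot <- n_ran <- 0
    for (aa in names(code$degeneracy)[code$degeneracy >= 2]) {
      fam <- code$family[[aa]]
      opt_in <- intersect(fam, optimal)
      if (length(opt_in) == 0) next
      tot <- sum(v[fam])
      n_opt <- n_opt + sum(v[opt_in])
      n_tot <- n_tot + tot
      n_ran <- n_ran + tot * length(opt_in) / length(fam)
    }
    expect_equal(cbi(v, optimal), (n_opt - n_ran) / (n_tot - n_ran),
                 tolerance = 1e-12)
  }
})

test_that("the per-gene index table is coherent and carries its attributes", {
  set.seed(37)
  tr <- sample_transcriptome(synthetic_config(n_genes = 60, seed = 37))
  idx <- codon_usage_indices(tr$cds)
  expect_equal(nrow(idx), 60)
  expect_true(all(c("enc", "enc_expected", "enc_deviation", "cai", "cbi",
                    "fop", "gc3s", "pr2_x", "fpkm") %in% names(idx)))
  expect_true(all(idx$enc >= 20 & idx$enc <= 61, na.rm = TRUE))
  expect_true(all(idx$cai > 0 & idx$cai <= 1, na.rm = TRUE))
  expect_s3_class(attr(idx, "cai_weights"), "cai_weights")
  expect_equal(idx$enc_deviation,
               (idx$enc_expected - idx$enc) / idx$enc_expected)
})
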