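test_that("codon alignment handles identity and gaps", {
  s <- "ATGGCTGAAAAATTTTGTCACTAA"
  aln <- align_ortholog_pair(s, s)
  expect_equal(attr(aln, "n_codons_aligned"), 7) # stop stripped
  expect_equal(aln$codon_a, aln$codon_b)

  # deletion of one codon -> one gap, aligned codons = len - 1
  cods <- tokenize_codons(s)
  s_del <- paste(cods[-4], collapse = "")
  aln2 <- align_ortholog_pair(s, s_del)
  expect_equal(attr(aln2, "n_codons_aligned"), 6)
  expect_error(align_ortholog_pair("TAA", "TAA"), "length is 0")
})

test_that("NG86 site counts sum to 3 per aligned codon", {
  set.seed(61)
  tabs <- codonscope:::ng86_tables()
  code <- genetic_code()
  expect_true(all(abs(
    (tabs$syn_sites[code$sense_codons] +
       (3 - tabs$syn_sites[code$sense_codons])) - 3
  ) < 1e-12))
  # spot values: TTT has one synonymous third-position change out of
  # three non-stop alternatives; ATG and TGG have none.
  expect_equal(unname(tabs$syn_sites["TTT"]), 1 / 3)
  expect_equal(unname(tabs$syn_sites["ATG"]), 0)
  expect_equal(unname(tabs$syn_sites["TGG"]), 0)
})

test_that("NG86 estimates match a brute-force pathway-enumeration oracle", {
  set.seed(62)
  code <- genetic_code()
  for (i in 1:5) {
    n <- 40
    ca <- sample(code$sense_codons, n, replace = TRUE)
    cb <- ca
    mut <- sample(n, 8)
    cb[mut] <- sample(code$sense_codons, 8, replace = TRUE)
    aln <- tibble::tibble(codon_a = ca, codon_b = cb)
    est <- ng86_kaks(aln)
    oracle <- oracle_ng86(ca, cb)
    expect_equal(est$ks, oracle$ks, tolerance = 1e-10)
    expect_equal(est$ka, oracle$ka, tolerance = 1e-10)
  }
})

test_that("identical sequences give ka = ks = 0 with undefined omega", {
  s <- strrep("GCTGAAAAATTT", 30)
  est <- ng86_kaks(align_ortholog_pair(s, s))
  expect_equal(est$ka, 0)
  expect_equal(est$ks, 0)
  expect_true(is.na(est$omega))
  expect_equal(est$selection_class, "undefined")
})

test_that("a single synonymous change yields ka = 0 and ks > 0", {
  set.seed(63)
  base <- vapply(1:100, function(i) "GAA", character(1))
  a <- paste(base, collapse = "")
  b_cod <- base
  b_cod[50] <- "GAG"
  b <- paste(b_cod, collapse = "")
  est <- ng86_kaks(align_ortholog_pair(a, b))
  expect_equal(est$ka, 0)
  expect_gt(est$ks, 0)
})

test_that("the estimator is symmetric in its arguments", {
  set.seed(64)
  g <- sample_gene(200, 0.2)
  h <- evolve_ortholog(g, 0.03, 0.1)
  e1 <- ng86_kaks(align_ortholog_pair(g, h))
  e2 <- ng86_kaks(align_ortholog_pair(h, g))
  expect_equal(e1$ka, e2$ka)
  expect_equal(e1$ks, e2$ks)
})

test_that("selection classification partitions by omega with a neutral boundary", {
  pairs <- tibble::tibble(
    id_a = letters[1:5], id_b = LETTERS[1:5],
    ka = c(0.2, 0.01, 0, 0.05, 0.02),
    ks = c(0.1, 0.1, 0, 0.05, 0),
    omega = c(2, 0.1, NA, 1, Inf)
  )
  cls <- classify_selection(pairs)
  expect_equal(cls$pairs$selection_class,
               c("positive", "purifying", "undefined", "neutral", "undefined"))
  s <- cls$summary
  expect_equal(s$n[s$selection_class == "positive"], 1L)
  expect_equal(s$n[s$selection_class == "purifying"], 1L)
  # infinite omega excluded from the overall mean
  expect_equal(s$mean_omega[s$selection_class == "overall"], mean(c(2, 0.1, 1)))
})

test_that("kaks_table runs over an ortholog map and recovers planted divergence", {
  set.seed(65)
  sim <- sample_ortholog_pairs(8, n_codons = 300, ka_target = 0.02,
                               ks_target = 0.1)
  kk <- kaks_table(sim$a, sim$b, sim$orthologs)
  expect_equal(nrow(kk), 8)
  expect_true(all(kk$ka >= 0 & kk$ks >= 0))
  expect_equal(median(kk$ks), 0.1, tolerance = 0.35)
  expect_equal(median(kk$ka), 0.02, tolerance = 0.45)
})

test_that("divergence-index correlation detects a planted ENc-omega coupling", {
  set.seed(66)
  n <- 60
  beta <- runif(n, 0, 1.5)
  cds_a <- make_cds(vapply(seq_len(n), function(i) sample_gene(250, beta[i]),
                           character(1)),
                    ids = sprintf("a%03d", seq_len(n)))
  # omega increases with beta (so decreases with ENc): planted coupling
  omega_t <- 0.1 + 0.4 * beta
  cds_b <- make_cds(vapply(seq_len(n), function(i) {
    evolve_ortholog(cds_a$sequence[i], ka_target = omega_t[i] * 0.2,
                    ks_target = 0.2)
  }, character(1)), ids = sprintf("b%03d", seq_len(n)))
  kk <- kaks_table(cds_a, cds_b,
                   tibble::tibble(id_a = cds_a$gene_id, id_b = cds_b$gene_id))
  idx <- codon_usage_indices(cds_a, optimal_set = NA)
  corr <- divergence_index_correlation(kk, idx, stratum = "purifying")
  cell <- corr[corr$var1 == "omega" & corr$var2 == "enc", ]
  expect_lt(cell$r, 0) # higher bias (low ENc) goes with higher omega
  expect_error(
    divergence_index_correlation(kk[0, ], idx, stratum = "purifying"),
    "at least 3"
  )
})

test_that("external Ka/Ks tables are accepted through the injection hook", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    id_a = c("x", "y"), id_b = c("u", "v"), ka = c(0.02, 0.1), ks = c(0.1, 0.05)
  ), path)
  kk <- read_kaks_tsv(path)
  expect_equal(kk$omega, c(0.2, 2))
  expect_equal(kk$selection_class, c("purifying", "positive"))
})
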