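test_that("CA of identical rows has zero inertia and zero coordinates", {
  mat <- matrix(rep(c(1, 2, 3, 4), each = 5), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  res <- correspondence_analysis(mat)
  expect_equal(res$total_inertia, 0, tolerance = 1e-12)
  expect_true(all(abs(as.matrix(res$gene_coords[, grep("^Axis", names(res$gene_coords))])) < 1e-8))
})

test_that("CA inertia equals chi-square / N and matches the eigen oracle", {
  set.seed(71)
  for (i in 1:5) {
    mat <- matrix(rpois(6 * 8, lambda = 20) + 1, nrow = 6,
                  dimnames = list(paste0("g", 1:6), paste0("c", 1:8)))
    res <- suppressWarnings(correspondence_analysis(mat, n_axes = 5))
    chi2 <- suppressWarnings(chisq.test(mat)$statistic)
    expect_equal(res$total_inertia, unname(chi2) / sum(mat), tolerance = 1e-10)
    oracle <- oracle_ca(mat)
    expect_equal(res$total_inertia, oracle$inertia, tolerance = 1e-10)
    k <- res$n_axes
    expect_equal(res$inertia$inertia, oracle$eigenvalues[seq_len(k)],
                 tolerance = 1e-8)
    # principal coordinates reproduce the eigenvalues: mass-weighted
    # sum of squared gene coordinates per axis equals the axis inertia
    coords <- as.matrix(res$gene_coords[, paste0("Axis", seq_len(k))])
    r <- rowSums(mat) / sum(mat)
    expect_equal(colSums(coords^2 * r), res$inertia$inertia,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("CA on vegan's toy route agrees as an independent cross-check", {
  skip_if_not_installed("vegan")
  set.seed(72)
  mat <- matrix(rpois(7 * 9, 15) + 1, nrow = 7,
                dimnames = list(paste0("g", 1:7), paste0("c", 1:9)))
  res <- suppressWarnings(correspondence_analysis(mat, n_axes = 3))
  cca_fit <- vegan::cca(mat)
  expect_equal(res$inertia$inertia,
               unname(cca_fit$CA$eig[1:3]), tolerance = 1e-8)
})

test_that("a planted GC3 gradient dominates CA axis 1", {
  set.seed(73)
  beta <- runif(150, 0, 1)
  cds <- make_cds(vapply(seq_along(beta), function(i) sample_gene(200, beta[i]),
                         character(1)))
  coa <- correspondence_analysis(cds)
  idx <- composition_table(cds)
  joined <- dplyr::inner_join(coa$gene_coords, idx, by = "gene_id")
  expect_gt(abs(cor(joined$Axis1, joined$gc3s)), 0.9)
})

test_that("axis correlations recover a self-correlation of 1", {
  set.seed(74)
  cds <- make_cds(vapply(1:40, function(i) sample_gene(150, runif(1)), character(1)))
  coa <- correspondence_analysis(cds)
  idx <- codon_usage_indices(cds, optimal_set = NA)
  idx$fpkm <- coa$gene_coords$Axis1[match(idx$gene_id, coa$gene_coords$gene_id)]
  corr <- axis_correlations(coa, idx, method = "spearman")
  cell <- corr[corr$var1 == "Axis1" & corr$var2 == "fpkm", ]
  expect_equal(cell$r, 1)
})

test_that("GC classes use strict outer boundaries", {
  expect_equal(as.character(gc_class(c(0.44, 0.45, 0.60, 0.61))),
               c("low", "mid", "mid", "high"))
  expect_error(gc_class(1.2), "\\[0, 1\\]")
})

test_that("GC3s tertiles are disjoint, ordered and deterministic under ties", {
  idx <- tibble::tibble(gene_id = sprintf("g%04d", 1:3000),
                        gc3s = seq(0.1, 0.9, length.out = 3000))
  g <- gc3_tertiles(idx, 1000)
  expect_length(g$low, 1000)
  expect_length(g$mid, 1000)
  expect_length(g$high, 1000)
  expect_equal(length(intersect(g$low, g$mid)), 0)
  expect_equal(length(intersect(g$mid, g$high)), 0)
  expect_lt(max(idx$gc3s[idx$gene_id %in% g$low]),
            min(idx$gc3s[idx$gene_id %in% g$high]))

  idx2 <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), gc3s = 0.5)
  expect_identical(gc3_tertiles(idx2, 10), gc3_tertiles(idx2, 10))
  expect_error(gc3_tertiles(idx2, 11), "too few")
})

test_that("index correlation matrix is symmetric with unit diagonal and honors monotone invariance", {
  set.seed(75)
  tr <- sample_transcriptome(synthetic_config(n_genes = 80, seed = 75))
  idx <- codon_usage_indices(tr$cds, optimal_set = NA)
  cm <- suppressWarnings(index_correlation_matrix(idx))
  self <- cm[cm$var1 == cm$var2 & cm$var1 == "gc3s", ]
  expect_equal(self$r, 1)
  ab <- cm[cm$var1 == "enc" & cm$var2 == "gc3s", ]
  ba <- cm[cm$var1 == "gc3s" & cm$var2 == "enc", ]
  expect_equal(ab$r, ba$r)
  # spearman invariance under a monotone transform of one variable
  idx2 <- idx
  idx2$fpkm <- log1p(idx2$fpkm)
  cm2 <- suppressWarnings(index_correlation_matrix(idx2))
  expect_equal(cm$r[cm$var1 == "fpkm" & cm$var2 == "gc3s"],
               cm2$r[cm2$var1 == "fpkm" & cm2$var2 == "gc3s"])
})

test_that("species RSCU matrix rows conserve family sums and flag duplicates", {
  set.seed(76)
  cds1 <- make_cds(vapply(1:10, function(i) sample_gene(150, 0.1), character(1)),
                   species = "sp1")
  cds2 <- cds1
  cds2$species <- "sp2"
  mat <- species_rscu_matrix(dplyr::bind_rows(cds1, cds2))
  expect_equal(mat["sp1", ], mat["sp2", ])
  code <- genetic_code()
  aa <- code$codon_to_aa[colnames(mat)]
  sums <- tapply(mat["sp1", ], aa, sum)
  present <- !is.na(sums)
  expect_equal(as.numeric(sums[present]),
               as.numeric(code$degeneracy[names(sums)[present]]),
               tolerance = 1e-9)
})

test_that("clustering merges identical rows first and matches a tiny merge oracle", {
  mat <- rbind(a = c(1, 0, 0, 1), b = c(1, 0, 0, 1), c = c(0, 2, 2, 0))
  hc <- cluster_species(mat)
  expect_equal(hc$height[1], 0)
  first_merge <- rownames(mat)[-hc$merge[1, ]]
  expect_setequal(first_merge, c("a", "b"))
  expect_true(all(diff(hc$height) >= 0))

  # 3-species oracle: nearest pair by euclidean distance merges first
  set.seed(77)
  m2 <- matrix(runif(3 * 6), nrow = 3, dimnames = list(c("x", "y", "z"), NULL))
  d <- as.matrix(dist(m2))
  diag(d) <- Inf
  nearest <- rownames(m2)[arrayInd(which.min(d), dim(d))]
  hc2 <- cluster_species(m2)
  expect_setequal(rownames(m2)[-hc2$merge[1, ]], nearest)

  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(mat))
})

test_that("a planted two-cluster species design is recovered", {
  set.seed(78)
  mk <- function(beta, label) {
    cds <- make_cds(vapply(1:15, function(i) sample_gene(200, beta), character(1)),
                    species = label)
    cds
  }
  all_cds <- dplyr::bind_rows(mk(1.2, "rich1"), mk(1.1, "rich2"),
                              mk(0, "poor1"), mk(0.05, "poor2"))
  mat <- species_rscu_matrix(all_cds)
  hc <- cluster_species(mat)
  groups <- cutree(hc, k = 2)
  expect_equal(groups[["rich1"]], groups[["rich2"]])
  expect_equal(groups[["poor1"]], groups[["poor2"]])
  expect_true(groups[["rich1"]] != groups[["poor1"]])
})

test_that("species PCA matches the eigen oracle and handles duplicates", {
  set.seed(79)
  m <- matrix(runif(4 * 6), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("c", 1:6)))
  p <- pca_species(m, n_components = 2)
  ev <- eigen(cov(m), symmetric = TRUE)
  expect_equal(p$explained[1:2],
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-10)
  scores_oracle <- scale(m, center = TRUE, scale = FALSE) %*% ev$vectors[, 1:2]
  expect_equal(abs(as.matrix(p$scores[, c("PC1", "PC2")])),
               abs(scores_oracle), tolerance = 1e-8, ignore_attr = TRUE)

  m2 <- rbind(m, s5 = m[1, ])
  p2 <- pca_species(m2)
  expect_equal(unlist(p2$scores[1, -1]), unlist(p2$scores[5, -1]),
               tolerance = 1e-10, ignore_attr = TRUE)

  # rank-1 structure -> PC1 fraction ~ 1
  r1 <- outer(c(1, 2, 3), runif(6))
  rownames(r1) <- paste0("r", 1:3)
  expect_gt(suppressWarnings(pca_species(r1))$explained[1], 0.999)
})

test_that("tidiers expose coordinates and fit summaries", {
  set.seed(80)
  cds <- make_cds(vapply(1:25, function(i) sample_gene(120, runif(1)), character(1)))
  coa <- correspondence_analysis(cds)
  expect_s3_class(tidy(coa), "tbl_df")
  g <- glance(coa)
  expect_equal(g$n_genes, 25)
  expect_true(g$axis1_fraction >= g$axis2_fraction)
  frac <- tidy(coa, "inertia")$fraction
  expect_true(all(diff(frac) <= 1e-12))
  expect_lte(sum(frac), 1 + 1e-9)
})
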