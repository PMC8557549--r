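#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon j in family i is the observed count divided by the count
#' expected under uniform synonymous usage: `RSCU_ij = x_ij / ((1/k_i) * sum_j
#' x_ij)`. Values above 1 mark preferred codons. Met, Trp and stop codons are
#' excluded, leaving the 59 informative codons. Families absent from the gene
#' give `NA` (undefined), not 0.
#'
#' @param counts Named codon count vector (see [count_codons()]), a genes x 64
#'   count matrix (pooled by summation), or a nucleotide string.
#' @return A tibble with columns `aa` (three-letter amino acid), `codon`,
#'   `count`, `rscu`, ordered by amino acid then codon.
#' @examples
#' rscu(count_codons(c(rep("TTT", 3), "TTC")))[1:2, ]
#' @export
rscu <- function(counts) {
  if (is.character(counts)) counts <- count_codons(counts)
  code <- genetic_code()
  v <- as_count_vector(counts)
  abort_if(sum(v[code$sense_codons]) < 1, "need at least one sense codon")
  inf <- code$informative_codons
  aa <- code$codon_to_aa[inf]
  fam_tot <- tapply(v[inf], aa, sum)[aa]
  k <- code$degeneracy[aa]
  vals <- as.numeric(ifelse(fam_tot > 0, v[inf] / (fam_tot / k), NA_real_))
  tibble::tibble(
    aa = unname(code$aa3[aa]),
    codon = inf,
    count = unname(v[inf]),
    rscu = unname(vals)
  )
}

# Genes x 59 RSCU matrix (NA where a family is absent from a gene).
rscu_matrix <- function(m) {
  code <- genetic_code()
  inf <- code$informative_codons
  aa <- code$codon_to_aa[inf]
  x <- m[, inf, drop = FALSE]
  fam_tot <- t(rowsum(t(x), group = aa))          # genes x families
  expected <- fam_tot[, aa, drop = FALSE] / rep(code$degeneracy[aa], each = nrow(x))
  out <- x / expected
  out[expected == 0] <- NA_real_
  dimnames(out) <- list(rownames(m), inf)
  out
}

#' Per-gene RSCU table
#'
#' @param cds A filtered CDS tibble.
#' @return A tibble: `gene_id` plus one column per informative codon.
#' @export
rscu_by_gene <- function(cds) {
  assert_cds_tbl(cds)
  rm <- rscu_matrix(codon_count_matrix(cds))
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(rm)),
    tibble::as_tibble(rm)
  )
}

# Per-family bias-corrected homozygosity Fhat = (n*sum(p^2) - 1)/(n - 1) for
# each gene (rows of m); NA where family count < min_family_n.
family_homozygosity <- function(m, min_family_n = 2L) {
  code <- genetic_code()
  fams <- names(code$degeneracy)[code$degeneracy >= 2L]
  out <- sapply(fams, function(a) {
    cods <- code$family[[a]]
    x <- m[, cods, drop = FALSE]
    n <- rowSums(x)
    sump2 <- rowSums((x / ifelse(n > 0, n, 1))^2)
    ifelse(n >= min_family_n, (n * sump2 - 1) / (n - 1), NA_real_)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), fams))
  out
}

# Vectorized ENc over a genes x 64 count matrix. Returns a tibble.
enc_from_counts <- function(m, min_family_n = 2L) {
  code <- genetic_code()
  fhat <- family_homozygosity(m, min_family_n = min_family_n)
  cls <- degeneracy_classes(code)
  class_mean <- function(aas) unname(rowMeans(fhat[, aas, drop = FALSE], na.rm = TRUE))
  f2 <- class_mean(cls$k2)
  f3 <- class_mean(cls$k3)
  f4 <- class_mean(cls$k4)
  f6 <- class_mean(cls$k6)
  # A class with no usable family (all NA) yields NaN; one with mean 0 cannot
  # be inverted. Both count as absent.
  absent <- function(f) !is.finite(f) | f <= 0
  inv2 <- ifelse(absent(f2), NA_real_, 1 / f2)
  inv4 <- ifelse(absent(f4), NA_real_, 1 / f4)
  # Absent 3-fold (Ile) or 6-fold class: interpolate 1/F from the two-
  # and four-fold classes (Wright-style fallback).
  interp <- (inv2 + inv4) / 2
  inv3 <- ifelse(absent(f3), interp, 1 / f3)
  inv6 <- ifelse(absent(f6), interp, 1 / f6)

  n_usable <- unname(rowSums(!is.na(fhat)))
  raw <- 2 + 9 * inv2 + inv3 + 5 * inv4 + 3 * inv6
  defined <- n_usable >= 2 & !absent(f2) & !absent(f4)
  enc <- ifelse(defined, pmin(raw, 61), NA_real_)
  tibble::tibble(
    gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    enc = enc,
    f2 = ifelse(is.finite(f2), f2, NA_real_),
    f3 = ifelse(is.finite(f3), f3, NA_real_),
    f4 = ifelse(is.finite(f4), f4, NA_real_),
    f6 = ifelse(is.finite(f6), f6, NA_real_),
    capped = defined & raw > 61
  )
}

#' Wright's effective number of codons (ENc)
#'
#' Estimates ENc for one gene from per-family codon homozygosities. For each
#' synonymous family with at least `min_family_n` codons, the bias-corrected
#' homozygosity is `Fhat = (n * sum(p^2) - 1) / (n - 1)`; class means F2, F3,
#' F4, F6 over the 2-, 3-, 4- and 6-fold degeneracy classes then give
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. Raw estimates above 61 are capped at
#' 61 (no bias); 20 means exactly one codon per amino acid. If the 3-fold
#' (Ile) or a 6-fold class is absent its 1/F term is interpolated as the mean
#' of 1/F2 and 1/F4; if the 2- or 4-fold class is absent (or fewer than two
#' families are usable) ENc is undefined.
#'
#' @param counts Named codon count vector, count matrix row set, or nucleotide
#'   string for a single gene.
#' @param min_family_n Minimum codon count for a family to enter its class
#'   mean (the estimator is undefined at n = 1).
#' @return One-row tibble: `enc` (in `[20, 61]` or `NA`), class means
#'   `f2`..`f6`, and `capped` (`TRUE` iff the raw estimate exceeded 61).
#' @examples
#' # One codon per amino acid, each 5 times: maximal bias
#' gene <- rep(vapply(genetic_code()$family, `[[`, "", 1)[
#'   names(which(genetic_code()$degeneracy >= 2))], 5)
#' enc(count_codons(gene))$enc # 20
#' @export
enc <- function(counts, min_family_n = 2L) {
  if (is.character(counts)) counts <- count_codons(counts)
  v <- as_count_vector(counts)
  m <- matrix(v, nrow = 1, dimnames = list("gene", names(v)))
  enc_from_counts(m, min_family_n = min_family_n)
}

#' Expected ENc under GC3s-only constraint
#'
#' The null expectation of ENc when codon usage is shaped only by the silent-
#' site GC content: `ENc_exp = 2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)`,
#' capped at 61 (the estimator's no-bias ceiling) for plotting.
#'
#' @param gc3s Silent-site GC fraction(s) in `[0, 1]`.
#' @param cap Cap values at 61 (default) or return the raw curve.
#' @return Numeric vector of expected ENc values.
#' @examples
#' enc_expected(0.5) # 60.5
#' @export
enc_expected <- function(gc3s, cap = TRUE) {
  abort_if(any(gc3s < 0 | gc3s > 1, na.rm = TRUE), "gc3s must be in [0, 1]")
  out <- 2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
  if (cap) out <- pmin(out, 61)
  out
}

#' Relative deviation of observed from expected ENc
#'
#' `(ENc_exp - ENc_obs) / ENc_exp`, the quantity histogrammed (bin width 0.1)
#' in ENc-plot analyses; positive values mean the gene is more biased than its
#' GC3s alone predicts.
#'
#' @param enc_obs Observed ENc value(s).
#' @param gc3s Matching silent-site GC fraction(s).
#' @return Numeric vector of relative deviations.
#' @export
enc_deviation <- function(enc_obs, gc3s) {
  expd <- enc_expected(gc3s)
  (expd - enc_obs) / expd
}

#' Build CAI relative-adaptiveness weights from a reference gene set
#'
#' Pools the codon counts of the reference genes, computes pooled RSCU, floors
#' zero-count codons at RSCU 0.01 and normalizes within each family by the
#' family maximum: `w_ij = RSCU_ij / max_family(RSCU)`. By convention the
#' reference set contains the most biased (proxy: most highly expressed)
#' genes.
#'
#' @param reference Either a CDS tibble, a genes x 64 count matrix, or a named
#'   64-codon count vector of the pooled reference.
#' @param description Provenance string stored with the weights.
#' @return A tibble `aa`, `codon`, `w` (class `cai_weights`), with the
#'   description as attribute `reference_description`. Within each family
#'   `max(w) = 1` and all `w > 0`.
#' @export
build_cai_weights <- function(reference, description = "user-supplied reference") {
  if (is.data.frame(reference)) reference <- codon_count_matrix(reference)
  v <- as_count_vector(reference)
  abort_if(sum(v) == 0, "empty reference set")
  r <- rscu(v)
  vals <- ifelse(is.na(r$rscu) | r$count == 0, 0.01, pmax(r$rscu, 0.01))
  w <- stats::ave(vals, r$aa, FUN = function(x) x / max(x))
  out <- tibble::tibble(aa = r$aa, codon = r$codon, w = w)
  attr(out, "reference_description") <- description
  class(out) <- c("cai_weights", class(out))
  out
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative-adaptiveness weights over the gene's sense
#' codons, excluding Met, Trp and stops. Higher CAI means stronger codon usage
#' bias towards the reference set's preferred codons.
#'
#' @param counts Named codon count vector or nucleotide string.
#' @param weights A [build_cai_weights()] table.
#' @return CAI value in `(0, 1]`.
#' @export
cai <- function(counts, weights) {
  if (is.character(counts)) counts <- count_codons(counts)
  v <- as_count_vector(counts)
  x <- v[weights$codon]
  n <- sum(x)
  abort_if(n < 1, "no informative codons in gene")
  exp(sum(x * log(weights$w)) / n)
}

#' Frequency of optimal codons (Fop)
#'
#' Share of a gene's synonymous sense codons (Met/Trp excluded) that belong to
#' the optimal-codon set.
#'
#' @param counts Named codon count vector or nucleotide string.
#' @param optimal_set Character vector of optimal codons.
#' @return Value in `[0, 1]`.
#' @export
fop <- function(counts, optimal_set) {
  abort_if(length(optimal_set) == 0, "optimal_set is empty")
  if (is.character(counts) && is.null(names(counts))) counts <- count_codons(counts)
  v <- as_count_vector(counts)
  inf <- genetic_code()$informative_codons
  denom <- sum(v[inf])
  abort_if(denom == 0, "no synonymous codons in gene")
  sum(v[intersect(optimal_set, inf)]) / denom
}

#' Codon bias index (CBI)
#'
#' `CBI = (N_opt - N_ran) / (N_tot - N_ran)` where, over the families that
#' contain at least one optimal codon, `N_opt` is the observed count of
#' optimal codons, `N_tot` the family total and `N_ran` the count expected by
#' chance (`family total * optimal codons in family / family size`). 1 means
#' exclusively optimal codons; 0 means usage at chance frequency.
#'
#' @inheritParams fop
#' @return Value `<= 1`, or `NA` when `N_tot = N_ran` (degenerate).
#' @export
cbi <- function(counts, optimal_set) {
  abort_if(length(optimal_set) == 0, "optimal_set is empty")
  if (is.character(counts) && is.null(names(counts))) counts <- count_codons(counts)
  code <- genetic_code()
  v <- as_count_vector(counts)
  fams <- code$family[code$degeneracy >= 2L]
  n_opt <- n_tot <- n_ran <- 0
  for (cods in fams) {
    opt_in <- intersect(cods, optimal_set)
    if (length(opt_in) == 0) next
    tot <- sum(v[cods])
    n_opt <- n_opt + sum(v[opt_in])
    n_tot <- n_tot + tot
    n_ran <- n_ran + tot * length(opt_in) / length(cods)
  }
  if (n_tot == n_ran) {
    return(NA_real_)
  }
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Per-gene codon usage index table
#'
#' The central per-gene table: composition ([composition_table()]) joined with
#' ENc, expected ENc and its relative deviation, CAI, CBI, Fop and expression.
#' When `cai_weights` or `optimal_set` are not supplied they are derived
#' self-consistently from the data: CAI weights from the 10% lowest-ENc genes
#' (the high-bias, high-expression-proxy decile) and the optimal set from the
#' delta-RSCU comparison of the ENc extremes (see [find_optimal_codons()]).
#'
#' @param cds A filtered CDS tibble.
#' @param cai_weights Optional [build_cai_weights()] table.
#' @param optimal_set Optional character vector of optimal codons; `NULL`
#'   derives it from the data, `NA` skips Fop/CBI.
#' @param reference_fraction Fraction of lowest-ENc genes used for the default
#'   CAI reference.
#' @param pr2_scope Passed to [composition_table()].
#' @return A tibble, one row per gene: composition columns plus `enc`,
#'   `enc_expected`, `enc_deviation`, `cai`, `cbi`, `fop`, `fpkm`, `species`.
#' @export
codon_usage_indices <- function(cds, cai_weights = NULL, optimal_set = NULL,
                                reference_fraction = 0.10,
                                pr2_scope = "fourfold_only") {
  assert_cds_tbl(cds)
  m <- codon_count_matrix(cds)
  comp <- composition_from_counts(m, pr2_scope = pr2_scope)
  enc_tbl <- enc_from_counts(m)

  out <- comp
  out$enc <- enc_tbl$enc
  out$enc_expected <- enc_expected(out$gc3s)
  out$enc_deviation <- enc_deviation(out$enc, out$gc3s)

  if (is.null(cai_weights)) {
    ord <- order(out$enc, out$gene_id)
    defined <- ord[!is.na(out$enc[ord])]
    n_ref <- max(1L, floor(reference_fraction * length(defined)))
    ref_ids <- out$gene_id[defined[seq_len(n_ref)]]
    cai_weights <- build_cai_weights(
      colSums(m[rownames(m) %in% ref_ids, , drop = FALSE]),
      description = sprintf(
        "self-consistent reference: %d lowest-ENc genes (fraction %.2f)",
        n_ref, reference_fraction
      )
    )
  }
  w <- stats::setNames(cai_weights$w, cai_weights$codon)
  x <- m[, cai_weights$codon, drop = FALSE]
  n_inf <- rowSums(x)
  out$cai <- ifelse(n_inf > 0, exp((x %*% log(w))[, 1] / n_inf), NA_real_)

  if (is.null(optimal_set)) {
    optimal_set <- tryCatch(
      optimal_codon_set(find_optimal_codons(cds, indices = out))$codon,
      error = function(e) character(0)
    )
  }
  if (length(optimal_set) > 0 && !anyNA(optimal_set)) {
    out$fop <- apply(m, 1, function(r) fop(r, optimal_set))
    out$cbi <- apply(m, 1, function(r) cbi(r, optimal_set))
  } else {
    out$fop <- NA_real_
    out$cbi <- NA_real_
  }

  out$fpkm <- if ("fpkm" %in% names(cds)) cds$fpkm[match(out$gene_id, cds$gene_id)] else NA_real_
  out$species <- if ("species" %in% names(cds)) cds$species[match(out$gene_id, cds$gene_id)] else NA_character_
  attr(out, "cai_weights") <- cai_weights
  attr(out, "optimal_set") <- optimal_set
  out
}
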