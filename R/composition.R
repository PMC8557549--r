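#' Count codons in one gene
#'
#' Exact multiset count of the codon tokens of one gene over all 64 codons.
#'
#' @param codons Character vector of codon tokens (see [tokenize_codons()]),
#'   or a nucleotide string.
#' @return Named integer vector of length 64 (all codons, zero-filled), with
#'   attribute `n_sense` = number of sense codons counted.
#' @examples
#' count_codons(c("ATG", "GCT", "GCT"))[c("ATG", "GCT")]
#' @export
count_codons <- function(codons) {
  code <- genetic_code()
  if (length(codons) == 1L && nchar(codons[1]) > 3L) {
    codons <- split_codons(codons)
  }
  abort_if(length(codons) == 0L, "no codons to count")
  bad <- which(!(codons %in% code$codons))
  abort_if(
    length(bad) > 0,
    paste0("unknown codon '", codons[bad[1]], "' at position ", bad[1])
  )
  counts <- tabulate(factor(codons, levels = code$codons), nbins = 64L)
  counts <- stats::setNames(as.integer(counts), code$codons)
  attr(counts, "n_sense") <- sum(counts[code$sense_codons])
  counts
}

#' Per-gene codon count matrix
#'
#' @param cds A CDS tibble.
#' @return Integer matrix, genes x 64 codons, rownames = `gene_id`.
#' @export
codon_count_matrix <- function(cds) {
  assert_cds_tbl(cds)
  code <- genetic_code()
  m <- t(vapply(cds$sequence, function(s) {
    tabulate(factor(split_codons(s), levels = code$codons), nbins = 64L)
  }, integer(64), USE.NAMES = FALSE))
  dimnames(m) <- list(cds$gene_id, code$codons)
  m
}

# Composition statistics from a genes x 64 count matrix. Works row-wise and
# fully vectorized; the per-gene wrapper and the table builder both call this.
composition_from_counts <- function(m, pr2_scope = c("fourfold_only", "all_silent")) {
  pr2_scope <- match.arg(pr2_scope)
  code <- genetic_code()
  codons <- code$codons
  stopifnot(identical(colnames(m), codons))

  base_at <- function(pos) substr(codons, pos, pos)
  gc_at <- function(pos) base_at(pos) %in% c("G", "C")

  n_codons <- unname(rowSums(m))
  gc_tot <- unname((m %*% (gc_at(1) + gc_at(2) + gc_at(3)))[, 1])
  gc1 <- unname((m %*% gc_at(1))[, 1]) / n_codons
  gc2 <- unname((m %*% gc_at(2))[, 1]) / n_codons
  gc3 <- unname((m %*% gc_at(3))[, 1]) / n_codons

  # Silent-site statistics over synonymously variable codons only
  # (families with k >= 2; Met, Trp and stops excluded).
  syn <- codons %in% degenerate_codons(code)
  n_syn <- unname((m %*% syn)[, 1])
  gc3s_num <- unname((m %*% (syn & gc_at(3)))[, 1])
  gc3s <- ifelse(n_syn > 0, gc3s_num / n_syn, NA_real_)

  # CodonW-convention B3s: occurrences of base B at synonymous third positions
  # over third positions where B could occur as a synonymous variant.
  x3s <- vapply(c("A", "T", "G", "C"), function(b) {
    num <- unname((m %*% (syn & base_at(3) == b))[, 1])
    avail <- syn & vapply(
      code$codon_to_aa[codons],
      function(a) a %in% names(code$third_base_available) &&
        b %in% code$third_base_available[[a]],
      logical(1)
    )
    den <- unname((m %*% avail)[, 1])
    ifelse(den > 0, num / den, NA_real_)
  }, numeric(nrow(m)))
  if (is.null(dim(x3s))) {
    x3s <- matrix(x3s, nrow = 1, dimnames = list(NULL, c("A", "T", "G", "C")))
  }

  pr2 <- pr2_from_counts(m, scope = pr2_scope)

  tibble::tibble(
    gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    length_bp = as.integer(3 * n_codons),
    gc = gc_tot / (3 * n_codons),
    gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2,
    gc3s = gc3s,
    a3s = as.numeric(x3s[, "A"]), t3s = as.numeric(x3s[, "T"]),
    g3s = as.numeric(x3s[, "G"]), c3s = as.numeric(x3s[, "C"]),
    pr2_x = pr2$x, pr2_y = pr2$y
  )
}

# PR2 coordinates from a genes x 64 matrix.
pr2_from_counts <- function(m, scope = c("fourfold_only", "all_silent")) {
  scope <- match.arg(scope)
  code <- genetic_code()
  codons <- colnames(m)
  in_scope <- if (scope == "fourfold_only") {
    codons %in% code$fourfold_codons
  } else {
    codons %in% degenerate_codons(code)
  }
  third <- substr(codons, 3, 3)
  cnt <- function(b) unname((m %*% (in_scope & third == b))[, 1])
  a3 <- cnt("A"); t3 <- cnt("T"); g3 <- cnt("G"); c3 <- cnt("C")
  list(
    x = ifelse(g3 + c3 > 0, g3 / (g3 + c3), NA_real_),
    y = ifelse(a3 + t3 > 0, a3 / (a3 + t3), NA_real_)
  )
}

#' Composition profile of one gene
#'
#' Overall GC, positional GC (GC1/GC2/GC3, GC12 = their mean over positions 1
#' and 2), silent-site GC3s and single-base silent fractions A3s/T3s/G3s/C3s,
#' plus PR2-plot coordinates.
#'
#' GC3s and the B3s fractions are computed over synonymously variable third
#' positions only (one-fold Met/Trp and stop codons excluded). Each B3s uses
#' the CodonW-style denominator: third positions of synonymous codons in whose
#' family base B can occur as a synonymous variant — so the four values need
#' not sum to 1.
#'
#' @param sequence A nucleotide string or one-row CDS tibble.
#' @param pr2_scope Codon scope for the PR2 point: `"fourfold_only"` (third
#'   positions of fourfold-degenerate boxes, the default) or `"all_silent"`.
#' @return A one-row tibble (see [composition_table()] for columns).
#' @examples
#' composition_profile("GCGGCGGCG")$gc3s # 1
#' @export
composition_profile <- function(sequence, pr2_scope = "fourfold_only") {
  if (is.data.frame(sequence)) {
    abort_if(nrow(sequence) != 1L, "pass a single sequence")
    id <- sequence$gene_id
    sequence <- sequence$sequence
  } else {
    id <- "gene"
  }
  counts <- count_codons(sequence)
  m <- matrix(counts, nrow = 1, dimnames = list(id, names(counts)))
  composition_from_counts(m, pr2_scope = pr2_scope)
}

#' Per-gene composition table
#'
#' Vectorized [composition_profile()] over a CDS set.
#'
#' @param cds A filtered CDS tibble.
#' @inheritParams composition_profile
#' @return A tibble with one row per gene: `gene_id`, `length_bp`, `gc`,
#'   `gc1`, `gc2`, `gc3`, `gc12`, `gc3s`, `a3s`, `t3s`, `g3s`, `c3s`,
#'   `pr2_x`, `pr2_y`.
#' @export
composition_table <- function(cds, pr2_scope = "fourfold_only") {
  assert_cds_tbl(cds)
  composition_from_counts(codon_count_matrix(cds), pr2_scope = pr2_scope)
}

#' PR2 point of one gene
#'
#' Parity-rule-2 coordinates: `x = G3/(G3+C3)`, `y = A3/(A3+T3)` over the
#' configured third-position scope. `(0.5, 0.5)` marks balanced use of the
#' complementary bases. A zero denominator yields `NA` (flagged point,
#' excluded from plots).
#'
#' @param counts A named 64-codon count vector (see [count_codons()]) or a
#'   nucleotide string.
#' @param scope `"fourfold_only"` or `"all_silent"`.
#' @return One-row tibble with `pr2_x`, `pr2_y`.
#' @export
pr2_point <- function(counts, scope = "fourfold_only") {
  if (is.character(counts)) counts <- count_codons(counts)
  v <- as_count_vector(counts)
  m <- matrix(v, nrow = 1, dimnames = list("gene", names(v)))
  p <- pr2_from_counts(m, scope = scope)
  tibble::tibble(pr2_x = p$x, pr2_y = p$y)
}
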