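# Typical eukaryotic proteome amino-acid frequencies (renormalized), used as
# the default composition of synthetic genes.
default_aa_frequencies <- function() {
  f <- c(
    A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
    E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
    M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
    Y = 0.032, V = 0.073
  )
  f / sum(f)
}

#' Configuration for the synthetic transcriptome generator
#'
#' Defaults emulate the study conditions of a shrimp hepatopancreas
#' transcriptome: ~9400 filtered unigenes, lengths log-normal above 400 bp,
#' weak per-gene C/G-ending codon bias (beta drawn from a Beta distribution),
#' log-normal FPKM rank-correlated with the bias strength, and ortholog
#' divergence targets equal to the reported genome-wide mean Ka and Ks.
#'
#' @param n_genes Number of genes.
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length
#'   (bp); lengths are floored at `min_length`.
#' @param min_length Minimum gene length (bp).
#' @param beta_shape1,beta_shape2 Beta-distribution parameters of the
#'   per-gene bias strength beta in `[0, 1]`.
#' @param rho Gaussian-copula rank correlation between beta and FPKM.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal FPKM parameters.
#' @param aa_frequencies Named 20-vector of amino-acid frequencies.
#' @param ka_target,ks_target Default planted divergence for ortholog pairs.
#' @param seed Integer seed; the generator draws all randomness from one
#'   stream seeded with it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 9414L,
                             length_meanlog = log(1200), length_sdlog = 0.45,
                             min_length = 402L,
                             beta_shape1 = 1.5, beta_shape2 = 6,
                             rho = 0.6,
                             fpkm_meanlog = 2, fpkm_sdlog = 1.5,
                             aa_frequencies = default_aa_frequencies(),
                             ka_target = 0.002, ks_target = 0.019,
                             seed = 1L) {
  abort_if(n_genes < 0, "n_genes must be >= 0")
  abort_if(rho < -1 || rho > 1, "rho must be in [-1, 1]")
  abort_if(min_length < 3, "min_length must be >= 3")
  structure(
    list(
      n_genes = as.integer(n_genes),
      length_meanlog = length_meanlog, length_sdlog = length_sdlog,
      min_length = as.integer(min_length),
      beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
      rho = rho,
      fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
      aa_frequencies = aa_frequencies,
      ka_target = ka_target, ks_target = ks_target,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Sample one synthetic coding sequence
#'
#' Amino acids are drawn i.i.d. from the configured frequencies; within each
#' synonymous family the codon is chosen with probability proportional to
#' `exp(beta * s)` where `s = +1` for C/G-ending and `-1` for A/T-ending
#' codons. `beta = 0` gives uniform family usage (no bias, ENc near 61);
#' large beta concentrates usage on C/G-ending codons and drives ENc down.
#' An ATG start is prepended and a random stop codon appended. Draws come
#' from the current RNG state, so results are deterministic under a fixed
#' seed.
#'
#' @param n_codons Number of interior (non-start, non-stop) codons.
#' @param beta Bias strength in `[0, 1]` (values above 1 are allowed for
#'   stress tests).
#' @param aa_frequencies Named amino-acid frequency vector.
#' @return A nucleotide string of length `3 * (n_codons + 2)`.
#' @export
sample_gene <- function(n_codons, beta, aa_frequencies = default_aa_frequencies()) {
  abort_if(n_codons < 1, "n_codons must be >= 1")
  code <- genetic_code()
  aas <- sample(names(aa_frequencies), n_codons, replace = TRUE,
                prob = aa_frequencies)
  cod <- character(n_codons)
  for (a in unique(aas)) {
    fam <- code$family[[a]]
    idx <- which(aas == a)
    if (length(fam) == 1L) {
      cod[idx] <- fam
    } else {
      w <- exp(beta * ifelse(code$cg_ending[fam], 1, -1))
      cod[idx] <- fam[sample.int(length(fam), length(idx), replace = TRUE, prob = w)]
    }
  }
  paste0("ATG", paste(cod, collapse = ""),
         code$stop_codons[sample.int(3L, 1L)])
}

#' Sample a synthetic transcriptome
#'
#' Generates `n_genes` coding sequences with per-gene bias strengths drawn
#' from the configured Beta distribution and FPKM values coupled to the bias
#' through a Gaussian copula with rank correlation `rho` — planting the
#' expression/bias structure (high FPKM with high GC3s, low A3s/T3s) the
#' downstream correlation analyses are designed to detect.
#'
#' @param config A [synthetic_config()].
#' @param species_label Species label for the CDS tibble.
#' @param fasta,expression,truth Optional output paths; when given, the CDS
#'   set, the `gene_id`/`fpkm` TSV and the ground-truth table are written
#'   there.
#' @return A list: `cds` (CDS tibble ready for the pipeline) and `truth`
#'   (tibble: `gene_id`, `beta`, `gc3_target` — the expected C/G share at
#'   two-fold silent sites — and `fpkm`).
#' @export
sample_transcriptome <- function(config = synthetic_config(),
                                 species_label = "synthetic",
                                 fasta = NULL, expression = NULL, truth = NULL) {
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0) {
    empty <- tibble::tibble(gene_id = character(0), species = character(0),
                            sequence = character(0), fpkm = numeric(0))
    return(list(
      cds = empty,
      truth = tibble::tibble(gene_id = character(0), beta = numeric(0),
                             gc3_target = numeric(0), fpkm = numeric(0))
    ))
  }
  z1 <- stats::rnorm(n)
  z2 <- config$rho * z1 + sqrt(1 - config$rho^2) * stats::rnorm(n)
  beta <- stats::qbeta(stats::pnorm(z1), config$beta_shape1, config$beta_shape2)
  fpkm <- stats::qlnorm(stats::pnorm(z2), config$fpkm_meanlog, config$fpkm_sdlog)
  len_bp <- pmax(config$min_length,
                 round(stats::rlnorm(n, config$length_meanlog, config$length_sdlog)))
  n_codons <- pmax(1L, len_bp %/% 3L - 2L)
  seqs <- vapply(seq_len(n), function(i) {
    sample_gene(n_codons[i], beta[i], config$aa_frequencies)
  }, character(1))
  ids <- sprintf("g%05d", seq_len(n))
  cds <- tibble::tibble(gene_id = ids, species = species_label,
                        sequence = seqs, fpkm = fpkm)
  truth_tbl <- tibble::tibble(
    gene_id = ids, beta = beta,
    gc3_target = stats::plogis(2 * beta), fpkm = fpkm
  )
  if (!is.null(fasta)) write_cds_fasta(cds, fasta)
  if (!is.null(expression)) {
    readr::write_tsv(tibble::tibble(gene_id = ids, fpkm = fpkm), expression)
  }
  if (!is.null(truth)) readr::write_tsv(truth_tbl, truth)
  list(cds = cds, truth = truth_tbl)
}

# Per-codon lists of single-base synonymous / nonsynonymous replacements
# (targets never stops), cached.
codon_change_tables <- function() {
  if (!is.null(.cs_cache$changes)) {
    return(.cs_cache$changes)
  }
  code <- genetic_code()
  c2a <- code$codon_to_aa
  bases <- c("A", "C", "G", "T")
  syn <- nonsyn <- vector("list", length(code$sense_codons))
  names(syn) <- names(nonsyn) <- code$sense_codons
  for (cod in code$sense_codons) {
    s_t <- n_t <- character(0)
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        x <- cod
        substr(x, pos, pos) <- b
        if (c2a[x] == "*") next
        if (c2a[x] == c2a[cod]) s_t <- c(s_t, x) else n_t <- c(n_t, x)
      }
    }
    syn[[cod]] <- s_t
    nonsyn[[cod]] <- n_t
  }
  .cs_cache$changes <- list(syn = syn, nonsyn = nonsyn)
  .cs_cache$changes
}

#' Evolve a diverged ortholog from a coding sequence
#'
#' Applies Poisson numbers of synonymous and nonsynonymous single-base codon
#' changes, calibrated so the NG86 site-normalized expectations equal the
#' planted targets: the event counts are drawn with means `S * p` and
#' `N * p`, where S and N are the sequence's NG86 synonymous and
#' nonsynonymous site counts and `p = 3/4 (1 - exp(-4/3 d))` inverts the
#' Jukes-Cantor correction for target divergence d. Events are interleaved in
#' random order; each picks a codon (weighted by its number of available
#' changes of that type) and replaces it with a random synonymous or
#' nonsynonymous neighbour. Changes through stop codons never occur.
#'
#' @param sequence Nucleotide string or one-row CDS tibble.
#' @param ka_target,ks_target Planted substitutions per site; both must be
#'   <= 0.5 (beyond that the process saturates and the targets are not
#'   recoverable).
#' @return The mutated nucleotide string.
#' @export
evolve_ortholog <- function(sequence, ka_target, ks_target) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  abort_if(ka_target < 0 || ks_target < 0, "targets must be >= 0")
  abort_if(ka_target > 0.5 || ks_target > 0.5,
           "targets above 0.5 substitutions/site saturate the process")
  code <- genetic_code()
  tabs <- ng86_tables()
  changes <- codon_change_tables()

  cod <- split_codons(sequence)
  is_sense <- cod %in% code$sense_codons
  s_sites <- sum(tabs$syn_sites[cod[is_sense]])
  n_sites <- 3 * sum(is_sense) - s_sites

  inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  n_syn <- stats::rpois(1, s_sites * inv_jc(ks_target))
  n_non <- stats::rpois(1, n_sites * inv_jc(ka_target))
  if (n_syn + n_non == 0) {
    return(sequence)
  }
  events <- sample(c(rep("s", n_syn), rep("n", n_non)))
  w_syn <- ifelse(is_sense, lengths(changes$syn)[cod], 0)
  w_non <- ifelse(is_sense, lengths(changes$nonsyn)[cod], 0)
  w_syn[is.na(w_syn)] <- 0
  w_non[is.na(w_non)] <- 0
  for (ev in events) {
    w <- if (ev == "s") w_syn else w_non
    if (sum(w) == 0) next
    i <- sample.int(length(cod), 1L, prob = w)
    opts <- if (ev == "s") changes$syn[[cod[i]]] else changes$nonsyn[[cod[i]]]
    cod[i] <- opts[sample.int(length(opts), 1L)]
    w_syn[i] <- length(changes$syn[[cod[i]]])
    w_non[i] <- length(changes$nonsyn[[cod[i]]])
  }
  paste(cod, collapse = "")
}

#' Sample a set of diverged ortholog pairs
#'
#' Convenience wrapper: generates `n_pairs` ancestral genes and evolves one
#' diverged copy of each at the planted (ka, ks) targets.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Interior codons per gene.
#' @param ka_target,ks_target Planted divergence (recycled across pairs).
#' @param beta Bias strength for the ancestral genes.
#' @return A list of CDS tibbles `a` and `b`, plus an `orthologs` mapping
#'   tibble (`id_a`, `id_b`).
#' @export
sample_ortholog_pairs <- function(n_pairs, n_codons = 500L,
                                  ka_target = 0.002, ks_target = 0.019,
                                  beta = 0.1) {
  ka_target <- rep_len(ka_target, n_pairs)
  ks_target <- rep_len(ks_target, n_pairs)
  seq_a <- vapply(seq_len(n_pairs), function(i) sample_gene(n_codons, beta),
                  character(1))
  seq_b <- vapply(seq_len(n_pairs), function(i) {
    evolve_ortholog(seq_a[i], ka_target[i], ks_target[i])
  }, character(1))
  ids_a <- sprintf("a%05d", seq_len(n_pairs))
  ids_b <- sprintf("b%05d", seq_len(n_pairs))
  list(
    a = tibble::tibble(gene_id = ids_a, species = "species_a",
                       sequence = seq_a, fpkm = NA_real_),
    b = tibble::tibble(gene_id = ids_b, species = "species_b",
                       sequence = seq_b, fpkm = NA_real_),
    orthologs = tibble::tibble(id_a = ids_a, id_b = ids_b)
  )
}
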