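# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (string counting, explicit loops,
# enumeration) and share no code with the package internals they check.

make_cds <- function(sequences, ids = NULL, species = "toy", fpkm = NA_real_) {
  tibble::tibble(
    gene_id = ids %||% sprintf("g%03d", seq_along(sequences)),
    species = species,
    sequence = sequences,
    fpkm = fpkm
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random in-frame CDS over sense codons (no internal stops), given length in
# codons; draws from the current RNG.
random_cds_string <- function(n_codons) {
  code <- genetic_code()
  paste(sample(code$sense_codons, n_codons, replace = TRUE), collapse = "")
}

# Brute-force GC fraction by character counting.
oracle_gc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  mean(chars %in% c("G", "C"))
}

# Brute-force RSCU by explicit per-family loops.
oracle_rscu <- function(codon_vec) {
  code <- genetic_code()
  out <- list()
  for (aa in names(code$degeneracy)[code$degeneracy >= 2]) {
    fam <- code$family[[aa]]
    tot <- sum(codon_vec %in% fam)
    for (cod in fam) {
      out[[cod]] <- if (tot == 0) NA_real_ else {
        sum(codon_vec == cod) / (tot / length(fam))
      }
    }
  }
  out
}

# Brute-force family homozygosity Fhat = (n * sum p^2 - 1) / (n - 1).
oracle_fhat <- function(codon_vec, aa) {
  code <- genetic_code()
  fam <- code$family[[aa]]
  counts <- vapply(fam, function(cod) sum(codon_vec == cod), numeric(1))
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

# Brute-force codon pair counting with a double loop.
oracle_pair_counts <- function(token_lists) {
  code <- genetic_code()
  env <- new.env()
  for (tokens in token_lists) {
    if (length(tokens) < 2) next
    for (i in seq_len(length(tokens) - 1)) {
      a <- tokens[i]; b <- tokens[i + 1]
      if (a %in% code$stop_codons || b %in% code$stop_codons) next
      key <- paste(a, b)
      env[[key]] <- (env[[key]] %||% 0L) + 1L
    }
  }
  as.list(env)
}

# Brute-force NG86 on an aligned codon pair list: explicit per-codon site
# fractions and recursive pathway enumeration.
oracle_ng86 <- function(ca, cb) {
  code <- genetic_code()
  c2a <- code$codon_to_aa
  bases <- c("A", "C", "G", "T")
  site_s <- function(cod) {
    s <- 0
    for (pos in 1:3) {
      syn <- 0; ok <- 0
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        alt <- cod; substr(alt, pos, pos) <- b
        if (c2a[alt] == "*") next
        ok <- ok + 1
        if (c2a[alt] == c2a[cod]) syn <- syn + 1
      }
      if (ok > 0) s <- s + syn / ok
    }
    s
  }
  pair_diffs <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    paths <- list()
    walk <- function(cur, remaining, sd, nd, blocked) {
      if (length(remaining) == 0) {
        paths[[length(paths) + 1]] <<- c(sd, nd, blocked)
        return(invisible())
      }
      for (p in remaining) {
        nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
        walk(nxt, setdiff(remaining, p),
             sd + (c2a[nxt] == c2a[cur] && c2a[nxt] != "*"),
             nd + (c2a[nxt] != c2a[cur] || c2a[nxt] == "*"),
             blocked || c2a[nxt] == "*")
      }
    }
    walk(a, pos, 0, 0, FALSE)
    m <- do.call(rbind, paths)
    open <- m[m[, 3] == 0, , drop = FALSE]
    if (nrow(open) == 0) open <- m
    c(mean(open[, 1]), mean(open[, 2]))
  }
  S <- (sum(vapply(ca, site_s, 1)) + sum(vapply(cb, site_s, 1))) / 2
  N <- 3 * length(ca) - S
  dmat <- t(vapply(seq_along(ca), function(i) pair_diffs(ca[i], cb[i]), numeric(2)))
  Sd <- sum(dmat[, 1]); Nd <- sum(dmat[, 2])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ks = jc(Sd / S), ka = jc(Nd / N))
}

# Brute-force CA via eigendecomposition of t(S) %*% S.
oracle_ca <- function(mat) {
  p <- mat / sum(mat)
  r <- rowSums(p); cm <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - outer(r, cm)) %*% diag(1 / sqrt(cm))
  ev <- eigen(t(s) %*% s, symmetric = TRUE)
  list(inertia = sum(diag(t(s) %*% s)),
       eigenvalues = ev$values[ev$values > 1e-12])
}
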