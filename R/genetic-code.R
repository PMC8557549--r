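#' @keywords internal
#' @importFrom rlang .data
#' @importFrom dplyr n
"_PACKAGE"

# Package-level cache for derived genetic-code tables and NG86 lookup matrices.
.cs_cache <- new.env(parent = emptyenv())

#' The standard genetic code and derived synonymous-family tables
#'
#' Returns the standard nuclear genetic code together with every derived table
#' the rest of the package consumes: the synonymous families, degeneracy
#' classes, the 59 "informative" codons (sense codons minus the one-fold Met
#' and Trp), fourfold-degenerate codon boxes and per-codon third-base
#' annotations. The object is built once per session and cached.
#'
#' @details
#' Degeneracy classes of the standard code: 2 one-fold amino acids (Met, Trp),
#' 9 two-fold, 1 three-fold (Ile), 5 four-fold and 3 six-fold (Leu, Ser, Arg).
#' The six-fold families are additionally split into their four-fold box
#' (e.g. CTN for Leu) and two-fold remainder, which is what fourfold-site
#' selections (PR2 analysis) use.
#'
#' @return A list with elements:
#' \describe{
#'   \item{codons}{all 64 codons (DNA alphabet), fixed order}
#'   \item{codon_to_aa}{named character vector, codon to one-letter amino acid
#'     (`"*"` for stop)}
#'   \item{sense_codons, stop_codons}{the 61 / 3 codon sets}
#'   \item{informative_codons}{the 59 codons used for RSCU/CA, ordered by
#'     amino acid then codon}
#'   \item{family}{named list: amino acid to its synonymous codon set}
#'   \item{degeneracy}{named integer: amino acid to family size k}
#'   \item{fourfold_codons}{the 32 codons in fourfold-degenerate boxes}
#'   \item{third_base}{named character: codon to its third base}
#'   \item{cg_ending}{named logical: codon ends in C or G}
#'   \item{aa3}{named character: one-letter to three-letter amino acid}
#' }
#' @examples
#' code <- genetic_code()
#' length(code$informative_codons) # 59
#' code$degeneracy[["L"]]          # 6
#' @export
genetic_code <- function() {
  if (!is.null(.cs_cache$code)) {
    return(.cs_cache$code)
  }
  c2a <- Biostrings::GENETIC_CODE
  codons <- names(c2a)
  sense <- codons[c2a != "*"]
  stops <- codons[c2a == "*"]
  family <- split(sense, c2a[sense])
  degeneracy <- vapply(family, length, integer(1))
  informative <- setdiff(sense, c("ATG", "TGG"))
  informative <- informative[order(c2a[informative], informative)]

  # Fourfold-degenerate boxes: 2-nt prefixes whose four completions encode
  # one amino acid (includes the 4-fold halves of the six-fold families).
  prefixes <- unique(substr(sense, 1, 2))
  fourfold <- unlist(lapply(prefixes, function(p) {
    quad <- paste0(p, c("T", "C", "A", "G"))
    if (length(unique(c2a[quad])) == 1L && all(quad %in% sense)) quad else character(0)
  }))

  third <- substr(codons, 3, 3)
  names(third) <- codons

  # For each degenerate family, which bases occur at its synonymous third
  # positions (the CodonW-style denominators for A3s/T3s/G3s/C3s).
  third_avail <- lapply(family, function(cods) sort(unique(substr(cods, 3, 3))))

  aa3 <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val"
  )

  code <- list(
    codons = codons,
    codon_to_aa = c2a,
    sense_codons = sense,
    stop_codons = stops,
    informative_codons = informative,
    family = family,
    degeneracy = degeneracy,
    fourfold_codons = fourfold,
    third_base = third,
    third_base_available = third_avail,
    cg_ending = stats::setNames(third %in% c("C", "G"), codons),
    aa3 = aa3
  )
  .cs_cache$code <- code
  code
}

# Degenerate sense codons: members of families with k >= 2 (59 codons).
degenerate_codons <- function(code = genetic_code()) {
  code$informative_codons
}

# Families with k >= 2, as a named list, split by degeneracy class.
degeneracy_classes <- function(code = genetic_code()) {
  deg <- code$degeneracy
  list(
    k2 = names(deg)[deg == 2L],
    k3 = names(deg)[deg == 3L],
    k4 = names(deg)[deg == 4L],
    k6 = names(deg)[deg == 6L]
  )
}
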