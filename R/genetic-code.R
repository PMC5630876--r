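#' Standard genetic code services
#'
#' The package works throughout with the standard nuclear genetic code:
#' 61 sense codons, 3 stop codons (TAA, TAG, TGA). Codons are indexed
#' 1..61 in lexicographic (A < C < G < T) order of the sense codons; this
#' ordering defines the state space of all codon substitution models here.
#'
#' @return `genetic_code()` returns a list with components
#'   `codons` (61 sense codons), `stops` (3 stop codons), `aa` (named
#'   amino-acid letter per sense codon), and `fourfold` (logical per sense
#'   codon: third position fully degenerate).
#' @export
genetic_code <- function() .gc_env$code

.gc_env <- new.env(parent = emptyenv())

.build_genetic_code <- function() {
  nts <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  all64 <- sort(all64)
  # amino acid per codon, standard code
  aa_tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  stopifnot(length(aa_tab) == 64L, all(sort(names(aa_tab)) == all64))
  stops <- names(aa_tab)[aa_tab == "*"]
  codons <- sort(setdiff(all64, stops))
  aa <- aa_tab[codons]
  # 4-fold degeneracy at the third position: the first two positions fix
  # the amino acid whatever the third nucleotide is (and no stop arises)
  doublets <- substr(codons, 1, 2)
  fourfold <- vapply(codons, function(cd) {
    fam <- paste0(substr(cd, 1, 2), nts)
    all(fam %in% codons) && length(unique(aa_tab[fam])) == 1L
  }, logical(1))
  list(codons = codons, stops = stops, aa = aa, fourfold = fourfold,
       doublets = doublets)
}

.gc_env$code <- .build_genetic_code()

#' Translate an in-frame codon sequence
#'
#' Gap codons (`---`) translate to `-`; codons containing `N` or a partial
#' gap translate to `X` and are treated as missing downstream. Internal
#' stop codons are an error unless `allow_stop = TRUE`, in which case they
#' translate to `*`.
#'
#' @param codon_seq a DNA string with length divisible by 3 (gaps allowed).
#' @param allow_stop keep internal stop codons as `*` instead of erroring.
#' @param code genetic code as returned by [genetic_code()].
#' @return a protein string, one character per codon.
#' @export
translate_codons <- function(codon_seq, allow_stop = FALSE,
                             code = genetic_code()) {
  n <- nchar(codon_seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3")
  if (n == 0L) return("")
  cods <- substring(codon_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  cods <- toupper(cods)
  out <- character(length(cods))
  aa <- code$aa
  for (i in seq_along(cods)) {
    cd <- cods[i]
    if (cd == "---") {
      out[i] <- "-"
    } else if (cd %in% code$stops) {
      if (!allow_stop)
        stop("internal stop codon at codon index ", i)
      out[i] <- "*"
    } else if (!is.na(aa[cd])) {
      out[i] <- aa[[cd]]
    } else {
      out[i] <- "X"   # ambiguous (N) or partially gapped codon
    }
  }
  paste(out, collapse = "")
}

#' Index sense codons of an in-frame alignment
#'
#' Maps every codon of a codon alignment to its 1..61 state index;
#' gap/ambiguous/partial codons become `NA` (missing data in the
#' likelihood).
#'
#' @param aln codon alignment (character matrix of nucleotides, see
#'   [as_alignment_matrix()]).
#' @param code genetic code.
#' @return integer matrix, sequences x codon columns.
#' @export
codon_states <- function(aln, code = genetic_code()) {
  stopifnot(is.matrix(aln), ncol(aln) %% 3L == 0L)
  ncod <- ncol(aln) %/% 3L
  out <- matrix(NA_integer_, nrow(aln), ncod,
                dimnames = list(rownames(aln), NULL))
  for (j in seq_len(ncod)) {
    cods <- toupper(paste0(aln[, 3L * j - 2L], aln[, 3L * j - 1L], aln[, 3L * j]))
    idx <- match(cods, code$codons)
    out[, j] <- idx
  }
  out
}
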