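#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()]; accepts wrapped
#' lines and trailing whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- trimws(sub("\\s.*$", "", names(x)))
  out
}

#' Write sequences to FASTA (60-column wraps)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Convert sequences to an alignment matrix
#'
#' Alignments are represented as character matrices (rows = sequences,
#' columns = alignment columns, rownames = sequence ids).
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return character matrix.
#' @export
as_alignment_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  stopifnot(!is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("aligned sequences must all have equal length; got lengths ",
         paste(sort(unique(nchar(seqs))), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

#' Collapse an alignment matrix back to strings
#' @param m alignment matrix.
#' @return named character vector.
#' @export
alignment_strings <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Parse a Newick tree
#'
#' Wrapper around [ape::read.tree()] adding the error contract used
#' throughout: unbalanced parentheses and duplicate tip labels are
#' reported with position information.
#'
#' @param text a Newick string.
#' @return an `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  no <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nc <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (no != nc)
    stop("unbalanced parentheses in Newick string: ", no, " '(' vs ",
         nc, " ')'")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  tr
}

#' Serialize a tree to Newick
#' @param tree an `ape::phylo`.
#' @return a Newick string.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

#' Write an alignment in relaxed PHYLIP format
#'
#' Sequential relaxed PHYLIP (name, space, full sequence per line), the
#' format consumed by ML tree software for supermatrices.
#'
#' @param m alignment matrix or named character vector.
#' @param path output file.
#' @export
write_phylip <- function(m, path) {
  m <- as_alignment_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(m), ncol(m)), con)
  writeLines(paste(rownames(m), apply(m, 1L, paste, collapse = "")), con)
  invisible(path)
}

.revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  chars <- rev(strsplit(toupper(dna), "")[[1]])
  paste(comp[chars], collapse = "")
}

#' Extract the longest open reading frame
#'
#' Scans all three frames of the forward strand and (by default) the
#' reverse complement for the longest ATG-initiated, stop-free stretch
#' of codons (the usual transcript ORF convention). Ties are broken in
#' favour of the forward strand, then the lowest frame index. A
#' terminal stop codon bounding the ORF is not part of the reported
#' protein.
#'
#' @param dna a DNA string (length >= 3).
#' @param both_strands also scan the reverse complement (default TRUE).
#' @return list with `protein`, `cds`, `strand` ("+"/"-"), `frame` (0..2),
#'   and `found` (FALSE when no codon-length stop-free window exists).
#' @export
extract_longest_orf <- function(dna, both_strands = TRUE) {
  dna <- toupper(gsub("\\s", "", dna))
  if (nchar(dna) < 3L) stop("DNA sequence shorter than one codon")
  code <- genetic_code()
  best <- list(protein = "", cds = "", strand = "+", frame = 0L, found = FALSE)
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    s <- if (st == "+") dna else .revcomp(dna)
    for (fr in 0:2) {
      ncod <- (nchar(s) - fr) %/% 3L
      if (ncod < 1L) next
      starts <- fr + seq(1L, by = 3L, length.out = ncod)
      cods <- substring(s, starts, starts + 2L)
      is_stop <- cods %in% code$stops
      # runs of non-stop codons
      r <- rle(!is_stop)
      ends <- cumsum(r$lengths)
      begins <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        run <- cods[begins[k]:ends[k]]
        atg <- which(run == "ATG")[1]
        if (is.na(atg)) next
        run <- run[atg:length(run)]
        if (length(run) > nchar(best$protein)) {
          aa <- code$aa[run]
          aa[is.na(aa)] <- "X"
          best <- list(protein = paste(aa, collapse = ""),
                       cds = paste(run, collapse = ""),
                       strand = st, frame = fr, found = TRUE)
        }
      }
    }
  }
  best
}

#' Back-translate a protein alignment to codons
#'
#' Expands each protein column to the corresponding codon triplet using
#' the ungapped coding sequence of each row; protein gaps become `---`.
#'
#' @param protein_aln protein alignment (matrix or named strings).
#' @param cds_by_id named character vector of ungapped coding sequences.
#' @return codon alignment matrix (3x the protein columns).
#' @export
back_translate <- function(protein_aln, cds_by_id) {
  p <- as_alignment_matrix(protein_aln)
  out <- matrix("-", nrow(p), 3L * ncol(p),
                dimnames = list(rownames(p), NULL))
  for (i in seq_len(nrow(p))) {
    id <- rownames(p)[i]
    cds <- cds_by_id[[id]]
    if (is.null(cds) || is.na(cds))
      stop("no coding sequence supplied for ", id)
    cds <- toupper(gsub("-", "", cds))
    res_cols <- which(p[i, ] != "-")
    if (3L * length(res_cols) != nchar(cds))
      stop("CDS length mismatch for ", id, ": ", nchar(cds),
           " nt vs ", length(res_cols), " residues")
    prot <- translate_codons(cds, allow_stop = FALSE)
    obs <- paste(p[i, res_cols], collapse = "")
    if (prot != obs) {
      d <- which(strsplit(prot, "")[[1]] != strsplit(obs, "")[[1]])[1]
      stop("CDS does not translate to aligned protein for ", id,
           "; first discordant residue at position ", d)
    }
    for (k in seq_along(res_cols)) {
      j <- res_cols[k]
      out[i, (3L * j - 2L):(3L * j)] <-
        strsplit(substr(cds, 3L * k - 2L, 3L * k), "")[[1]]
    }
  }
  out
}

#' Translate every row of a codon alignment
#'
#' @param codon_aln codon alignment (matrix or named strings).
#' @param allow_stop passed to [translate_codons()].
#' @return protein alignment matrix.
#' @export
translate_alignment <- function(codon_aln, allow_stop = FALSE) {
  s <- alignment_strings(as_alignment_matrix(codon_aln))
  as_alignment_matrix(vapply(s, translate_codons, "", allow_stop = allow_stop))
}
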