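#' Extract four-fold degenerate sites from a codon alignment
#'
#' A codon column yields a third-position site only when every non-gap,
#' unambiguous codon in it belongs to a four-fold degenerate family
#' (third position free) and all share the same first two nucleotides,
#' so that no substitution at the extracted site can ever change any
#' sequence's amino acid. Gap codons contribute gaps. This strict
#' column-wide criterion keeps phylogeny estimation independent of
#' protein-level selection.
#'
#' @param c in-frame codon alignment matrix.
#' @param code genetic code.
#' @return nucleotide alignment matrix of the extracted third positions,
#'   with attribute `codon_cols` (source codon column indices).
#' @export
fourfold_sites <- function(c, code = genetic_code()) {
  m <- as_alignment_matrix(c)
  stopifnot(ncol(m) %% 3L == 0L)
  ncod <- ncol(m) %/% 3L
  ff_codons <- code$codons[code$fourfold]
  keep <- logical(ncod)
  third <- matrix("-", nrow(m), ncod, dimnames = list(rownames(m), NULL))
  for (j in seq_len(ncod)) {
    block <- m[, (3L * j - 2L):(3L * j), drop = FALSE]
    cods <- toupper(paste0(block[, 1], block[, 2], block[, 3]))
    nongap <- cods != "---"
    ok <- any(nongap) &&
      all(cods[nongap] %in% ff_codons) &&
      length(unique(substr(cods[nongap], 1, 2))) == 1L
    if (ok) {
      keep[j] <- TRUE
      third[nongap, j] <- substr(cods[nongap], 3, 3)
    }
  }
  out <- third[, keep, drop = FALSE]
  attr(out, "codon_cols") <- which(keep)
  out
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Species absent from a gene are filled with gaps; columns present in
#' fewer than half of the species are trimmed (strict less-than: exactly
#' half is kept); partition ranges are recomputed after trimming. Row
#' order is lexicographic by species.
#'
#' @param genes named list of nucleotide alignment matrices with species
#'   rownames.
#' @param min_present_frac minimum fraction of species with data per
#'   column (default 0.5).
#' @return list of class `supermatrix`: `matrix`, `partitions`
#'   (data.frame gene/start/end; genes emptied by trimming are absent),
#'   `gap_fraction` (per species).
#' @export
build_supermatrix <- function(genes, min_present_frac = 0.5) {
  if (is.null(names(genes)))
    names(genes) <- sprintf("gene%03d", seq_along(genes))
  species <- sort(unique(unlist(lapply(genes, rownames))))
  n <- length(species)
  blocks <- list()
  parts <- data.frame(gene = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  at <- 0L
  for (g in names(genes)) {
    m <- as_alignment_matrix(genes[[g]])
    if (anyDuplicated(rownames(m)))
      stop("duplicate species in gene ", g, ": ",
           paste(unique(rownames(m)[duplicated(rownames(m))]),
                 collapse = ", "))
    full <- matrix("-", n, ncol(m), dimnames = list(species, NULL))
    full[rownames(m), ] <- m
    present <- colSums(full != "-")
    keep <- present >= n * min_present_frac  # strict "< half" trimmed
    full <- full[, keep, drop = FALSE]
    if (ncol(full) == 0L) next
    blocks[[g]] <- full
    parts <- rbind(parts, data.frame(gene = g, start = at + 1L,
                                     end = at + ncol(full)))
    at <- at + ncol(full)
  }
  mat <- if (length(blocks)) do.call(cbind, blocks) else
    matrix("-", n, 0L, dimnames = list(species, NULL))
  colnames(mat) <- NULL
  gap_fraction <- rowSums(mat == "-") / max(1L, ncol(mat))
  structure(list(matrix = mat, partitions = parts,
                 gap_fraction = gap_fraction),
            class = "supermatrix")
}

#' Write a supermatrix and its partition file
#'
#' Relaxed PHYLIP plus a RAxML-style partition file
#' (`DNA, gene = start-end`).
#'
#' @param sm a [build_supermatrix()] result.
#' @param phylip_path,partition_path output files.
#' @export
write_supermatrix <- function(sm, phylip_path, partition_path) {
  write_phylip(sm$matrix, phylip_path)
  lines <- sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                   sm$partitions$start, sm$partitions$end)
  writeLines(lines, partition_path)
  invisible(list(phylip = phylip_path, partitions = partition_path))
}
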