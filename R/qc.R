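# residue index per cell: for each row, the running count of non-gap
# characters; NA at gaps
.residue_index <- function(m) {
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    res <- m[i, ] != "-"
    out[i, res] <- seq_len(sum(res))
  }
  out
}

# column of residue r of row `id` in alignment m: map[[id]][r]
.residue_columns <- function(m) {
  ri <- .residue_index(m)
  lapply(stats::setNames(seq_len(nrow(m)), rownames(m)), function(i) {
    which(!is.na(ri[i, ]))
  })
}

.check_same_content <- function(primary, alt) {
  dg <- function(m) gsub("-", "", alignment_strings(m))
  a <- dg(primary); b <- dg(alt)
  if (!setequal(names(a), names(b)) || any(a[names(b)] != b))
    stop("alternative alignment does not contain the same ungapped ",
         "sequences as the primary")
}

#' Aligner-concordance column filter
#'
#' Scores each primary column 0-9 by the fraction of its residue pairs
#' that are co-aligned (placed in one column) in every alternative
#' alignment of the same sequences; `floor(9 x fraction)`. Only columns
#' with the maximum score of 9 -- total concordance across aligners --
#' are kept. Columns with fewer than two residues carry no pair evidence
#' and score 9.
#'
#' @param primary protein alignment (matrix or named strings).
#' @param alternatives list of alternative alignments of the same
#'   ungapped sequences.
#' @return list: `alignment` (kept columns), `scores` (per primary
#'   column), `kept` (column indices).
#' @export
concordance_filter <- function(primary, alternatives) {
  m <- as_alignment_matrix(primary)
  alts <- lapply(alternatives, as_alignment_matrix)
  for (a in alts) .check_same_content(m, a)
  ri <- .residue_index(m)
  # per alternative: column position of each primary residue
  pos <- lapply(alts, function(a) {
    rc <- .residue_columns(a)
    out <- matrix(NA_integer_, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) {
      cols <- rc[[rownames(m)[i]]]
      out[i, ] <- cols[ri[i, ]]
    }
    out
  })
  scores <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    rows <- which(!is.na(ri[, j]))
    n <- length(rows)
    if (n < 2L) { scores[j] <- 9L; next }
    key <- do.call(paste, c(lapply(pos, function(p) p[rows, j]),
                            list(sep = "/")))
    sizes <- table(key)
    agree <- sum(choose(sizes, 2))
    total <- choose(n, 2)
    scores[j] <- as.integer(floor(9 * agree / total))
  }
  kept <- which(scores == 9L)
  list(alignment = m[, kept, drop = FALSE], scores = scores, kept = kept)
}

# residue-pair map from a global pairwise alignment of two ungapped
# sequences: matrix with columns (residue in x, residue in y)
.pairwise_map <- function(x, y, match = 2, mismatch = -1,
                          gap_opening = 4, gap_extension = 1) {
  letters_all <- sort(unique(c(strsplit(x, "")[[1]], strsplit(y, "")[[1]])))
  sm <- matrix(mismatch, length(letters_all), length(letters_all),
               dimnames = list(letters_all, letters_all))
  diag(sm) <- match
  pa <- Biostrings::pairwiseAlignment(x, y, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_opening,
                                      gapExtension = gap_extension)
  ax <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ay <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  rx <- cumsum(ax != "-")
  ry <- cumsum(ay != "-")
  both <- ax != "-" & ay != "-"
  cbind(rx[both], ry[both])
}

#' Transitive-consistency column filter
#'
#' Builds a library of global pairwise alignments of all ungapped
#' sequence pairs and scores each column 0-9 by the fraction of its
#' residue pairings supported by the library; only score-9 columns are
#' kept. With fewer than three sequences the alignment passes through
#' unchanged with a warning.
#'
#' @param a protein alignment (matrix or named strings).
#' @param match,mismatch,gap_opening,gap_extension pairwise-alignment
#'   scoring parameters.
#' @return list: `alignment`, `scores`, `kept`.
#' @export
consistency_filter <- function(a, match = 2, mismatch = -1,
                               gap_opening = 4, gap_extension = 1) {
  m <- as_alignment_matrix(a)
  if (nrow(m) < 3L) {
    warning("fewer than 3 sequences; consistency filter passes through")
    return(list(alignment = m, scores = rep(9L, ncol(m)),
                kept = seq_len(ncol(m))))
  }
  seqs <- gsub("-", "", alignment_strings(m))
  n <- nrow(m)
  lib <- vector("list", n * n)
  dim(lib) <- c(n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    lib[[i, j]] <- .pairwise_map(seqs[i], seqs[j], match, mismatch,
                                 gap_opening, gap_extension)
  }
  supported <- function(i, j, ri, rj) {
    mp <- lib[[i, j]]
    any(mp[, 1] == ri & mp[, 2] == rj)
  }
  ri <- .residue_index(m)
  scores <- integer(ncol(m))
  for (col in seq_len(ncol(m))) {
    rows <- which(!is.na(ri[, col]))
    # a lone residue has no supporting pair in any pairwise alignment
    if (length(rows) < 2L) { scores[col] <- 0L; next }
    tot <- 0L; sup <- 0L
    for (ii in seq_along(rows)) for (jj in seq_along(rows)) {
      if (jj <= ii) next
      i <- rows[ii]; j <- rows[jj]
      tot <- tot + 1L
      if (supported(i, j, ri[i, col], ri[j, col])) sup <- sup + 1L
    }
    scores[col] <- as.integer(floor(9 * sup / tot))
  }
  kept <- which(scores == 9L)
  list(alignment = m[, kept, drop = FALSE], scores = scores, kept = kept)
}

#' Codon occupancy filter
#'
#' Removes codon columns absent (gapped or incomplete) in at least half
#' of the sequences -- the boundary is inclusive, so a column missing
#' from exactly half the species is removed.
#'
#' @param c codon alignment matrix.
#' @param min_present_frac fraction that must be present (default 0.5).
#' @return list: `alignment`, `kept` (codon column indices).
#' @export
occupancy_filter_codons <- function(c, min_present_frac = 0.5) {
  m <- as_alignment_matrix(c)
  stopifnot(ncol(m) %% 3L == 0L)
  ncod <- ncol(m) %/% 3L
  n <- nrow(m)
  present <- vapply(seq_len(ncod), function(j) {
    block <- m[, (3L * j - 2L):(3L * j), drop = FALSE]
    sum(rowSums(block == "-") == 0L)
  }, numeric(1))
  absent <- n - present
  # "absent in at least half" is inclusive: remove when absent >= n * (1 - frac)
  keep <- absent + 1e-9 < n * (1 - min_present_frac)
  cols <- as.vector(vapply(which(keep), function(j)
    (3L * j - 2L):(3L * j), integer(3)))
  list(alignment = m[, cols, drop = FALSE], kept = which(keep))
}

.alignment_area <- function(m) {
  if (nrow(m) == 0L) return(0)
  gapfree <- sum(colSums(m == "-") == 0L)
  gapfree * nrow(m)
}

#' Greedy gap-rich sequence removal
#'
#' Repeatedly removes the sequence whose exclusion most increases the
#' alignment area (gap-free columns x retained sequences) until no
#' single removal helps; ties broken by input order. Poorly aligned
#' gap-rich rows -- often residual paralogs -- are discarded this way.
#'
#' @param a alignment (matrix or named strings).
#' @return list: `alignment`, `removed` (ids in removal order).
#' @export
maxalign_select <- function(a) {
  m <- as_alignment_matrix(a)
  removed <- character(0)
  repeat {
    if (nrow(m) <= 2L) break
    area <- .alignment_area(m)
    gains <- vapply(seq_len(nrow(m)), function(i)
      .alignment_area(m[-i, , drop = FALSE]), numeric(1))
    if (max(gains) <= area) break
    drop <- which.max(gains)  # first index on ties
    removed <- c(removed, rownames(m)[drop])
    m <- m[-drop, , drop = FALSE]
  }
  list(alignment = m, removed = removed)
}

#' Confidence masking with gap and similarity column trimming
#'
#' Replaces residues whose alignment confidence is at or below the
#' threshold with gaps (the boundary is inclusive: 0.93 is masked), then
#' removes columns gapped in at least 40% of sequences, then columns
#' whose similarity (mean pairwise identity of the non-gap residues)
#' falls below 0.001.
#'
#' @param a protein alignment.
#' @param residue_conf per-residue confidences in `[0, 1]` (same shape;
#'   NA allowed at gaps).
#' @param conf_threshold masking threshold (default 0.93, inclusive).
#' @param gap_frac gap-fraction trim threshold (default 0.4, inclusive).
#' @param sim_threshold similarity trim threshold (default 0.001,
#'   strict).
#' @return list: `alignment`, `kept` (column indices), `masked`
#'   (logical matrix on the input shape), `gap_trimmed`, `sim_trimmed`.
#' @export
confidence_mask_and_trim <- function(a, residue_conf, conf_threshold = 0.93,
                                     gap_frac = 0.4, sim_threshold = 0.001) {
  m <- as_alignment_matrix(a)
  if (!all(dim(residue_conf) == dim(m)))
    stop("confidence matrix shape ", paste(dim(residue_conf), collapse = "x"),
         " does not match alignment ", paste(dim(m), collapse = "x"))
  masked <- m != "-" & !is.na(residue_conf) & residue_conf <= conf_threshold
  m[masked] <- "-"
  gf <- colSums(m == "-") / nrow(m)
  gap_trimmed <- which(gf >= gap_frac - 1e-12)
  sim <- vapply(seq_len(ncol(m)), function(j) {
    res <- m[m[, j] != "-", j]
    if (length(res) < 2L) return(1)
    tot <- choose(length(res), 2)
    same <- sum(choose(table(res), 2))
    same / tot
  }, numeric(1))
  sim_trimmed <- setdiff(which(sim < sim_threshold), gap_trimmed)
  kept <- setdiff(seq_len(ncol(m)), union(gap_trimmed, sim_trimmed))
  list(alignment = m[, kept, drop = FALSE], kept = kept, masked = masked,
       gap_trimmed = gap_trimmed, sim_trimmed = sim_trimmed)
}

# take codon columns matching kept protein columns, gapping masked cells
.codons_from_protein_columns <- function(codon_aln, kept, masked = NULL) {
  m <- as_alignment_matrix(codon_aln)
  out <- matrix("-", nrow(m), 3L * length(kept),
                dimnames = list(rownames(m), NULL))
  for (k in seq_along(kept)) {
    j <- kept[k]
    block <- m[, (3L * j - 2L):(3L * j), drop = FALSE]
    if (!is.null(masked)) block[masked[, j], ] <- "-"
    out[, (3L * k - 2L):(3L * k)] <- block
  }
  out
}

#' Run a full alignment-filtering pipeline on one gene
#'
#' Pipeline A (concordance/consistency): translate, keep totally
#' concordant columns across the alternative alignments, keep
#' consistency score 9 columns, map back to codons. Pipeline B
#' (confidence): mask low-confidence residues, trim gap-rich and
#' low-similarity columns, map back to codons. Both then apply the codon
#' occupancy filter and greedy gap-rich sequence removal; if sequences
#' were discarded the species criteria are re-checked and the pipeline
#' re-run on the surviving rows, otherwise the gene is rejected.
#'
#' @param codon_aln in-frame codon alignment (rows named by species).
#' @param pipeline `"A"` or `"B"`.
#' @param alternatives list of alternative protein alignments
#'   (pipeline A).
#' @param confidences per-residue confidence matrix on the translated
#'   alignment (pipeline B).
#' @param classes species class table (see [filter_ortholog_taxa()]).
#' @param required_sisters passed to [filter_ortholog_taxa()].
#' @param min_species,min_endo,min_ecto species criteria.
#' @return list with `status` (`"passed"`/`"rejected"`), `alignment`
#'   (filtered codon matrix when passed), and `report` (columns removed
#'   per rule in original codon-column coordinates, sequences removed,
#'   re-check outcome).
#' @export
run_filter_pipeline <- function(codon_aln, pipeline = c("A", "B"),
                                alternatives = NULL, confidences = NULL,
                                classes = NULL,
                                required_sisters = character(0),
                                min_species = 5L, min_endo = 2L,
                                min_ecto = 2L) {
  pipeline <- match.arg(pipeline)
  m <- as_alignment_matrix(codon_aln)
  all_removed_seqs <- character(0)
  report <- list(concordance_removed = integer(0),
                 consistency_removed = integer(0),
                 occupancy_removed = integer(0),
                 gap_trimmed = integer(0), sim_trimmed = integer(0),
                 masked_residues = 0L,
                 sequences_removed = character(0),
                 recheck_passed = NA)
  for (round in 1:2) {
    prot <- translate_alignment(m)
    if (pipeline == "A") {
      if (is.null(alternatives)) stop("pipeline A needs alternatives")
      alts <- lapply(alternatives, function(a) {
        a <- as_alignment_matrix(a)
        a[rownames(a) %in% rownames(m), , drop = FALSE]
      })
      cf <- concordance_filter(prot, alts)
      report$concordance_removed <- setdiff(seq_len(ncol(prot)), cf$kept)
      ts <- consistency_filter(cf$alignment)
      report$consistency_removed <- cf$kept[setdiff(
        seq_along(cf$kept), ts$kept)]
      kept <- cf$kept[ts$kept]
      codons <- .codons_from_protein_columns(m, kept)
    } else {
      if (is.null(confidences)) stop("pipeline B needs confidences")
      conf <- confidences[rownames(m), , drop = FALSE]
      cm <- confidence_mask_and_trim(prot, conf)
      report$masked_residues <- sum(cm$masked)
      report$gap_trimmed <- cm$gap_trimmed
      report$sim_trimmed <- cm$sim_trimmed
      kept <- cm$kept
      codons <- .codons_from_protein_columns(m, kept, cm$masked)
    }
    oc <- occupancy_filter_codons(codons)
    report$occupancy_removed <- kept[setdiff(seq_along(kept), oc$kept)]
    mx <- maxalign_select(oc$alignment)
    if (!length(mx$removed)) {
      report$sequences_removed <- all_removed_seqs
      return(list(status = "passed", alignment = mx$alignment,
                  report = report))
    }
    all_removed_seqs <- c(all_removed_seqs, mx$removed)
    survivors <- setdiff(rownames(m), mx$removed)
    ok <- if (is.null(classes)) length(survivors) >= min_species else
      filter_ortholog_taxa(survivors, classes, required_sisters,
                           min_species, min_endo, min_ecto)
    report$recheck_passed <- ok
    report$sequences_removed <- all_removed_seqs
    if (!ok) return(list(status = "rejected", alignment = NULL,
                         report = report))
    m <- m[survivors, , drop = FALSE]
  }
  list(status = "passed", alignment = mx$alignment, report = report)
}
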