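#' Branch-site selection scan of one gene
#'
#' Runs the full per-gene testing scheme: for each alignment variant the
#' tree is pruned to the taxa with data, the foreground branch re-marked
#' on the stem of the surviving endothermic tips, branch lengths
#' estimated once under M0, and the branch-site test run at each
#' starting omega. All resulting p-values are Benjamini-Hochberg
#' adjusted within the gene and the gene is called under selection only
#' when every adjusted p-value is below `alpha`. Called genes receive
#' the synonymous-saturation screen (one-ratio and free-ratio fits).
#'
#' @param variants named list of codon alignment matrices (typically the
#'   outputs of the two filtering pipelines; a rejected pipeline is
#'   passed as NULL and makes the gene untestable).
#' @param tree base tree (all taxa, branch lengths) -- not yet pruned.
#' @param endo_species endothermic taxa defining the foreground.
#' @param starts starting omega values (default `c(0.5, 1, 1.5)`).
#' @param alpha significance level (default 0.05).
#' @param freq_model codon frequency model (default `"F3x4"`).
#' @param n_required tests required for a call (default
#'   `length(starts) * length(variants)`).
#' @param saturation run the dS saturation screen on selected genes.
#' @return list of class `gene_scan`: `tests` (data.frame with one row
#'   per variant x start: log-likelihoods, LRT statistic, raw and
#'   adjusted p), `status`, `saturation` (list or NULL), `omega2`
#'   (foreground omega of the best alternative fit).
#' @export
scan_gene <- function(variants, tree, endo_species,
                      starts = c(0.5, 1, 1.5), alpha = 0.05,
                      freq_model = "F3x4", n_required = NULL,
                      saturation = TRUE) {
  if (is.null(names(variants)))
    names(variants) <- LETTERS[seq_along(variants)]
  if (is.null(n_required)) n_required <- length(starts) * length(variants)
  rows <- list()
  best_alt <- NULL
  m0_first <- NULL
  tree_first <- NULL
  for (v in names(variants)) {
    aln <- variants[[v]]
    if (is.null(aln)) next
    aln <- as_alignment_matrix(aln)
    keep <- intersect(tree$tip.label, rownames(aln))
    tr <- prune_taxa(tree, keep)
    tr <- tryCatch(mark_foreground(tr, endo_species),
                   error = function(e) NULL)
    if (is.null(tr)) next
    tr_fit <- .keep_fg(ape::unroot(tr), tr)
    m0 <- fit_model(aln, tr_fit, "M0", freq_model = freq_model)
    bl_tree <- m0$tree
    if (is.null(m0_first)) { m0_first <- m0; tree_first <- bl_tree }
    for (s in starts) {
      alt <- fit_model(aln, bl_tree, "bsA", start_omega = s,
                       freq_model = freq_model,
                       init = list(kappa = m0$params$kappa))
      nul <- fit_model(aln, bl_tree, "bsA_null", start_omega = s,
                       freq_model = freq_model,
                       init = list(kappa = alt$params$kappa,
                                   p0 = alt$params$p0, p1 = alt$params$p1,
                                   omega0 = alt$params$omega0))
      lrt <- branch_site_lrt(alt, nul)
      if (is.null(best_alt) || alt$loglik > best_alt$loglik) best_alt <- alt
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, start_omega = s, lnl_alt = alt$loglik,
        lnl_null = nul$loglik, stat = lrt$stat, p_raw = lrt$p)
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(0), start_omega = numeric(0),
               lnl_alt = numeric(0), lnl_null = numeric(0),
               stat = numeric(0), p_raw = numeric(0))
  tests$p_adj <- if (nrow(tests)) bh_adjust(tests$p_raw) else numeric(0)
  status <- consensus_call(tests$p_adj, alpha, n_required)
  sat <- NULL
  if (saturation && status == "selected" && !is.null(tree_first)) {
    fr <- fit_model(variants[[1]], tree_first, "free_ratio",
                    freq_model = freq_model, start_omega = 0.5)
    sat <- saturation_screen(m0_first, fr)
  }
  structure(list(tests = tests, status = status, saturation = sat,
                 omega2 = if (!is.null(best_alt)) best_alt$params$omega2
                          else NA_real_),
            class = "gene_scan")
}

#' @export
print.gene_scan <- function(x, ...) {
  cat("Gene scan:", x$status, "(", nrow(x$tests), "tests )\n")
  if (nrow(x$tests)) print(x$tests, row.names = FALSE, digits = 4)
  if (!is.null(x$saturation))
    cat("saturation flag:", x$saturation$flag, " dS overall:",
        signif(x$saturation$ds_overall, 3), "\n")
  invisible(x)
}

#' Scan a whole (synthetic or real) study
#'
#' Applies [scan_gene()] to every gene. When `filter = TRUE` each gene
#' first passes through both alignment-filtering pipelines -- pipeline A
#' against programmatically generated alternative alignments, pipeline B
#' against residue confidences -- which on clean data is the identity;
#' with `filter = FALSE` the raw alignment is used for both variants.
#'
#' @param genes named list of codon alignments.
#' @param tree base tree with all taxa.
#' @param endo_species endothermic taxa.
#' @param classes species class table (for the pipeline re-check).
#' @param filter run the alignment-filtering pipelines per gene.
#' @param ... passed to [scan_gene()].
#' @return data.frame with one row per gene: `gene`, `status`,
#'   `n_tests`, `min_p_adj`, `max_p_adj`, `omega2`, `saturated`; the
#'   per-gene `gene_scan` objects are attached as attribute `scans`.
#' @export
scan_study <- function(genes, tree, endo_species, classes = NULL,
                       filter = FALSE, ...) {
  scans <- lapply(names(genes), function(g) {
    aln <- as_alignment_matrix(genes[[g]])
    if (filter) {
      prot <- translate_alignment(aln)
      alts <- make_alternative_alignments(prot, k = 2, corruption_frac = 0,
                                          seed = 1)
      pa <- run_filter_pipeline(aln, "A", alternatives = alts$alternatives,
                                classes = classes)
      pb <- run_filter_pipeline(aln, "B", confidences = alts$confidences,
                                classes = classes)
      variants <- list(A = if (pa$status == "passed") pa$alignment,
                       B = if (pb$status == "passed") pb$alignment)
    } else {
      variants <- list(A = aln, B = aln)
    }
    scan_gene(variants, tree, endo_species, ...)
  })
  names(scans) <- names(genes)
  out <- data.frame(
    gene = names(genes),
    status = vapply(scans, `[[`, "", "status"),
    n_tests = vapply(scans, function(s) nrow(s$tests), integer(1)),
    min_p_adj = vapply(scans, function(s)
      if (nrow(s$tests)) min(s$tests$p_adj) else NA_real_, numeric(1)),
    max_p_adj = vapply(scans, function(s)
      if (nrow(s$tests)) max(s$tests$p_adj) else NA_real_, numeric(1)),
    omega2 = vapply(scans, `[[`, numeric(1), "omega2"),
    saturated = vapply(scans, function(s)
      if (is.null(s$saturation)) NA else s$saturation$flag, logical(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scans") <- scans
  out
}
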