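#' Simulate a species tree with a marked endothermic clade
#'
#' Produces the study-shaped input: a rooted tree whose endothermic taxa
#' are monophyletic, with the stem of that clade (the branch the
#' branch-site test targets) longer than the background branches --
#' mirroring the deep divergence of the endothermic lineages from their
#' ectothermic sisters. The endothermic clade is chosen so its stem is an
#' internal branch (never a root edge).
#'
#' @param n_taxa number of tips (>= 4; balanced shape needs a power of 2).
#' @param shape `"balanced"`, `"pectinate"` or `"coalescent"`.
#' @param blen background branch length (expected substitutions per
#'   codon; default 0.08).
#' @param endo_stem length of the endothermic stem branch (default 0.25).
#' @param n_endo endothermic clade size (default `max(2, n_taxa %/% 4)`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `tree` (marked via [mark_foreground()]),
#'   `endo_species`, and `classes` (species/class table).
#' @export
simulate_tree <- function(n_taxa = 8, shape = c("balanced", "pectinate",
                                                "coalescent"),
                          blen = 0.08, endo_stem = 0.25, n_endo = NULL,
                          seed = 1) {
  shape <- match.arg(shape)
  stopifnot(n_taxa >= 4)
  set.seed(seed)
  tr <- switch(shape,
    balanced = {
      if (bitwAnd(n_taxa, n_taxa - 1L) != 0L)
        stop("balanced shape needs a power-of-2 taxon count")
      ape::stree(n_taxa, "balanced")
    },
    pectinate = ape::stree(n_taxa, "left"),
    coalescent = ape::rcoal(n_taxa)
  )
  tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tr$edge.length <- rep(blen, nrow(tr$edge))
  if (is.null(n_endo)) n_endo <- max(2L, n_taxa %/% 4L)
  ntip <- ape::Ntip(tr)
  # candidate clades: internal, non-root, of the requested size
  sizes <- vapply((ntip + 2L):(ntip + tr$Nnode), function(nd)
    length(ape::extract.clade(tr, nd)$tip.label), integer(1))
  cand <- ((ntip + 2L):(ntip + tr$Nnode))[sizes == n_endo]
  if (!length(cand))
    stop("no internal clade of size ", n_endo, " in this tree shape")
  node <- cand[1L]
  endo <- ape::extract.clade(tr, node)$tip.label
  tr$edge.length[tr$edge[, 2] == node] <- endo_stem
  tr <- mark_foreground(tr, endo)
  classes <- data.frame(species = tr$tip.label,
                        class = ifelse(tr$tip.label %in% endo,
                                       "endo", "ecto"),
                        stringsAsFactors = FALSE)
  list(tree = tr, endo_species = endo, classes = classes)
}

#' Simulate a codon alignment under the branch-site site-class model
#'
#' Each codon draws a site class i.i.d. from the four-class scheme of
#' [site_classes()]; its states evolve down the tree by sampling from
#' exact transition matrices (matrix exponentials of the class generator,
#' with the foreground branch switching to the foreground omega).
#' Setting `omega2 = 1` reduces to the branch-site null. The state space
#' contains no stop codons, so simulated alignments never do either.
#'
#' @param tree a marked tree (e.g. from [simulate_tree()]).
#' @param n_codons alignment length in codons (default 300).
#' @param kappa transition/transversion ratio (default 2.5).
#' @param pi codon frequencies (default uniform over the 61 sense codons).
#' @param p0,p1 site-class proportions (defaults 0.45/0.40, so 15% of
#'   sites are available to the foreground classes).
#' @param omega0 purifying ratio (default 0.15).
#' @param omega2 foreground ratio (default 1, i.e. the null).
#' @param seed RNG seed.
#' @return list with `aln` (codon alignment matrix) and `truth` (the
#'   generating parameters and per-site class labels).
#' @export
simulate_codon_alignment <- function(tree, n_codons = 300, kappa = 2.5,
                                     pi = rep(1 / 61, 61), p0 = 0.45,
                                     p1 = 0.40, omega0 = 0.15, omega2 = 1,
                                     seed = 1) {
  set.seed(seed)
  classes <- site_classes(p0, p1, omega0, omega2)
  has_fg <- !is.null(attr(tree, "foreground_clade"))
  if (!has_fg && omega2 != 1)
    stop("omega2 != 1 needs a marked foreground branch")
  fg_row <- if (has_fg) {
    pt <- .prep_tree(tree)
    foreground_edge(pt$tree)
  } else NA_integer_
  pt <- .prep_tree(tree)
  edge <- pt$edge
  elen <- pt$elen
  ntip <- pt$ntip
  mu <- .bs_scale(pi, kappa, classes)
  sys_of <- function(w) {
    Q <- build_rate_matrix(pi, kappa, w, scale = FALSE) / mu
    .eig_system(Q, pi)
  }
  uw <- unique(c(classes$w_bg, classes$w_fg))
  sys_list <- lapply(uw, sys_of)
  names(sys_list) <- as.character(uw)

  cls <- sample(1:4, n_codons, replace = TRUE, prob = classes$prop)
  code <- genetic_code()
  states <- matrix(NA_integer_, ntip + pt$tree$Nnode, n_codons)
  root <- edge[nrow(edge), 1]
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  # preorder: reverse postorder guarantees parents before children
  for (e in rev(seq_len(nrow(edge)))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    is_fg <- has_fg && e == fg_row
    for (k in unique(cls)) {
      idx <- which(cls == k)
      w <- if (is_fg) classes$w_fg[k] else classes$w_bg[k]
      P <- .pmat_r(sys_list[[as.character(w)]], elen[e])
      ps <- states[parent, idx]
      for (s in unique(ps)) {
        sel <- idx[ps == s]
        states[child, sel] <- sample.int(61L, length(sel), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  tips <- states[seq_len(ntip), , drop = FALSE]
  aln <- matrix("", ntip, 3L * n_codons,
                dimnames = list(pt$tree$tip.label, NULL))
  codon_chars <- do.call(rbind, strsplit(code$codons, ""))
  for (j in seq_len(n_codons)) {
    aln[, (3L * j - 2L):(3L * j)] <- codon_chars[tips[, j], , drop = FALSE]
  }
  truth <- list(site_class = classes$class[cls], kappa = kappa, pi = pi,
                p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2,
                tree = tree, seed = seed)
  list(aln = aln, truth = truth)
}

#' Simulate a homolog gene-family tree with known ortholog truth
#'
#' Grafts gene duplications onto a species tree, optionally makes the
#' duplication stems deep (> 0.5, the deep-paralog cutting target), adds
#' spurious long tips (length 3, the absolute-length trimming target),
#' and drops tips at a loss rate. Truth records which tips form the
#' single-copy ortholog set (the primary copy).
#'
#' @param species_tree ingroup species tree (`ape::phylo`).
#' @param dup_rate expected number of duplication events (Poisson,
#'   capped at 2).
#' @param loss_rate per-tip loss probability within duplicated copies.
#' @param spurious_tip_rate per-species probability of a spurious long
#'   tip.
#' @param deep_paralog make duplication stems longer than 0.5.
#' @param outgroups number of single-copy outgroup species prepended at
#'   the root (default 2).
#' @param seed RNG seed.
#' @return a [homolog_tree()] with attribute `truth`: list of
#'   `ortholog_tips` (labels of the true single-copy set),
#'   `outgroup_species`, `duplications`.
#' @export
simulate_gene_family <- function(species_tree, dup_rate = 0, loss_rate = 0,
                                 spurious_tip_rate = 0, deep_paralog = FALSE,
                                 outgroups = 2, seed = 1) {
  set.seed(seed)
  stopifnot(dup_rate >= 0, loss_rate >= 0, spurious_tip_rate >= 0)
  tr <- species_tree
  species <- tr$tip.label
  tr$tip.label <- paste0(species, "|c1")
  # attach outgroups as a basal ladder: (ogN,(...,(og1, ingroup)))
  if (outgroups > 0) {
    og <- sprintf("og%d", seq_len(outgroups))
    txt <- sub(";$", "", ape::write.tree(tr))
    for (g in og) txt <- paste0("(", g, "|c1:0.6,", txt, ":0.2):0.2")
    tr <- ape::read.tree(text = paste0(sub(":0.2$", "", txt), ";"))
  } else {
    og <- character(0)
  }
  ndup <- min(stats::rpois(1, dup_rate), 2L)
  dup_events <- list()
  for (d in seq_len(ndup)) {
    # duplicate a random ingroup clade of >= 2 tips
    ntip <- ape::Ntip(tr)
    cand <- (ntip + 2L):(ntip + tr$Nnode)
    sizes <- vapply(cand, function(nd) {
      tl <- ape::extract.clade(tr, nd)$tip.label
      if (any(grepl("^og", tl)) || any(grepl("\\|d", tl))) 0L
      else length(tl)
    }, integer(1))
    cand <- cand[sizes >= 2 & sizes <= max(2L, ape::Ntip(species_tree) %/% 2L)]
    if (!length(cand)) break
    node <- sample(cand, 1L)
    clade <- ape::extract.clade(tr, node)
    copy <- clade
    copy$tip.label <- sub("\\|c1$", paste0("|d", d), copy$tip.label)
    # losses within the duplicated copy
    lost <- copy$tip.label[stats::runif(ape::Ntip(copy)) < loss_rate]
    if (length(lost) >= ape::Ntip(copy) - 1L) lost <- lost[-1L]
    if (length(lost)) copy <- ape::drop.tip(copy, lost)
    stem <- if (deep_paralog) 0.7 else 0.3
    copy$root.edge <- stem
    host_stem <- tr$edge.length[tr$edge[, 2] == node]
    tr <- ape::bind.tree(tr, copy, where = node, position = host_stem / 2)
    dup_events[[d]] <- list(clade = clade$tip.label, stem = stem)
  }
  # spurious long tips (attached to primary-copy tips only, so every
  # spurious pendant edge keeps its full length)
  for (sp in species) {
    if (stats::runif(1) < spurious_tip_rate) {
      hosts <- which(grepl("\\|c1$", tr$tip.label))
      host <- hosts[sample.int(length(hosts), 1L)]
      tip <- ape::read.tree(text = paste0("(", sp, "|spur:3);"))
      tip$root.edge <- 0.05
      host_len <- tr$edge.length[tr$edge[, 2] == host]
      tr <- ape::bind.tree(tr, tip, where = host,
                           position = host_len / 2)
    }
  }
  labels <- tr$tip.label
  spp <- sub("\\|.*$", "", labels)
  chars <- ifelse(grepl("\\|c1$", labels), 300L,
                  ifelse(grepl("\\|d", labels), 200L, 50L))
  chars <- chars + sample.int(50L, length(chars), replace = TRUE)
  ht <- homolog_tree(tr, species = spp, aligned_chars = chars)
  attr(ht, "truth") <- list(
    ortholog_tips = labels[grepl("\\|c1$", labels) & !spp %in% og],
    outgroup_species = og,
    duplications = dup_events)
  ht
}

#' Perturbed alternative alignments with known corrupted columns
#'
#' Emulates re-aligning the same sequences with different aligners: `k`
#' copies of a protein alignment in which a chosen fraction of columns
#' is locally re-gapped differently per copy (each corrupted column is
#' split into two, every row's residue landing in one of the two slots
#' at random). Also emits per-residue confidences: 1.0 in clean columns
#' and uniformly below the 0.93 masking threshold in corrupted ones.
#'
#' @param aln protein alignment (matrix or named strings).
#' @param k number of alternative alignments (>= 2).
#' @param corruption_frac fraction of columns to corrupt.
#' @param seed RNG seed.
#' @return list: `alternatives` (list of `k` matrices), `corrupted`
#'   (primary column indices), `confidences` (matrix, primary shape).
#' @export
make_alternative_alignments <- function(aln, k = 3, corruption_frac = 0.2,
                                        seed = 1) {
  stopifnot(k >= 2, corruption_frac >= 0, corruption_frac <= 1)
  set.seed(seed)
  m <- as_alignment_matrix(aln)
  L <- ncol(m)
  ncor <- round(corruption_frac * L)
  corrupted <- sort(sample.int(L, ncor))
  alts <- vector("list", k)
  for (a in seq_len(k)) {
    cols <- vector("list", L)
    for (j in seq_len(L)) {
      if (j %in% corrupted) {
        left <- stats::runif(nrow(m)) < 0.5
        c1 <- ifelse(left, m[, j], "-")
        c2 <- ifelse(left, "-", m[, j])
        cols[[j]] <- cbind(c1, c2)
      } else {
        cols[[j]] <- m[, j, drop = FALSE]
      }
    }
    am <- do.call(cbind, cols)
    rownames(am) <- rownames(m)
    colnames(am) <- NULL
    alts[[a]] <- am
  }
  conf <- matrix(1, nrow(m), L, dimnames = dimnames(m))
  if (ncor > 0)
    conf[, corrupted] <- matrix(stats::runif(nrow(m) * ncor, 0.3, 0.93),
                                nrow(m))
  conf[m == "-"] <- NA_real_
  list(alternatives = alts, corrupted = corrupted, confidences = conf)
}

#' Simulate a small selection study with known truth
#'
#' Generates `n_genes` codon alignments on one species tree: the first
#' `n_selected` genes evolve with a foreground omega of `omega2_sel` on
#' the endothermic stem, the rest under the branch-site null. Gene seeds
#' derive deterministically from `seed`.
#'
#' @param n_genes total genes (default 30).
#' @param n_selected genes under positive selection (default 5).
#' @param n_taxa,n_codons problem size per gene.
#' @param omega2_sel foreground omega of the selected genes (default 4).
#' @param seed study seed.
#' @param ... passed to [simulate_codon_alignment()].
#' @return list with `tree` (marked), `classes`, `genes` (list of
#'   alignments), `truth` (logical vector: selected).
#' @export
simulate_study <- function(n_genes = 30, n_selected = 5, n_taxa = 8,
                           n_codons = 300, omega2_sel = 4, seed = 1, ...) {
  sim <- simulate_tree(n_taxa = n_taxa, seed = seed)
  selected <- seq_len(n_genes) <= n_selected
  genes <- lapply(seq_len(n_genes), function(g) {
    simulate_codon_alignment(
      sim$tree, n_codons = n_codons,
      omega2 = if (selected[g]) omega2_sel else 1,
      seed = seed * 10000L + g, ...)$aln
  })
  names(genes) <- sprintf("gene%03d", seq_len(n_genes))
  list(tree = sim$tree, classes = sim$classes, endo_species =
         sim$endo_species, genes = genes, truth = selected, seed = seed)
}
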