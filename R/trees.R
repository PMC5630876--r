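#' Prune a base tree to a taxon subset
#'
#' Removes all tips not in `keep`, collapsing unary nodes and summing
#' branch lengths so that all pairwise path lengths among kept taxa are
#' preserved (the standard per-gene tree construction when some taxa
#' lack data for a gene).
#'
#' @param base an `ape::phylo` with branch lengths.
#' @param keep character vector of tip labels to retain (>= 2).
#' @return pruned `ape::phylo`.
#' @export
prune_taxa <- function(base, keep) {
  unknown <- setdiff(keep, base$tip.label)
  if (length(unknown))
    stop("taxa not in base tree: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(base, keep)
}

#' Mark the foreground branch above the endothermic clade
#'
#' The branch tested for selection is the stem of the most recent common
#' ancestor of the surviving endothermic tips. The mark is stored as the
#' set of tip labels the branch subtends (attribute `foreground_clade`),
#' which survives re-rooting and reordering.
#'
#' @param tree `ape::phylo`.
#' @param endo_species character vector of endothermic taxon labels.
#' @return the tree with attribute `foreground_clade` set.
#' @export
mark_foreground <- function(tree, endo_species) {
  present <- intersect(tree$tip.label, endo_species)
  if (length(present) < 1L)
    stop("no endothermic tips present in tree")
  if (length(present) == 1L) {
    clade <- present
  } else {
    mrca <- ape::getMRCA(tree, present)
    clade <- ape::extract.clade(tree, mrca)$tip.label
    if (!setequal(clade, present))
      stop("endothermic tips are not monophyletic in this tree (clade of ",
           "their MRCA also contains: ",
           paste(setdiff(clade, present), collapse = ", "), ")")
    root <- ape::Ntip(tree) + 1L
    if (mrca == root)
      stop("endothermic clade has no stem branch (its MRCA is the root)")
  }
  attr(tree, "foreground_clade") <- sort(clade)
  tree
}

#' Locate the marked foreground edge
#'
#' @param tree a tree previously passed through [mark_foreground()] (or
#'   carrying a `foreground_clade` attribute).
#' @return the row index in `tree$edge` of the foreground branch.
#' @export
foreground_edge <- function(tree) {
  clade <- attr(tree, "foreground_clade")
  if (is.null(clade)) stop("tree has no marked foreground branch")
  ntip <- ape::Ntip(tree)
  if (length(clade) == 1L) {
    child <- match(clade, tree$tip.label)
  } else {
    child <- ape::getMRCA(tree, clade)
    below <- ape::extract.clade(tree, child)$tip.label
    if (!setequal(below, clade))
      stop("marked foreground clade is not a clade of this tree")
  }
  e <- which(tree$edge[, 2] == child)
  if (length(e) != 1L) stop("foreground branch not found")
  e
}

# carry the foreground mark through an ape operation that rebuilds the tree
.keep_fg <- function(new, old) {
  attr(new, "foreground_clade") <- attr(old, "foreground_clade")
  new
}

#' Unroot a tree, preserving its foreground mark
#'
#' Reversible codon models make the likelihood root-invariant; fitting
#' on the unrooted tree removes the unidentifiable split of the root
#' edge. The foreground mark (a tip set) survives unrooting as long as
#' the marked clade is not a child of the root.
#'
#' @param tree a marked `ape::phylo`.
#' @return unrooted tree with the mark carried over.
#' @export
unroot_marked <- function(tree) {
  .keep_fg(ape::unroot(tree), tree)
}

#' Tip-to-tip path length
#' @param tree `ape::phylo` with branch lengths.
#' @param a,b tip labels.
#' @return patristic distance between `a` and `b`.
#' @export
tip_distance <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  d[a, b]
}
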