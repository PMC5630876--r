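#' Homolog gene tree with tip metadata
#'
#' A gene-family tree whose tips carry the species of origin and the
#' number of aligned characters supporting the contig (used by the
#' species-repeat and duplication tie-breaks).
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param species species label per tip (in `tree$tip.label` order).
#' @param aligned_chars aligned-character count per tip (>= 0).
#' @return object of class `homolog_tree`: list with `tree` and `tips`
#'   (data.frame of `label`, `species`, `aligned_chars`).
#' @export
homolog_tree <- function(tree, species, aligned_chars = NULL) {
  stopifnot(inherits(tree, "phylo"),
            length(species) == ape::Ntip(tree))
  if (is.null(aligned_chars)) aligned_chars <- rep(0L, ape::Ntip(tree))
  stopifnot(all(aligned_chars >= 0))
  structure(list(tree = tree,
                 tips = data.frame(label = tree$tip.label,
                                   species = species,
                                   aligned_chars = aligned_chars,
                                   stringsAsFactors = FALSE)),
            class = "homolog_tree")
}

# subset tip metadata to the tips surviving in a derived tree
.subset_ht <- function(ht, tree) {
  tips <- ht$tips[match(tree$tip.label, ht$tips$label), , drop = FALSE]
  rownames(tips) <- NULL
  structure(list(tree = tree, tips = tips), class = "homolog_tree")
}

# drop tips from a homolog tree; returns NULL when < 2 tips would remain
.drop_ht <- function(ht, labels) {
  remaining <- setdiff(ht$tree$tip.label, labels)
  if (length(remaining) < 2L) return(NULL)
  .subset_ht(ht, ape::drop.tip(ht$tree, labels))
}

# length of the branch that is sister to a tip (min over siblings at
# multifurcations)
.sister_branch_length <- function(tree, tip_idx) {
  parent <- tree$edge[tree$edge[, 2] == tip_idx, 1]
  sibs <- tree$edge[, 2][tree$edge[, 1] == parent]
  sibs <- setdiff(sibs, tip_idx)
  if (!length(sibs)) return(Inf)
  min(tree$edge.length[match(sibs, tree$edge[, 2])])
}

#' Trim spurious long terminal branches
#'
#' Iteratively removes tips whose pendant branch exceeds the absolute
#' threshold or is more than `rel_threshold` times the length of its
#' sister branch, longest offender first, re-evaluating after each
#' removal until a fixed point. Such tips are typically mis-assembled
#' contigs or gross ortholog misassignments.
#'
#' @param ht a [homolog_tree()].
#' @param abs_threshold absolute pendant-length cutoff (default 2.0;
#'   strictly greater-than).
#' @param rel_threshold sister-relative cutoff (default 10.0).
#' @return trimmed `homolog_tree`, or `NULL` when fewer than two tips
#'   survive (gene dropped).
#' @export
trim_spurious_tips <- function(ht, abs_threshold = 2.0, rel_threshold = 10.0) {
  repeat {
    tr <- ht$tree
    ntip <- ape::Ntip(tr)
    pend <- tr$edge.length[match(seq_len(ntip), tr$edge[, 2])]
    sis <- vapply(seq_len(ntip), .sister_branch_length, numeric(1),
                  tree = tr)
    bad <- which(pend > abs_threshold | pend > rel_threshold * sis)
    if (!length(bad)) return(ht)
    worst <- bad[which.max(pend[bad])]
    ht <- .drop_ht(ht, tr$tip.label[worst])
    if (is.null(ht)) return(NULL)
  }
}

# is the tip set `tips` (labels) a clade of `tree`?
.is_clade <- function(tree, tips) {
  if (length(tips) <= 1L) return(TRUE)
  m <- ape::getMRCA(tree, tips)
  setequal(ape::extract.clade(tree, m)$tip.label, tips)
}

# can a group of same-species tips be collapsed? yes when the other
# tips inside their MRCA clade are absent (monophyly) or form a single
# clade (paraphyly)
.collapsible <- function(tree, tips) {
  if (length(tips) <= 1L) return(TRUE)
  m <- ape::getMRCA(tree, tips)
  inside <- ape::extract.clade(tree, m)$tip.label
  other <- setdiff(inside, tips)
  if (!length(other)) return(TRUE)
  .is_clade(tree, other)
}

#' Collapse same-species repeats to the best-supported contig
#'
#' Splice variants and isoforms surface as monophyletic or paraphyletic
#' groups of tips from one species; within each such group only the tip
#' with the most aligned characters is kept (ties broken by
#' lexicographic label).
#'
#' @param ht a [homolog_tree()].
#' @return collapsed `homolog_tree`.
#' @export
collapse_species_repeats <- function(ht) {
  repeat {
    tr <- ht$tree
    changed <- FALSE
    for (sp in unique(ht$tips$species[duplicated(ht$tips$species)])) {
      labs <- ht$tips$label[ht$tips$species == sp]
      # greedy merge of collapsible groups
      groups <- as.list(labs)
      merged <- TRUE
      while (merged && length(groups) > 1L) {
        merged <- FALSE
        for (i in seq_along(groups)) {
          for (j in seq_along(groups)) {
            if (j <= i) next
            comb <- c(groups[[i]], groups[[j]])
            if (.collapsible(tr, comb)) {
              groups[[i]] <- comb
              groups[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
      }
      for (g in groups) {
        if (length(g) < 2L) next
        info <- ht$tips[match(g, ht$tips$label), ]
        info <- info[order(-info$aligned_chars, info$label), ]
        drop <- info$label[-1L]
        out <- .drop_ht(ht, drop)
        if (is.null(out)) return(ht)  # would leave < 2 tips; stop here
        ht <- out
        changed <- TRUE
      }
      if (changed) break
    }
    if (!changed) return(ht)
  }
}

#' Cut deep paralog stems
#'
#' Severs every internal branch longer than the threshold (old
#' duplication stems) and returns the resulting pieces with at least two
#' tips each.
#'
#' @param ht a [homolog_tree()].
#' @param threshold internal branch-length cutoff (default 0.5; strictly
#'   greater-than).
#' @return list of `homolog_tree` pieces.
#' @export
cut_deep_paralogs <- function(ht, threshold = 0.5) {
  tr <- ht$tree
  ntip <- ape::Ntip(tr)
  internal <- which(tr$edge[, 2] > ntip)
  bad <- internal[tr$edge.length[internal] > threshold]
  if (!length(bad)) return(list(ht))
  worst <- bad[which.max(tr$edge.length[bad])]
  node <- tr$edge[worst, 2]
  clade_tips <- ape::extract.clade(tr, node)$tip.label
  pieces <- list()
  below <- if (length(clade_tips) >= 2L)
    .subset_ht(ht, ape::extract.clade(tr, node)) else NULL
  above <- .drop_ht(ht, clade_tips)
  for (piece in list(below, above)) {
    if (is.null(piece)) next
    pieces <- c(pieces, cut_deep_paralogs(piece, threshold))
  }
  pieces
}

#' Extract single-copy ortholog sets from a rooted homolog tree
#'
#' Roots the gene tree on the outgroup taxa, marks duplication nodes by
#' species-set overlap between child subtrees, and resolves them from
#' the root down: at a duplication the child covering more ingroup
#' species is kept (ties broken by summed aligned characters); clean
#' clades are emitted as ortholog sets. Outgroups are removed from the
#' emitted sets.
#'
#' @param ht a [homolog_tree()].
#' @param outgroup_species character vector of outgroup species.
#' @return list of ortholog sets (named character vectors,
#'   species -> tip label) with >= 2 species each.
#' @export
prune_rt_orthologs <- function(ht, outgroup_species) {
  sp <- ht$tips$species
  og_tips <- ht$tips$label[sp %in% outgroup_species]
  if (!length(og_tips)) stop("no outgroup tips in tree")
  og_sp <- sp[sp %in% outgroup_species]
  if (anyDuplicated(og_sp))
    stop("outgroup species duplicated: ",
         paste(unique(og_sp[duplicated(og_sp)]), collapse = ", "))
  tr <- ht$tree
  if (length(setdiff(tr$tip.label, og_tips)) < 2L)
    stop("fewer than two ingroup tips")
  rooted <- tryCatch(
    ape::root(tr, outgroup = og_tips, resolve.root = TRUE),
    error = function(e) stop("cannot root on outgroups: ",
                             conditionMessage(e)))
  ing <- ape::drop.tip(rooted, og_tips)
  info <- ht$tips[match(ing$tip.label, ht$tips$label), ]

  ntip <- ape::Ntip(ing)
  nnode <- ing$Nnode
  kids <- split(ing$edge[, 2], ing$edge[, 1])
  spset <- vector("list", ntip + nnode)
  charsum <- numeric(ntip + nnode)
  isdup <- anydup <- logical(ntip + nnode)
  po <- ape::reorder.phylo(ing, "postorder")$edge
  nodes_po <- unique(po[, 1])
  for (i in seq_len(ntip)) {
    spset[[i]] <- info$species[i]
    charsum[i] <- info$aligned_chars[i]
  }
  for (v in nodes_po) {
    ch <- kids[[as.character(v)]]
    sets <- lapply(ch, function(c) spset[[c]])
    overlap <- FALSE
    if (length(sets) > 1L) {
      for (a in seq_along(sets)) for (b in seq_along(sets)) {
        if (b > a && length(intersect(sets[[a]], sets[[b]]))) overlap <- TRUE
      }
    }
    spset[[v]] <- unique(unlist(sets))
    charsum[v] <- sum(charsum[ch])
    isdup[v] <- overlap
    anydup[v] <- overlap || any(anydup[ch])
  }

  out <- list()
  emit <- function(v) {
    labs <- ape::extract.clade(ing, v)$tip.label
    i <- match(labs, info$label)
    set <- stats::setNames(labs, info$species[i])
    if (length(set) >= 2L) out[[length(out) + 1L]] <<- set
  }
  resolve <- function(v) {
    if (v <= ntip) return(invisible())
    if (!anydup[v]) { emit(v); return(invisible()) }
    ch <- kids[[as.character(v)]]
    if (isdup[v]) {
      nsp <- vapply(ch, function(c) length(spset[[c]]), integer(1))
      best <- ch[nsp == max(nsp)]
      if (length(best) > 1L)
        best <- best[which.max(charsum[best])]
      else best <- best[1L]
      resolve(best)
    } else {
      for (c in ch) resolve(c)
    }
  }
  resolve(ntip + 1L)
  out
}

#' Species-count and class filter for an ortholog set
#'
#' A gene is analysable when it covers enough species (>= 5), at least
#' two endothermic and two ectothermic species, and every required
#' sister taxon.
#'
#' @param o ortholog set (named vector, species -> sequence id) or a
#'   character vector of species.
#' @param classes data.frame with `species` and `class`
#'   (`"endo"`/`"ecto"`) or a named character vector.
#' @param required_sisters species that must be present (default none).
#' @param min_species,min_endo,min_ecto thresholds (defaults 5/2/2).
#' @return TRUE when all criteria are met.
#' @export
filter_ortholog_taxa <- function(o, classes, required_sisters = character(0),
                                 min_species = 5L, min_endo = 2L,
                                 min_ecto = 2L) {
  species <- if (!is.null(names(o))) names(o) else o
  if (is.data.frame(classes))
    classes <- stats::setNames(classes$class, classes$species)
  cl <- classes[species]
  if (any(is.na(cl)))
    stop("unclassified species: ",
         paste(species[is.na(cl)], collapse = ", "))
  length(species) >= min_species &&
    sum(cl == "endo") >= min_endo &&
    sum(cl == "ecto") >= min_ecto &&
    all(required_sisters %in% species)
}
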