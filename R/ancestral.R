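.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# reversible amino-acid generator: q_ij = s_ij * f_j, scaled to one
# expected substitution per unit time
.aa_generator <- function(freqs = rep(1 / 20, 20), exchangeability = NULL) {
  if (is.null(exchangeability))
    exchangeability <- matrix(1, 20, 20)  # Poisson
  Q <- exchangeability * rep(freqs, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

.aa_pmat <- function(Q, freqs, t) {
  s <- sqrt(freqs)
  B <- Q * outer(s, 1 / s)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  P <- (es$vectors / s) %*% (exp(es$values * t) * (t(es$vectors) * rep(s, each = 20)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Marginal ancestral amino-acid reconstruction
#'
#' Empirical-Bayes marginal reconstruction on a fixed tree: a down-pass
#' computes the conditional likelihood of the data below every node, an
#' up-pass propagates the likelihood of everything outside it; their
#' product gives the posterior state distribution per internal node and
#' column. The default model is Poisson (equal exchangeabilities and
#' frequencies); both are pluggable.
#'
#' @param aln protein alignment (rows must cover the tree tips). Gaps
#'   and `X` are missing data.
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param freqs amino-acid frequencies (length 20, order ACDEFGHIKLMNPQRSTVWY).
#' @param exchangeability optional symmetric 20x20 exchangeability
#'   matrix.
#' @return object of class `ancestral_states`: list with `posterior`
#'   (list per internal node id of 20 x columns matrices), `map`
#'   (max-posterior character matrix, rownames = internal node ids),
#'   `all_gap` (logical matrix: node x column where every tip below is
#'   gapped), `tree`.
#' @export
marginal_asr <- function(aln, tree, freqs = rep(1 / 20, 20),
                         exchangeability = NULL) {
  m <- as_alignment_matrix(aln)
  miss <- setdiff(tree$tip.label, rownames(m))
  if (length(miss))
    stop("tips missing from alignment: ", paste(miss, collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  L <- ncol(m)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  Q <- .aa_generator(freqs, exchangeability)
  pt <- ape::reorder.phylo(tree, "postorder")
  edge <- pt$edge
  elen <- pt$edge.length
  root <- edge[nrow(edge), 1]
  P <- lapply(seq_len(nrow(edge)), function(e) .aa_pmat(Q, freqs, elen[e]))

  state_idx <- matrix(match(m, .AA), nrow(m), ncol(m))
  # down-pass conditionals
  down <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) {
    D <- matrix(1, 20, L)
    s <- state_idx[i, ]
    known <- which(!is.na(s))
    D[, known] <- 0
    D[cbind(s[known], known)] <- 1
    down[[i]] <- D
  }
  all_gap <- matrix(FALSE, ntip + nnode, L)
  all_gap[seq_len(ntip), ] <- t(apply(m, 1, function(r) r == "-" | r == "X"))
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 1]; c <- edge[e, 2]
    contrib <- P[[e]] %*% down[[c]]
    if (is.null(down[[v]])) down[[v]] <- contrib else
      down[[v]] <- down[[v]] * contrib
  }
  for (v in (ntip + 1L):(ntip + nnode)) {
    ch <- edge[edge[, 1] == v, 2]
    all_gap[v, ] <- apply(all_gap[ch, , drop = FALSE], 2, all)
  }
  # up-pass: outside partials (include the root prior)
  up <- vector("list", ntip + nnode)
  up[[root]] <- matrix(freqs, 20, L)
  preorder <- rev(seq_len(nrow(edge)))
  for (e in preorder) {
    v <- edge[e, 1]; c <- edge[e, 2]
    sibs <- setdiff(kids[[as.character(v)]], e)
    outside <- up[[v]]
    for (se in sibs) outside <- outside * (P[[se]] %*% down[[edge[se, 2]]])
    up[[c]] <- t(P[[e]]) %*% outside
  }
  posterior <- vector("list", nnode)
  map <- matrix(NA_character_, nnode, L)
  for (v in (ntip + 1L):(ntip + nnode)) {
    post <- up[[v]] * down[[v]]
    norm <- colSums(post)
    norm[norm == 0] <- 1
    post <- sweep(post, 2, norm, "/")
    posterior[[v - ntip]] <- post
    map[v - ntip, ] <- .AA[apply(post, 2, which.max)]
  }
  rownames(map) <- as.character((ntip + 1L):(ntip + nnode))
  names(posterior) <- rownames(map)
  structure(list(posterior = posterior, map = map,
                 all_gap = all_gap, tree = tree),
            class = "ancestral_states")
}

#' Substitutions between two ancestral nodes
#'
#' Lists the columns where the maximum-posterior states of two nodes
#' differ -- e.g. the endotherm ancestor against its closest ectotherm
#' ancestor -- with reference coordinates when a mapping to a reference
#' protein is supplied. Columns where either node has no data below it
#' (all-gap) are excluded and counted.
#'
#' @param states a [marginal_asr()] result.
#' @param node_a,node_b internal node ids (ape numbering).
#' @param ref_map optional integer vector mapping alignment columns to
#'   reference coordinates (NA = unmapped; such columns are reported
#'   with their alignment coordinate and `mapped = FALSE`).
#' @return data.frame with `column`, `position`, `mapped`, `state_a`,
#'   `state_b`, `posterior_a`, `posterior_b`; attribute `excluded_gap`
#'   counts columns skipped for missing data.
#' @export
ancestral_diffs <- function(states, node_a, node_b, ref_map = NULL) {
  ids <- rownames(states$map)
  ka <- match(as.character(node_a), ids)
  kb <- match(as.character(node_b), ids)
  if (is.na(ka) || is.na(kb))
    stop("unknown internal node; known ids: ", ids[1], "..",
         ids[length(ids)])
  L <- ncol(states$map)
  gap_a <- states$all_gap[as.integer(node_a), ]
  gap_b <- states$all_gap[as.integer(node_b), ]
  usable <- !(gap_a | gap_b)
  differ <- usable & states$map[ka, ] != states$map[kb, ]
  cols <- which(differ)
  pos <- if (is.null(ref_map)) rep(NA_integer_, length(cols)) else
    ref_map[cols]
  out <- data.frame(
    column = cols,
    position = ifelse(is.na(pos), cols, pos),
    mapped = !is.na(pos),
    state_a = states$map[ka, cols],
    state_b = states$map[kb, cols],
    posterior_a = vapply(cols, function(j)
      max(states$posterior[[ka]][, j]), numeric(1)),
    posterior_b = vapply(cols, function(j)
      max(states$posterior[[kb]][, j]), numeric(1)))
  attr(out, "excluded_gap") <- sum(!usable & states$map[ka, ] != states$map[kb, ])
  out
}
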