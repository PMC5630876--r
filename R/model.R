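#' @useDynLib thermosel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# precomputed codon-pair structure: which pairs differ at exactly one
# position, whether the change is a transition, whether it is synonymous
.codon_pairs <- local({
  code <- .gc_env$code
  n <- length(code$codons)
  split_mat <- do.call(rbind, strsplit(code$codons, ""))
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(split_mat[, p], split_mat[, p], "!=")
  one <- ndiff == 1L
  ti_pair <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  is_ti <- matrix(FALSE, n, n)
  for (p in 1:3) {
    diff_p <- outer(split_mat[, p], split_mat[, p], "!=")
    ti_p <- outer(split_mat[, p], split_mat[, p], ti_pair)
    is_ti <- is_ti | (one & diff_p & ti_p)
  }
  is_syn <- outer(code$aa, code$aa, "==") & one
  list(one = one, ti = is_ti, syn = is_syn)
})

#' Build a reversible codon rate matrix
#'
#' Single-nucleotide-change generator: `q_ij = pi_j`, times `kappa` for
#' transitions and `omega` for non-synonymous changes; zero for
#' multi-position changes; diagonal set so rows sum to zero. With
#' `scale = TRUE` the matrix is normalised so the expected number of
#' substitutions per unit branch length is 1 at stationarity.
#'
#' @param pi stationary codon frequencies (length 61, sums to 1).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega non-synonymous/synonymous rate ratio (>= 0).
#' @param scale normalise the total rate to 1.
#' @return 61 x 61 generator matrix.
#' @export
build_rate_matrix <- function(pi, kappa, omega, scale = TRUE) {
  stopifnot(length(pi) == 61L, abs(sum(pi) - 1) < 1e-8, kappa > 0, omega >= 0)
  cp <- .codon_pairs
  Q <- matrix(0, 61L, 61L)
  Q[cp$one] <- rep(pi, each = 61L)[cp$one]
  Q[cp$ti] <- Q[cp$ti] * kappa
  nonsyn <- cp$one & !cp$syn
  Q[nonsyn] <- Q[nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    Q <- Q / mu
  }
  Q
}

# total rate (expected substitutions per unit time) of an unscaled Q
.q_rate <- function(Q, pi) -sum(pi * diag(Q))

# synonymous fraction of the substitution flow of a generator
.syn_fraction <- function(Q, pi) {
  cp <- .codon_pairs
  flow <- pi * Q
  fs <- sum(flow[cp$syn])
  fn <- sum(flow[cp$one & !cp$syn])
  fs / (fs + fn)
}

# spectral system of a reversible generator (P(t) = A1 exp(Lam t) A2)
.eig_system <- function(Q, pi) {
  s <- sqrt(pi)
  B <- Q * outer(s, 1 / s)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  list(A1 = es$vectors / s, A2 = t(es$vectors) * rep(s, each = 61L),
       lam = es$values)
}

# memoised spectral system of the *unscaled* generator: rescaling a
# generator only rescales its eigenvalues, so one decomposition per
# (kappa, omega) serves every scaling and every optimizer step that
# leaves them unchanged
.get_sys <- function(pi, kappa, w, cache = NULL) {
  key <- paste0(format(kappa, digits = 17), "|", format(w, digits = 17))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  Q <- build_rate_matrix(pi, kappa, w, scale = FALSE)
  s <- .eig_system(Q, pi)
  s$rate <- .q_rate(Q, pi)
  if (!is.null(cache)) {
    keys <- ls(cache)
    if (length(keys) > 80L)  # bound memory; keep the prepared tree
      rm(list = setdiff(keys, "__bs_tree"), envir = cache)
    cache[[key]] <- s
  }
  s
}

.scale_sys <- function(sys, mu) {
  sys$lam <- sys$lam / mu
  sys
}

# dense transition matrix from a spectral system (used by the simulator)
.pmat_r <- function(sys, t) {
  P <- sys$A1 %*% (exp(sys$lam * t) * sys$A2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Branch-site model A site-class scheme
#'
#' Four site classes: class 0 (`0 < omega0 < 1` on all branches), class 1
#' (neutral everywhere), and classes 2a/2b where the foreground branch
#' switches to `omega2 >= 1` while the background keeps `omega0` (2a) or
#' 1 (2b). The proportions of 2a and 2b split `1 - p0 - p1` in the ratio
#' `p0 : p1`.
#'
#' @param p0,p1 proportions of classes 0 and 1 (`p0 + p1 <= 1`).
#' @param omega0 purifying ratio in (0, 1).
#' @param omega2 foreground ratio (>= 1; fixed at 1 under the null).
#' @return data.frame with columns `class`, `prop`, `w_bg`, `w_fg`.
#' @export
site_classes <- function(p0, p1, omega0, omega2) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12)
  p2 <- max(0, 1 - p0 - p1)
  denom <- p0 + p1
  if (denom <= 0) {
    p2a <- p2 / 2
    p2b <- p2 / 2
  } else {
    p2a <- p2 * p0 / denom
    p2b <- p2 * p1 / denom
  }
  data.frame(
    class = c("0", "1", "2a", "2b"),
    prop = c(p0, p1, p2a, p2b),
    w_bg = c(omega0, 1, omega0, 1),
    w_fg = c(omega0, 1, omega2, omega2),
    stringsAsFactors = FALSE
  )
}

#' Codon model parameter container
#'
#' @param model one of `"M0"`, `"free_ratio"`, `"bsA"`, `"bsA_null"`.
#' @param kappa transition/transversion ratio.
#' @param pi stationary codon frequencies (length 61).
#' @param omega single ratio (M0) or per-edge vector (free_ratio).
#' @param p0,p1,omega0,omega2 branch-site mixture parameters.
#' @return object of class `codon_params`.
#' @export
codon_params <- function(model = c("M0", "free_ratio", "bsA", "bsA_null"),
                         kappa, pi, omega = NULL, p0 = NULL, p1 = NULL,
                         omega0 = NULL, omega2 = NULL) {
  model <- match.arg(model)
  stopifnot(length(pi) == 61L, all(pi >= 0), abs(sum(pi) - 1) < 1e-6)
  if (model == "bsA_null") omega2 <- 1
  if (model %in% c("bsA", "bsA_null")) {
    stopifnot(!is.null(p0), !is.null(p1), !is.null(omega0), !is.null(omega2))
    stopifnot(omega0 >= 0, omega0 < 1, omega2 >= 1)
  } else {
    stopifnot(!is.null(omega))
  }
  structure(list(model = model, kappa = kappa, pi = pi, omega = omega,
                 p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2),
            class = "codon_params")
}

#' Estimate stationary codon frequencies from an alignment
#'
#' @param aln codon alignment matrix.
#' @param model `"F3x4"` (position-specific nucleotide frequencies,
#'   the conventional default), `"F1x4"`, `"F61"` (empirical codon
#'   frequencies) or `"uniform"`.
#' @return length-61 frequency vector over the sense codons.
#' @export
codon_frequencies <- function(aln, model = c("F3x4", "F1x4", "F61", "uniform")) {
  model <- match.arg(model)
  code <- genetic_code()
  if (model == "uniform") return(rep(1 / 61, 61L))
  aln <- as_alignment_matrix(aln)
  nts <- c("A", "C", "G", "T")
  if (model == "F61") {
    st <- codon_states(aln)
    cnt <- tabulate(st[!is.na(st)], nbins = 61L)
    pi <- cnt + 0.5  # regularise unobserved codons
    return(pi / sum(pi))
  }
  pos <- (seq_len(ncol(aln)) - 1L) %% 3L + 1L
  f <- matrix(0, 3L, 4L, dimnames = list(NULL, nts))
  for (p in 1:3) {
    tab <- table(factor(aln[, pos == p], levels = nts))
    f[p, ] <- as.numeric(tab)
  }
  if (model == "F1x4") f <- matrix(colSums(f), 3L, 4L, byrow = TRUE,
                                   dimnames = list(NULL, nts))
  f <- f + 0.5
  f <- f / rowSums(f)
  sp <- strsplit(code$codons, "")
  pi <- vapply(sp, function(x) f[1, x[1]] * f[2, x[2]] * f[3, x[3]],
               numeric(1))
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

# -- internal tree/alignment preparation for the likelihood engine ------

.prep_tree <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(tree = tr, edge = tr$edge, elen = tr$edge.length,
       ntip = ape::Ntip(tr))
}

.pattern_compress <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  pats <- states[, u, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[u])))
  site_of <- match(key, key[u])
  pats[is.na(pats)] <- 0L
  list(pats = pats, w = w, site_of = site_of)
}

# order tip-state rows to match the tree's tip numbering
.tip_states <- function(aln, tree) {
  states <- codon_states(as_alignment_matrix(aln))
  miss <- setdiff(tree$tip.label, rownames(states))
  if (length(miss))
    stop("tree tips missing from alignment: ", paste(miss, collapse = ", "))
  states[tree$tip.label, , drop = FALSE]
}

# scale factor for branch-site generators: expected substitutions per
# unit time under the background mixture
.bs_scale <- function(pi, kappa, classes) {
  rates <- vapply(unique(classes$w_bg), function(w)
    .q_rate(build_rate_matrix(pi, kappa, w, scale = FALSE), pi), numeric(1))
  names(rates) <- as.character(unique(classes$w_bg))
  sum(classes$prop * rates[as.character(classes$w_bg)])
}

#' Site log-likelihoods of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61 sense-codon states. For branch-site
#' models the tree must carry a marked foreground branch (see
#' [mark_foreground()]); the likelihood is a mixture over the four site
#' classes with the foreground branch switching rate ratio. Gap and
#' ambiguous codons contribute a partial likelihood of 1 over all states.
#'
#' @param aln codon alignment (matrix or named strings).
#' @param tree `ape::phylo` with branch lengths (tips must appear in the
#'   alignment).
#' @param params a [codon_params()] object.
#' @return list with `per_site` (log-likelihood per codon column) and
#'   `total`.
#' @export
site_log_likelihood <- function(aln, tree, params) {
  stopifnot(inherits(params, "codon_params"))
  states <- .tip_states(aln, tree)
  pc <- .pattern_compress(states)
  if (params$model %in% c("bsA", "bsA_null")) {
    per_pat <- .bs_pattern_loglik(tree, pc$pats, params)
  } else {
    per_pat <- .single_pattern_loglik(tree, pc$pats, params)
  }
  per_site <- per_pat[pc$site_of]
  list(per_site = per_site, total = sum(per_pat * pc$w))
}

.single_pattern_loglik <- function(tree, pats, params, cache = NULL) {
  pt <- .prep_tree(tree)
  if (params$model == "M0") {
    s <- .get_sys(params$pi, params$kappa, params$omega, cache)
    sys <- list(.scale_sys(s, s$rate))
    sys_idx <- rep(1L, nrow(pt$edge))
  } else { # free_ratio: omega per edge of the *postorder* tree
    omg <- params$omega
    if (length(omg) != nrow(pt$edge))
      stop("free_ratio needs one omega per edge (", nrow(pt$edge), ")")
    uw <- unique(omg)
    sys <- lapply(uw, function(w) {
      s <- .get_sys(params$pi, params$kappa, w, cache)
      .scale_sys(s, s$rate)
    })
    sys_idx <- match(omg, uw)
  }
  prune_loglik_cpp(pt$edge, pt$elen, sys_idx, pats,
                   lapply(sys, `[[`, "A1"), lapply(sys, `[[`, "A2"),
                   lapply(sys, `[[`, "lam"), params$pi)
}

# mixture log-likelihood per pattern for branch-site models; the tree is
# re-rooted at the parent of the foreground edge so the paired-class
# engine can reuse all background computations
.bs_pattern_loglik <- function(tree, pats, params, cache = NULL) {
  classes <- site_classes(params$p0, params$p1, params$omega0, params$omega2)
  prep <- if (!is.null(cache)) cache[["__bs_tree"]] else NULL
  if (is.null(prep)) {
    tr <- .reroot_at_fg(tree)
    pt <- .prep_tree(tr)
    prep <- list(pt = pt, fg_row = .fg_row_postorder(pt))
    if (!is.null(cache)) cache[["__bs_tree"]] <- prep
  }
  pt <- prep$pt
  fg_row <- prep$fg_row
  s_w0 <- .get_sys(params$pi, params$kappa, params$omega0, cache)
  s_w1 <- .get_sys(params$pi, params$kappa, 1, cache)
  s_w2 <- if (params$omega2 == 1) s_w1 else
    .get_sys(params$pi, params$kappa, params$omega2, cache)
  rates <- c(s_w0$rate, s_w1$rate, s_w0$rate, s_w1$rate)
  mu <- sum(classes$prop * rates)  # background mixture rate
  sys_w0 <- .scale_sys(s_w0, mu)
  sys_w1 <- .scale_sys(s_w1, mu)
  sys_w2 <- .scale_sys(s_w2, mu)
  # rows: fg edge under background omega / under foreground omega
  ll_a <- classpair_loglik_cpp(pt$edge, pt$elen, fg_row, pats,
                               sys_w0$A1, sys_w0$A2, sys_w0$lam,
                               sys_w2$A1, sys_w2$A2, sys_w2$lam, params$pi)
  ll_b <- classpair_loglik_cpp(pt$edge, pt$elen, fg_row, pats,
                               sys_w1$A1, sys_w1$A2, sys_w1$lam,
                               sys_w2$A1, sys_w2$A2, sys_w2$lam, params$pi)
  # class order: 0, 1, 2a, 2b
  mat <- rbind(ll_a[1, ], ll_b[1, ], ll_a[2, ], ll_b[2, ])
  w <- classes$prop
  mx <- apply(mat, 2L, max)
  log(colSums(w * exp(sweep(mat, 2L, mx)))) + mx
}

# re-root (if needed) so that the foreground edge hangs off the root
.reroot_at_fg <- function(tree) {
  fg <- foreground_edge(tree)
  parent <- tree$edge[fg, 1]
  root <- ape::Ntip(tree) + 1L
  if (parent == root) return(tree)
  out <- ape::root(tree, node = parent, resolve.root = FALSE)
  .keep_fg(out, tree)
}

.fg_row_postorder <- function(pt) {
  tr <- pt$tree
  fg <- foreground_edge(tr)
  fg
}
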