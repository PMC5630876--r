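# Independent oracles used across the suite. These deliberately avoid
# the package's own computational paths: transition matrices come from
# Matrix::expm (Pade approximation, not the spectral route), likelihoods
# from explicit enumeration of internal states, p-value adjustments from
# a literal step-up implementation.

# enumerate all internal-state combinations to compute the exact
# log-likelihood of a (small) codon alignment under M0 or branch-site
# models
brute_site_loglik <- function(aln, tree, params) {
  states <- thermosel:::.tip_states(as_alignment_matrix(aln), tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  attr(tr, "foreground_clade") <- attr(tree, "foreground_clade")
  edge <- tr$edge
  elen <- tr$edge.length
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  root <- edge[nrow(edge), 1]
  if (params$model %in% c("bsA", "bsA_null")) {
    classes <- site_classes(params$p0, params$p1, params$omega0,
                            params$omega2)
    mu <- thermosel:::.bs_scale(params$pi, params$kappa, classes)
  } else {
    classes <- data.frame(class = "0", prop = 1, w_bg = params$omega,
                          w_fg = params$omega)
    mu <- NA
  }
  fg <- if (!is.null(attr(tr, "foreground_clade")))
    foreground_edge(tr) else NA
  Pm <- function(w, t) {
    Q <- build_rate_matrix(params$pi, params$kappa, w, scale = is.na(mu))
    if (!is.na(mu)) Q <- Q / mu
    as.matrix(Matrix::expm(Q * t))
  }
  ints <- (ntip + 1):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:61), nnode)))
  total <- 0
  for (site in seq_len(ncol(states))) {
    lik_site <- 0
    for (k in seq_len(nrow(classes))) {
      Ps <- lapply(seq_len(nrow(edge)), function(e) {
        w <- if (!is.na(fg) && e == fg) classes$w_fg[k] else classes$w_bg[k]
        Pm(w, elen[e])
      })
      lik <- params$pi[grid[, match(root, ints)]]
      for (e in seq_len(nrow(edge))) {
        p <- edge[e, 1]; c <- edge[e, 2]
        sp <- grid[, match(p, ints)]
        if (c <= ntip) {
          s <- states[c, site]
          lik <- lik * (if (is.na(s)) 1 else Ps[[e]][cbind(sp, s)])
        } else {
          lik <- lik * Ps[[e]][cbind(sp, grid[, match(c, ints)])]
        }
      }
      lik_site <- lik_site + classes$prop[k] * sum(lik)
    }
    total <- total + log(lik_site)
  }
  total
}

# marginal posterior of a chosen internal node by enumeration over all
# internal states (20 amino-acid states, Poisson model)
brute_asr_posterior <- function(aln, tree, node, freqs = rep(1 / 20, 20)) {
  AA <- thermosel:::.AA
  m <- as_alignment_matrix(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  m <- m[tr$tip.label, , drop = FALSE]
  root <- edge[nrow(edge), 1]
  Q <- thermosel:::.aa_generator(freqs)
  Ps <- lapply(elen, function(t) as.matrix(Matrix::expm(Q * t)))
  ints <- (ntip + 1):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  out <- matrix(0, 20, ncol(m))
  for (site in seq_len(ncol(m))) {
    s_tip <- match(m[, site], AA)
    lik <- freqs[grid[, match(root, ints)]]
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1]; c <- edge[e, 2]
      sp <- grid[, match(p, ints)]
      if (c <= ntip) {
        s <- s_tip[c]
        lik <- lik * (if (is.na(s)) 1 else Ps[[e]][cbind(sp, s)])
      } else {
        lik <- lik * Ps[[e]][cbind(sp, grid[, match(c, ints)])]
      }
    }
    st <- grid[, match(node, ints)]
    for (a in 1:20) out[a, site] <- sum(lik[st == a])
    out[, site] <- out[, site] / sum(out[, site])
  }
  out
}

# literal Benjamini-Hochberg step-up
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# two-sided Fisher exact p by full hypergeometric enumeration
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, c1, n - c1, r1),
                  numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# quick random in-frame codon alignment (gapless) without stop codons
random_codon_alignment <- function(n_seq, n_codons, seed) {
  set.seed(seed)
  code <- genetic_code()
  m <- matrix("", n_seq, 3 * n_codons,
              dimnames = list(sprintf("sp%02d", seq_len(n_seq)), NULL))
  for (j in seq_len(n_codons)) {
    cods <- sample(code$codons, n_seq, replace = TRUE)
    m[, (3 * j - 2):(3 * j)] <- do.call(rbind, strsplit(cods, ""))
  }
  m
}
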