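.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# dN/dS decomposition of one branch from the model's substitution flow:
# t is in expected substitutions per codon; the synonymous fraction of
# flow under the branch's omega, divided by the synonymous fraction of
# sites (flow under omega = 1), gives per-site dS and dN.
.branch_dnds <- function(t, omega, kappa, pi) {
  Q1 <- build_rate_matrix(pi, kappa, 1, scale = FALSE)
  rhoS <- .syn_fraction(Q1, pi)
  Qw <- build_rate_matrix(pi, kappa, omega, scale = FALSE)
  fS <- .syn_fraction(Qw, pi)
  c(dS = t * fS / (3 * rhoS), dN = t * (1 - fS) / (3 * (1 - rhoS)))
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Bounded quasi-Newton optimisation on transformed parameters:
#' `log(kappa)`, `log(omega)` (M0/free-ratio), logit of `omega0`,
#' `log(omega2 - 1)` (so `omega2 >= 1` always holds; it is fixed at 1
#' under the branch-site null), and additive log-ratios of the class
#' proportions. Under M0 the branch lengths are estimated jointly
#' (log-transformed); the free-ratio and branch-site models keep the
#' supplied branch lengths fixed, the intended workflow being one M0 fit
#' per gene whose branch lengths are reused (see [scan_gene()]).
#'
#' @param aln codon alignment (matrix or named strings).
#' @param tree `ape::phylo` with starting branch lengths; for branch-site
#'   models it must carry a foreground mark ([mark_foreground()]).
#' @param model `"M0"`, `"free_ratio"`, `"bsA"` or `"bsA_null"`.
#' @param start_omega starting rate ratio; for branch-site models it
#'   seeds `omega0` (clamped below 1) and `omega2` (clamped above 1).
#' @param freq_model codon frequency model, see [codon_frequencies()].
#' @param optimize_blen estimate branch lengths (default: only under M0).
#' @param init optional list of starting values (`kappa`, and for
#'   branch-site models `p0`, `p1`, `omega0`) -- e.g. to warm-start the
#'   null fit from the alternative's optimum.
#' @param control passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return a `codon_fit` list: `model`, `loglik`, `params`
#'   ([codon_params()]), `tree` (with fitted branch lengths under M0),
#'   `branches` (per-branch `t`, `omega`, `dN`, `dS`), `convergence`
#'   (0 = converged), `start_omega`.
#' @export
fit_model <- function(aln, tree,
                      model = c("M0", "free_ratio", "bsA", "bsA_null"),
                      start_omega = 0.5,
                      freq_model = "F3x4",
                      optimize_blen = NULL,
                      init = NULL,
                      control = list()) {
  model <- match.arg(model)
  aln <- as_alignment_matrix(aln)
  pi <- codon_frequencies(aln, freq_model)
  if (is.null(optimize_blen)) optimize_blen <- model == "M0"
  if (model %in% c("bsA", "bsA_null") && is.null(attr(tree, "foreground_clade")))
    stop("branch-site models require a marked foreground branch")

  states <- .tip_states(aln, tree)
  pc <- .pattern_compress(states)
  nedge <- nrow(tree$edge)
  t0 <- pmax(tree$edge.length, 1e-4)

  # parameter packing -------------------------------------------------
  if (model == "M0") {
    k0 <- if (!is.null(init$kappa)) init$kappa else 2
    par0 <- c(log(t0), log(k0), log(max(start_omega, 1e-3)))
    lower <- c(rep(log(1e-6), nedge), log(0.05), log(1e-4))
    upper <- c(rep(log(50), nedge), log(50), log(20))
    unpack <- function(p) {
      list(elen = exp(p[seq_len(nedge)]),
           params = codon_params("M0", kappa = exp(p[nedge + 1L]), pi = pi,
                                 omega = exp(p[nedge + 2L])))
    }
  } else if (model == "free_ratio") {
    k0 <- if (!is.null(init$kappa)) init$kappa else 2
    par0 <- c(log(k0), rep(log(max(start_omega, 1e-3)), nedge))
    lower <- c(log(0.05), rep(log(1e-4), nedge))
    upper <- c(log(50), rep(log(999), nedge))
    unpack <- function(p) {
      list(elen = NULL,
           params = codon_params("free_ratio", kappa = exp(p[1L]), pi = pi,
                                 omega = exp(p[-1L])))
    }
  } else {
    w0_start <- min(max(start_omega, 0.05), 0.9)
    w2_start <- max(start_omega, 1.001)
    k_start <- 2; p0_start <- 0.5; p1_start <- 0.35
    if (!is.null(init)) {
      if (!is.null(init$kappa)) k_start <- init$kappa
      if (!is.null(init$omega0)) w0_start <- min(max(init$omega0, 1e-3), 0.99)
      if (!is.null(init$p0)) p0_start <- init$p0
      if (!is.null(init$p1)) p1_start <- init$p1
      tot <- p0_start + p1_start
      if (tot > 0.98) { p0_start <- p0_start / tot * 0.98
                        p1_start <- p1_start / tot * 0.98 }
      p0_start <- max(p0_start, 1e-3); p1_start <- max(p1_start, 1e-3)
    }
    p2_start <- max(1 - p0_start - p1_start, 1e-3)
    # class proportions via additive log-ratio against p2 = 1 - p0 - p1
    base <- c(log(k_start), log(p0_start / p2_start),
              log(p1_start / p2_start), .logit(w0_start))
    if (model == "bsA") {
      par0 <- c(base, log(w2_start - 1))
      lower <- c(log(0.05), -15, -15, .logit(1e-4), log(1e-4))
      upper <- c(log(50), 15, 15, .logit(0.999), log(999))
    } else {
      par0 <- base
      lower <- c(log(0.05), -15, -15, .logit(1e-4))
      upper <- c(log(50), 15, 15, .logit(0.999))
    }
    unpack <- function(p) {
      e1 <- exp(p[2L]); e2 <- exp(p[3L])
      denom <- 1 + e1 + e2
      w2 <- if (model == "bsA") 1 + exp(p[5L]) else 1
      list(elen = NULL,
           params = codon_params(model, kappa = exp(p[1L]), pi = pi,
                                 p0 = e1 / denom, p1 = e2 / denom,
                                 omega0 = .inv_logit(p[4L]), omega2 = w2))
    }
  }

  # objective ----------------------------------------------------------
  work_tree <- tree
  cache <- new.env(parent = emptyenv())
  nll <- function(p) {
    u <- unpack(p)
    tr <- work_tree
    if (!is.null(u$elen)) tr$edge.length <- u$elen
    ll <- tryCatch({
      if (u$params$model %in% c("bsA", "bsA_null")) {
        sum(.bs_pattern_loglik(tr, pc$pats, u$params, cache) * pc$w)
      } else {
        sum(.single_pattern_loglik(tr, pc$pats, u$params, cache) * pc$w)
      }
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ctl <- utils::modifyList(list(maxit = 500L, factr = 1e9), control)
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctl)
  if (model == "bsA") {
    # the likelihood surface has a local optimum at omega2 = 1 where the
    # selected-class mass also collapses; probe a coarse omega2 grid
    # with the class-2 proportion reopened and restart when it helps
    u_cur <- unpack(opt$par)
    ratio <- max(u_cur$params$p0, 1e-3) /
      max(u_cur$params$p0 + u_cur$params$p1, 2e-3)
    p2_new <- 0.1
    z1 <- log(max(ratio * (1 - p2_new), 1e-3) / p2_new)
    z2 <- log(max((1 - ratio) * (1 - p2_new), 1e-3) / p2_new)
    for (w2_try in c(2, 4, 8)) {
      p_try <- opt$par
      p_try[2:3] <- c(z1, z2)
      p_try[length(p_try)] <- log(w2_try - 1)
      if (nll(p_try) < opt$value - 1e-3) {
        opt2 <- stats::optim(p_try, nll, method = "L-BFGS-B",
                             lower = lower, upper = upper, control = ctl)
        if (opt2$value < opt$value) opt <- opt2
      }
    }
  }
  u <- unpack(opt$par)
  fitted_tree <- work_tree
  if (!is.null(u$elen)) fitted_tree$edge.length <- u$elen

  branches <- NULL
  if (model %in% c("M0", "free_ratio")) {
    omg <- if (model == "M0") rep(u$params$omega, nedge) else u$params$omega
    dn_ds <- t(vapply(seq_len(nedge), function(e)
      .branch_dnds(fitted_tree$edge.length[e], omg[e], u$params$kappa, pi),
      numeric(2)))
    branches <- data.frame(parent = fitted_tree$edge[, 1],
                           child = fitted_tree$edge[, 2],
                           t = fitted_tree$edge.length, omega = omg,
                           dS = dn_ds[, "dS"], dN = dn_ds[, "dN"])
  }

  structure(list(model = model, loglik = -opt$value, params = u$params,
                 tree = .keep_fg(fitted_tree, tree), branches = branches,
                 convergence = opt$convergence, start_omega = start_omega,
                 np = length(par0), n_codons = sum(pc$w)),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit:", x$model, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10), "\n")
  cat("  kappa:", signif(x$params$kappa, 4), "\n")
  if (x$model %in% c("bsA", "bsA_null")) {
    cat("  p0:", signif(x$params$p0, 4), " p1:", signif(x$params$p1, 4),
        " omega0:", signif(x$params$omega0, 4),
        " omega2:", signif(x$params$omega2, 4), "\n")
  } else if (x$model == "M0") {
    cat("  omega:", signif(x$params$omega, 4), "\n")
  }
  invisible(x)
}

#' Branch-site likelihood ratio test
#'
#' Twice the log-likelihood difference between the branch-site model and
#' its null (foreground omega fixed at 1), clamped at zero, referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param fit_alt `codon_fit` under `"bsA"`.
#' @param fit_null `codon_fit` under `"bsA_null"`.
#' @return list with `stat`, `p`, `df`.
#' @export
branch_site_lrt <- function(fit_alt, fit_null) {
  if (fit_alt$model != "bsA" || fit_null$model != "bsA_null")
    stop("expected a bsA fit and a bsA_null fit")
  if (fit_alt$n_codons != fit_null$n_codons)
    stop("fits are not on the same data")
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (via [stats::p.adjust()]),
#' applied per gene across its six branch-site tests in the scan.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Six-test consensus call
#'
#' A gene is called under selection only when all six adjusted p-values
#' (two alignment pipelines x three starting omegas) fall below `alpha`.
#' With fewer than six tests (e.g. one pipeline rejected the gene) the
#' gene is not callable.
#'
#' @param p_adj adjusted p-values for one gene.
#' @param alpha significance level (default 0.05).
#' @param n_required number of tests required (default 6).
#' @return `"selected"`, `"not_selected"`, or `"untested"`.
#' @export
consensus_call <- function(p_adj, alpha = 0.05, n_required = 6L) {
  p_adj <- p_adj[!is.na(p_adj)]
  if (length(p_adj) < n_required) return("untested")
  if (all(p_adj < alpha)) "selected" else "not_selected"
}

#' Synonymous-saturation screen
#'
#' Flags genes whose synonymous distance is saturated: overall dS > 1
#' in the one-ratio fit, or dS > 1 on the foreground (endothermic stem)
#' branch in the free-ratio fit.
#'
#' @param one_ratio `codon_fit` under M0.
#' @param free_ratio `codon_fit` under free_ratio on the same gene; its
#'   tree must carry the foreground mark.
#' @return list with `flag`, `ds_overall`, `ds_foreground`.
#' @export
saturation_screen <- function(one_ratio, free_ratio) {
  stopifnot(one_ratio$model == "M0", free_ratio$model == "free_ratio")
  ds_overall <- sum(one_ratio$branches$dS)
  fg <- foreground_edge(free_ratio$tree)
  ds_fg <- free_ratio$branches$dS[fg]
  list(flag = ds_overall > 1 || ds_fg > 1,
       ds_overall = ds_overall, ds_foreground = ds_fg)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than the observed
#' table's (via [stats::fisher.test()]); the enrichment mechanics used
#' for annotation-category tests.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("empty margin in 2x2 table; p = 1")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Probability of independent selection in both lineages
#'
#' Crude estimate, assuming all genes equally likely to be selected:
#' the product of the two per-lineage selection fractions among the `n`
#' genes tested in both lineages.
#'
#' @param a genes selected in lineage 1 (of the shared set).
#' @param b genes selected in lineage 2.
#' @param n shared tested genes.
#' @return `(a/n) * (b/n)`; report with [round_sig()] to one significant
#'   figure.
#' @export
overlap_probability <- function(a, b, n) {
  stopifnot(n > 0, a >= 0, b >= 0)
  if (a > n || b > n) stop("counts cannot exceed the shared gene total")
  (a / n) * (b / n)
}

#' Round to significant figures (reporting helper)
#' @param x numeric.
#' @param digits significant digits (default 1).
#' @export
round_sig <- function(x, digits = 1) signif(x, digits)

#' Percentage truncated to a fixed number of decimals
#'
#' `percent_truncated(139, 7032)` is `1.9`: the convention used when a
#' selected-gene count is reported as a percentage of genes tested.
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimals kept (default 1).
#' @export
percent_truncated <- function(k, n, digits = 1) {
  floor(k / n * 100 * 10^digits) / 10^digits
}
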