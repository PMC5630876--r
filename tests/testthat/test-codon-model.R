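test_that("codon rate matrix has the required structure", {
  pi <- rep(1 / 61, 61)
  Q <- build_rate_matrix(pi, kappa = 2.5, omega = 0.3)
  code <- genetic_code()
  i <- match("TTT", code$codons); j <- match("GGG", code$codons)
  expect_equal(Q[i, j], 0)                      # two-position change
  expect_equal(rowSums(Q), rep(0, 61), tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)  # scaled rate
  # detailed balance
  piQ <- pi * Q
  expect_equal(piQ, t(piQ), tolerance = 1e-12)

  # unequal frequencies keep reversibility
  set.seed(1)
  pi2 <- rgamma(61, 2); pi2 <- pi2 / sum(pi2)
  Q2 <- build_rate_matrix(pi2, kappa = 4, omega = 1.7)
  expect_equal(pi2 * Q2, t(pi2 * Q2), tolerance = 1e-12)
})

test_that("transition matrices behave as a stochastic semigroup", {
  set.seed(2)
  pi <- rgamma(61, 2); pi <- pi / sum(pi)
  Q <- build_rate_matrix(pi, 2, 0.5)
  sys <- thermosel:::.eig_system(Q, pi)
  P0 <- thermosel:::.pmat_r(sys, 0)
  expect_equal(P0, diag(61), tolerance = 1e-8)
  for (t in c(0.01, 0.3, 2)) {
    P <- thermosel:::.pmat_r(sys, t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
    expect_equal(as.vector(pi %*% P), pi, tolerance = 1e-10)  # stationarity
    expect_true(all(P >= 0))
  }
})

test_that("site-class proportions follow the branch-site scheme", {
  sc <- site_classes(0.45, 0.40, 0.15, 4)
  expect_equal(sum(sc$prop), 1)
  expect_equal(sc$prop[3], 0.15 * 0.45 / 0.85)
  expect_equal(sc$prop[4], 0.15 * 0.40 / 0.85)
  expect_equal(sc$w_fg, c(0.15, 1, 4, 4))
  expect_equal(sc$w_bg, c(0.15, 1, 0.15, 1))
})

test_that("likelihood limits: zero and infinite branch lengths", {
  # two identical tips at zero distance: site likelihood -> pi_codon
  tr <- parse_newick("(a:1e-9,b:1e-9);")
  aln <- c(a = "ATG", b = "ATG")
  pi <- rep(1 / 61, 61)
  p <- codon_params("M0", kappa = 2, pi = pi, omega = 0.5)
  ll <- site_log_likelihood(aln, tr, p)
  expect_equal(ll$total, log(1 / 61), tolerance = 1e-6)

  # very long branches: tips independent, likelihood -> prod pi
  tr2 <- parse_newick("(a:60,b:60,c:60);")
  aln2 <- c(a = "ATG", b = "TTT", c = "GGG")
  ll2 <- site_log_likelihood(aln2, tr2, p)
  expect_equal(ll2$total, 3 * log(1 / 61), tolerance = 1e-4)

  # gap codons are missing data: a fully gapped row adds nothing
  aln3 <- c(a = "ATG", b = "ATG", c = "---")
  tr3 <- parse_newick("(a:1e-9,b:1e-9,c:0.5);")
  ll3 <- site_log_likelihood(aln3, tr3, p)
  expect_equal(ll3$total, log(1 / 61), tolerance = 1e-6)
})

test_that("branch-site LRT uses the chi-square(1) upper tail", {
  mk <- function(ll, model) structure(list(model = model, loglik = ll,
                                           n_codons = 100), class = "codon_fit")
  expect_equal(branch_site_lrt(mk(-10, "bsA"), mk(-10, "bsA_null"))$p, 1)
  expect_equal(branch_site_lrt(mk(-8.0795, "bsA"), mk(-10, "bsA_null"))$p,
               0.05, tolerance = 1e-3)
  expect_equal(branch_site_lrt(mk(-6.6825, "bsA"), mk(-10, "bsA_null"))$p,
               0.01, tolerance = 1e-3)
  # negative statistics clamp to zero
  expect_equal(branch_site_lrt(mk(-11, "bsA"), mk(-10, "bsA_null"))$stat, 0)
  expect_error(branch_site_lrt(mk(-10, "M0"), mk(-10, "bsA_null")),
               "expected")
})

test_that("BH adjustment matches the literal step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(0.031), 0.031)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_equal(bh_adjust(p), bh_step_up(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("consensus requires all six adjusted p-values below alpha", {
  expect_equal(consensus_call(rep(0.01, 6)), "selected")
  expect_equal(consensus_call(c(rep(0.01, 5), 0.06)), "not_selected")
  expect_equal(consensus_call(rep(0.01, 5)), "untested")
  expect_equal(consensus_call(c(rep(0.01, 5), NA)), "untested")
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  t2 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_2x2(t2), fisher_enum(t2), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum(tab),
                 tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)),
                 "empty margin")
  expect_equal(p0, 1)
})

test_that("independent-overlap probability and reporting helpers", {
  expect_equal(overlap_probability(14, 22, 1192), 14 * 22 / 1192^2)
  expect_equal(overlap_probability(0, 5, 100), 0)
  expect_equal(overlap_probability(10, 10, 10), 1)
  expect_error(overlap_probability(11, 2, 10), "exceed")
  expect_equal(round_sig(2.1677e-4), 2e-4)
  expect_equal(percent_truncated(139, 7032), 1.9)
  expect_equal(percent_truncated(19, 1719), 1.1)
})

test_that("foreground marking targets the endothermic stem", {
  sim <- simulate_tree(8, seed = 1)
  tr <- sim$tree
  fe <- foreground_edge(tr)
  below <- ape::extract.clade(tr, tr$edge[fe, 2])$tip.label
  expect_setequal(below, sim$endo_species)

  # pruning away an endotherm: mark moves to the surviving tips' MRCA
  keep <- setdiff(tr$tip.label, sim$endo_species[1])
  pruned <- mark_foreground(prune_taxa(tr, keep),
                            sim$endo_species)
  expect_setequal(attr(pruned, "foreground_clade"),
                  setdiff(sim$endo_species, sim$endo_species[1]))

  # paraphyletic endotherms are an error
  expect_error(mark_foreground(tr, c(sim$endo_species[1], "sp08")),
               "monophyletic")
})

test_that("saturation screen flags high synonymous distance", {
  sim <- simulate_tree(8, seed = 1, blen = 0.05, endo_stem = 0.1)
  a <- simulate_codon_alignment(sim$tree, n_codons = 120, seed = 5)
  tru <- unroot_marked(sim$tree)
  m0 <- fit_model(a$aln, tru, "M0")
  fr <- fit_model(a$aln, m0$tree, "free_ratio",
                  init = list(kappa = m0$params$kappa))
  sat <- saturation_screen(m0, fr)
  expect_false(sat$flag)    # short tree: nowhere near saturation
  expect_gt(sat$ds_overall, 0)
  # thresholds: doctor the fits to the reported boundary cases
  m0_hot <- m0; m0_hot$branches$dS <- m0$branches$dS /
    sum(m0$branches$dS) * 1.14
  expect_true(saturation_screen(m0_hot, fr)$flag)
  fr_hot <- fr; fr_hot$branches$dS[foreground_edge(fr$tree)] <- 1.2
  expect_true(saturation_screen(m0, fr_hot)$flag)
})
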