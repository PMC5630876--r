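test_that("simulated trees have the requested shape, classes and scale", {
  sim <- simulate_tree(8, seed = 1)
  expect_equal(ape::Ntip(sim$tree), 8L)
  expect_equal(nrow(sim$tree$edge), 14L)  # rooted binary: 2n - 2 edges
  expect_length(sim$endo_species, 2L)
  expect_true(ape::is.monophyletic(sim$tree, sim$endo_species))
  expect_setequal(sim$classes$class, c("endo", "ecto"))

  # determinism under a fixed seed
  sim2 <- simulate_tree(8, seed = 1)
  expect_equal(write_newick(sim$tree), write_newick(sim2$tree))

  # doubling the branch-length scale doubles the total tree length
  a <- simulate_tree(8, seed = 2, blen = 0.05, endo_stem = 0.1)
  b <- simulate_tree(8, seed = 2, blen = 0.10, endo_stem = 0.2)
  expect_equal(sum(b$tree$edge.length), 2 * sum(a$tree$edge.length))

  # the foreground stem is never a root edge
  root <- ape::Ntip(sim$tree) + 1L
  fe <- foreground_edge(sim$tree)
  expect_false(sim$tree$edge[fe, 1] == root)
})

test_that("codon simulation is reproducible, stop-free and class-faithful", {
  sim <- simulate_tree(8, seed = 3)
  a1 <- simulate_codon_alignment(sim$tree, n_codons = 50, seed = 9)
  a2 <- simulate_codon_alignment(sim$tree, n_codons = 50, seed = 9)
  expect_identical(a1$aln, a2$aln)
  expect_silent(translate_alignment(a1$aln))  # no internal stops

  # p0 = 1: every site in class 0
  a3 <- simulate_codon_alignment(sim$tree, n_codons = 30, p0 = 1, p1 = 0,
                                 seed = 10)
  expect_true(all(a3$truth$site_class == "0"))

  # omega2 = 1 reduces to the null: truth records it
  a4 <- simulate_codon_alignment(sim$tree, n_codons = 30, omega2 = 1,
                                 seed = 11)
  expect_equal(a4$truth$omega2, 1)
})

test_that("long-branch simulation approaches the stationary distribution", {
  # single long branch: empirical codon frequencies approach pi
  tr <- parse_newick("(a:30,b:30);")
  a <- simulate_codon_alignment(tr, n_codons = 3000, p0 = 1, p1 = 0,
                                omega0 = 0.5, seed = 12)
  st <- codon_states(a$aln)
  freq <- tabulate(st, nbins = 61) / length(st)
  chi2_long <- sum((freq - 1 / 61)^2 / (1 / 61))
  # short branch from a single root draw stays far from uniform across
  # the two tips jointly; the long-branch chi-square must be small
  expect_lt(chi2_long, 0.05)
})

test_that("alternative-alignment corruption carries exact truth", {
  aln <- random_codon_alignment(6, 40, seed = 15)
  prot <- translate_alignment(aln)
  out <- make_alternative_alignments(prot, k = 3, corruption_frac = 0.25,
                                     seed = 16)
  expect_length(out$alternatives, 3L)
  expect_length(out$corrupted, 10L)
  # clean columns identical in every copy is vacuous here since column
  # indices shift; instead: corruption 0 gives identical copies
  out0 <- make_alternative_alignments(prot, k = 3, corruption_frac = 0,
                                      seed = 17)
  for (alt in out0$alternatives) expect_equal(alt, prot)
  expect_true(all(out0$confidences == 1))

  # corrupted-residue confidences sit at or below the masking threshold
  expect_true(all(out$confidences[, out$corrupted] <= 0.93, na.rm = TRUE))
  expect_true(all(out$confidences[, -out$corrupted] == 1, na.rm = TRUE))

  # alternatives still contain the same ungapped sequences
  dg <- function(m) gsub("-", "", alignment_strings(m))
  for (alt in out$alternatives) expect_equal(dg(alt), dg(prot))
})

test_that("gene families mirror the species tree when rates are zero", {
  st <- simulate_tree(8, seed = 4)$tree
  g <- simulate_gene_family(st, dup_rate = 0, loss_rate = 0,
                            spurious_tip_rate = 0, seed = 5)
  expect_equal(ape::Ntip(g$tree), 10L)  # 8 species + 2 outgroups
  truth <- attr(g, "truth")
  expect_length(truth$ortholog_tips, 8L)
  # with a deep duplication the stem exceeds the paralog threshold
  g2 <- simulate_gene_family(st, dup_rate = 5, deep_paralog = TRUE,
                             seed = 6)
  if (length(attr(g2, "truth")$duplications)) {
    stems <- vapply(attr(g2, "truth")$duplications, `[[`, numeric(1),
                    "stem")
    expect_true(all(stems > 0.5))
  }
  # spurious tips are long enough for the absolute trimming rule
  g3 <- simulate_gene_family(st, spurious_tip_rate = 1, seed = 7)
  spur <- grep("spur", g3$tree$tip.label)
  pend <- g3$tree$edge.length[match(spur, g3$tree$edge[, 2])]
  expect_true(all(pend > 2))
  trimmed <- trim_spurious_tips(g3)
  expect_length(grep("spur", trimmed$tree$tip.label), 0L)
})

test_that("study simulation labels selected genes and derives gene seeds", {
  study <- simulate_study(n_genes = 4, n_selected = 2, n_codons = 20,
                          seed = 8)
  expect_length(study$genes, 4L)
  expect_equal(study$truth, c(TRUE, TRUE, FALSE, FALSE))
  study2 <- simulate_study(n_genes = 4, n_selected = 2, n_codons = 20,
                           seed = 8)
  expect_identical(study$genes, study2$genes)
  # different gene indices give different alignments
  expect_false(identical(study$genes[[3]], study$genes[[4]]))
})
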