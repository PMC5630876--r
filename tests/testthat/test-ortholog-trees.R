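ht_from_newick <- function(txt, species = NULL, chars = NULL) {
  tr <- parse_newick(txt)
  if (is.null(species)) species <- sub("_.*$", "", tr$tip.label)
  if (is.null(chars)) chars <- rep(100L, ape::Ntip(tr))
  homolog_tree(tr, species, chars)
}

test_that("spurious tips are trimmed by absolute and relative rules", {
  # absolute: 2.5 > 2 removed; 2.0 kept (strict >, sisters long enough
  # that the relative rule stays silent)
  ht <- ht_from_newick("((a_1:2.5,b_1:0.3):0.1,(c_1:2.0,d_1:0.3):0.1);")
  out <- trim_spurious_tips(ht)
  expect_setequal(out$tree$tip.label, c("b_1", "c_1", "d_1"))

  # relative: 0.50 vs sister tip 0.04 (ratio 12.5) removed
  ht2 <- ht_from_newick("((a_1:0.5,b_1:0.04):0.1,(c_1:0.1,d_1:0.1):0.1);")
  out2 <- trim_spurious_tips(ht2)
  expect_setequal(out2$tree$tip.label, c("b_1", "c_1", "d_1"))

  # fixed point: all short branches untouched, and idempotent
  ht3 <- ht_from_newick("((a_1:0.1,b_1:0.1):0.1,(c_1:0.1,d_1:0.1):0.1);")
  out3 <- trim_spurious_tips(ht3)
  expect_equal(out3$tree$tip.label, ht3$tree$tip.label)
  again <- trim_spurious_tips(out3)
  expect_equal(again$tree$tip.label, out3$tree$tip.label)
})

test_that("same-species repeats collapse to the best-supported contig", {
  # sister tips: keep the one with more aligned characters
  ht <- ht_from_newick("((spA_c1:0.1,spA_c2:0.1):0.1,spB_c1:0.1);",
                       species = c("spA", "spA", "spB"),
                       chars = c(100L, 80L, 90L))
  out <- collapse_species_repeats(ht)
  expect_setequal(out$tree$tip.label, c("spA_c1", "spB_c1"))

  # paraphyletic grade spA_c1,(spA_c2,spB): keep higher-char spA_c2
  ht2 <- ht_from_newick("(spA_c1:0.1,(spA_c2:0.1,spB_c1:0.1):0.1);",
                        species = c("spA", "spA", "spB"),
                        chars = c(50L, 90L, 70L))
  out2 <- collapse_species_repeats(ht2)
  expect_setequal(out2$tree$tip.label, c("spA_c2", "spB_c1"))

  # all distinct species: identity
  ht3 <- ht_from_newick("((a_1:0.1,b_1:0.1):0.1,c_1:0.1);")
  expect_equal(collapse_species_repeats(ht3)$tree$tip.label,
               ht3$tree$tip.label)
})

test_that("deep paralog stems are cut into subtrees", {
  # one internal branch of 0.6 in a 6-tip tree: two pieces
  ht <- ht_from_newick(paste0("(((a_1:.1,b_1:.1):0.6,(c_1:.1,d_1:.1):.1):.1,",
                              "(e_1:.1,f_1:.1):.1);"))
  pieces <- cut_deep_paralogs(ht)
  expect_length(pieces, 2L)
  sizes <- sort(vapply(pieces, function(p) ape::Ntip(p$tree), integer(1)))
  expect_equal(sizes, c(2L, 4L))

  # boundary: 0.5 is kept (strict >), no cut
  ht2 <- ht_from_newick("((a_1:.1,b_1:.1):0.5,(c_1:.1,d_1:.1):.1);")
  expect_length(cut_deep_paralogs(ht2), 1L)

  # chained cuts match the exhaustive edge-removal partition
  txt <- paste0("(((a_1:.1,b_1:.1):0.7,((c_1:.1,d_1:.1):0.9,",
                "(e_1:.1,f_1:.1):.1):.1):.1,((g_1:.1,h_1:.1):.1,",
                "(i_1:.1,j_1:.1):.1):.1);")
  ht3 <- ht_from_newick(txt)
  pieces3 <- cut_deep_paralogs(ht3)
  got <- lapply(pieces3, function(p) sort(p$tree$tip.label))
  # oracle: deleting the >0.5 edges partitions tips into the components
  # {a,b}, {c,d}, and the rest
  want <- list(c("a_1", "b_1"), c("c_1", "d_1"),
               c("e_1", "f_1", "g_1", "h_1", "i_1", "j_1"))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
})

test_that("RT pruning resolves duplications toward more ingroup species", {
  # no duplication: all ingroup species in a single set
  ht <- ht_from_newick(
    "((((a_1:.1,b_1:.1):.1,(c_1:.1,d_1:.1):.1):.1,og1_1:.3):.1,og2_1:.4);")
  sets <- prune_rt_orthologs(ht, c("og1", "og2"))
  expect_length(sets, 1L)
  expect_setequal(names(sets[[1]]), c("a", "b", "c", "d"))

  # one duplication, 5 vs 3 species: the 5-species side is returned
  five <- "(a_1:.1,(b_1:.1,(c_1:.1,(d_1:.1,e_1:.1):.1):.1):.1)"
  three <- "(a_2:.1,(b_2:.1,c_2:.1):.1)"
  txt <- paste0("((", five, ":.1,", three, ":.1):.1,og1_1:.3);")
  ht2 <- ht_from_newick(txt)
  sets2 <- prune_rt_orthologs(ht2, "og1")
  expect_length(sets2, 1L)
  expect_setequal(names(sets2[[1]]), c("a", "b", "c", "d", "e"))
  expect_true(all(grepl("_1$", sets2[[1]])))

  # equal species counts: tie broken by summed aligned characters
  left <- "(a_1:.1,b_1:.1)"
  right <- "(a_2:.1,b_2:.1)"
  ht3 <- ht_from_newick(paste0("((", left, ":.1,", right, ":.1):.1,og1_1:.3);"),
                        chars = c(200L, 200L, 150L, 150L, 100L))
  sets3 <- prune_rt_orthologs(ht3, "og1")
  expect_equal(unname(sets3[[1]][c("a", "b")]), c("a_1", "b_1"))

  expect_error(prune_rt_orthologs(ht3, "nope"), "no outgroup")
})

test_that("RT pruning output is single-copy on simulated gene families", {
  st <- simulate_tree(8, seed = 2)$tree
  for (s in 1:300) {
    g <- simulate_gene_family(st, dup_rate = 1, loss_rate = 0.2,
                              spurious_tip_rate = 0.2, seed = s)
    g2 <- collapse_species_repeats(trim_spurious_tips(g))
    if (is.null(g2)) next
    sets <- prune_rt_orthologs(g2, attr(g, "truth")$outgroup_species)
    for (x in sets) {
      expect_false(anyDuplicated(names(x)) > 0)
      expect_false(any(names(x) %in% attr(g, "truth")$outgroup_species))
    }
  }
  # congruent family (no duplications): pruning returns all species
  g0 <- simulate_gene_family(st, dup_rate = 0, seed = 1)
  g0s <- prune_rt_orthologs(g0, attr(g0, "truth")$outgroup_species)
  expect_length(g0s, 1L)
  expect_setequal(names(g0s[[1]]), st$tip.label)
})

test_that("ortholog species filter enforces counts, classes and sisters", {
  cl <- data.frame(species = sprintf("sp%02d", 1:8),
                   class = rep(c("endo", "ecto"), each = 4))
  expect_false(filter_ortholog_taxa(sprintf("sp%02d", 1:4), cl))      # 4 < 5
  expect_true(filter_ortholog_taxa(c("sp01", "sp02", "sp05", "sp06",
                                     "sp07"), cl))
  expect_false(filter_ortholog_taxa(c("sp01", "sp05", "sp06", "sp07",
                                      "sp08"), cl))                   # 1 endo
  expect_false(filter_ortholog_taxa(c("sp01", "sp02", "sp05", "sp06",
                                      "sp07"), cl,
                                    required_sisters = "sp08"))
  expect_error(filter_ortholog_taxa(c("sp01", "sp02", "mystery", "sp05",
                                      "sp06"), cl), "unclassified")
})

test_that("taxon pruning preserves path lengths and induced topology", {
  base <- parse_newick("((A:1,B:1):1,C:2);")
  pr <- prune_taxa(base, c("A", "C"))
  expect_equal(tip_distance(pr, "A", "C"), 4)
  expect_equal(sort(pr$tip.label), c("A", "C"))

  expect_equal(sort(prune_taxa(base, base$tip.label)$tip.label),
               sort(base$tip.label))
  expect_error(prune_taxa(base, c("A", "Z")), "Z")

  set.seed(11)
  big <- ape::rtree(12)
  d_full <- ape::cophenetic.phylo(big)
  for (r in 1:10) {
    keep <- sample(big$tip.label, 6)
    sub <- prune_taxa(big, keep)
    d_sub <- ape::cophenetic.phylo(sub)[keep, keep]
    expect_equal(d_sub, d_full[keep, keep], tolerance = 1e-10)
  }
})
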