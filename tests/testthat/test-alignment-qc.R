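test_that("concordance scores match explicit residue-pair enumeration", {
  prot <- as_alignment_matrix(c(a = "MKLF", b = "MKLF", c = "MKLF",
                                d = "MKLF"))
  # identical alternatives: everything scores 9
  id <- concordance_filter(prot, list(prot, prot))
  expect_equal(id$scores, rep(9L, 4))
  expect_equal(id$kept, 1:4)

  # shift one residue of one sequence in one alternative
  alt <- as_alignment_matrix(c(a = "MKL-F", b = "MKLF-", c = "MKLF-",
                               d = "MKLF-"))
  cf <- concordance_filter(prot, list(alt))
  expect_lt(cf$scores[4], 9L)
  expect_equal(cf$scores[1:3], rep(9L, 3))
  expect_equal(cf$kept, 1:3)

  # pair-counting oracle on a 4-sequence toy with two alternatives:
  # in alt2 sequences a,b put residue 3 elsewhere than c,d
  alt2 <- as_alignment_matrix(c(a = "MKL-F", b = "MKL-F", c = "MK-LF",
                                d = "MK-LF"))
  cf2 <- concordance_filter(prot, list(prot, alt2))
  # column 3: pairs {ab, ac, ad, bc, bd, cd} -> agree {ab, cd} = 2/6
  expect_equal(cf2$scores[3], as.integer(floor(9 * 2 / 6)))
  expect_equal(cf2$scores[c(1, 2, 4)], rep(9L, 3))
})

test_that("consistency filter agrees with a brute pairwise library", {
  # closely related (simulated) sequences: the pairwise library
  # reproduces the residue pairings, all columns score 9
  sim <- simulate_tree(4, shape = "pectinate", seed = 3)
  aln <- simulate_codon_alignment(sim$tree, n_codons = 15, seed = 3)$aln
  prot <- translate_alignment(aln)
  ts <- consistency_filter(prot)
  expect_equal(ts$scores, rep(9L, ncol(prot)))

  # a unique inserted residue is unsupported by every pairwise alignment
  prot2 <- as_alignment_matrix(c(a = "MKKKQFF", b = "MKKK-FF",
                                 c = "MKKK-FF", d = "MKKK-FF"))
  ts2 <- consistency_filter(prot2)
  expect_equal(ts2$scores[setdiff(1:7, 5)], rep(9L, 6))

  expect_warning(
    pass <- consistency_filter(as_alignment_matrix(c(a = "MK", b = "MK"))),
    "fewer than 3")
  expect_equal(pass$kept, 1:2)
})

test_that("codon occupancy boundaries are inclusive at half", {
  m <- random_codon_alignment(6, 4, seed = 5)
  gap <- function(m, rows, codon) { m[rows, (3 * codon - 2):(3 * codon)] <- "-"; m }
  m <- gap(m, 1:4, 2)  # absent in 4 of 6 -> removed
  m <- gap(m, 1:3, 3)  # absent in exactly half -> removed
  m <- gap(m, 1, 4)    # absent in 1 of 6 -> kept
  oc <- occupancy_filter_codons(m)
  expect_equal(oc$kept, c(1L, 4L))
  expect_equal(ncol(oc$alignment), 6L)
})

test_that("greedy gap-rich removal matches exhaustive subset search", {
  aln <- random_codon_alignment(5, 10, seed = 8)
  expect_equal(maxalign_select(aln)$removed, character(0))

  # one sequence 90% gaps among dense sequences is removed
  aln2 <- aln
  aln2[5, 1:27] <- "-"
  mx <- maxalign_select(aln2)
  expect_equal(mx$removed, "sp05")

  # exhaustive subset-area oracle: on two redundant gap-rich rows the
  # greedy result attains the best area over all row subsets
  area <- thermosel:::.alignment_area
  aln3 <- aln
  aln3[4, 1:15] <- "-"
  aln3[5, 10:27] <- "-"
  mx3 <- maxalign_select(aln3)
  best <- 0
  for (k in 2:5) {
    combs <- utils::combn(5, k)
    for (ci in seq_len(ncol(combs)))
      best <- max(best, area(aln3[combs[, ci], , drop = FALSE]))
  }
  expect_equal(area(mx3$alignment), best)
  expect_setequal(mx3$removed, c("sp04", "sp05"))
})

test_that("confidence masking and column trimming honour the boundaries", {
  aln <- random_codon_alignment(10, 10, seed = 9)
  prot <- translate_alignment(aln)
  conf <- matrix(1, nrow(prot), ncol(prot))
  conf[1, 2] <- 0.93          # boundary: masked
  conf[2, 3] <- 0.9301        # just above: kept
  cm <- confidence_mask_and_trim(prot, conf)
  expect_true(cm$masked[1, 2])
  expect_false(cm$masked[2, 3])

  # column with gaps in exactly 40% of sequences is removed
  prot2 <- prot
  prot2[1:4, 5] <- "-"
  conf2 <- matrix(1, nrow(prot2), ncol(prot2))
  cm2 <- confidence_mask_and_trim(prot2, conf2)
  expect_true(5 %in% cm2$gap_trimmed)
  expect_false(5 %in% cm2$kept)

  # all confident, no gaps: identity
  cm3 <- confidence_mask_and_trim(prot, matrix(1, nrow(prot), ncol(prot)))
  expect_equal(cm3$alignment, prot)
  expect_error(confidence_mask_and_trim(prot, conf[, 1:3]), "shape")
})

test_that("filter pipelines are the identity on clean alignments", {
  sim <- simulate_tree(8, seed = 1)
  a <- simulate_codon_alignment(sim$tree, n_codons = 60, seed = 3)
  prot <- translate_alignment(a$aln)
  alts <- make_alternative_alignments(prot, k = 3, corruption_frac = 0,
                                      seed = 2)
  pa <- run_filter_pipeline(a$aln, "A", alternatives = alts$alternatives,
                            classes = sim$classes)
  expect_equal(pa$status, "passed")
  expect_equal(pa$alignment, a$aln)
  pb <- run_filter_pipeline(a$aln, "B", confidences = alts$confidences,
                            classes = sim$classes)
  expect_equal(pb$status, "passed")
  expect_equal(pb$alignment, a$aln)
})

test_that("corrupted columns are removed and low-coverage genes rejected", {
  sim <- simulate_tree(8, seed = 1)
  a <- simulate_codon_alignment(sim$tree, n_codons = 80, seed = 4)
  prot <- translate_alignment(a$aln)
  alts <- make_alternative_alignments(prot, k = 3, corruption_frac = 0.2,
                                      seed = 5)
  pa <- run_filter_pipeline(a$aln, "A", alternatives = alts$alternatives,
                            classes = sim$classes)
  expect_equal(pa$status, "passed")
  kept_cols <- setdiff(seq_len(ncol(prot)),
                       union(pa$report$concordance_removed,
                             union(pa$report$consistency_removed,
                                   pa$report$occupancy_removed)))
  expect_length(intersect(kept_cols, alts$corrupted), 0L)

  # a gene whose maxalign removal leaves too few endotherms is rejected
  aln2 <- a$aln
  endo <- sim$endo_species
  aln2[endo[1], 31:240] <- "-"   # one endotherm nearly all gaps
  keep5 <- c(endo[1:2], setdiff(rownames(aln2), endo)[1:3])
  aln2 <- aln2[keep5, ]
  prot2 <- translate_alignment(aln2)
  alts2 <- make_alternative_alignments(prot2, k = 2, corruption_frac = 0,
                                       seed = 6)
  pb <- run_filter_pipeline(aln2, "B", confidences = alts2$confidences,
                            classes = sim$classes)
  expect_equal(pb$status, "rejected")
  expect_false(pb$report$recheck_passed)
  expect_true(endo[1] %in% pb$report$sequences_removed)
})

test_that("filters only remove, never alter retained residues", {
  sim <- simulate_tree(8, seed = 2)
  a <- simulate_codon_alignment(sim$tree, n_codons = 50, seed = 11)
  prot <- translate_alignment(a$aln)
  alts <- make_alternative_alignments(prot, k = 3, corruption_frac = 0.15,
                                      seed = 12)
  pa <- run_filter_pipeline(a$aln, "A", alternatives = alts$alternatives,
                            classes = sim$classes)
  out <- pa$alignment
  expect_equal(ncol(out) %% 3, 0)
  # every output column exists identically in the input
  in_str <- apply(a$aln, 2, paste, collapse = "")
  out_str <- apply(out, 2, paste, collapse = "")
  expect_true(all(out_str %in% in_str))
  # translates without internal stops
  expect_silent(translate_alignment(out))
})
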