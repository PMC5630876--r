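#!/usr/bin/env Rscript
# Ancestral reconstruction for the genes called under selection (or,
# failing any call, the first scanned gene): marginal amino-acid
# posteriors on the species tree, then the substitutions separating the
# endotherm ancestor from its closest ectotherm ancestor.

library(thermosel)

study_dir <- file.path("results", "study")
tree <- parse_newick(readLines(file.path(study_dir, "species_tree.nwk")))
classes <- read.delim(file.path(study_dir, "species_classes.tsv"))
endo <- classes$species[classes$class == "endo"]
summary <- read.delim(file.path("results", "scan_summary.tsv"))

targets <- summary$gene[summary$status == "selected"]
if (!length(targets)) targets <- summary$gene[1]

all_subs <- list()
for (g in targets) {
  aln <- as_alignment_matrix(
    read_fasta(file.path("results", "filtered", "A", paste0(g, ".fasta"))))
  prot <- translate_alignment(aln)
  asr <- marginal_asr(prot, tree)
  node_endo <- ape::getMRCA(tree, endo)
  # closest ectotherm ancestor: the parent of the endothermic stem
  node_ecto <- tree$edge[tree$edge[, 2] == node_endo, 1]
  d <- ancestral_diffs(asr, node_endo, node_ecto)
  if (nrow(d)) d$gene <- g
  all_subs[[g]] <- d
}
subs <- do.call(rbind, all_subs)
write.table(subs, file.path("results", "ancestral_substitutions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Reconstructed ancestors for %d gene(s): %s.\n",
            length(targets), paste(targets, collapse = ", ")),
    sprintf("%d amino-acid substitutions on the endothermic stem ",
            if (is.null(subs)) 0L else nrow(subs)),
    "(endotherm ancestor vs closest ectotherm ancestor).\n",
    "Details in results/ancestral_substitutions.tsv.\n")
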