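---
title: "Methods: branch-site scans for convergent selection in endothermic fishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-site scans for convergent selection in endothermic fishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Tunas and lamnid sharks have evolved regional endothermy independently,
separated by roughly 400 million years. A natural genomic question is
whether the same metabolic genes experienced positive selection on the
stem branch of each endothermic clade. `thermosel` implements the full
desk-side machinery for that question: turning homolog gene trees into
single-copy ortholog sets, filtering alignments stringently enough for
branch-site inference, running the branch-site likelihood-ratio test on
a designated foreground branch with a strict multi-test consensus, and
reconstructing the ancestral protein changes on the endothermic stems.
Because transcriptome-scale assemblies are not desk-scale inputs, the package pairs every step with a synthetic-data generator
that produces codon alignments with *known* truth, so each claim the
pipeline makes is testable.

## The codon model

Codon substitution follows a reversible Markov generator over the 61
sense codons. For codons $i \ne j$:

$$q_{ij} = \begin{cases}
0 & \text{more than one position differs}\\
\pi_j & \text{synonymous transversion}\\
\kappa \pi_j & \text{synonymous transition}\\
\omega \pi_j & \text{non-synonymous transversion}\\
\omega \kappa \pi_j & \text{non-synonymous transition,}
\end{cases}$$

where $\kappa$ is the transition/transversion rate ratio, $\pi$ the
stationary codon frequencies, and $\omega = d_N/d_S$ the ratio of
non-synonymous to synonymous substitution rates per site. The generator
is scaled so branch lengths are expected substitutions per codon.
Likelihoods are computed by Felsenstein pruning over the 61 states
(compiled code), with transition matrices obtained from the spectral
decomposition of the symmetrised generator; gap and ambiguous codons
contribute a partial likelihood of one over all states.

### Branch-site model A and its null

The branch-site test partitions sites into four classes. With
proportions $p_0, p_1$ and $p_{2a} = (1-p_0-p_1)\,p_0/(p_0+p_1)$,
$p_{2b} = (1-p_0-p_1)\,p_1/(p_0+p_1)$:

| class | background $\omega$ | foreground $\omega$ |
|-------|--------------------|---------------------|
| 0     | $\omega_0 \in (0,1)$ | $\omega_0$ |
| 1     | 1                  | 1 |
| 2a    | $\omega_0$         | $\omega_2 \ge 1$ |
| 2b    | 1                  | $\omega_2 \ge 1$ |

The foreground branch is the stem of the endothermic clade
(`mark_foreground()` places it above the MRCA of the surviving
endothermic tips; non-monophyletic endotherms are an error and the gene
is excluded). The null model fixes $\omega_2 = 1$. The test statistic
$2\Delta\ell$ (clamped at zero) is referred to $\chi^2_1$ — deliberately
not the 50:50 boundary mixture — which
makes the test conservative near the boundary. Mixture generators are
scaled by the expected background substitution rate so that branch
lengths keep their interpretation under both models.

## The per-gene testing scheme

Per gene and per alignment variant: taxa absent from the alignment are
pruned from the base tree (path lengths preserved), branch lengths are
estimated once under M0 and held fixed for the branch-site fits (a
deliberate stability/runtime choice; `optimize_blen` re-enables
per-model estimation), and the LRT is run at the three starting
$\omega$ values 0.5, 1, 1.5. With two alignment pipelines this yields
six tests per gene. All six p-values are Benjamini–Hochberg adjusted
*within the gene* — an unusual scope, kept deliberately because the
six tests probe one hypothesis about one gene — and the gene is called under selection only when all
six adjusted p-values fall below $\alpha = 0.05$. Genes with fewer than
six completed tests (a pipeline rejected the gene) are "untested", not
"not selected". Called genes are screened for synonymous saturation:
overall $d_S > 1$ under the one-ratio model, or $d_S > 1$ on the
foreground branch under the free-ratio model. Per-branch $d_N$ and
$d_S$ come from partitioning the fitted generator's substitution flow
into synonymous and non-synonymous parts, normalised by the
model-implied fractions of synonymous and non-synonymous sites.

### Numerical choices

Optimisation is bounded quasi-Newton (L-BFGS-B) on transformed
parameters: $\log\kappa$, $\log t_e$, logit $\omega_0$,
$\log(\omega_2 - 1)$, and additive log-ratios of $(p_0, p_1)$ against
$p_{2} = 1 - p_0 - p_1$. Convergence tolerance corresponds to
$|\Delta\ell| \approx 10^{-7}$. The branch-site surface has a
well-known local optimum at $\omega_2 = 1$ with the selected-class mass
collapsed; after convergence the fitter probes $\omega_2 \in \{2,4,8\}$
with the class-2 proportion reopened to 0.1 and restarts when a probe
improves the likelihood. The starting $\omega$ seeds both $\omega_0$
(clamped below 1) and $\omega_2$ (clamped above 1). Codon frequencies
default to F3x4 with a $10^{-10}$ floor before renormalisation (F1x4,
F61 and uniform are options). Negative LRT statistics are clamped to
zero. Trees are unrooted before fitting; the reversible model makes the
likelihood root-invariant, and unrooting removes the unidentifiable
split of the root edge.

## Ortholog inference from gene trees

Homolog trees are cleaned by four rules, each threshold a strict
(`>`) boundary: terminal branches
longer than 2, or more than 10 times their sister branch, are trimmed
iteratively (longest first, to a fixed point); monophyletic or
paraphyletic same-species tip groups collapse to the tip with the most
aligned characters (paraphyly operationalised as: the other tips inside
the group's MRCA clade form at most one clade); internal branches
longer than 0.5 are cut as deep paralog stems; and rooted-ingroup
("RT") resolution walks from the outgroup root, at each duplication
node (child species sets overlap) descending into the child with more
ingroup species, ties broken by summed aligned characters, emitting
maximal single-copy subtrees. Genes pass to analysis only with at least
five species, two endotherms, two ectotherms, and every required sister
taxon.

## Alignment filtering

Alignment error is the dominant source of branch-site false positives,
so two independent pipelines gate every gene. The external aligners
themselves are out of scope; the filters consume alternative
alignments (or residue confidences) supplied by the caller or the
generator.

* **Pipeline A.** A primary column scores
  $\lfloor 9 f \rfloor$ where $f$ is the fraction of its residue pairs
  co-aligned in *every* alternative alignment; only total concordance
  (9) survives. Then a transitive-consistency pass builds global
  pairwise alignments of all ungapped sequence pairs (match 2,
  mismatch −1, gap open 4, extend 1 — configurable) and keeps columns
  whose residue pairings are fully library-supported; lone residues
  have no support and score 0.
* **Pipeline B.** Residues with confidence $\le 0.93$ are masked to
  gaps (inclusive boundary, the recommended default), then columns with
  $\ge 40\%$ gaps, then columns with mean pairwise identity $< 0.001$
  are trimmed.

Both pipelines then drop codon columns absent in at least half of the
species (inclusive) and run a greedy area-maximising removal of
gap-rich sequences (area = gap-free columns × retained rows). If
sequences were removed, the species criteria are re-checked: failing
genes are rejected, passing genes re-filtered without the removed
rows. Filters only ever delete columns/rows (or mask residues in B);
retained residues are never altered, so the back-translation step is a
pure column selection on the original codon alignment.

## 4-fold degenerate supermatrix

For phylogeny inference to be independent of protein-level selection,
only third positions of codon columns where *every* non-gap codon is
four-fold degenerate *and* shares the same first two nucleotides are
extracted — under that column-wide criterion no substitution at the
site can alter any amino acid (a per-sequence criterion is available
behind a flag). Gene matrices are concatenated with species absent from
a gene gap-filled, columns with fewer than half the species present
trimmed (strict `<`: exactly half is kept, complementing the codon
filter's inclusive rule), partitions recomputed, and per-species gap
fractions reported.

## Ancestral reconstruction

Marginal empirical-Bayes reconstruction on the fixed tree: a down-pass
computes conditionals, an up-pass the outside partials, their product
the per-node, per-column posterior over the 20 amino acids. The default
model is Poisson with equal frequencies; exchangeabilities and
frequencies are pluggable.
Substitutions between the endotherm ancestor and its closest ectotherm
ancestor are listed with reference-protein coordinates when a mapping
is supplied; columns with no data below either node are excluded.

## What the generator emulates — and what it does not

`simulate_tree()` builds an 8-taxon tree (by default) whose
endothermic clade is a two-tip internal clade: background branches
0.08 expected substitutions per codon, endothermic stem 0.25,
reflecting that the endothermic lineages diverged deeply from their
ectothermic sisters. `simulate_codon_alignment()` draws a site class
per codon i.i.d. (the mixture model's own exchangeability assumption)
with defaults $p_0 = 0.45$, $p_1 = 0.40$ (15% of sites available to
selection), $\omega_0 = 0.15$, $\kappa = 2.5$, uniform codon
frequencies for analytic transparency (an F3x4-style option exists),
and evolves sites by sampling from exact transition matrices — no
Gillespie discretisation error at any branch length. Gene families add
duplications, losses, deep paralog stems and spurious long tips on top
of the species tree; alignment corruption splits chosen columns into
two half-occupied columns per alternative copy and assigns corrupted
residues confidences below the masking threshold. All generators are
bit-reproducible under a fixed seed and never emit internal stop
codons.

What passing tests on these data do *not* show: robustness to real
assembly artifacts, splice-variant chimeras, base-composition
heterogeneity across lineages, indel-rich alignments, or model
misspecification (the generator and the fitter share the codon model
family by construction). The synthetic study demonstrates internal
correctness and calibration, not transcriptome-scale operating
characteristics.

## Problem sizes and expectations at desk scale

The validation suite uses sizes chosen for a single CPU: LRT
calibration on 200 null genes of 8 taxa × 300 codons (one test per
gene, primary alignment, start 1.5 — the full six-test consensus is
exercised by a separate 30-gene end-to-end study at 120 codons);
parameter recovery over 50 replicates per $\omega$ at 200 codons; RT
single-copy checks over 300 simulated families. Under $\chi^2_1$ the
null rejection rate sits well below the nominal 5%, which is expected
and conservative. Detection power for $\omega_2 = 4$ at 15% selected
sites on a 0.25-substitution stem is intrinsically moderate at 300
codons — the branch-site test at these settings is known to trade
power for false-positive control, and the package reports whatever the
acceptance script measures rather than a target. The same arithmetic
shapes the end-to-end study: with only a few genes called per 30-gene
study, the false-discovery *ratio* is count-noise dominated (a single
false call among three calls reads as 0.33 even when the expected FDR
is well under 0.2), so the test suite asserts count-level properties —
false calls rare among the nulls, adjusted p-values separating the
truth classes — and the acceptance script reports the study's
TP/FP/FDR as computed quantities.

## Known limitations

No site-level empirical-Bayes identification of selected sites; no
codon models beyond M0, free-ratio and branch-site A/null; BH scope is
per gene (six tests), not genome-wide, by design fidelity; branch
lengths are M0 plug-ins for the branch-site fits unless re-optimised;
the ORF extractor follows the ATG-initiated convention of transcript
ORF callers (a forward-strand-only flag exists for stranded
libraries).
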