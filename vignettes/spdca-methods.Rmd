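---
title: "Predicting heterodimer interfaces from paired ortholog alignments"
author: "spdca maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting heterodimer interfaces from paired ortholog alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdca)
```

## The problem

Transient protein--protein interactions, such as G-protein-coupled receptor
(GPCR) heterodimers, are hard to resolve structurally: the complexes are
membrane-embedded, short-lived, and rarely crystallise.  Yet the residues
that carry most of the binding energy -- the interface *hot-spots* -- leave
a statistical footprint in evolution: when two proteins interact across
many species, substitutions at interface positions of one protein tend to
be compensated at the contacting positions of the other.

`spdca` implements a two-step strategy for locating such hot-spots:

1. **Inter-protein direct coupling analysis.**  Orthologs of the two
   proteins are concatenated species-by-species into a paired alignment
   (cMSA), and a global Potts model is inferred by pseudo-likelihood
   maximisation (plmDCA).  The Frobenius norms of the inter-protein
   coupling blocks give an evolutionary score \(P_{ij}\) for every residue
   pair \((i, j)\) of the two proteins.
2. **Structure-prior Gaussian convolution.**  Because interfaces are
   peptides, not isolated residues, the raw coupling map is convolved
   with a separable Gaussian kernel localised by each protein's topology
   annotation:
   \[
   Q_{ij} \;=\; \sum_{\alpha = i - l}^{i + l}\;\sum_{\beta = j - l}^{j + l}
   P'_{\alpha\beta}\,
   e^{-\left(a(\alpha - i)^2 + b(\beta - j)^2\right)},
   \]
   where \(P'\) is \(P\) with per-column prior masks applied, \(l\) is the
   half-window (interpreted as the average length of the peptides involved
   in the interaction), and \(a, b\) are normalised kernel variances.
   Contiguous blocks of high \(Q\) are reported as rectangular candidate
   interfaces labelled with the topology domains they fall in.

The per-column windowed sums make isolated noisy couplings fade and
peptide-scale blocks of moderate couplings stand out, which is the entire
point of the convolution step.

## Reading of the convolution formula

Two details of the formula are fixed here as package contracts:

* The summand uses \(P'_{\alpha\beta}\), i.e. the coupling value at the
  *window* position.  Reading the summand at the fixed centre \((i, j)\)
  would make \(Q\) a constant multiple of \(P\) away from the boundaries
  and no convolution at all; only the convolution reading is consistent
  with a Gaussian-kernel smoothing step.
* Window indices outside the matrix contribute zero (boundary clipping).
  Proteins are not periodic, so wrap-around would couple the N- and
  C-termini artificially.

`l` is used as the half-window of the sums, i.e. a window of \(2l + 1\)
columns.  Descriptions of the method sometimes quote \(l\) as the *total*
number of interacting amino acids; the summation limits are the
operational definition used here, and `priorParams(l = ...)` documents
this.

The implementation computes \(Q = K_A P' K_B\) with banded symmetric
kernel matrices, which is algebraically identical to the quadruple loop;
the test-suite keeps an independent brute-force quadruple-loop oracle and
a cumulative-sum boxcar oracle for the \(a = b = 0\) limit.

## How structure enters

The printed formula contains only \(a\), \(b\), \(l\) and the window
indices; how the secondary-structure information enters is left open by
the method's description.  The package takes the most conservative
reading: the prior enters as **multiplicative per-column masks** on
\(P\) before convolution (`buildPriorMask`), plus the use of topology
segments when labelling hot-spots.  The default mask keeps the
non-transmembrane categories (N-terminal, C-terminal, ICL, ECL), because
coevolutionary inference performs poorly inside membrane-embedded
helices, whose conservation is dominated by the lipid environment.  With
all-ones masks the unmasked formula is recovered exactly, which is also a
regression test.  An optional real-valued per-column weight file can
express buried/exposed weighting; no default source for it is assumed.

## Model fitting choices

plmDCA is fitted per column as a weighted multinomial logistic regression
(asymmetric plmDCA), with:

* sequence reweighting at identity threshold `theta = 0.8` (weight
  \(1/n_r\) where \(n_r\) counts rows within 80% identity of row *r*);
* L2 penalties `regFields = 0.01` and `regCouplings = 0.01 (L - 1)`,
  published plmDCA conventions;
* L-BFGS-B with analytic gradients (compiled), projected-gradient
  tolerance \(10^{-5}\), iteration cap 200.  The fit is deterministic
  given the inputs; reaching the iteration cap at the stated tolerance is
  accepted and recorded in `model@meta$convergence`;
* per-pair symmetrisation by averaging the two per-column estimates,
  then zero-sum gauge fixing;
* scores are Frobenius norms over **non-gap states** (the gap is a full
  Potts state during fitting but contributes no score; gap-rich column
  pairs would otherwise dominate interface maps);
* the average product correction (APC) is applied by default, with
  negative corrected scores clipped to zero.  APC is standard
  false-positive control for DCA even when a method description omits it;
  `couplingScores(model, apc = FALSE)` reproduces the literal raw-score
  path, and both variants are recorded in the score TSV.

A mean-field DCA fitter (inverse regularised covariance of one-hot
encodings) is included as an internal cross-check oracle only.

The 70--90% ortholog identity filter is applied to *aligned* rows
(identity over mutually ungapped columns); whether the filter precedes or
follows alignment is not specified by the method description, and the
aligned-row reading is the reproducible one given that this package
consumes alignments rather than producing them.  "Similarity" is
implemented as fractional identity, the standard parameter-free choice.

## The synthetic validation studies

No deposited alignment reproduces the published receptor analyses
bit-for-bit (ortholog sets are database-version-dependent), so the
package validates itself on synthetic data whose ground truth is known.
`makePlantedModel` draws a two-block Potts model -- fields i.i.d. normal
with standard deviation 0.5, couplings zero except at planted
inter-protein pairs where \(J(s, t) = \text{strength} \cdot [s = t]\)
(identity-favouring, so mutual-information oracles are direct) -- and
`sampleMSA` samples from it by vectorised parallel Gibbs chains (one
chain per row by default, `chains < m` switches to thinned recording).
Parallel chains mix trivially for these sparsely coupled models and make
the sampler fast in R; an exhaustive 2-column test checks the sampled
distribution against the exact Boltzmann law.

The two canonical studies fix the conditions once:

* `plantedCouplingStudy`: 30 + 30 columns, q = 8, five planted pairs of
  strength 2.0, M = 2000 sequences, theta = 0.8, APC on; reports
  precision@5 of the inter-protein ranking.
* `plantedInterfaceStudy`: one 7-residue interacting peptide pair
  (matched diagonal couplings, strength 2.0) in the same geometry;
  convolution with half-window `l = 3` (a 7-column window matching the
  planted peptide length) and `a = b = 0.05` (kernel standard deviation
  \(1/\sqrt{2a} \approx 3\) residues, again the peptide scale);
  hot-spots from the top 5% of cells (the planted rectangle is 49 of 900
  cells, i.e. about 5%) with merge separation 3.  Reports the cell-set
  Jaccard overlap between the top rectangle and the planted region.

These sizes keep a full five-to-ten-replicate study inside a few minutes
on one CPU while leaving the inference well-conditioned (Meff near 2000).
The generator emulates planted direct couplings only: it has no
phylogenetic correlation between rows, no indels, and no spatial
correlation of the background.  Passing these studies therefore shows the
inference and convolution machinery recovers what it is designed to
recover; it does not certify performance on real ortholog sets, where
phylogeny inflates couplings and the identity filter and reweighting do
real work.

The published receptor settings `a = b = 0.001, l = 21` remain the
package defaults (`spdcaConfig()`, `priorParams()`); they correspond to
full-length receptors (~400 residues), not to the 30-column synthetic
proteins.  No re-optimisation of these values is attempted, since the
original optimisation procedure is not described.

## Hot-spot extraction

Cells strictly above the \((1 - \text{topFraction})\) quantile of
\(Q\) are grouped into 8-connected components, bounding boxes closer than
`minSeparation` on both axes are merged, and rectangles are ranked by
peak score.  Defaults `topFraction = 0.01`, `minSeparation = 10` yield a
handful of rectangles on receptor-sized maps; both are configuration
parameters, as no extraction threshold is part of the method's published
description.  A constant map yields no hot-spot (with a warning) rather
than an arbitrary one.  Rectangles are labelled per axis by the segment
covering the majority of their columns, ties going to the lower-start
segment.

## Physicochemical profiles

Interface peptides of receptor heterodimers tend to differ from the rest
of the sequence in charge, hydrophobicity and helix propensity.
`propertyProfile` computes sliding-window means (default window 9,
odd-width, clipped at the ends, gap-aware) over canonical scales shipped
with the package: Kyte--Doolittle hydrophobicity, Hopp--Woods
hydrophilicity, Grantham polarity, integer side-chain charge at pH 7,
Charton polarizability, residue side-chain volumes, Chou--Fasman helix
propensity and theoretical maximum SASA.  The original figures do not
name their scales or window; these canonical choices are user-replaceable
(`propertyScales(path)`), and the windowing -- not the scale -- is the
tested contract.  A "secondary-structure similarity" profile has no
published formula and is represented by the helix-propensity scale, with
this caveat.  `interfaceContrast` compares inside- vs outside-interface
columns with a rank-sum statistic and a seeded permutation p-value.

## Trajectory validation criteria

For coarse-grained simulations of predicted interface peptides the
package provides the analysis side only (simulation engines are out of
scope): multi-MODEL PDB parsing (via `bio3d`), Kabsch superposition RMSD
(SVD with reflection correction), radius of gyration, residue contact
maps under the rule *at least 2 heavy-atom pairs strictly closer than
5.0 Å* (`minAtomPairs = 1` reproduces the laxer "any two atoms"
reading), native-contact fractions, and the Debye--Hückel screened
electrostatic energy
\[
V = K_{Elec} \sum_{i<j} \frac{q_i q_j}{\epsilon_r\, r_{ij}}
    e^{-r_{ij}/l_D},
\qquad K_{Elec} = 332.24\ \mathrm{kcal\,mol^{-1}\,e^{-2}\,Å},
\]
with one bead per charged residue at the C\(\beta\) atom and integer
side-chain charges at pH 7 (His neutral; table configurable).  The Debye
length defaults to 10 Å and can be derived from temperature and ionic
strength (`debyeLength`), cross-checked in the tests against the aqueous
textbook value \(3.04/\sqrt{I}\) Å.  Published descriptions of the
simulation setup quote both 20 Å and 30 Å initial monomer separations;
this module analyses whatever coordinates it is given and makes no
separation assumption.

## Numerical and degenerate-input conventions

* Columns are 1-based and ranges inclusive, matching the `R291-S412`
  style of interface notation.
* Unknown alignment symbols are mapped to the gap and counted; all-gap
  rows have undefined identity and are dropped with a warning.
* Isoform ties (equal identity) keep the first record in file order.
* An empty identity-filter result is a warning, not an error.
* The fitted pseudo-likelihood, optimizer settings and convergence codes
  are retained in `model@meta`.
* All stochastic steps (Gibbs sampling, permutation tests, pipeline
  runs) consume explicit seeds; `runPipeline` reruns are byte-identical.

## Known limitations

* Phylogenetic structure in real ortholog sets is not modelled by the
  generator; identity-based reweighting mitigates but does not remove it.
* The convolution is reported unnormalised; only relative ranking of
  rectangles is meaningful, and no significance test for rectangles is
  provided (none is defined by the method).
* plmDCA at receptor scale (L ~ 900 paired columns) is computationally
  heavier than the synthetic studies shown here; the implementation is
  O(L^2 q^2) per optimizer step.
* Remote retrieval (blastp, UniProt) and alignment construction
  (clustal-Omega) are out of scope; the package consumes alignments.
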