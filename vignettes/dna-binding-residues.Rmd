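---
title: "Predicting DNA-binding residues from structure with distance-weighted patch features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-binding residues from structure with distance-weighted patch features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnabind)
```

## The problem

A small fraction of the residues on a DNA-binding protein's surface make
direct contact with DNA. Given only the protein's 3D structure (and a
sequence profile), we want to rank and classify its surface residues by how
likely they are to bind DNA. This is the structure-based residue-level
binding-site prediction problem of structural proteomics: the input is a
protein chain whose partner DNA is unknown; the output is a continuous
score and a binary call for every surface residue.

`pdnabind` implements a complete pipeline for this task: dataset
construction from protein–DNA complexes, feature encoding, classifier
training under heavy class imbalance, and evaluation with precision–recall
statistics.

## Dataset construction rules

Two geometric rules define the learning problem.

**Surface residues.** A residue is on the surface when its all-atom
solvent-accessible surface area (ASA) is at least 10 % (inclusive) of its
maximum in an extended ALA-X-ALA tripeptide. ASA is computed by a
Shrake–Rupley implementation written for this package (NACCESS-compatible
van der Waals radii: C 1.76, N 1.65, O 1.40, S 1.85 Å; probe 1.4 Å; 960
deterministic quasi-uniform sphere points per atom by default — the
point count is configurable, and doubling it moves residue areas by well
under 1 %). Reference maxima are the bundled Hubbard–Thornton all-atom
values (`max_asa_reference()`), user-overridable. ASA is always computed
on the isolated protein chain, never on the complex, so DNA-bound and
DNA-free forms of the same protein receive identical surface annotation.

**Binding residues.** In a protein–DNA complex, a surface residue is a
binding residue when any of its heavy atoms lies within 4.5 Å (inclusive)
of any heavy atom of a nucleic-acid residue. All other surface residues
are non-binding; buried residues are excluded from the problem entirely.

Five ASA components are tracked per residue (all-atom, main-chain,
side-chain, polar side-chain, non-polar side-chain). Following the
convention that side chains begin at the alpha carbon, CA is counted in
both the main-chain and side-chain components, so
`aa = mc + sc − ASA(CA)` while `ap + np = sc` exactly. Relative
accessibility is reported for the all-atom component, the only one any
downstream rule consumes; per-component maxima can be supplied through the
`max_asa_table` argument if needed.

## Feature encoding

Every surface residue is represented by 43 numbers built from its
*surface patch*: the residue itself plus its L−1 spatially nearest surface
residues of the same chain by Cα distance (default L = 25; ties broken by
chain position).

**Weighting factor.** Each patch member contributes according to a
distance-dependent weight w(d) with w(0) = 1 and strict monotone decrease.
Three schemes are shipped — reciprocal `1/(1+d)` (default), exponential
`exp(−d/σ)`, and linear `1 − d/d_max` (floored just above 0) — selectable
everywhere via the `scheme` argument. The reciprocal form is the default
because it is the simplest parameter-free function with the required
properties; all downstream code is scheme-agnostic, and the monotonicity
and normalization properties asserted by the tests hold for every scheme.

**RW-PSSM (40 values).** PSSM log-odds (20 per residue, read from
PSI-BLAST `-out_ascii_pssm` files; the package never runs PSI-BLAST) are
squashed into (0,1) by the logistic function. The first 20 features are
the central residue's scaled row; the last 20 are, per amino-acid type,
the weighted average of that column over the patch *neighbors* —
`F_a = Σ w_i M_{s(i),a} / Σ w_i`, central residue excluded since its raw
row already occupies the first block. A patch with no neighbors yields
zeros there, so the encoding is 40-dimensional for every L. The
alternative concatenated encoding (C-PSSM, `20·L` values, zero-padded) is
provided for comparison experiments; at L = 25 it is 500-dimensional.

**Interface propensity (IP) and WIP.** IP measures per-type enrichment
among binding vs non-binding surface residues:

`IP_a = log2( ((N_Ba + ψ)/(N_B + 20ψ)) / ((N_NBa + ψ)/(N_NB + 20ψ)) )`

with a symmetric pseudocount ψ = 1. This form is centered at zero
(equal frequencies give exactly 0), positive for interface-enriched
types, and exactly antisymmetric under label exchange. WIP is the
weighted patch average of IP over all patch members, central residue
included.

**Betweenness centrality (BC) and WBC.** The chain is recast as a contact
network: one vertex per Cα, an edge when two Cα atoms are within 8 Å
(inclusive). Normalized betweenness

`BC(v) = Σ_{s≠v≠t} σ_st(v)/σ_st / ((n−1)(n−2)/2)`

is computed by Brandes' accumulation over unordered pairs; unreachable
pairs contribute zero, and graphs with fewer than three vertices get all
zeros with a warning. Degree and closeness centrality (reachable-component
convention) are available for comparison. WBC is the weighted patch
average of BC, central residue included.

**ScASA.** The central residue's raw side-chain ASA (alpha carbon
included). Only the central value enters the final vector; its weighted
patch average is available separately.

Whether the central residue joins the WBC/WIP averages is configurable in
`patch_average()` by constructing patches accordingly; inclusion is the
default for consistency with the patch-average definition used throughout.

## Classifier and protocol

An RBF-kernel SVM (via `e1071`, i.e. LibSVM) consumes the 43-column
matrix. Binding residues are typically ~15 % of the surface, so training
uses *balanced undersampling*: all binding residues plus an equal-size
random sample of non-binding ones. Testing never removes non-binding
residues — every surface residue of a test chain is scored.

Feature columns are z-scored with training-set statistics (zero-variance
columns are centred and left unscaled, contributing nothing to the RBF
distance). Defaults C = 1, γ = 1/43: the hyperparameters are deliberately
the library defaults, since nothing in the protocol depends on tuning
them, and any grid search should be confined to training folds. The
decision score is oriented so that larger means more binding-like; the
default calling threshold is 0 and is overridable at prediction time.

Cross-validation is **chain-level**: chains, never residues, are dealt
into 5 folds (sizes differing by at most one). Per fold, the interface
propensity table is rebuilt from the four training folds only — the table
is label-derived, so anything else would leak test labels — then features
are assembled, negatives sampled, the SVM fitted, and the untouched
imbalanced test fold scored. Reported metrics are the unweighted mean over
folds (fold-level averaging; chain-level averaging for per-chain
comparisons is available from the stored per-residue scores — the two do
not coincide because F1 is not linear).

## Evaluation

Recall, precision and F1 use the 0/0 → 0 convention. The headline metric
is the area under the precision–recall curve, appropriate under heavy
imbalance where ROC curves are overly optimistic. The curve is built over
all distinct score thresholds (ties share a threshold) and interpolated
*non-linearly*: between achievable (TP, FP) points, FP is linear in TP, so
precision is evaluated at every unit of TP — the standard correction for
the fact that linear interpolation in PR space overstates the area. The
area integrates precision over recall from the smallest achievable recall
(one true positive), anchored below that recall at the first point's
precision; a perfect ranking scores exactly 1 and random scores
concentrate near the class prevalence.

Paired method comparisons use the two-sided Wilcoxon signed-rank test
(exact distribution up to 49 untied pairs, normal approximation with tie
and continuity correction otherwise; all-tied input returns p = 1 with a
warning).

The rank-based case study (`rank_case_study()`) evaluates a single scalar
— BC, WBC, IP or WIP — by taking the top k surface residues (k defaulting
to the number of true binding residues, which forces recall = precision)
with ties broken by chain position.

## Synthetic fixtures: what they emulate and what they do not

`fixture_spec()` / `generate_complex()` build desk-scale protein–DNA
complexes: an idealized α-helical chain (rise 1.5 Å, twist 100°, Cα radius
2.3 Å — giving realistic contact density at the 8 Å cutoff), backbone
N/CA/C/O plus radially pointing side-chain pseudo-atoms whose reach
follows residue size, and a DNA pseudo-chain of heavy P/C1' atoms placed a
controlled offset outside the side chains of a designated binding site.
The binding site occupies one helix face (+3/+4 steps); planted residues
are drawn from types with side-chain reach ≥ 2.5 Å so the DNA pseudo-atoms
clear neighboring backbones, and a configurable fraction (default 0.6) are
ARG/LYS, mimicking the basic-residue enrichment of real interfaces. With
an offset below 4.5 Å the generator *guarantees* (and verifies) that the
distance rule recovers exactly the planted set; impossible geometry is
rejected. Synthetic PSSMs are Normal(0, 1) log-odds with the R/K columns
shifted by a configurable effect size (default 1.5 SD) at binding
positions.

Generation is fully deterministic given the spec seed, to the point of
byte-identical PDB text.

The defaults — 20 chains of 60 residues, 8 planted binding residues
(prevalence ≈ 13 % of the surface), DNA offset 3 Å, effect size 1.5 SD —
are the conditions under which the package's end-to-end tests run; they
keep the full annotate → featurize → train → evaluate loop under a few
seconds per chain set on one CPU.

What passing these tests shows: the geometric rules, encodings, protocol
and metrics are implemented correctly and a planted signal of realistic
size is recovered (cross-validated PR-AUC far above prevalence, collapsing
to prevalence under label permutation). What it does not show: performance
on real proteins. Real structures have irregular topology, buried cores
(the fixtures' small helices are almost entirely surface), correlated
evolutionary signal, and contact networks whose betweenness actually
discriminates interfaces; the fixtures' uniform helices make BC/WBC nearly
uninformative by design, which is visible in the synthetic case-study
numbers. Validation on real protein–DNA complexes requires supplying PDB
files and PSI-BLAST profiles.

## Numerical choices and degenerate inputs

* Thresholds are inclusive: RSA ≥ 0.10 is surface, distance ≤ 4.5 Å is
  binding, Cα distance ≤ 8 Å is a contact.
* First alternate location kept per atom; insertion codes are part of the
  residue key; only the first MODEL of multi-model files is read; common
  modified residues (MSE, SEP, TPO, PTR, HYP, CSO, PCA) map to their
  parent type, anything else is classified `other` and excluded.
* Patch and top-k ties break by ascending chain position, making every
  ranking deterministic.
* Residues with no heavy atoms are dropped from ASA with a warning;
  unknown residue types get `NA` RSA (never surface) with a warning;
  chains without DNA label every surface residue non-binding with a
  warning.
* The fold count, seeds and sampled negatives are pure functions of the
  supplied seed; repeated runs are bit-identical.

## Limitations

* The ASA and centrality code is pure R; it is comfortable at desk scale
  (hundreds of residues) but not tuned for proteome-scale scans.
* The exact functional form of the distance weighting is a modelling
  choice; results at a fixed L are mildly sensitive to it, which is why it
  is configurable and why the tests only assert scheme-independent
  properties.
* No trained model for real proteins ships with the package: training
  data (complexes and profiles) must be provided by the user.
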