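# pdnabind

Prediction of DNA-binding residues on protein surfaces from 3D structure,
using a reduced set of distance-weighted surface-patch features and an
RBF-kernel support vector machine.

## The problem and the method

Only a small fraction of a DNA-binding protein's surface residues touch
DNA. Given a protein chain's structure (and a PSI-BLAST sequence profile),
`pdnabind` scores every surface residue for DNA binding. For whom: anyone
annotating newly solved structures, prioritising mutagenesis targets, or
studying protein–DNA recognition who needs a transparent, fully
re-trainable residue-level predictor rather than a black-box server.

The pipeline:

* **Surface annotation.** Shrake–Rupley accessible surface area
  (NACCESS-compatible radii, probe 1.4 Å); a residue is *surface* when its
  all-atom ASA ≥ 10 % of the extended ALA-X-ALA tripeptide maximum. In a
  complex, a surface residue is *binding* when any heavy atom is within
  4.5 Å of a DNA heavy atom.
* **Contact network.** Vertices are Cα atoms; edges connect pairs within
  8 Å. Betweenness centrality, normalized by the unordered pair count,

      BC(v) = [ Σ_{s≠v≠t} σ_st(v) / σ_st ] / [ (n−1)(n−2)/2 ]

* **Patch features.** Each surface residue's patch is itself plus its
  L−1 nearest surface residues (Cα distance, L = 25). A weight
  w(d) = 1/(1+d) (configurable) discounts distant members. The 43-value
  encoding is:
  * RW-PSSM (40): the central residue's 20 logistic-scaled PSSM values,
    plus per-column weighted averages over the patch neighbours,
    F_a = Σ w_i M_{s(i),a} / Σ w_i;
  * WIP (1): weighted patch average of the interface propensity
    IP_a = log2 of the pseudocounted binding/non-binding odds ratio of
    amino-acid type a;
  * WBC (1): weighted patch average of betweenness centrality;
  * ScASA (1): the central residue's side-chain ASA.
* **Classifier.** RBF-kernel SVM (e1071/LibSVM), trained on all binding
  residues plus an equal random sample of non-binding ones; evaluated by
  chain-level 5-fold cross-validation on untouched, imbalanced test folds
  with recall, precision, F1 and the area under the precision–recall curve
  (non-linear interpolation), plus Wilcoxon signed-rank comparisons and a
  top-k ranking case-study mode.

A synthetic protein–DNA fixture generator (idealized helices, planted
binding sites, signal-bearing PSSMs) makes the whole pipeline runnable and
testable without any downloads.

## Worked example

Generate six synthetic protein–DNA complexes with planted binding sites
(8 of 60 residues each, DNA 3 Å from the site, a 1.5 SD PSSM signal), and
cross-validate the full 43-feature model at chain level:

```r
library(pdnabind)

spec <- fixture_spec(n_chains = 6, seed = 42)
dataset <- synthetic_dataset(spec)
dataset
#> Synthetic dataset: 6 chains, 360 surface residues (48 binding)

cv <- dbp_cv(dataset, k = 3, seed = 7)
cv
#> 3-fold chain-level cross-validation (6 chains, seed 7)
#>  fold n_chains n_residues recall precision    f1 pr_auc
#>     1        2        120  0.938     0.500 0.652  0.816
#>     2        2        120  0.938     0.294 0.448  0.742
#>     3        2        120  0.562     0.692 0.621  0.679
#> mean over folds: recall 0.812  precision 0.495  F1 0.574  PR-AUC 0.745
```

What the numbers mean: binding residues are 13.3 % of this surface, so a
scoreless classifier would sit at PR-AUC ≈ 0.133; the cross-validated
PR-AUC of 0.745 shows the planted evolutionary/compositional signal is
recovered on held-out chains. Recall 0.81 / precision 0.50 are the
operating point at decision threshold 0 — typical behaviour for a model
trained on balanced samples and tested on imbalanced chains.

Single-structure use mirrors the same steps:

```r
s   <- read_structure("protein.pdb")
ann <- annotate_structure(s, chain_id = "A")        # ASA, RSA, labels
p   <- read_pssm("protein.pssm")
ch  <- prepare_chain(s, "A", p, L = 25)             # graph, patches, BC
x   <- assemble_features(ch, ip_table)              # 43 columns
fit <- dbp_fit(x_train, y_train)                    # RBF SVM
predict(fit, x, threshold = 0)                      # scores + calls
```

A thin command-line front end over these functions is installed at
`inst/scripts/pdnabind-cli.R` (subcommands `fixtures`, `annotate`,
`features`, `cv`, `casestudy`).

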