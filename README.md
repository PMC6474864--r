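# pdxsep

Bulk RNA-seq of a patient-derived xenograft (PDX) is a mixture: the engrafted
human tumor (graft) and the mouse stroma that replaces the human
microenvironment (host). Any comparison of a PDX against its donor tumor has
to separate those two signals first, and then distinguish genuine
engraftment-induced expression changes from artifacts of the separation
itself. `pdxsep` implements that whole workflow for people who run or
evaluate PDX transcriptome studies:

* a k-mer classifier that labels each read pair **graft / host / both /
  neither / ambiguous** from the two reference transcriptomes, retaining
  {graft, ambiguous, both} as the "human" portion;
* transcript-level pseudo-alignment quantification of the retained reads;
* paired (patient-blocked) negative-binomial differential expression with
  TMM normalization, a mean-CPM expression filter, and Benjamini–Hochberg
  FDR control;
* a **pipeline-sensitivity control**: the same non-xenografted donor samples
  are processed with and without the classification step, and any resulting
  "DEGs" are flagged as technical artifacts and excluded downstream, with
  their human–mouse conservation compared against the background;
* donor–PDX concordance: per-pair expression correlations, dendrogram
  pair alignment under average-linkage clustering on correlation distance,
  and per-gene Spearman association of PDX expression with passage number;
* gene-list overlap enrichment (hypergeometric and Fisher tests) against an
  independent stroma-vs-epithelium differential list;
* a synthetic dual-species cohort generator with known ground truth that
  makes every stage testable end to end.

## The model in brief

Reads are classified by canonical k-mer membership (k = 25 by default).
For a read pair, `h`, `m`, `b`, `u` count k-mer positions found only in the
graft reference, only in the host reference, in both, or in neither; the
category is `graft` if `h>0 ∧ m=0`, `host` if `m>0 ∧ h=0`, `ambiguous` if
`h>0 ∧ m>0`, `both` if only shared k-mers were seen, else `neither`.
An error-free graft read can never contain a host-only k-mer, so it is always
retained — the retention theorem the test suite asserts. Conversely a host
read pair survives as "both" only when no divergent site falls inside either
mate, which happens with probability `c^(2L)` for per-base conservation `c`
and read length `L`; at `L = 51`, leakage is only appreciable above
`c ≈ 0.96`, which is why classification artifacts concentrate in highly
conserved genes.

Differential expression per gene fits a negative-binomial log-linear model
with patient indicator terms plus a condition term and offsets
`log(TMM-effective library size)`, and tests the condition term by a
likelihood-ratio test against χ²₁. Dispersions come from a
leverage-corrected Pearson moment equation shrunk toward a pooled common
value. PDX–donor differential genes (XDGs) are called at FDR < 0.05 and
|log2FC| > 1 after excluding pipeline artifacts.

## Worked example

```r
library(pdxsep)

design <- cohort_design(n_pairs = 4, fragments_per_sample = 20000, seed = 42)
cohort <- simulate_cohort(design, n_genes = 500)
wf     <- run_xdg_workflow(cohort)
```

This simulates four donor/PDX pairs (500 genes, 20k read pairs per sample,
a 30% stromal compartment in donors replaced by mouse stroma in the PDX at a
16% host-read fraction), then runs both arms of the analysis. Inspecting the
result:

```
artifact genes: 0
XDGs: 152 ( 151 down / 1 up )
mean donor-PDX r, all genes:       0.18
mean donor-PDX r, XDGs excluded:   0.8
aligned pairs after exclusion: 4 / 4
stroma/epithelium overlap: k = 150 , OR = 969 , p = 7.3e-98
PH01_X true host fraction: 0.159 | reads retained as human: 0.842
```

Reading this: the pipeline-sensitivity control found no artifact genes (with
exact k-mer membership and error-free-retention, the control is a near-exact
null — see the vignette); 152 XDGs were called, almost all down-regulated in
the PDX, matching the loss of the human stromal compartment; excluding them
raises the mean donor–PDX correlation from 0.18 to 0.80 and makes all four
pairs cluster as siblings; and the XDG list overlaps the simulated
stroma-vs-epithelium differential list almost perfectly. About 16% of PDX
reads were mouse and were removed by classification. Absolute correlation
values are depth- and gene-count-dependent; at desk-scale simulation depths
they sit well below what deep sequencing produces, but the improvement on
exclusion is the stable signal.

## Vignette

`vignettes/pdx-deconvolution.Rmd` documents the model and its assumptions,
the simulator's design (including which parameters are free choices rather
than literature values), numerical details of the NB fitting, and known
limitations.
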