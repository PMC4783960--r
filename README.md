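# apopnet

Naive Bayesian evidence integration for predicting protein–protein
interaction (PPI) networks, with downstream identification of apoptotic hub
proteins, permutation-based differential expression (SAM) and consensus
miRNA assignment.

`apopnet` is aimed at systems-biology analysts who want a fully seeded,
testable re-implementation of the classic likelihood-ratio approach to PPI
inference: curated interactions form a Gold Standard Positive set (GSP),
compartment-incompatible pairs a Gold Standard Negative set (GSN), several
heterogeneous genomic evidence channels are discretized and weighted by
class-conditional likelihood ratios, and candidate pairs are scored by the
naive Bayes product. Because the real resources (HPRD/BioGRID-scale
interactomes, GO annotations, Pfam domain tables, ortholog databases,
microarray series) are external and huge, the package ships a
synthetic-data generator that emulates every one of them with embedded
ground truth, so the entire chain is verifiable end to end on a desk.

## The model

For a candidate pair with discretized evidence `E1, …, En` (smallest shared
biological-process size, domain–domain interaction support, co-expression
correlation bin, per-species interolog flags), the posterior odds of
interaction are

    O_posterior = O_prior × LR(E1, …, En),
    LR(E1, …, En) = Π_i LR(E_i)          (conditional independence)

where each per-channel ratio is estimated from the gold standards,

    LR(bin) = P(bin | GSP) / P(bin | GSN),

with an additive pseudo-count keeping empty bins finite. Pairs with a
composite LR at or above a cutoff (default 20) enter the predicted network.
Held-out gold pairs (the Standard Test set) yield ROC curves, AUC
(trapezoidal; equal to the Mann–Whitney ordering probability),
`sensitivity = TP/positives` and `specificity = 1 − FP/negatives`.

Hub proteins are called by four toggleable criteria: degree ≥ 300 (30 for
sub-network analyses), ≥ 300 edges to known apoptotic proteins (200 as the
novel-hub standard), membership in the network's dense area (k-core,
k = 3), and differential expression under apoptotic stress. Differential
expression uses SAM (two-class unpaired): a moderated statistic
`d = Δmean / (s + s0)` against a permutation null, with delta tuned so the
estimated FDR (median permuted calls / observed calls) stays within 5%.
Per-gene miRNA regulators are the strict intersection of per-tool target
predictions.

## Worked example

```r
library(apopnet)

w <- generate_world(world_config(n_proteins = 200, n_filler = 260,
                                 n_positive_pairs = 500,
                                 n_negative_pairs = 2000, seed = 42))
ev <- w$evidence
lt <- estimate_lrs(ev, ev$label, w$config$binning)
print(lt)
#> Likelihood table: 9 channels, trained on 500 positives / 2000 negatives (pseudo-count 1)
#>   ssbp: LR <=10=7.29, 11-50=3.02, 51-200=0.832, >200=0.326, absent=0.381
#>   ddi: LR true=6.44, false=0.711
#>   coexpr: LR [-1,0.2)=0.408, [0.2,0.5)=0.832, [0.5,0.8)=1.72, [0.8,1]=4.88, absent=0.657
#>   interolog.mmusculus: LR true=5.2, false=0.728
#>   ... (one boolean channel per model organism)

roc <- roc_curve(composite_lr(ev, lt), ev$label, cutoff = 20)
print(roc)
#> ROC over 464 distinct thresholds; AUC = 0.9164
#> At cutoff 20 : TP=176 FP=10 TN=1990 FN=324 sensitivity=0.3520 specificity=0.9950
```

Small shared processes, supported domain pairs, high co-expression and
conserved interologs all earn ratios well above 1 among true interactors,
exactly as configured in the generator's ground truth; integrating them
separates positives from negatives (AUC 0.92) far better than any single
channel, and the LR ≥ 20 operating point is conservative (specificity
0.995 at sensitivity 0.35).

The caspase-9 consensus worked example — three tool hit lists of sizes
51, 14 and 156 sharing exactly five miRNAs:

```r
ct <- mirna_consensus(casp9_example())
ct$consensus
#> "hsa-miR-124;hsa-miR-182;hsa-miR-504;hsa-miR-506;hsa-miR-96"
```

`run_pipeline(pipeline_config(outdir, seed))` executes the whole chain —
gold standards → evidence → training → prediction → evaluation → network
and hubs → SAM → miRNA consensus — writing per-stage TSV/JSON artifacts and
an MD5 manifest; identical configurations reproduce identical files.

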