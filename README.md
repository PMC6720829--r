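# tipin

Protein complexes are groups of proteins that physically assemble to carry
out a cellular function, but a static protein–protein interaction (PPI)
network hides *when* those assemblies exist: during the cell cycle a protein
is only intermittently active. `tipin` implements a dynamic-network approach
to complex detection for anyone working with a reliability-scored PPI
network (STRING-style scores on the 1–999 scale) and a time-course
expression data set:

1. **Temporal networks.** Expression is normalized per gene to its
   undulation above base level, `gep_i(t) = (ev_it − min_t ev) / (max_t ev −
   min_t ev)`; gene *i* is *active* at time *t* iff `gep_i(t) ≥ φ`. The
   temporal network at *t* keeps edge (i, j) with score
   `da_ij(t) = ap_i(t)·ap_j(t)·a_ij`.
2. **Temporal-interval networks (TI-PINs).** For every closed interval
   `[t_low, t_high]` the interval network keeps the edges present at *every*
   time point of the interval, scored by the interval minimum
   `b_ij = min_t da_ij(t)` (computed bottom-up by the recurrence
   `b[l,h] = min(b[l,h−1], b[l+1,h])`). T time points give T·(T+1)/2
   networks, preserving interactions that persist over time.
3. **Seed-expansion identification.** In each interval network, clusters
   grow from high-degree seeds by admitting neighbours linked by an
   r-reliable edge (`b ≥ r`) that keep three conditions true:
   - *joint colocalization*: all members share ≥ 1 of 22 subcellular
     compartments (`JC > 0`);
   - *joint coexpression*: the windowed mean of the product of the members'
     normalized expression over the interval's `l + 4` window satisfies
     `JQ ≥ γ`;
   - *expanding-cluster condition*: the candidate's minimal GO semantic
     similarity to its r-reliable cluster neighbours clears the threshold in
     at least two of the three ontologies (CC ≥ σ, MF ≥ ω, BP ≥ θ), with the
     term-level kernel `sim(go₁,go₂) = e^{−0.2·l}·tanh(0.3·h)·tanh(30·d)`
     driven by the maximum-informative common ancestor's depth *h* and
     information content *d*.
4. **Evaluation.** Predicted catalogs are scored against a reference
   (e.g. CYC2008) with the overlap score `|∩|²/(|ic|·|kc|)`, precision /
   recall / f-measure, Frac, MMR, Sn/PPV/Acc, the composite
   `FAM = Frac + Acc + MMR`, the exact-match count #PM, and hypergeometric
   GO enrichment (over-expression score at ψ = 0.01).

A fully synthetic benchmark generator with planted ground-truth complexes
makes the entire pipeline testable offline.

## Worked example

```r
library(tipin)

spec <- synthetic_spec(seed = 11, n_complexes = 6, n_background = 40)
gt   <- generate_bundle(spec)

pipe <- build_tipins(gt$base_edges, gt$scored_edges, gt$expression, phi = 0.1)
pipe$network
#> scored_network: 66 proteins, 246 interactions
length(pipe$tipins)          # T = 12 time points -> 12*13/2 interval networks
#> [1] 78

bundle  <- annotation_bundle(gt$dag, gt$annotations)
catalog <- run_icjointle(pipe$tipins, pipe$gep, gt$localization, bundle,
                         icj_thresholds())   # r=999, sigma=.7, omega=.6, theta=.1, gamma=.01
catalog
#> complex_catalog: 6 complexes ( 97 before deduplication )

match_report(catalog$complexes, gt$complexes)
#> match_report (lambda=0.2): #PM=6 fm=1.000 Frac=1.000 Acc=1.000 MMR=1.000 FAM=3.000 #PMxFAM=18.00

ov <- overexpression_score(catalog$complexes, bundle$BP$prot_terms, pipe$network$nodes)
sprintf("over-expression score: %.2f (%d of %d significant)", ov$score, ov$n_significant, ov$n_total)
#> "over-expression score: 1.00 (6 of 6 significant)"
```

The 97 raw clusters collapse to 6 after exact deduplication because each
planted complex is re-found in every sub-interval of its activity window;
`#PM = 6` with `FAM = 3` means all six planted complexes were recovered
exactly (Frac, Acc and MMR all attain 1), and every one is significantly
enriched for its planted GO term at ψ = 0.01.

## Command line

The installed script `exec/tipin` (or `tipin_cli()` from R) exposes the
pipeline stages:

```sh
tipin simulate --seed 1 --out bundle/
tipin build    --ppi bundle/ppi_base.tsv --scores bundle/ppi_scored.tsv \
               --expr bundle/expression.tsv --phi 0.1 --out tipins/
tipin identify --ppi bundle/ppi_base.tsv --scores bundle/ppi_scored.tsv \
               --expr bundle/expression.tsv --loc bundle/localization.tsv \
               --obo bundle/ontology.obo --gaf bundle/annotations.gaf \
               --out predicted.txt
tipin evaluate --pred predicted.txt --ref bundle/complexes.txt
```

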