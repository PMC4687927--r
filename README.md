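# barreltm

Prediction of transmembrane β-strand regions in outer-membrane β-barrel
proteins, from sequence alone.

β-barrel membrane proteins — porins, transporters, adhesins and toxins of
the gram-negative outer membrane, mitochondria and chloroplasts — cross
the bilayer with short antiparallel β-strands of roughly 6–12 residues.
Because these strands are amphipathic, hydrophobicity profiles that work
for α-helical membrane proteins fail here, and the tight 2–5 residue
turns between hairpin strands make the boundaries hard to place. This
package implements a two-layer predictor for these regions, aimed at
structural bioinformaticians who need per-residue transmembrane
annotations for candidate barrel proteins, and at method developers who
want a fully self-contained, trainable reference implementation.

## Method

**Layer 1 — window classification.** A protein of *n* residues is cut
into *n − 9* overlapping windows of *w* = 10 residues. Each window *S* is
encoded by its amino-acid adjacency matrix *A*, where
*A(a, b)* = number of positions *i* with *S_i = a* and *S_{i+1} = b*
(ordered pairs, N→C), flattened row-major into a 400-dimensional
pair-frequency descriptor. A class-weighted RBF-kernel support vector
machine, tuned by a two-level (C, γ) grid search under stratified
10-fold cross-validation, labels every window *tm* or *ntm*. Class
imbalance is handled by per-class soft margins
C_tm = C, C_ntm = C · n_tm / n_ntm.

**Layer 2 — boundary refinement.** Runs of ≥ 4 consecutive *tm* windows
(one isolated *ntm* window may be bridged inside runs of ≥ 7) become
stretches; the stretch covering windows *i..j* spans residues
*i .. j + w − 1*. Long spans, typically fused β-hairpins, are split into
sub-regions of ≈ 13 residues. Within each (sub-)region, every candidate
segment bounded by constituent window termini with 6 ≤ length ≤ 12 is
scored by a position-specific preference table,
score = score_N(first residue) + score_C(last residue), and the most
central of the top three positive scorers is reported:
TM = { r : mid(r) → mid(R), r ∈ Top3 }.

Training utilities build labeled segment sets from annotated proteins
(exact membrane-embedded strands as *tm*; loops chopped into ~10-residue
*ntm* fragments), partition them with a Kohonen self-organizing map so
both training and validation sets sample every occupied map unit, and
estimate the boundary preference table by log-odds of terminal residue
usage. A synthetic β-barrel generator (alternating strands/loops, dyad
hydrophobic–polar repeat, aromatic-girdle termini) makes the whole
pipeline trainable and testable without any external database.

## Worked example

```r
library(barreltm)
spec  <- barrel_spec()                       # 8-strand synthetic barrels
train <- generate_corpus(spec, 40, seed = 100)
test  <- generate_corpus(spec, 5, seed = 200, prefix = "new")

seg   <- corpus_segments(train)              # labeled tm/ntm segments
split <- som_split(seg, seed = 1)            # SOM train/validation split
x     <- descriptor_matrix(split$training$sequence)
gs    <- grid_search(x, split$training$label, folds = 5,
                     log2C = seq(-1, 7, by = 2),
                     log2gamma = seq(-9, -1, by = 2),
                     refine_radius = 0, seed = 1)
model <- train_svm(x, split$training$label, C = gs$C, gamma = gs$gamma)
model
#> <btm_classifier> radial kernel, C=2 gamma=0.03125 (C_tm=2, C_ntm=1.446)
#>   trained on 653 segments (tm=274, ntm=379); self-consistency 98.47%

table <- estimate_preference_table(train)
predict_protein(test[[1]]$seq, model, table)
#>   protein_id start end length    score stretch
#> 1   new_0001    28  33      6 4.943217       1
#> 2   new_0001    41  49      9 3.748116       1
#> 3   new_0001    63  68      6 4.412225       2
#> 4   new_0001    75  85     11 4.943217       2
#> 5   new_0001   107 113      7 4.390445       3
#> 6   new_0001   116 127     12 4.943217       3
#> 7   new_0001   147 154      8 4.449312       4
#> 8   new_0001   160 170     11 4.319353       4
```

Each row is one predicted transmembrane strand (1-based inclusive
residue coordinates, its boundary-preference score, and the stretch it
was refined from). This protein's eight planted strands are at 28–36,
41–49, 63–72, 75–81, 105–111, 114–122, 147–154 and 160–168 — all eight
are recovered, with boundaries within a few residues. Region-level
evaluation over the five test proteins:

```r
pred <- predict_corpus(lapply(test, function(p) p$seq), model, table)
evaluate_corpus(pred, corpus_regions(test))$summary
#>   known predicted TP FP FN sensitivity precision segment_overlap
#> 1    40        46 37  9  3        92.5  80.43478        69.08557
```

`sensitivity` is the percentage of known strands recovered (a true
positive overlaps exactly one known strand), `precision` the percentage
of predictions that are real, and `segment_overlap` an SOV-style
length-weighted overlap quality score.

## Command line

The same pipeline is scriptable through the installed `exec/barreltm`
entry point:

```sh
BTM=$(Rscript -e 'cat(file.path(find.package("barreltm"), "exec", "barreltm"))')
Rscript $BTM synth    --n 40 --seed 3 --fasta c.fasta --regions c.tsv
Rscript $BTM train    --fasta c.fasta --regions c.tsv --out-dir model --coarse
Rscript $BTM predict  --fasta c.fasta --model model/model.rds \
                      --table model/preference.tsv --out pred.tsv
Rscript $BTM evaluate --predictions pred.tsv --regions c.tsv
```

Region files are TSV (`protein_id`, `start`, `end`; 1-based inclusive);
`--bed` exports 0-based half-open BED. The shipped preference table
(`inst/extdata/preference_synthetic.tsv`) is estimated from the
synthetic corpus; supply your own (via `estimate_preference_table()` on
real annotated barrels) for production use.

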