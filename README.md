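# pddisc — pattern discovery and disentanglement for mixed-mode tabular data

`pddisc` finds statistically significant associations of attribute values
(AVs) in a relational table — clinical records, aligned-site tables,
categorical surveys — and *disentangles* them: when associations that stem
from different underlying sources (diseases, taxa, functional groups)
overlap inside the same rows, it separates them into per-source pattern
clusters, links each cluster to the entities that carry it, detects
mislabelled entities, and corrects their class. The output is a
three-space knowledge base (knowledge space, pattern space, entity space)
rather than a black-box score, so every decision can be traced back to the
patterns and entities that support it.

## Method

For each pair of distinct attribute values with marginal counts
`Occ(AV_a)`, `Occ(AV_b)`, co-occurrence `Occ(AV_a ↔ AV_b)` and `T` records,
the association weight is the adjusted standardized residual

    SR = (Occ(AV_a ↔ AV_b) − Exp) / √Exp × (1 − Occ(AV_a)·Occ(AV_b) / T²),
    Exp = Occ(AV_a)·Occ(AV_b) / T .

The pipeline then:

1. builds the Entity-ID **address table** (per-AV sorted entity-ID lists),
   so any AV-set's support is a list intersection, never a table rescan;
2. assembles the K×K **SR matrix** over all distinct AVs;
3. applies **PCA (uncentered) to the SR matrix** and re-expresses each
   principal component as a rank-1 reconstructed SR matrix — a candidate
   *disentangled space* (DS), kept when its maximum reconstructed residual
   exceeds 1.96 (95% level);
4. clusters AVs within each DS into statistically connected **AV-groups**
   (connected components of the significant-association graph) and refines
   them into **AV-subgroups** by the Dice overlap of their entity covers
   (average-linkage agglomeration, 50% cutoff), yielding coded units
   `DSU[#DS #AVG #AVSG]`;
5. grows **high-order patterns** inside each DSU and accepts a candidate
   `P` when `SR(P) = R(P)/√V(P)` exceeds the threshold, with
   `R(P) = (Occ(P) − Exp(P))/√Exp(P)`, `Exp(P) = M·∏ Occ(AV)/M`,
   `V(P) = 1 − ∏ Occ(AV)/M`, keeping only delta-closed patterns;
6. clusters entities to DSUs by maximal shared-AV percentage; and
7. assigns every entity a class status — `Cor`rect, `Inc`orrect,
   `Und`ecided, `OL` (outlier) or `Cra` (class readjusted, i.e. a corrected
   mislabel) — in both a with-label (wCL) and a no-label (nCL) run, and
   integrates the two. Class-association accuracy is
   `100 × (#Cor + #confirmed readjusted) / N`.

## Worked example

The built-in generator reproduces the package's reference scenario: 400
entities × 6 attributes of uniform-random letters with three disjoint
implanted AV triples ({A2=P, A3=Q, A5=R} on entities 75–129, two more on
150–219 and 240–324), each tied to a class, plus optional label noise.

```r
library(pddisc)

d   <- synth_generate(synth_spec(label_flip_rate = 0.05), seed = 11)
fit <- pdd(d$data, class_col = "class", eid_col = "eid")
summary(fit)
```

```
Disentangled-space units:
        dsu n_avs cover n_patterns union_size dominant_class
 DSU[1 1 1]     3    70          4          3             C2
 DSU[1 2 1]     3    85          4          3             C3
 DSU[2 1 1]     3    55          3          3             C1
 DSU[2 1 2]     1    28          0          0           <NA>
 DSU[2 2 1]     2    86          1          2             C3
 ...

Final class status counts:
Cor Cra  OL Und
202  25 172   1

Class association accuracy: 50.50% -> 56.75% after readjustment
Entity clustering accuracy: 68.50% -> 73.50% after readjustment
```

Each implanted triple is recovered as the top pattern of its own DSU, with
the DSU's patterns concentrated on the implant's class (`dominant_class`).
Entities carrying an implant but a flipped label re-emerge as `Cra` with
the implant's class; entities that are pure background carry no pattern
and are reported as outliers (`OL`) — which is why the headline accuracy
on this deliberately noisy replica sits near 56%, not 100%: 172 of the 400
entities have no signal at all, and the statuses say so explicitly.
`export_kb(fit, "out/")` writes `knowledge_space.tsv`,
`pattern_space.json`, `entity_space.tsv` and `provenance.json`;
`residuals(fit)` returns the SR matrix, `plot(fit)` the AV projections on
the leading disentangled spaces, and `predict(fit, newdata)` classifies
new rows by pattern coverage.

A thin command-line wrapper is installed at `inst/cli/pdd.R`
(`Rscript pdd.R run --input data.csv --class-col class --out DIR`, and
`pdd.R synth` for the generator).

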