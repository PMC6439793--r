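# sketchoverlap

Curators of protein family databases face a recurring question: given a
candidate family — typically the result set of a profile-HMM or sequence
similarity search, i.e. a collection of matched regions on protein
sequences — does it cover new residue space, or does it overlap families
the database already holds? Answering exactly means intersecting
residue-level sets that can hold tens of millions of elements, once per
existing family. `sketchoverlap` answers it approximately but in
sub-second time, using bottom-n MinHash sketches, so the check can run
interactively on every search a user performs. Its intended users are
family-database curators and pipeline authors doing overlap quality
control; the input is any table of `(family, protein, start, end)` region
matches.

## The statistics

A family is the set of elements `(protein accession, ⌊i/w⌋)` over every
residue coordinate `i` its regions cover, where `w` is a chunking window
(`w = 1` keeps single-residue resolution). For two sets A and B:

- **Jaccard index** `JI(A,B) = |A ∩ B| / |A ∪ B|` — symmetric similarity;
- **Jaccard containment** `JC(A,B) = |A ∩ B| / |A|` — the fraction of A
  inside B; `JC(A,B) = 1` iff A ⊆ B, which is the signal that a candidate
  is a superset ("superior model") of an existing family.

Exact computation needs a full set intersection, `O(min(|A|,|B|))` with
hash maps. Instead, hash every element with a seeded 64-bit-state hash
`h`, and keep only the sketch `MINₙ(A′)`: the `n` smallest values of
`A′ = {h(x) : x ∈ A}` (the whole of `A′` when `|A′| < n`). Because
`MINₙ(MINₙ(A′) ∪ MINₙ(B′)) = MINₙ(A′ ∪ B′)`, a uniform `n`-sample of the
union is computable from the two sketches alone, and

```
JI ≈ |MINₙ(A′ ∪ B′) ∩ MINₙ(A′) ∩ MINₙ(B′)| / |MINₙ(A′ ∪ B′)|
JC ≈ |MINₙ(A′) ∩ B′| / |MINₙ(A′)|
```

are unbiased proportion estimates with standard error `≈ √(p(1−p)/n)`,
independent of family size. Both become exact when `n` reaches the set
sizes. Containment probes need full membership in `B′`, so the index
stores each family's complete hash set alongside its sketch; chunking
with `w > 1` is what keeps those sets small.

A query is compared against every indexed family and classified:
**novel** (no family reaches the containment threshold in either
direction), **single_family**, **multi_family_same_clan** (all
overlapping families share one clan — a novel clan member or a superior
model, not necessarily an error), or **multi_family_mixed**. A family
with `JC(family, query) ≥ 0.95` and a smaller element set than the query
is flagged `superior`: the query covers it entirely plus new residues.

## Worked example

```r
library(sketchoverlap)
fx  <- scenario_fixtures(seed = 42)                     # 4 families, 3 queries
idx <- build_index(fx$families, hash_params(window = 4),
                   capacity = 200, clans = fx$clans)
classify(compare_query(fx$queries$superset, idx))
#> <overlap_report> scenario: single_family (jc_threshold=0.50)
#>   family_id ji_estimate jc_query_in_family jc_family_in_query clan_id superior
#> 1     FAM_A   0.6190476          0.6190476                  1    <NA>     TRUE

classify(compare_query(fx$queries$clan, idx))
#> <overlap_report> scenario: multi_family_same_clan (jc_threshold=0.50)
#>   family_id ji_estimate jc_query_in_family jc_family_in_query clan_id superior
#> 1   CLAN_X2   0.3953488            0.53125          0.6071429   CL001    FALSE
#> 2   CLAN_X1   0.3571429            0.46875          0.6000000   CL001    FALSE
```

The first query contains every element of `FAM_A`
(`jc_family_in_query = 1`) plus extra coverage, so it is flagged as a
superior model for that single family. The second straddles two families
that both belong to clan `CL001`: each family is ~60% contained in the
query, putting both past the 0.5 threshold, and since all overlapping
families share one clan the query is reported as a potential novel clan
member rather than a cross-clan conflict.

The same flow is available from a shell via the installed script
(`system.file("exec", "sketch-overlap", package = "sketchoverlap")`):

```sh
sketch-overlap simulate --config cfg.json --out sim
sketch-overlap index    --regions sim/regions.tsv --clans sim/clans.tsv --n 200 --w 4 --out idx
sketch-overlap compare  --index idx --query query.tsv --jc-threshold 0.5 --out report.json
sketch-overlap exact    --regions sim/regions.tsv --query query.tsv   # oracle mode
sketch-overlap bench    --sizes 100,1000,10000 --n 25,50,100,200
```

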