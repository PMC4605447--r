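# lingomcc

Text-based chemical similarity screening for SMILES libraries in R.

Large-scale compound comparison — screening every molecule of a query
library against every molecule of a database (the *multiple compound
comparison*, MCC, problem) — is a routine step in ligand-based virtual
screening. `lingomcc` implements the LINGO family of string-similarity
methods for this task: each molecule's SMILES string is treated purely as
text and fragmented into its overlapping 4-character substrings
(*Lingos*), and two molecules are compared by the Tanimoto (Jaccard)
coefficient of their Lingo collections. For libraries *Q* (k compounds)
and *D* (r compounds) the engine computes all k × r coefficients and
reports the database hits above a similarity threshold.

## The statistic

For a SMILES string of length *l* and window width *q* (default 4), the
*l − q + 1* sliding windows are each packed big-endian into a 32-bit
integer *score*; the compound's profile stores the sorted unique scores,
their multiplicities (*LINGO numbers*), the string length (*LINGO
length*), and the distinct-window count (*LINGO magnitude*). For two
profiles A, B the multiset Tanimoto coefficient is

    T(A, B) = Σ_g min(n_A(g), n_B(g)) / ( Σ_g n_A(g) + Σ_g n_B(g) − Σ_g min(n_A(g), n_B(g)) )

where *n_X(g)* is the multiplicity of q-gram *g* in X — computed by a
single linear merge of the two sorted score arrays. A set-based variant
(multiplicities ignored) is available as `mode = "set"`. Two compounds
both too short to produce any Lingo score 0 by convention.

Because the pairwise work varies between compounds, the engine estimates
per-compound workload by one of four profile-derived measures — score sum
(`S`), Lingo count (`N`), string length (`L`), distinct-Lingo count
(`M`) — and partitions the query across an abstract pool of workers
(greedy LPT or sorted round-robin), the software analogue of balancing
thread blocks and devices. Partitioning affects scheduling only: results
are bit-identical for every worker count, strategy, and policy.

## Worked example

Screen one compound against a 1,000-compound synthetic library spiked
with a near-duplicate (one character substituted):

```r
library(lingomcc)

lib  <- gen_library(1000, length_dist = c(20, 80), seed = 42)
base <- lib[1, ]
near <- mutate_pair(base, 1, seed = 7)      # 1 substitution in 68 characters
db   <- rbind(lib, near)

res <- run_mcc(base, db, mcc_config(n_workers = 2))
res$hits
#>  query_id        db_id tanimoto
#>   S000001      S000001 1.000000
#>   S000001 S000001_mut1 0.884058
res$n_pairs
#> [1] 1001
```

The base compound matches itself exactly (1.0); the single substitution
destroys at most 4 of its 65 overlapping 4-grams, leaving the mutant at
0.884 — above the default report threshold of 0.85, which is *strict*
("more than"), so a pair scoring exactly 0.85 is not reported.

Per-compound profiles are inspectable directly:

```r
build_profile("c1ccccc1O")
#> <lingo_profile> q=4 length=9 magnitude=5
#>   scores:  828597091 1664181091 1667445071 1667457841 1667457891
#>   numbers: 1 1 1 1 2
```

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lingo-mcc.R", package = "lingomcc"))')
Rscript $CLI synth   --n 10000 --min-len 20 --max-len 80 --seed 42 --out lib.smi
Rscript $CLI profile --in lib.smi --out profiles.tsv
Rscript $CLI compare --query lib.smi --db lib.smi --out hits.tsv \
    --threshold 0.85 --workers 4 --strategy M --manifest run.json
```

`compare` writes a TSV hit report (`query_id  db_id  tanimoto`, ordered
by query, then descending coefficient) and, on request, a JSON run
manifest with input checksums, per-phase wall times, and per-worker load
statistics. Exit status: 0 success, 2 usage error, 1 runtime error.

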