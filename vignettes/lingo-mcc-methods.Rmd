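---
title: "LINGO-based multiple compound comparison: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LINGO-based multiple compound comparison: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingomcc)
```

## The model

`lingomcc` measures chemical similarity without any chemistry: a SMILES
string is treated as plain ASCII text, and a molecule is modeled as the
multiset of its overlapping `q`-character substrings (Lingos). This
text-only view is the method's defining assumption — it trades structural
awareness for speed, and has repeatedly been shown to rank similar
molecules comparably to fingerprint methods when `q = 4`.

For a string of length $l$, the sliding window with offset 1 yields
$l - q + 1$ Lingos (none if $l < q$). Each 4-character Lingo is packed
big-endian into a 32-bit integer *score*
($c_0 2^{24} + c_1 2^{16} + c_2 2^8 + c_3$, with $c_i$ the ASCII codes),
so that integer comparison of scores is equivalent to lexicographic
comparison of substrings; sorting scores therefore sorts substrings. A
compound's *profile* stores the strictly ascending unique scores, the
multiplicity of each (the *LINGO numbers*), the character count (*LINGO
length* $l$), and the number of distinct Lingos (*LINGO magnitude*).
Profile invariants are enforced structurally: `sum(numbers)` always
equals $\max(0, l - q + 1)$.

Two profiles are compared by the Tanimoto (Jaccard) coefficient of their
Lingo collections, computed in one linear pass over the two sorted score
arrays. Two interpretations are supported:

* **multiset** (the default): intersection $\sum_g \min(n_A(g), n_B(g))$,
  union $\sum_g n_A(g) + \sum_g n_B(g)$ minus the intersection. This is
  the accumulation rule of SIML-style SMILES q-gram engines, which this
  implementation follows; repeated substrings in one molecule count with
  their multiplicity.
* **set**: multiplicities ignored; intersection is the count of shared
  scores, union `magnitude_A + magnitude_B` minus that count.

The choice matters most for strings with many internal repeats (e.g. long
aliphatic chains, where `CCCC` recurs): multiset mode penalizes a
multiplicity mismatch, set mode does not. Both are exposed because the
accumulation rule is the one genuinely open modeling decision in this
family of methods; multiset is the default and the mode used everywhere
unless stated.

```{r}
tanimoto(build_profile("CCCCC"), build_profile("CCCC"))                 # 1/2
tanimoto(build_profile("CCCCC"), build_profile("CCCC"), mode = "set")   # 1
```

## Degenerate inputs and numerical choices

* **Strings shorter than `q`** produce an empty profile rather than an
  error — real libraries contain 1–3-character SMILES (`C`, `O`, `CC`).
  Similarity involving one empty profile is 0 because the intersection
  is empty; similarity of **two empty profiles is defined as 0**, not 1
  or NaN: a molecule too short to produce any Lingo matches nothing.
  This convention is deliberate and surfaces at `q > l` corner cases.
* **Coefficients are doubles.** Each coefficient is one division of two
  exactly-representable integers, so results carry no accumulation-order
  sensitivity; the oracle-equivalence tests assert agreement to 1e-12
  and exact cases (e.g. 17/20) are exact.
* **Packing byte order** is unobservable in the similarity values (any
  injective packing gives identical coefficients); big-endian is chosen
  so sorted scores coincide with lexicographically sorted substrings,
  which makes profiles human-checkable. For `q > 4` the same layout uses
  wider integers held in doubles, exact up to `q = 6`; `q = 4` is the
  validated default.
* **The hit threshold is strict** (`>`): a pair scoring exactly the
  threshold is excluded. Consequently `threshold = 1` reports nothing,
  even for identical compounds — intentional, documented, and tested.
* **Ring-digit normalization is off by default.** The optional
  `ring_digit_zeroing` flag rewrites ring-closure digits (outside bracket
  atoms) to `0`, for compatibility with the original LINGO formulation;
  the engine validated here operates on raw strings.

## Workload estimation and partitioning

All-to-all comparison is embarrassingly parallel but heterogeneous: the
merge cost of a pair is linear in the two magnitudes. The engine
estimates each query compound's cost by one of four profile-derived
measures — `S` (sum of unique scores), `N` (Lingo count, which equals
$l - q + 1$), `L` (string length), `M` (magnitude) — and partitions the
query across `n_workers` abstract workers. `N` and `L` differ by the
constant $q - 1$ for every non-degenerate compound, so they induce the
same ordering; this structural fact explains why strategy choice barely
matters in practice, and the suite asserts it. `M` is the default: it is
the direct bound on merge cost. `S` is a score-mass heuristic retained
for completeness.

Two deterministic assignment policies are provided. *Greedy LPT* (the
default) sorts compounds by estimated workload descending and assigns
each to the worker minimizing `(load + workload) / weight`; on
equal-weight workers it carries the classical $4/3 - 1/(3m)$ makespan
guarantee, which the tests verify against an exhaustive-enumeration
optimum on small instances. *Sorted round-robin* deals the sorted list
cyclically, mimicking the assignment of a sorted database to consecutive
threads; it ignores weights. Ties are broken by lower compound index,
then lower worker number, making every partition reproducible. Worker
weights default to equal and model heterogeneous device capability.

**Workers are an abstraction.** In the hardware-oriented formulation of
this method, the two partitioning levels are threads within a block and
GPU cards; here both collapse onto one worker pool whose blocks are
computed sequentially in worker order. This keeps every algorithmic
decision (estimation, sorting, assignment, merging of partial results)
intact and testable while guaranteeing bit-identical output for every
worker count, strategy, and policy — an invariant the suite checks
end-to-end on a 500 × 500 run. The load-balance quality itself is
observable through `imbalance()` and the per-worker load statistics in
the CLI manifest, not through wall-clock ratios, which are
hardware-bound and out of scope.

## The engine

`compare_a2a()` runs the three phases — profile construction, partitioned
comparison, merge — and materializes the full k × r matrix; it is the
path the correctness tests sweep against a brute-force oracle.
`run_mcc()` is the screening path: it filters each worker block to
above-threshold hits immediately, so the full matrix never exists in
memory at once (at r compounds per block row, the matrix path needs
8·k·r bytes; streaming needs only the hit list). Both return an
instrumented pairwise-comparison count, which scales exactly as k·r.
A one-compound query is the one-to-all special case of the same code
path. Database profiles are shared by all workers; only the query is
split, mirroring the replicate-database/split-query layout of the
multi-device formulation.

## The synthetic generator

`gen_library()` emulates a screening library *textually*: i.i.d.
characters from the organic-subset SMILES alphabet, lengths uniform on
[20, 80] by default (tens to hundreds of characters, the regime of
drug-like SMILES), ids `S000001…`, fully determined by its seed. Two
caveats are documented loudly:

* Generated strings are **not valid molecules**, and need not be: every
  computation in the package depends only on textual statistics (length,
  alphabet, repeat structure). Passing tests demonstrate correctness of
  the string algorithms, not chemical meaningfulness of the scores on
  real libraries.
* Real SMILES have strongly non-uniform character frequencies and
  long-range repeat structure (rings, branches); uniform sampling
  under-produces repeated 4-grams relative to real libraries, so typical
  synthetic pairwise similarities are lower than typical real-library
  similarities. Threshold-sensitive behavior is therefore tested with
  constructed pairs (`mutate_pair()`, exact-coefficient constructions),
  not with random ones.

The one structural constraint imposed on generated strings: the first
character is never `#`, which is not a legal SMILES opening and would
collide with the `.smi` comment convention, breaking write/read
round-trips.

`mutate_pair()` substitutes an exact number of positions; since one
substitution destroys at most `q` overlapping windows, the substitution
count gives fine control over similarity to the base — used to place
pairs just above or below the report threshold.

## Problem sizes used in validation

The shipped suite validates at sizes a single CPU handles in minutes,
chosen to exercise every code path rather than to benchmark: 1,000
random string pairs (lengths 0–200) for oracle equivalence of both
modes; 10,000 pairs for the similarity axioms; 100 random scheduling
instances (≤ 12 jobs, ≤ 3 workers) against the exhaustive optimum;
500 × 500 all-to-all runs for worker/strategy/policy invariance of the
hit report; and a 1,000 × 1,000 end-to-end screen (10^6 pair
comparisons). The C++ merge kernel completes the 10^6-pair screen in
seconds; the dominant cost at these sizes is profile construction in R,
which is linear in total library text.

## Known limitations

* No GPU or multi-process execution: the worker pool is a scheduling
  abstraction, chosen for determinism. Plugging the per-worker blocks
  into a process pool is mechanical but would make bit-identity claims
  platform-dependent, so it is intentionally absent.
* SMILES canonicalization is out of scope; two different SMILES spellings
  of the same molecule are different strings, and scored as such. Callers
  wanting canonical input should canonicalize upstream.
* `S` workload uses the unweighted sum over unique scores; a
  multiplicity-weighted variant is conceivable but unvalidated, and the
  near-equivalence of all four strategies makes it unrewarding.
* The `.smi` reader is deliberately minimal (no SDF/MOL2, no gzip); it
  enforces printable ASCII because score packing assumes one byte per
  character.
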