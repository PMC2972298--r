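---
title: "Methods: integrating EST digital-northern and microarray expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating EST digital-northern and microarray expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estarray)
```

## The problem

EST sequencing counts ("digital northerns") and microarray hybridizations
measure the same biology through different instruments. A gene index
assembles all public ESTs of a species into tentative consensus sequences
(TCs) and records, for each TC, how many ESTs came from each cDNA library —
and because each library was made from one tissue or condition, those
counts are an expression measure. `estarray` combines that in silico
measure with experimental expression columns so that a condition-specific
candidate gene must show up in both.

## The selection model

Libraries are partitioned into three states. The filter retains a TC iff

* it has at least one EST from the **MUST** group — OR semantics: any MUST
  library suffices, and
* it has zero ESTs from every **MUST_NOT** library,

while **MAY** libraries never affect membership. Two design points were
genuinely open and were fixed as follows:

* **Empty MUST group.** The MUST clause is vacuously true, so the filter
  reduces to the MUST_NOT exclusion; a warning is emitted. This keeps the
  filter monotone (moving a library from MAY to MUST_NOT can only shrink
  the retained set) and composable. An AND-across-MUST variant is not
  implemented.
* **Default state.** Libraries absent from a selection file are MAY — the
  neutral "does not matter" state.

## The likelihood-ratio score

Each retained TC is scored with the single-gene log-likelihood ratio of
Stekel, Git & Falciani (2000). With used libraries U (states MUST and MAY;
zero-size libraries are dropped with a warning rather than erroring),
counts x_i, library sizes N_i and overall frequency f = Σx_i / ΣN_i:

R = Σ_{i ∈ U, x_i > 0} x_i ln( x_i / (N_i f) )

Numerical conventions: natural log (the base only rescales a ranking
score); 0·ln 0 = 0; tiny negative floating error (> −10⁻¹²) is clamped to
0 since R is analytically nonnegative; a TC with no EST in U scores R = 0
with a warning (reachable only with empty-MUST selections). Whether the
score should run over the MUST+MAY set or over all libraries is a genuine
modelling choice; MUST+MAY was chosen because MUST_NOT libraries are
excluded from the question being asked. Ranking is by descending R with a
lexicographic tc_id tie-break, making the order total and deterministic.
No significance threshold is attached: R is used purely as a ranking
score, and per-library pairwise tests are out of scope.

## The expression join

TCs map to platform reporters via a simple TSV or 12-column tabular BLAST
output (query = reporter, subject = TC; best bit score per (reporter, TC)
pair). Policies, all configurable:

* **Aggregation** of multiple reporter values per experiment: `mean`
  (default — least surprising for log-scale values), `median`, `max`. For a
  single reporter all three coincide.
* **Missing values**: `drop` (default) excludes the TC and itemizes it in
  the drop report, mirroring the observable behaviour of analyzing only
  represented genes; `impute_column_mean` substitutes the experiment
  column's mean.
* **min_score**: off by default; the original mapping criteria of such
  pipelines are typically unpublished, so all map rows are accepted.
* Platform value semantics (log2 ratios vs significance-test means) are
  carried as metadata only; the columns are clustered side by side without
  cross-platform renormalization.

The invariant `retained = joined + dropped` holds with exactly one primary
reason code (`NO_REPORTER`, `MISSING_VALUE`) per dropped TC.

## Clustering

Features are the configured experiment columns, optionally preceded by R.
Since R (tens to hundreds of nats) and log2 ratios (units) differ by
orders of magnitude, standardization defaults to **on** when R is mixed
with expression columns and off otherwise; the z-score uses the sample
(n−1) standard deviation, and a constant column maps to zeros with a
warning.

Clustering is agglomerative Ward in the **D2 convention**: merge heights h
satisfy h² = 2·ΔSSE, the increase in total within-cluster sum of squares,
computed on Euclidean distances. D2 is the textbook minimum-variance
method and reproduces identically across ecosystems, which matters because
the legacy "ward" of 2010-era statistical backends was ambiguous between
the D and D2 conventions. Heights are monotone nondecreasing, so cutting
by "undoing the last k−1 merges" coincides with height-threshold cutting.
Cut labels 1..k are assigned by each cluster's first leaf in dendrogram
leaf order, making the labelling a pure function of the tree; successive
cuts form a nested chain in which exactly one cluster splits per
increment. k is accepted in 1..n programmatically; the CLI warns outside
the conventional 2..8 exploration range, and when k is unset the pipeline
emits all cuts 2..8 plus a size table (the GO summary then uses k = 4, a
typical exploratory choice).

## GO summaries

Per cluster, member TCs are counted per directly-annotated GO term (ids
normalized from `GO:0005524`, `0005524` or bare `5524` forms) and the top
5 terms are reported with counts and member fractions. This is
**descriptive counting, not enrichment**: no hypergeometric test and no
ancestor propagation along the GO graph, deliberately, to avoid claiming
statistics the procedure does not compute.

## The synthetic study

Real gene-index and expression-warehouse inputs are external, versioned
databases; the generator replaces them with a seeded, internally
consistent study whose defaults are the package's reference conditions:

* 20 libraries of 2000–5000 ESTs (uniform), the first 6 being condition
  ("mycorrhizal-root" style, ids prefixed `#AM` to exercise `#`-prefixed
  id handling) libraries;
* 1000 TCs with lognormal(0, 1) base abundances; per library, 80% of the
  ESTs are allocated to TCs by weighted multinomial sampling (the rest are
  withheld as unassembled singletons, so per-library conservation holds by
  construction); 100 planted condition TCs are upweighted 10× in condition
  libraries only;
* two platforms with two condition-contrast expression columns each;
  reporter dropout 5% per platform, 10% chance of a second reporter;
  background values ~ N(0, 0.75), condition TCs shifted by an effect size
  of 2 on the log2-ratio scale (a strong but realistic contrast response;
  the same Gaussian family is used for both platforms, their differing
  semantics carried as metadata);
* a 50-term GO pool whose first tenth is reserved for condition TCs, so
  clusters acquire distinct predominant terms;
* everything deterministic given the seed (byte-identical file output),
  with the planted truth shipped in a manifest so tests never re-derive it.

TCs that receive no EST anywhere are removed, as they would not exist in a
real gene index. What the generator does **not** emulate: species-specific
library-size or GC distributions, assembly artifacts, cross-hybridization,
probe-level GeneChip summarization, or correlated noise between
experiments. Passing tests therefore demonstrate correctness of the
statistics and plumbing under a clean planted-signal model, not
performance on real hybridization data.

## Problem sizes and verification

The suite verifies the R statistic against an independently coded direct
evaluation on 1000 random instances (2–10 libraries, N_i up to 10⁵),
the filter against brute-force clause enumeration, the Ward merges against
an exhaustive objective stepper for n ≤ 8 with monotonicity checked up to
n = 200, cut refinement for all k ≤ 8, planted-signal recovery (≥ 80% of
condition TCs in the top R quartile; Rand ≥ 0.8 for the k = 2 cut) on
three fixed seeds of the full 1000-TC study, and byte-identical
end-to-end reruns on a 120-TC demo study. Export formats (profile CSV,
merge-table TSV, Newick, coordinate CSV) round-trip exactly; numeric file
output uses 17 significant digits so parsed doubles are bit-identical.

## Known limitations

* One reporter mapping to several TCs is allowed and each (TC, reporter)
  pair is treated independently; whether legacy pipelines deduplicated
  reporter reuse is unknowable.
* No BLAST execution, probe summarization, GO DAG traversal, alternative
  linkages, or interactive 3D viewing (coordinates are exported for
  external tools instead).
* R has no null calibration; treat it as a ranking score, not a p-value.
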