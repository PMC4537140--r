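---
title: "Methods: curating and meta-analysing palmitoylation proteomics studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and meta-analysing palmitoylation proteomics studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmeta)
```

# The problem

Protein S-palmitoylation — the reversible thioester attachment of palmitate
to cysteines — has been profiled by many independent proteomics studies,
each publishing a supplemental table of candidate palmitoyl-proteins. The
tables disagree in species (human, mouse, rat), identifier namespace
(UniProt entry names, Ensembl gene IDs, gene symbols, RefSeq accessions,
NCBI GI numbers), and detection chemistry (acyl-biotin exchange, acyl
resin-assisted capture, bioorthogonal fatty-acid labeling with or without a
hydroxylamine-cleavage control). `palmeta` turns such a collection of
per-study lists into one gene-level compendium and runs the downstream
meta-analysis: study clustering with bootstrap support, annotation-term
enrichment against an MS-proteome background, overlap testing against a
synaptic gene catalogue, and mining of disease mutations at cysteines with
palmitoylation evidence.

Because the original supplements are third-party journal files, the package
ships a synthetic-data generator that emulates every input with planted
ground truth. All tests, including the stochastic recovery checks, run
against generated data.

# Stage 1-2: identifier consolidation and the compendium

Each study table is resolved against a UniProt-style mapping database
(entry name, gene symbol, synonyms, full name, Entrez ID, species, reviewed
flag, plus Ensembl/RefSeq/GI cross-references). Resolution routes per
namespace:

* entry names, Ensembl genes, RefSeq accessions (version-stripped) and GI
  numbers match their own column;
* gene symbols try the primary symbol, then synonyms, then the full
  protein name — the first non-empty route wins, since primary names are
  more reliable than synonyms.

All matching is case-insensitive after whitespace trimming. We apply this
normalization on every route, not only symbols: mouse and rat symbol casing
differs systematically from human, and curated supplements frequently
change identifier case, while case carries no information in any of the
five namespaces. Identifiers are plain ASCII tokens in all supported
inputs, so no further Unicode normalization is performed.

When both reviewed (Swiss-Prot-style) and unreviewed (TrEMBL-style)
records match, only reviewed records are kept — manual annotation is the
higher-quality evidence. A species hint (the study's organism) then
prefers same-species records. Any residual ambiguity is broken
deterministically by the lexicographically smallest entry name, with a
logged warning; reproducibility is preferred over arbitrary dictionary
order. Unmatched identifiers are reported and excluded from the
compendium.

Records are collapsed into cross-species gene keys by uppercased gene
symbol (entry-name prefix as fallback for symbol-less records; on
conflict, the symbol route wins and the conflict is logged). Missing
species slots are filled from the database's reviewed records, inferring
homologs for genes not reported in all three species. The compendium then
holds one row per gene with a per-study 0/1 flag — set once per study no
matter how often the study reported the gene — per-method flags, the
study count, a neuronal/non-neuronal source class, and a confidence tier:

* `multi_method_with_HAM`: at least two methods including
  hydroxylamine-controlled bioorthogonal labeling (strongest evidence);
* `multi_method`: at least two methods;
* `multi_study`: at least two studies, one method;
* `single_study`: everything else.

The tier rule is evaluated in that order, so a single study that used two
methods (e.g. bioorthogonal labeling with and without the hydroxylamine
control) already counts as multi-method.

Curation exclusion rules (identifier + reason, per study) are applied
before matching; a rule that matches nothing warns rather than fails, so
rule lists can be shared across dataset revisions.

# Stage 3: study clustering

Studies are clustered on their gene presence/absence vectors with the
asymmetric binary (Jaccard) distance — discordant genes over genes present
in at least one of the two studies — and average linkage (UPGMA), with
ties broken by the lexicographically smallest pair of cluster labels.
Heights are reported as raw average-linkage distances (no halving), one
documented convention for all tests.

Support values follow the multiscale bootstrap: genes (rows) are resampled
with replacement at scale factors `r` in 0.5-1.4 (10 scales by default;
the resampling unit is genes because studies are the objects being
clustered and genes are the replicated observations). A clade counts as
recovered in a replicate only when its exact member set reappears — the
simplest well-defined edge matching. BP is the recovery fraction at scale
1; the approximately-unbiased AU value comes from a weighted least-squares
fit of `qnorm(1 - BP_r)` against `v * sqrt(r) + c / sqrt(r)` and equals
`1 - pnorm(v - c)`, the standard signed-distance/curvature convention
(AU tends to 1 for strongly supported clades). AU is reported as `NA` when
fewer than two scales are informative — never silently as 0 — and as 1
for clades recovered in every replicate at every scale. The default run
uses 5,000 samplings per scale, the convention for publication-grade
support values; at the full design scale (about 1,800 genes by 15
studies) 500-1,000 samplings already estimate BP to within about one
percentage point, which is why the test suite and the acceptance script
pass smaller counts explicitly, and the bootstrap loop reclusters with
`stats::hclust` for speed (the reference tree uses the package's own
deterministic implementation, and a test asserts both agree).

# Stage 4: enrichment

The background universe is the union of MS-proteome gene lists, with
compendium genes missing from that union appended, so the query is always
a subset of the background and MS-detectability bias cancels. Each
annotation term is tested with the one-sided (over-representation)
hypergeometric upper tail — consistent with the direction of the fold
enrichment `FE = (k/n) / (K/N)` — and corrected by Benjamini-Hochberg
within each annotation category, matching per-category reporting of
enrichment tables. A term is significant when `FDR < 0.001` **and**
`FE >= 2`; both conditions are required, the FE floor guarding against
huge, uninformative annotations that reach tiny FDRs on large queries.
Terms with fewer than 3 in-background genes are dropped (`min_term_size`,
configurable): one- and two-gene terms are unstable and uninformative.

Significant disease terms roll up to broad classes by first-match
keywords. The cancer pattern is applied before the nervous-system pattern:
histology names built on neural tissue ("neuroblastoma", "glioma") are
cancers, and a naive "neuro" keyword applied first would misroute them.
Unmatched names fall to `other` and are logged, leaving de-duplication of
repetitive annotations to the analyst.

# Stage 5: overlap

Overlap with an external gene list (a synaptic catalogue in the motivating
design) is tested on a 2x2 table built over the background universe with
disjoint cells — the only construction under which an exact test is valid.
The two-sided p-value uses the point-probability rule (sum of all
margin-fixed tables no more probable than the observed one), computed in
log space; membership joins on uppercased symbol. Both directions are
reported (list genes in the compendium; compendium genes in the list),
with percent overlaps, proportion-fold ratios, the sample odds ratio
(Haldane 0.5 correction only when a cell is zero), the conditional-MLE
odds ratio and its exact conditional confidence interval. No single
documented 2x2 construction reproduces every interval notation found in
the literature for such comparisons, so all variants are reported side by
side rather than privileging one.

# Stage 6: mutation mining

Disease mutation tables are parsed from `C6F`-style tokens (1-based
protein coordinates). Records must have a cysteine reference residue
confirmed by the sequence; mismatches are flagged `ref_mismatch` and
non-cysteine records `not_cysteine`. Passing records are classified by
strict precedence:

1. `known_palmitoylated` — position in the literature/annotation site
   list;
2. `predicted` — position in the supplied predictor output (predicted
   sites are an input file, never computed here);
3. `di_cys_adjacent` — an immediately adjacent cysteine (±1 residue);
   spaced pairs fall to the next rule;
4. `cys_rich_region` — at least `min_cys = 3` cysteines within some
   `window = 10`-residue window containing the site (both configurable;
   "cysteine-rich" has no standard definition, so the operationalization
   is exposed rather than hidden);
5. `no_evidence`.

A 21-residue context window, clamped at the termini, accompanies every
record.

# The synthetic-data generator

The generator's defaults encode the design of the motivating
meta-analysis, and they are fixed study conditions, not tuning knobs:

* 1,838 latent palmitoylome genes in a 17,858-gene background;
* 15 studies — 9 human, 5 mouse, 1 rat; three neuronal sources (mouse
  neural stem cells, mouse brain, rat synaptosomes); namespaces split
  across the five kinds; methods across ABE, acyl-RAC and bioorthogonal
  labeling (± hydroxylamine control);
* per-study detection probability 0.2: each gene of the latent
  palmitoylome is detected independently with this probability, giving
  roughly 250-450 genes per study, the observed range of individual
  palmitoyl-proteomics studies; planted-cluster studies share one
  Bernoulli detection profile (the two same-laboratory mouse studies by
  default), which is the simplest model that reproduces a tight,
  bootstrap-supported study pair;
* noise rate 0.117, split 50% case perturbation / 30% synonym
  substitution / 20% unmappable token. Case and synonym corruptions are
  recoverable by design, so the expected unmatched fraction is
  0.2 × 0.117 ≈ 2.3%, reproducing the ~97.7% average match rate of
  careful manual curation;
* annotation terms drawn so a term of size `K` has
  `k ~ Binomial(K, FE·n/N)` compendium genes — the expectation of the
  realized fold enrichment equals the target exactly while keeping
  genuine replicate-to-replicate randomness (decoys use `FE = 1`);
  a target with `FE·n/N > 1` is rejected as unattainable;
* a synaptic-style list whose overlap count is drawn from Fisher's
  noncentral hypergeometric distribution at the planted odds (default 7,
  list size 1,028), so odds = 1 reduces exactly to the central
  hypergeometric null and calibration tests are clean;
* protein sequences with cysteine-free backbones and planted sites on a
  40-residue grid — known, predicted, adjacent di-Cys, Cys-rich (three
  cysteines within five residues) and evidence-free — plus per-protein
  non-cysteine and reference-mismatch decoy mutations.

What the generator does **not** emulate: peptide- or spectrum-level
evidence, abundance, isoform ambiguity, method-specific false-positive
profiles (the chemistries fail in qualitatively different ways that no
published per-study error rates quantify), real typo distributions, or
correlated annotation structure (terms are sampled independently).
Passing the recovery tests therefore demonstrates that the pipeline's
statistics and bookkeeping are correct under a faithful presence/absence
model — not that any particular real protein is palmitoylated, and not
that the pipeline is robust to pathologies the generator does not model.

# Numerical and testing choices

* Hypergeometric tails come from `stats::phyper` (log-scale internally)
  and are verified against exhaustive draw enumeration for every
  parameter combination with `N <= 12`; the two-sided exact test is
  verified against full table enumeration for every table with `N <= 14`
  and random tables to `N = 40`, and against `stats::fisher.test`.
* The package's UPGMA is verified against a naive O(n³) re-scan oracle
  and against `stats::hclust` heights on random instances; the binary
  distance against the set formula and `stats::dist(method = "binary")`.
* Equal-distance merges and ambiguous identifier resolutions are broken
  lexicographically under C collation (`sort(method = "radix")`), so
  outputs are byte-identical across platforms and locales; determinism is
  asserted byte-wise in the tests.
* Stochastic recovery tests run at the full design scale (background
  17,858, compendium 1,838, 15 studies) with 100 enrichment replicates,
  200 overlap replicates and 500 bootstrap samplings per seed — sizes at
  which the Monte-Carlo error of each checked quantity is far below its
  acceptance margin.
* The GMT reader/writer is the package's own (the description field
  carries the term category, which established readers discard); a test
  cross-checks the gene sets against `fgsea::gmtPathways`.

# Known limitations

* Homolog inference is symbol-based; genes whose orthologs change symbol
  across species will not unify without a curated synonym entry.
* The compendium aggregates presence/absence only; it cannot weight
  studies by quality or size beyond the confidence tiers.
* AU values for clades at BP ≈ 0 or ≈ 1 across all scales are reported
  as `NA` or 1 rather than extrapolated.
* Disease-class rollups depend on the keyword map; domain-specific maps
  should be passed where the default's first-match order is too coarse.
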