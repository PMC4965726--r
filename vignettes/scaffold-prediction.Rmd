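---
title: "Predicting scaffold proteins from interactomes and domain architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting scaffold proteins from interactomes and domain architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffpred)
```

## The problem

Scaffold proteins organise signalling and metabolic reactions by physically
assembling two or more partner proteins. They are hard to recognise from
sequence alone: what defines them is a *structural capability* — holding two
partners at once — rather than a catalytic activity. `scaffpred` screens a
protein–protein interaction (PPI) network for proteins with that
capability, using three pieces of structural evidence per candidate
$s$ and partner pair $\{p_1, p_2\}$:

1. **Multiplicity** — $s$ interacts directly with at least two other
   proteins ($p_1, p_2 \in N(s)$, $p_1 \neq p_2$).
2. **Distinct-region recruitment** — there are domain–domain interactions
   (DDIs) linking a domain region $r_1$ of $s$ to a domain family of $p_1$
   and a *different* region $r_2$ of $s$ to a family of $p_2$. This is the
   step that separates scaffolds from **hub proteins**: a hub binds many
   partners *competitively* through one region and cannot hold two at the
   same time.
3. **Complex co-membership** — some catalogued protein complex contains
   $s$, $p_1$ and $p_2$ together.

Candidates are classified by which evidence they carry:

| Type | criterion 1 | criterion 2 | criterion 3 |
|------|-------------|-------------|-------------|
| I    | yes         | yes         | yes         |
| II   | yes         | yes         | no          |
| III  | yes         | no          | yes         |

Type I is the intended pattern; Types II and III exist because domain,
DDI and complex resources are incomplete, and requiring all three kinds of
evidence simultaneously would discard candidates that fail only through a
database gap. A protein passing criterion 1 alone is never reported.

Note that this is deliberately *looser* than the classical scaffold
definition (no catalytic activity, catalytically active partners, partners
interacting with each other): criterion 2 does not require the two partners
to interact, and nothing excludes candidates that are themselves enzymes.

## Decisions where the design was open

**Witness bookkeeping.** Evidence is recorded per partner *pair* (a
"witness"), not per region assignment: for a pair with several admissible
$(r_1, r_2)$ assignments only one deterministic representative is stored
(regions scanned in (copy index, family) order; the first admissible pair
wins). Recruitment of more than two partners is reconstructed downstream
from overlapping witnesses rather than enumerated, which would be
combinatorially explosive.

**What counts as a "different region".** By default two domain *instances*
are distinct, so two copies of the same family (e.g. tandem SH2 domains)
are two regions — they are distinct physical binding sites.
`region_semantics = "family"` requires two different families instead,
which is the conservative reading for pipelines whose domain assignments
are family-level only. Both are first-class and both are tested; the
default is the instance reading because it reflects the physics of
binding.

**Joint versus independent Type I.** `joint_witness = TRUE` (default)
calls Type I only when *one and the same* partner pair satisfies criteria
2 and 3 — the pair recruited through distinct regions is the pair found
with the scaffold in a complex. The independent reading
(`joint_witness = FALSE`: both criteria hold, possibly through different
pairs) is available as a flag. The joint rule is stricter and biologically
the more coherent statement of "the scaffold and its two partners exist
together simultaneously".

**Self-interactions** are stored but never counted as partners: a scaffold
must recruit two *other* proteins, and the method takes no position on
homodimers.

**Missing domain architectures.** A protein absent from the domain table
has an empty architecture. It can never satisfy criterion 2 but remains
eligible for Type III — structural resources are known to be incomplete,
and missing domain data should not veto complex evidence. A *partner*
without domains contributes no mediating region by default;
`require_partner_domain_known = FALSE` treats such a partner as
potentially compatible with every region of the candidate.

**Identifier handling.** Accessions are opaque, case-sensitive tokens.
UniProt isoform suffix stripping (`"P12345-2"` → `"P12345"`) exists as a
parser flag but is off by default, since silently merging isoforms changes
the network.

## Evaluation and association layers

Predictions are scored against gold-standard positive/negative accession
lists with the usual confusion-matrix panel (precision $a/(a{+}b)$,
sensitivity $a/(a{+}c)$, specificity $d/(b{+}d)$, accuracy, prevalence,
miss rate, fall-out, false omission rate). Metrics with a zero denominator
are reported as `NA`, never as 0. Percentages print with one decimal,
rounded half **up** (`format_pct()`), matching how such tables are
conventionally published; base `round()` rounds half to even and would
print 83.75 % as 83.7 %.

Group-versus-trait questions ("are Type I scaffolds enriched for disease
genes?") use a 2×2 table over an explicit protein universe with Pearson's
chi-square on one degree of freedom **without** continuity correction —
the plain observed-versus-expected statistic, which is also what the
published reference values for this analysis require — plus the risk ratio
$(a/(a{+}b))/(c/(c{+}d))$ and odds ratio $ad/bc$. A Yates-corrected
variant exists behind a flag. Rows are group membership, so the risk ratio
is orientation-dependent; chi-square and odds ratio are not.

Term enrichment is the hypergeometric upper tail
$P[X \ge k],\ X \sim \mathrm{Hypergeom}(N, K, n)$ — identical to Fisher's
one-sided exact test, which is also offered and gives the same p-values —
with Bonferroni or Benjamini–Hochberg adjustment. Terms absent from the
foreground are skipped. The background defaults to every protein in the
annotation map; pass an explicit universe when you have one, because the
background choice dominates enrichment results.

Scaffold–partner agreement (the `similarity` layer) asks, per type class,
how many scaffolds have any annotation ("known") and how many of those
share at least one term with at least one partner ("matched"). The match
rule is plain set overlap; no semantic similarity over an ontology graph
is attempted. The default scope compares against *witness* partners — the
recruited pairs are the scaffold's functional partners under the model —
with `all_partners` available for the permissive reading.

## The synthetic data generator

Real scaffold prediction needs curated PPI, Pfam, DDI and complex
snapshots that cannot be bundled. The generator builds complete synthetic
datasets with planted ground truth instead, one motif template per class
(see `sim_config()`): Type I plants the full pattern (two scaffold
families DDI-linked to two partners' families plus the triad complex),
Type II omits the complex, Type III keeps the complex but gives the
scaffold a single domain instance, and hub decoys get `hub_degree`
partners all docking through one region. Each motif draws its domain
families from a fresh namespace, and background proteins — wired among
themselves by an Erdős–Rényi rule — carry families that appear in no DDI
pair and belong to no complex. Consequently no accidental motif can form
and the planted labels are exact by construction, which is what makes the
noise-free recovery tests sharp. Dropout parameters then emulate
incomplete resources: `complex_dropout` erodes criterion 3 (Type I
degrades toward Type II), `ddi_dropout` erodes criterion 2 (Type I toward
Type III).

Annotations are planted so that a scaffold shares its localization and
pathway term with a witness partner at `annotation_match_rate`
(default 0.9, in the range of the agreement levels reported for real
predictions). Gold lists are the planted scaffolds (positives) versus hubs
plus background (negatives).

What the generator does **not** emulate: scale-free degree distributions,
correlated annotation structure, false-positive interactions, or
promiscuous domain families shared across unrelated proteins. Passing the
recovery tests therefore shows the engine implements its definitions
exactly — not that real interactomes are this clean. On real data the
dominant error source is resource incompleteness, which is exactly what
the dropout knobs probe.

Default sizes plant (5, 7, 3) scaffolds of Types I/II/III with 4 hub
decoys and 50 background proteins — every motif class exercised several
times while a whole dataset stays auditable by eye.

## Numerical and testing choices

* Ties are broken lexicographically everywhere (smallest qualifying
  complex id, sorted witness pairs, sorted output rows), so every run is
  byte-reproducible.
* The predictor is verified against a brute-force oracle that enumerates
  every (scaffold, $p_1$, $p_2$) triple and every region assignment, on
  200 random instances of up to 30 proteins covering both region
  semantics and both witness policies; recovery is checked across 20
  generator seeds. These sizes exercise every code path while keeping the
  default test run fast.
* The chi-square implementation is cross-checked against the closed form
  $n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ on 1000 random tables,
  and the hypergeometric tail against exhaustive enumeration of all
  $\binom{N}{n}$ foreground draws for $N \le 12$. A null simulation
  (2000 random foregrounds) confirms the enrichment test does not exceed
  its nominal type-I error.
* Degenerate inputs fail loudly: empty interaction files, overlapping gold
  lists, all-zero contingency tables and zero marginals are errors, not
  silent zeros.

## A worked example

```{r example}
d <- generate_scaffold_data(sim_config(seed = 42))
pred <- predict_scaffolds(d$net, d$arch, d$ddi, d$catalog)
prediction_counts(pred)

panel <- metric_panel(confusion(pred, d$gold_pos, d$gold_neg))
c(precision = format_pct(panel$precision),
  sensitivity = format_pct(panel$sensitivity))

partner_match_summary(pred, d$localization)
```

## Known limitations

* Predictions are binary; no reliability score ranks candidates.
* Only two-partner recruitment is certified; larger assemblies must be
  reconstructed from overlapping witnesses.
* Criterion 2 inherits every bias of the DDI resource: families without
  structural interaction evidence can never mediate a witness.
* The method is organism-agnostic and treats the input universe as given;
  it does not decide which interactions are trustworthy beyond the
  optional evidence filters.
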