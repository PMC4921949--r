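---
title: "Methods: variant-centric gene curation as a deterministic rules engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-centric gene curation as a deterministic rules engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genevalid)
```

## The model

genevalid operationalises a variant-centric view of clinical validity: the
question "does this gene cause this condition?" is deferred to the question
"does any clinically observed variant in this gene classify as pathogenic?".
This buys a single consistent lens — the variant-classification framework a
diagnostic lab already maintains — and removes the logical inconsistency of
calling a gene disease-causing while classifying every one of its observed
variants as uncertain.

The engine is fully deterministic. There is no fitted model and no
randomness anywhere in classification or assessment; the synthetic-data
generator is the only stochastic component and is seed-pinned.

### Evidence criteria

Each variant's evidence records map to weighted criteria:

| criterion | trigger | tier |
|---|---|---|
| segregation | combined LOD across families | strong / moderate / supporting by LOD cuts |
| functional | any assay with an aberrant effect | strong if mechanism-concordant, else capped at supporting |
| absence in controls | allele count 0 in a cohort of ≥ 10,000 alleles | moderate |
| population frequency | AF > 5×10⁻⁴ with allele count ≥ 5 | benign strong |
| case count | ≥ 3 unrelated probands of one condition | moderate, capped at supporting until that gene–condition link is strong |
| de novo | confirmed parentage | strong (retained when severe and infantile/childhood onset; otherwise capped when the link is not strong); assumed parentage starts at moderate |
| molecular consequence | nonsense / frameshift / splice / exonic deletion | very strong once the gene is proven, capped at supporting before |
| computational | pre-tagged in-silico support flag | supporting (never more) |

Independent families multiply odds, so per-family LOD scores are summed
before tiering; a combined multi-family value is stored as a single datum
with a family count. A `no_effect` assay contributes a supporting benign
criterion when no aberrant-effect assay exists for the variant.

Every cap records the original tier in `modulated_from`, so a report always
shows what the evidence *would* have been worth once the relationship is
established.

### Why the consequence cap keys on the gene, not the condition

The modulation cautions down-weight case reports by the relevance of the
presenting phenotype (condition-level) and molecular-consequence reasoning
by the understanding of the disease mechanism. Mechanism is a property of
the gene, not of one gene–condition pair, and the package anchors it to the
gene-level generic relationship ("GENE-related conditions"), which is
strong exactly when the gene is proven. The alternative — keying the
consequence cap to the specific observed condition — would make a
truncating variant permanently unclassifiable in a second condition whose
link is not yet strong, even in a long-proven loss-of-function gene, and
the known two-strong-conditions trajectories (recessive syndrome plus
heterozygous arrhythmia) would be unreachable from the conservative start.

### The combining table

Pathogenic requires one of: 1 very strong + ≥ 1 strong; 1 very strong +
≥ 2 moderate; 1 very strong + 1 moderate + 1 supporting; 1 very strong +
≥ 2 supporting; ≥ 2 strong; 1 strong + ≥ 3 moderate; 1 strong + 2 moderate
+ ≥ 2 supporting; 1 strong + 1 moderate + ≥ 4 supporting. Likely pathogenic:
1 very strong + 1 moderate; 1 strong + 1–2 moderate; 1 strong + ≥ 2
supporting; ≥ 3 moderate; 2 moderate + ≥ 2 supporting; 1 moderate + ≥ 4
supporting. Benign: 1 stand-alone, or ≥ 2 benign strong. Likely benign:
1 benign strong + 1 benign supporting, or ≥ 2 benign supporting. The empty
multiset is VUS.

Two conflict rules resolve contradictory evidence to VUS: co-occurrence of
strong evidence on both sides (≥ 1 very-strong/strong pathogenic with ≥ 1
stand-alone/strong benign), and simultaneous satisfaction of a
pathogenic-side and a benign-side row. A consequence worth documenting: the
usual monotonicity statement ("more benign evidence never moves a verdict
toward pathogenic") holds in the form *added evidence on one side never
enters or deepens the opposite side*. Adding a strong benign criterion to a
likely-benign multiset that also contains unused strong pathogenic evidence
moves the verdict to VUS — a loss of certainty forced by the conflict rule,
not a move into the pathogenic side. The test suite asserts exactly this
bounded form, and verifies the whole engine against an independent
row-scan oracle on all multisets with per-tier counts ≤ 5.

## Gene-level assessment

A gene is proven when some variant with at least one case observation
classifies pathogenic — evidence-only variants (e.g. a segregating variant
never curated into a case collection) do not count as clinically observed.
Strength assignment per (gene, condition):

* **strong** — ≥ 3 unrelated probands (distinct family ids) carrying a
  pathogenic variant and manifesting the condition;
* **emerging** — 1–2 such probands, gene already proven;
* **suggested** — no pathogenic variant, but a curated preliminary link
  (VUS-only case series, linkage, functional or animal data);
* **none** — otherwise.

A case manifests a condition when its condition id matches or when ≥ 60 %
of the condition's feature tokens appear in the case's phenotype features
(`phenotype_match`, configurable). The three-proband cut is a hedge against
expressivity coincidences and complex individual genotype, not a
statistical threshold; whether partial-phenotype matches should count
toward strong is deliberately left behind the configurable threshold.

For strictly recessive conditions a proband counts once and only when
biallelic: homozygous for a pathogenic variant, or compound-heterozygous
with *both* observed alleles pathogenic-classified. A multi-generation
segregating pedigree shares one family id and therefore counts as one
unrelated proband.

### The fixed point

Criterion assignment depends on gene status and link strength; those depend
on verdicts. `assess_validity()` starts maximally conservative — every gene
uncertain, every link not strong — and sweeps: classify all variants,
recompute statuses and assertions, repeat until the (verdict, status,
strength) state stops changing. Under this rule set verdicts never leave
the pathogenic classification once reached, statuses only move
uncertain → proven and strengths only upward, so the update is monotone on
a finite lattice and initialisation-order independence follows. The
reported `iterations` counts state-changing sweeps (the final verifying
sweep is not counted); the suite asserts it never exceeds the number of
genes + 1. The worked-example bundle converges in 2 sweeps: the first
proves genes through evidence-rich variants, the second reclassifies
variants (typically truncations) that needed a proven gene to escape their
caps.

### Phenotype expansion

For a gene asserted against two or more specific conditions at emerging
strength or above, each pair is judged in a fixed order: (1) if some
proband with a pathogenic variant manifests both conditions (by id or
feature overlap), the phenotype is **complex**; (2) else if the proband
sets are disjoint and the conditions' inheritance modes do not overlap,
they are **distinct conditions**; (3) else if the same pathogenic variant
appears in probands of each condition, **complex**; (4) otherwise
**not applicable**. The order matters: a founder truncation observed
biallelically in a recessive syndrome and heterozygously in a dominant
arrhythmia shares a *variant* across conditions but no proband, and the
inheritance-mode test correctly separates the two entities before the
shared-variant clause can fire.

## Panel design

The clinical-overlap map (presenting condition → underlying conditions that
can mimic or progress to it) ships as an editable JSON data file, not code:
it is a curated artefact and deliberately not comprehensive. Unspecified
cardiomyopathy/arrhythmia presentations are ordinary keys in the map, so
they may serve both as presenting features and as panel targets. Gene
classes are assigned with precedence proven-for-condition >
suspected-for-condition > proven-for-differential, so a gene strong for
both target and differential appears once, in its strongest role; genes
with only suggested links to a differential condition are excluded, since
the differential class requires conclusive proof. "Substantial proportion
of diagnostic yield" is a curated boolean per (gene, condition), with an
optional numeric fraction and a configurable fallback threshold
(default 0.05) when the flag is absent.

## Tunable parameters

All cut points live in one `rules_config()` object (units in parentheses):
segregation tiers 3.0 / 1.5 / 0.6 (log10 odds; 3.0 is the classical
linkage-significance bound, the lower cuts conventional halvings), benign
allele frequency 5×10⁻⁴ (proportion; suited to rare penetrant cardiac
disease, should rise with condition prevalence) with a minimum allele count
of 5, control-cohort floor 10,000 alleles, case-count/strong threshold 3
probands, phenotype-match fraction 0.6, yield-fraction fallback 0.05.

## The synthetic generator

`generate_synthetic()` builds bundles with construction-time truth: proven
genes receive one variant whose evidence dominates a pathogenic row from
the conservative start (LOD 3.2–4.5 over 2–4 families, a
mechanism-concordant assay, absence from 10⁵ control alleles) observed in
≥ 3 unrelated probands; uncertain genes receive only VUS-profile variants
(a single case report plus, with configurable proportions, weak segregation
LOD < 1.5, a non-concordant assay, or a common population observation) and
a preliminary case-series link. Generation is deterministic given the seed
and restores the session RNG state.

What this emulates is the *logical shape* of curated evidence, not its
messiness: real curation contends with conflicting case reports,
uncertain unrelatedness, partial phenotyping, and frequency estimates from
heterogeneous cohorts. Passing ground-truth recovery on these bundles shows
the engine implements its own rules faithfully — it does not show that the
rules themselves are complete for real literature evidence.

## Degenerate inputs and tie-breaks

Empty bundles assess to empty results; a variant with no evidence is VUS; a
condition with no feature tokens never matches by features; multiple
functional assays aggregate to a single criterion (concordant beats
non-concordant); multiple de novo cases keep the strongest qualifying one;
a cohort that is both "absent" and "common" is impossible by construction
(absence requires count 0), and frequency evidence takes precedence in the
population summary. Validation rejects non-finite LODs, inconsistent allele
counts, dangling references, duplicate ids, and misnamed generic
conditions, naming the offending record.

## Problem sizes

The shipped checks use: the 6-gene / 45-variant worked-example bundle; an
exhaustive 6⁷-multiset (279,936 case) sweep of the combining engine against
the row-scan oracle; 10⁴ randomized perturbation pairs for verdict
monotonicity; a 0–10 proband sweep for the strength thresholds; and 50
seeded synthetic bundles (default 10 genes each) for ground-truth recovery.

## Known limitations

Condition identity is a flat token vocabulary with feature-set matching —
no ontology reasoning; HGVS strings are syntax-checked tokens, never
normalised against transcripts; unrelatedness is exactly "distinct family
ids"; penetrance, onset and severity distributions, and mechanism
annotation beyond the concordance flag are out of scope; and in-silico
evidence enters only as a pre-tagged supporting flag, never computed.
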