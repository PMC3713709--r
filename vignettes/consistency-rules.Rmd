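---
title: "Flagging mispredicted proteins with consistency rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagging mispredicted proteins with consistency rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mispredqc)
library(dplyr)
```

## The problem

Gene prediction in intron-rich eukaryotic genomes is error-prone, and the
protein databases built on top of those predictions inherit the errors:
truncated proteins, chimeras fusing exons of unrelated genes, models missing
their targeting signals. mispredqc implements a quality-control engine built
on a simple premise: *a predicted protein is suspect when its annotated
features contradict what we know about how proteins work*. The contradictions
are cast as eleven consistency rules over three kinds of evidence:

1. **Domain content** — Pfam-style domain hits, some of which are
   *obligatory* for a compartment: families observed exclusively in
   extracellular, cytoplasmic or nuclear proteins.
2. **Membrane topology** — secretory signal peptides, signal anchors,
   transmembrane (TM) helices and GPI anchors, as called by the standard
   predictors (SignalP, PrediSi, TMHMM, Phobius, DGPI-class tools).
3. **Genomic provenance** — where the protein's coding segments align in the
   genome (BLAT PSL).

The engine does not run any of those predictors; it consumes their standard
output files, reconciles them, and judges consistency.

## The eleven rules

| id | fires when | rationale |
|----|------------|-----------|
| 1 | obligatory-extracellular domain, but no signal peptide, signal anchor or TM helix | extracellular material must be exported |
| 2 | extracellular **and** cytoplasmic domains, no TM helix | only a membrane pass lets both compartments co-exist |
| 3 | extracellular **and** nuclear domains | these compartments never mix in one chain |
| 4 | a domain hit far shorter/longer than its family's reference length | family lengths fall in narrow ranges; deviation means truncation |
| 5 | coding segments on two or more chromosomes | one gene, one chromosome |
| 6 | signal peptide **and** cytoplasmic domains, no TM helix | an exported protein cannot hold cytoplasmic domains |
| 7 | GPI anchor, no signal peptide | GPI-anchored proteins travel the secretory pathway |
| 8 | GPI anchor **and** cytoplasmic domains | a GPI protein is wholly extracellular |
| 9 | GPI anchor **and** nuclear domains | same |
| 10 | GPI anchor **and** TM helices | same |
| 11 | domain architecture absent from the known-architecture registry | architecture change is evolutionarily rare; novelty in a predicted protein is usually error |

Rules 3, 8 and 9 are deliberately unconditional co-occurrence rules: no
topology configuration rescues them. Rule 2 checks only the *presence* of a
membrane pass, not that it lies between the offending domains — topology-order
checking is out of scope.

Every rule reports evidence (the hits and features that triggered it), and a
record's report lists *all* conflicts raised, not the first one found.

## Consensus topology

The upstream predictors disagree routinely, and the combination policy the
rules see matters. The default policy is deliberately asymmetric:

* a feature is **present** if *any* predictor calls it;
* it is **absent** only when *every* predictor that voted agrees it is absent;
* a `"majority"` mode is available for users who prefer symmetric voting.

The asymmetry is the conservative choice for an error-flagging tool: most
rules fire on the *absence* of a signal, so demanding unanimous absence
minimises false flags caused by one predictor's miss. Spans of present
features are union spans of the supporting calls; helix calls are
interval-merged across predictors.

Two disambiguation layers sit on top of the votes:

* **Signal anchors.** None of the predictors' output formats carries an
  explicit "signal anchor" record — TMHMM and Phobius report an uncleaved
  N-terminal anchor as an ordinary TM helix. The consensus layer therefore
  classifies an N-terminal helix (start within `sp_tm_overlap_window`,
  default 45 residues) in the absence of a cleaved signal peptide as the
  signal anchor. Explicit `signal_anchor` votes supplied through the
  pre-annotated route are honoured as-is.
* **Effective TM helices.** Rules 2, 6 and 10 need *genuine* membrane
  passes. A helix overlapping the signal peptide/anchor within the first 45
  residues is the export signal, and on a GPI-anchored protein a helix lying
  entirely within the C-terminal `gpi_cterm_window` (default 40 residues) is
  the GPI attachment signal; both are excluded from effective counts. Rule 1
  intentionally uses the raw helix list: even an excluded helix witnesses
  *some* export signal.

If no predictor voted on a feature kind that a rule needs, the rule is not
silently passed: it is recorded as *skipped* with a reason, and the protein
can still be clean on the rules that were decidable.

## Thresholds and numerical choices

| parameter | default | why |
|-----------|---------|-----|
| `e_value_max` (domtblout) | 1e-3 | permissive enough to keep truncated domains (rule 4 must see them), strict enough to suppress noise |
| same-family hit merging | >50% mutual overlap, keep lower E-value | prevents double-counting in rules 1–3 and 11; ties broken by position |
| `size_rule_k` | 2.5 | flag when `|observed − reference| > k·sd`; ~1% two-sided under a normal length model |
| `size_rule_min_hmm_coverage` | 0.70 | fallback fractional bounds `[0.70, 1.30]·reference` for families without a recorded sd; `sd = 0` means fixed length |
| `sp_tm_overlap_window` | 45 | generous upper bound on signal peptide + anchor extent |
| `gpi_cterm_window` | 40 | typical GPI signal length |
| PSL `min_identity` / `min_coverage` | 0.95 / 0.80 | conservative same-genome alignment thresholds; top-scoring alignment kept per segment (score = matches − mismatches − gaps) |
| percentage rounding | half-up, 2 decimals | matches printed summary-table precision; base R's round-half-to-even would disagree on boundary counts |

Pfam accession versions (`PF01822.14`) are preserved for display but stripped
for every registry lookup and architecture comparison — family identity does
not change with model version. Architecture keys are the N→C ordered,
version-stripped family tuples with consecutive repeats collapsed by default
(so a tandem-repeat expansion does not count as a novel architecture);
comparison is exact ordered membership, with no clan-level grouping.

All coordinates are 1-based inclusive residue positions; each parser converts
from its format's native convention at the boundary (e.g. SignalP's reported
cleavage position is the first mature residue, so a positive call spans
`1..pos-1`; PSL query starts are 0-based half-open).

## Registries

Three reference resources drive the domain-aware rules: the
obligatory-localization lists, the domain-size references, and the
known-architecture list. These are user-supplied TSV/text files
(`load_registries()`); the package bundles a small **demo** set — a dozen
well-known families per compartment with hand-chosen reference lengths —
that is illustrative test data, not a curated production resource. The three
compartment sets must be pairwise disjoint ("obligatory" implies
exclusivity), and this is enforced at load.

The exact statistic behind the original domain-integrity criterion is not
recoverable (the curated reference tables are no longer hosted); the
mean ± k·sd criterion with the fractional fallback is this package's own
documented stand-in, with both knobs exposed in `engine_config()` and echoed
in conflict evidence for auditability.

## The synthetic-data generator

`generate_corpus()` builds deterministic corpora in which every record is
engineered to violate a chosen conflict set exactly — and nothing else — and
`emit_mock_tool_outputs()` serializes them in each predictor's native
dialect, so the parsers, the consensus layer and the rules are all testable
end-to-end without any external software. Two properties are enforced at
generation time:

* the engine itself is run on the freshly built corpus and generation fails
  if any record's conflict set differs from its plan (so the shipped
  expected reports can never drift from the engine);
* the same seed yields a byte-identical corpus.

One planted combination deserves a note: **rule 8 cannot be violated in
isolation.** Rule 8 requires a GPI anchor and a cytoplasmic domain; without
a signal peptide rule 7 also fires, and with one either rule 6 (no effective
TM) or rule 10 (an effective TM) also fires. A single-rule-8 request is
therefore rejected as an impossible plant, and rule 8 is exercised through
the documented `"6+8"` template. Similarly the engineered
extracellular + nuclear + GPI, no-signal-peptide record violates rules
{1, 3, 7, 9} — rule 1 has no GPI exemption, since a GPI anchor is not itself
an export signal.

What the generator does *not* emulate: realistic residue composition
(sequences are uniform-random with a Met start), predictor error profiles
(mock outputs are exact by construction), alternative splicing, or real
genome coordinates. Green tests therefore demonstrate that the machinery is
faithful to its stated logic on exactly specified inputs — not that the
upstream predictors are accurate on real proteins, nor that the demo
registries approximate the curated ones.

## Problem sizes used in the shipped checks

The package's own verification uses: the full 128-state boolean truth table
against an independently coded oracle; plant recovery on 20 seeded corpora
of 16 records each covering all eleven rules; emit/parse round-trip identity
on 5 corpora of 17 records; and exact recomputation of the published
database/species contamination percentages from their printed
analysed/flagged counts. These sizes exercise every code path while keeping
the default test run fast.

## Worked example

A secreted protein with a cleaved signal peptide and two extracellular
domains, the second truncated to 41 of its family's ~92 residues:

```{r worked}
reg <- demo_registries()
corpus <- generate_corpus(
  fixture_spec(seed = 1, n_clean = 2, planted = c("4" = 1)), reg
)
report <- evaluate_records(corpus$records, reg)
report
tidy(report)
glance(report)
```

The only conflict is rule 4, "domain size deviation", with the truncated hit
as evidence — the expected verdict for a gene model that lost an exon.

## Limitations

* The engine trusts its inputs: it cannot detect a predictor's false
  negative (e.g. a real signal peptide both SignalP and PrediSi missed).
* Obligatory-localization reasoning is only as good as the registry;
  families with genuinely dual localization must simply be left out of it.
* Rule 2 does not verify membrane topology order, rule 11 does not group
  families by clan, and CDD-style domain hits are not parsed — the engine
  standardises on Pfam-style accessions.
* Flagging is binary per rule; no error-likelihood score is produced, and
  the tool never attempts to *correct* a sequence.
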