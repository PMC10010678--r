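---
title: "Deciphering O-glycoprotease cleavage motifs from glycopeptide identifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciphering O-glycoprotease cleavage motifs from glycopeptide identifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMotif)
```

## The problem

O-glycoproteases (StcE, OgpA, IMPa and relatives) cleave protein backbones
only where specific O-glycans decorate specific sequence contexts. Their
substrate preferences must therefore be read out of site-localized
O-glycopeptide identifications: which residues flank the cleavage point,
which of them carry glycans, and which compositions are tolerated.
`glycoMotif` implements that readout as a deterministic pipeline over
identification tables (such as O-Pair Search `oglyco.psmtsv` exports,
normalized through a configurable column map):

1. **Filter** to the high-confidence glyco set: target records with
   q-value < 0.01, Level 1 localization, every site probability > 0.75, no
   N-glycosylation sequon (N–X–S/T, X ≠ P), length ≥ 5. Both comparisons are
   strict, matching the conventional thresholds. Unmodified records are
   dropped from the glyco set.
2. **Map** each peptide onto the search FASTA and classify each terminus as
   tryptic-like (protein terminus, initiator-Met clipping, or preceded
   by / ending in K/R) or protease-derived: categories `fully_tryptic`,
   `nterm`, `cterm`, `both`.
3. **Align** non-tryptic termini in a ±5-residue window: the peptide's first
   residue at P1′ for `nterm`, its last residue at P1 for `cterm`, two
   windows for `both`. Window characters come from the protein, gap-padded
   past the protein ends.
4. **Summarise**: per-position residue frequencies and information content
   (the sequence logo), percent of S/T residues observed glycosylated, and
   glycan composition distributions at chosen positions — the three panels
   of a peptide–glycan cleavage motif.

A declarative protease rule engine supplies in-silico digestion
(full / semi-specific / non-specific, missed-cleavage and length
accounting), and a glycan-conditional digestion simulator generates
synthetic datasets so the whole chain is testable by motif recovery without
any mass-spectrometry data.

## Statistics and conventions

**Information content.** For position $j$ with residue frequencies $f_{aj}$
over the 20-letter alphabet, $IC_j = \log_2 20 - H_j$ with
$H_j = -\sum_a f_{aj} \log_2 f_{aj}$ bits. Gap characters are excluded from
the frequency denominator: a padded position carries no residue evidence.
The small-sample correction $e(n) = 19 / (2 n \ln 2)$ can be subtracted
(clamped at zero); it is off by default and the report records which mode
was used, since logo-rendering services differ on this point.

**Percent glycosylated.** At each window position the numerator counts
windows with a localized glycan there and the denominator counts windows
whose residue at that position is S or T (serine and threonine summed)
*and lies within the identified peptide*. The restriction to the peptide is
deliberate: localization evidence cannot exist outside the identified
sequence, so a protein-context S/T two residues upstream of an N-aligned
peptide can never testify about its own glycosylation. Counting such
positions would systematically halve the apparent glycosylation at, for
example, P1′ of an enzyme that cleaves C-terminally to its glycosite
(every upstream fragment contributes a context-only S/T there). Positions
with an empty denominator serialize as the literal `NA`, never 0 — absence
of S/T is not a biological claim of 0% glycosylation.

**Counting unit.** Tallies default to identification (PSM) level; a
`"glycopeptide"` unit collapses windows by base sequence, site assignments,
side and locus first. Both units are first-class because summaries are
reported both ways in practice; per-file window counts are always emitted
so replicate-averaged figures can be reproduced downstream.

**Ambiguity and protein termini.** Peptides mapping to several loci are
dropped from motif statistics by default (each locus would contribute a
conflicting window); an enumerate-all policy is available. Protein termini
are treated as tryptic-like — they are not protease-cleavage evidence — so
terminal peptides contribute no window on that side.

## The rule engine

A `ProteaseRule` is a set of cleavage contexts over (P2, P1, P1′) residue
classes with cleavage between P1 and P1′, written compactly as `K|`, `|T`
or `[ST]x|[ST]`. Built-ins: Trypsin (`K|`, `R|`), Semi-Trypsin,
Non-Specific (all substrings, lengths 5–60), OgpA and IMPa (`|T`, `|S`),
StcE (`[ST]x|[ST]`), and combined X-Trypsin rules for sequential digests.
The engine is sequence-only by design: no mainstream search engine lets
cleavage depend on a modification, so glycan-conditionality lives in the
simulator, and combined rules exist precisely because an S/T-rich peptide
consumes the missed-cleavage budget fast (hence the budget of 12 on the
combined rules, versus 3 elsewhere; bounds 5–60 throughout — all
overridable per call).

```{r digest}
digestSequence("MKRPEPTIDEK", "Trypsin", missed = 0,
               minLength = 1, maxLength = 60)$peptide
enumerateCleavageSites("ATVTSG", "StcE")   # V3|T4: P2 = T2, P1' = T4
```

## The simulator: what it emulates, and what it does not

`SimulationConfig` + `GlycoproteinModel` describe a two-stage digestion of
synthetic glycoproteins. Glycoforms are drawn per instance: each S/T site
is occupied with its occupancy probability and occupied sites sample a
composition from a weighted menu. Cleavage is glycan-conditional: candidate
sites are the rule's sequence sites whose conditioning residue (P1′ for
OgpA/IMPa-style enzymes, P2 for StcE-style) is occupied; each is cut
independently with probability `efficiency`, multiplied by
`sialylationMultiplier` when the conditioning glycan carries NeuAc/NeuGc —
the simplest mechanism reproducing the known sialylation sensitivity of
OgpA, documented as a model choice, not a claim about enzyme kinetics. For
P1′-conditioned enzymes the default additionally requires an
un-glycosylated P1 residue, mirroring the established OgpA motif (a
decidedly non-glycosylated P1); this is switchable
(`requireUnmodifiedP1 = FALSE`). A complete trypsin stage (per-site miss
probability 0 by default) follows, emulating sequential protease
treatment.

Emission adds controlled noise: records sampled with replacement,
q-values with a configured fraction at/above 0.01, reversed-sequence
decoys with positions remapped, and false-localization events that move a
glycan to another S/T and downgrade the record below the Level 1
threshold. q-values are simulated, not estimated — the pipeline consumes
q-values and must be tested against controlled ones.

Simulator defaults are test parameters chosen once, not measured
quantities: five ~400-residue proteins at 20% S/T (mucin-like density),
occupancy 0.5, menu {Tn `N1` 0.3, T-antigen `N1H1` 0.7}, efficiency 0.9.
No quantitative cleavage efficiencies are published for these enzymes.
The simulator does **not** model spectra, intensities, retention times or
realistic FDR behaviour, and its occupancy draws are independent across
sites; passing recovery tests therefore demonstrates correctness of the
motif arithmetic and classification logic on idealized data, not
robustness to correlated real-world noise.

**Determinism and coupling.** All randomness flows from the single config
seed; identical configurations give byte-identical tables. A uniform draw
is consumed for every candidate site regardless of outcome, so re-running
the same seed at a lower sialylation multiplier yields a realized cut set
that is a subset of the original — the sialylation sweep
(`sialylationSweep()`, which emits one record per fragment) is monotone by
construction rather than approximately so.

```{r recovery}
models <- randomGlycoproteins(2, 250, 0.2, seed = 7)
cfg <- SimulationConfig(protease = "OgpA", nPSMs = 300L, seed = 7L)
res <- runRecover(cfg, models = models, nInstances = 8L)
round(pctGlycosylated(res$pipeline$report), 3)
res$cutPrecision
```

## Numerical and degenerate-input choices

- Zero-denominator percent values and all-gap information content are `NA`
  (serialized as literal `NA`).
- Frequency columns sum to 1 within 1e-9 wherever any non-gap residue is
  present; glycan tallies conserve every assignment.
- Malformed table rows are rejected with row-numbered errors by default;
  a permissive mode downgrades to warnings with a skipped-row count,
  because silent data loss corrupts motif statistics.
- An empty post-filter set, or a window set emptied by the fully-tryptic
  drop, raises an explicit "no cleavage evidence" error instead of an
  empty report.
- Candidate protease derivation (`motifToRule()`) takes, per position, the
  smallest residue class whose cumulative frequency reaches the threshold
  (default 0.9), falling back to the wildcard above four residues.

## Open choices made here

- The Level 1 filter and the 0.75 site-probability cut are both applied;
  Level 1 is defined via that probability upstream, so the pair is
  conservative and idempotent.
- The N-sequon test runs on the peptide sequence alone (filtering precedes
  mapping); a post-mapping context check for sequons split across the
  peptide boundary is out of scope here.
- The native O-Pair column headers are not standardized across versions;
  `metaMorpheusColumnMap()` ships plausible defaults, is fully
  overridable, and is validated against the canonical dialect.
- Shipped glycan databases under `inst/extdata/` are *synthetic* stand-ins
  (named accordingly) constructed from the published description of the
  12/22-composition sets; they parameterize simulations and validation
  only.

## Problem sizes used in the test suite

The suite exercises digestion-oracle equivalence on 500 random sequences
(length ≤ 80) across all built-in rules, window-extraction equivalence on
500 random loci, and motif recovery on five 400-residue proteins with 20
glycoform instances and 1000 sampled PSMs — sizes at which every recovery
statistic is stable while the whole suite runs in about two minutes.

## Limitations

Exact string matching only (no I/L equivalence); glycan compositions, not
structures; no recomputation of q-values or localization probabilities;
identification quality is taken at face value from the input table. The
candidate rules the pipeline emits are hypotheses for a refined search,
not definitive enzymology: nuanced requirements (such as glycosylation
required at P2 but merely tolerated at P1′) need defined substrates.
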