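# glycoMotif

Cleavage-motif discovery for O-glycoproteases from site-localized
O-glycopeptide identifications.

O-glycoproteases — StcE from enterohemorrhagic *E. coli*, OgpA from
*Akkermansia muciniphila*, IMPa from *Pseudomonas aeruginosa*, and a
growing list of relatives — cleave protein backbones only where particular
O-glycans decorate particular sequence contexts. Mapping those substrate
preferences requires aligning identified glycopeptides around their
non-tryptic termini and asking, position by position, which residues
appear, which S/T residues carry glycans, and which glycan compositions
are tolerated. `glycoMotif` is for glycoproteomics practitioners who have
identification tables (e.g. O-Pair Search `oglyco.psmtsv` exports) from a
sequential glycoprotease + trypsin digestion and want reproducible
cleavage motifs out of them.

## What it computes

Given identification tables and the search FASTA, the pipeline:

1. filters to the high-confidence glyco set (targets, q-value < 0.01,
   Level 1 localization, site probability > 0.75, no N–X–S/T sequon,
   length ≥ 5);
2. maps peptides onto the proteins and classifies termini against the
   tryptic boundary rule (`K|`, `R|`; protein termini and clipped
   initiator Met count as tryptic-like) into `fully_tryptic` / `nterm` /
   `cterm` / `both`;
3. aligns each non-tryptic terminus in a P5→P5′ window (peptide start at
   P1′ for N-terminal evidence, peptide end at P1 for C-terminal; two
   windows for `both`), reading context from the protein;
4. reports the three motif panels: per-position residue frequencies with
   information content IC = log2(20) − H (bits), percent of in-peptide
   S/T residues glycosylated, and glycan composition distributions at
   chosen positions (default P2, P1, P1′).

Around this sit a declarative protease rule engine (full / semi-specific /
non-specific digestion with missed-cleavage and length accounting;
built-ins: Trypsin, Semi-Trypsin, Non-Specific, OgpA, IMPa, StcE and
combined X-Trypsin rules) and a glycan-conditional digestion simulator
that generates synthetic glycoproteins and identification tables with
controlled noise, so motif recovery is testable end to end without
mass-spectrometry data.

## Worked example

Simulate an OgpA-style digestion (cleavage N-terminal to occupied S/T,
then complete trypsin) of five synthetic mucin-like glycoproteins, and
recover the motif:

```r
library(glycoMotif)

cfg <- SimulationConfig(protease = "OgpA", efficiency = 0.9,
                        nPSMs = 1000L, seed = 101L)
models <- randomGlycoproteins(5, 400, 0.2, occupancy = 0.5,
                              glycanMenu = c(N1 = 0.3, N1H1 = 0.7),
                              seed = 101)
res <- runRecover(cfg, models = models)
show(res$pipeline$report)
```

```
MotifReport over 758 window(s) [psm-level]
  position : P5    P4    P3    P2    P1    P1'   P2'   P3'   P4'   P5'
  top res  : T     S     A     S     T     S     S     T     S     S
  IC (bits):  0.27  0.16  0.10  0.18  0.21  3.32  0.22  0.07  0.13  0.14
  %glyco   :    80    28    25    13     0   100    50    23    21     3
```

Reading the panels: P1′ is an invariably glycosylated S/T (100%,
IC ≈ 3.3 bits — the S/T split costs one bit against log2(20)), P1 is
decidedly un-glycosylated (0%), and the flanks are unconstrained — the
OgpA signature. The glycan distribution at P1′
(`res$pipeline$report@glycanDistribution`) returns the simulated menu
(observed 0.67 / 0.33 against weights 0.7 / 0.3), and
`res$cutPrecision` is 1: every inferred cleavage coordinate is a true
simulated glyco cut. `runMotifPipeline()` runs the same chain on real
tables; with an output directory it writes `motif_report.tsv`,
`glycan_distribution.tsv`, `windows.tsv`, `mapped_peptides.tsv`, a
candidate protease definition derived from the motif, and a
`manifest.json` echoing configuration and per-stage counts.

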