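---
title: "Prioritising citrate-exporter candidates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising citrate-exporter candidates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cexscreen)
```

## The problem

*Aspergillus niger* secretes citrate at industrial scale, yet the plasma-membrane
transporter that exports it stayed unidentified for decades: there is no
substrate label to chase, and the proteome contains hundreds of
major-facilitator-superfamily transporters that all look alike. The screen this
package implements triangulates the exporter from three weak, independent
signals and one strong one:

1. **Sequence similarity to characterised citrate transporters**, captured by
   profile hidden Markov models built from seed alignments of proteins
   annotated for citrate transport.
2. **Producer/non-producer homology asymmetry**: a citrate exporter should be
   conserved in citrate-producing fungi (*A. kawachii*, *Yarrowia lipolytica*)
   and less so in close relatives that do not produce citrate (*A. flavus*,
   *A. terreus*, *S. cerevisiae*).
3. **Genomic proximity to citrate synthase (citA)**: fungal transporter genes
   often sit near the biosynthesis genes of their substrate.
4. **Condition-correlated expression**: across five strain/medium conditions
   of a two-strain RNA-seq design (producer NW186 vs parent NW305 under iron
   limitation, iron excess, and an arginine-to-citrulline supplement switch),
   the exporter should be induced exactly when citrate flux is high.

Signal 4 is the filter; signals 1–3 only generate candidates. Candidates from
all tracks are pushed through an ordered filter cascade and the survivors are
ranked by the log2 fold-change of the producer-vs-parent contrast under iron
limitation (`C1`), the condition most tightly coupled to citrate export.

## The filter cascade

Expression is summarised as **average nucleotide coverage** (avNtCov): per
replicate, `counts × read_length / gene_length` — the mean per-base read depth
of a gene — with mean and standard deviation taken over the two biological
replicates of each condition. The minimal criteria, applied to every
candidate in order and with per-criterion drop-out logging, are:

1. mean avNtCov ≥ 1 in all five conditions (the gene is expressed at all);
2. mean avNtCov ≥ 50 in `NW186 -Fe_a` (highest citrate production rate) and
   `NW186 +Fe_c` (highest overall citrate yield);
3. up-regulated in `C1` (`NW186 -Fe_a` vs `NW305 -Fe_a`);
4. up-regulated in `C2` (`NW186 +Fe_c` vs `NW186 +Fe_a`).

Homology-track candidates must additionally satisfy the stringent criteria:

5. at least one predicted transmembrane helix;
6. best-hit percent identity strictly higher in *A. kawachii* than in both
   *A. flavus* and *A. terreus*;
7. strictly higher in *Y. lipolytica* than in *S. cerevisiae*;
8. up-regulated in `C3` (`NW305 -Fe_a` vs `NW305 ++Fe_a`) — **advisory**: the
   parent strain shifts to oxalate production under iron limitation, so this
   contrast is a weaker proxy; notably the validated exporter CexA is itself
   C3-*down* (−1.75), which is why `soft_c3 = TRUE` is the default and
   criterion 8 is logged but non-blocking.

Two design points deserve justification:

* **"Up-regulated" defaults to lenient (`log2fc > 0`)** rather than the
  genome-wide differential-expression threshold (`log2fc ≥ 0.58` at
  FDR ≤ 0.05). The published shortlist retains rows with small and
  non-significant fold-changes, so the strict threshold cannot have been the
  gate for every track; both modes are exposed (`up_mode`).
* **Ties fail the asymmetry criteria.** "More similar" is read strictly; an
  equal identity in producer and non-producer carries no signal.

Survivors are ranked by descending `C1` log2 fold-change, ties broken by
ascending protein id, undefined fold-changes (zero-coverage genes) last.

## Expression model

CPM is plain library-size normalisation (`counts / column sum × 10⁶`); a gene
with mean CPM ≥ 1 counts as expressed. Fold-changes are
`log2((meanCPM_test + 0.5) / (meanCPM_ref + 0.5))`; the 0.5 pseudocount keeps
fold-changes finite for zero counts without materially biasing
well-expressed genes. P-values come from an exact conditional binomial test
on pooled replicate counts: conditioned on a gene's total count across both
groups, the test-group share is binomial with success probability equal to
the test group's share of the summed library sizes. Two-sidedness uses the
doubled-smaller-tail convention (`2·min(lower, upper)` tail, capped at 1),
which is computed in O(1) per gene from the binomial CDF; the
minimum-likelihood convention differs negligibly at these counts.
Benjamini–Hochberg adjustment is applied over all genes with defined
p-values. Genes with zero pooled counts in both groups are reported as
undefined (`NA`) rather than zero, mirroring the `#N/A` entries of the
published table.

No TMM/quantile normalisation or dispersion shrinkage is attempted: the
cascade consumes coverage thresholds and fold-change signs, not calibrated
per-gene inference, and the published per-gene values are treated as a
parsing fixture, not as numbers to reproduce (their normalisation is not
reconstructable; e.g. the printed 3.42 for the top candidate differs from
the log2 ratio of its printed coverages, 3.26).

## Profile HMM

`build_phmm()` follows the classic match/insert/delete architecture: columns
of the seed alignment with gap fraction < 0.5 become match states; emissions
and per-state transition distributions are maximum-likelihood counts with a
Laplace pseudocount of 1; the background distribution is the alignment's
overall residue frequency (gaps excluded, same pseudocount). The transition
set is `{M→M, M→I, M→D, I→M, I→I, D→M, D→D}`; the rare alignment paths that
would need `I→D`/`D→I` contribute their counts to `I→M`/`D→M`.

`forward_bits()` reports `log2 P(seq | model) / P(seq | background)`, summing
over all alignments. The model is **global in the model, local in the
sequence**: free flanking insert states at both termini emit background
residues at no cost, so a 600-residue multi-domain protein is not penalised
for carrying a transporter domain plus anything else. Numerically the
forward recursion runs in scaled linear space: values are kept relative to
an accumulated log scale and rescaled only when the row maximum approaches
the double-precision overflow bound. This is algebraically the standard
scaled forward pass and agrees with exhaustive path enumeration to 1e-9 in
the oracle tests, while being roughly an order of magnitude faster than a
log-sum-exp recursion at proteome scale. Viterbi scores (best single path)
are computed in plain log space and bound the forward score from below.

The score threshold for admitting HMM hits is genuinely unspecified in the
original screen; the package exposes `top_n` (default 25 of a 500-gene
synthetic proteome) instead of pretending to know a cutoff.

## Homology screen

Percent identity is computed from the optimal **global** affine-gap alignment
(BLOSUM62, gap open 10, gap extend 0.5; a gap of length L costs
`10 + 0.5·L`), as `100 × identical columns / alignment length`, gaps
included. Global alignment deliberately replaces a heuristic local search
tool: the screen compares full-length transporters, and the global optimum
is reproducible without seeding heuristics. Best hits are selected by
alignment *score* (not identity), ties broken by ascending id. Because
score-tied optima can differ in identity, `percent_identity()` canonicalises
its argument order, making the reported value symmetric. *A. nidulans* and
*A. fumigatus* appear in the original download list but in no criterion;
they are omitted from the predicate.

## Topology and proximity

Transmembrane counts are consumed from an external prediction table when
available. The built-in stand-in, `hydropathy_tm_count()`, is a deliberately
simple Kyte–Doolittle scanner: slide a 19-residue window left to right; on
crossing mean hydropathy 1.6, climb to the local maximum of the window mean
(so a helix is counted at its core, not at the first boundary window that
scrapes past the threshold — this also makes the count invariant to
prepended hydrophilic sequence), count one helix, consume the window,
continue. It is a documented convention shared with the synthetic generator,
not a re-implementation of a topology HMM.

The proximity track takes the `k = 10` genes up- and downstream of *citA*,
with distance measured in gene **ordinals** after sorting each contig by
coordinates — the screen's wording is "genes up- and downstream", not base
pairs — ignoring strand, excluding the anchor, truncating at contig ends.
Overlapping or nested genes keep distinct ordinals.

## The synthetic study

`generate_dataset()` emulates the study design so every stage is testable
without downloads: 500 genes × 5 conditions × 2 biological replicates of
negative-binomial counts with shared dispersion 0.05 (a typical bulk value
for near-isogenic replicates), per-sample depth drawn from a ±10% library
size band, background per-gene coverages lognormal (median ≈ 70,
sdlog 1.2, so roughly a quarter of background genes clear the avNtCov ≥ 50
key-condition bar) with **no systematic contrast**, and gene lengths of
300–2400 nt. The planted exporter is built as a moderately expressed gene
(baseline avNtCov 6) whose condition means encode induction under
citrate-producing conditions: multipliers (1, 2^e, 2^{2e}, 2, 2·2^e) over
(`NW305 ++Fe_a`, `NW305 -Fe_a`, `NW186 -Fe_a`, `NW186 +Fe_a`,
`NW186 +Fe_c`) give exactly +e log2FC in each of C1, C2 and C3 and, at the
default e = 3, coverages of about 380 and 96 in the two key conditions. Its
protein carries 12 hydrophobic 19-mers (AILVFM) between strongly
hydrophilic linkers so the hydropathy counter reports exactly 12; its
homologs are point-mutated copies ~78% identical in producer species and 15
points lower in non-producers, while background plasma-membrane proteins get
independently drawn identities (55–85%) with no systematic asymmetry; one
planted gene always lies within 10 loci of *citA*; and the seed alignment is
the planted protein plus five ~88%-identical mutants (one with a gapped
stretch), so the HMM track fires on it too. A planted effect of exactly 0 is
the accepted null configuration: the gene keeps every non-expression
signature but must then be removed by the expression cascade (effects in
(0, 0.58] are rejected as planting an undetectable signature).

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: read-level artefacts (mapping, multi-mapping,
GC bias), correlated or gene-specific dispersions, paralog families that
confound best-hit homology, operon-like co-regulation near *citA*, and real
transporter sequence structure beyond hydropathy. Recovery rates on this
generator validate the *pipeline logic*, not the biological discovery power
of the criteria.

## Self-checks and problem sizes

The test suite cross-checks each numeric kernel against an independent
brute-force oracle: forward scores against explicit path enumeration (models
with ≤ 2 match states, sequences of length ≤ 2), alignment scores and
identities against exhaustive enumeration of all global alignments (200
random pairs, lengths ≤ 8 with tractable products), and BH adjustment
against the hand formula (500 random p-vectors). The end-to-end study runs
the full pipeline on 100 seeded synthetic datasets at the default
conditions (planted gene rank 1 expected in ≥ 95), 100 null datasets
(minimal-criteria survival expected in ≤ 10), and 50 datasets for
fold-change parameter recovery (mean estimate within ±0.5 of the planted
3.0). `scripts/acceptance.R` recomputes the same quantities from scratch,
plus the re-ranking of the packaged published shortlist.

## Interfaces

All formats are plain text: FASTA (proteome, homolog databases, aligned seed
FASTA), a GFF3-like tab table of 1-based inclusive loci, a counts TSV whose
sample columns are `<condition token>_r<replicate>` (display labels such as
`"NW186 -Fe_a"` contain spaces and signs, so files use a fixed bidirectional
token mapping), a topology TSV, a YAML config, a shortlist TSV in the
published column layout (`mean ± sd`, `#N/A`), a per-criterion drop-out log
and a JSON run manifest. The R functions are the primary interface;
`run_all()` wires simulation → expression → HMM → homology → topology →
proximity → shortlist, and a thin command-line wrapper
(`inst/cli/cexscreen.R`) exposes the `simulate` and `all` entry points for
shell use.

## Known limitations

* The binomial test ignores biological overdispersion; with two replicates
  its FDRs are anti-conservative and should be read as ordering devices, not
  calibrated error rates (the default cascade uses fold-change signs only).
* Global alignment identity is not BLAST identity; absolute percentages
  differ from a local aligner's, though the screen only uses within-gene
  comparisons across species.
* The published per-gene fold-changes cannot be regenerated from public
  summaries, so the published table is used as a parser/ranking fixture
  only.
* With two replicates the coverage standard deviations are crude; the
  cascade thresholds means only.
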