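---
title: "mirloom: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirloom: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirloom)
```

mirloom analyses small RNA sequencing libraries for species without a
reference genome, using an EST collection as the mapping reference. This
vignette explains the models and procedures, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate about real data.

## Read model and preprocessing

Reads are collapsed into *unique reads*: identical full-length sequences
merged, with per-library occurrence counts. Reads differing in a single
nucleotide — or only in length — are never merged, so sequence
heterogeneity is preserved exactly. The internal alphabet is DNA (U is
converted to T on input; RNA-facing reports convert back), and all
human-facing coordinates are 1-based inclusive.

Preprocessing applies, in order: exact 3′ adapter trimming (longest read
suffix equal to an adapter prefix, minimum overlap 6 nt — the overlap
threshold is an explicit configuration, since exact-match trimming is this
package's own definition of the step), exclusion of reads containing N
(`poly_N`) or consisting of one repeated base (`homopolymer`), trimming of
trailing mononucleotide runs longer than 8 nt, an 18–30 nt length window
(mirroring gel size selection), a total-count filter (default ≥ 4 across
all libraries, the usual guard against sequencing-error artefacts when no
genome is available for error correction), and contaminant removal.
Contaminant matching removes a read iff it occurs exactly, full length, as
a substring of a contaminant reference **on either strand** — organellar or
viral reads can arise from both strands, so this step is deliberately not
strand-specific. Every step partitions its input (kept ∪ dropped = input),
so attrition accounting is exact.

## Annotation cascade

Classification is a fixed-order cascade; each read receives exactly one
category:

1. sense-perfect match to a protein-coding EST → `protein_coding`
   (degraded mRNA; strand-specific because the library protocol is);
2. a perfect match to a non-coding EST (either strand) is *recorded* and
   the read continues;
3. structural-RNA reference hit within ≤ 3 edits (gaps + mismatches,
   semi-global placement of the whole read, both strands) → the family's
   class (rRNA, tRNA, snRNA, snoRNA, other);
4. known-miRNA hit within ≤ 3 mismatches (ungapped) → `miRNA`, with the
   family label derived by stripping species prefixes and variant suffixes
   (`ath-miR156a` → `miR156`);
5. reads with a recorded non-coding hit → `noncoding_est`; otherwise
   `unmatched`.

The mismatch cap for the known-miRNA step is configurable
(`max_mismatches_mirbase`, default 3): the two natural readings of
"fewer than three" versus "three or fewer" differ by one unit, so the
bound is exposed rather than hard-coded. Ties across references at equal
edit count are broken by fewest mismatches, then reference order, and
affect only the recorded evidence, never the category. The search itself
is an exact dynamic-programming semi-global aligner (Rcpp): deterministic
and dependency-free where a BLAST-based pipeline would depend on external
binaries and scoring heuristics. BLAST-compatible score settings
(+5/−4, word 4) are kept in `align_params()` only as metadata for external
tabular interchange.

## Secondary structure

The builtin folder computes the minimum-energy *nested* structure
(no pseudoknots) under a deliberately simple stacking model: legal pairs
A:U, G:C, G:U with strengths 2, 3, 1; each stack of adjacent pairs
contributes minus the mean strength of its two pairs; each pair costs
+0.25 so isolated pairs never form; hairpin loops need ≥ 3 unpaired bases.
The optimum is found by dynamic programming over intervals with traceback
preferring helix continuation, and is verified in the test suite against
exhaustive enumeration of all nested structures for short sequences.

These energies are **not** on the thermodynamic (Turner/Mfold) scale. Every
`pair_table` is tagged with its backend, and `evaluate_candidate()` refuses
to score a fold against a regression trained on a different backend — an
MFE filter only makes sense when training and scoring share an energy
model. External structures (Vienna dot-bracket files, connect tables) can
be supplied through `read_dotbracket_file()` / `read_ct_file()` for use
with thermodynamic folders; the folding temperature (default 25 °C) is
recorded as metadata.

Terminology is fixed as follows, since informal usage overloads these
words: a *mismatch* is a symmetric 1:1 internal loop; a *bulge* is an
unpaired run on one strand only (larger asymmetric internal loops count as
bulges of their larger side); *continuous unpaired* is the longest unpaired
run within a span regardless of the opposite strand. This makes each filter
threshold a measurable quantity.

## Precursor prediction

Candidates are generated by placing mature reads on non-coding ESTs
(perfect placements for conserved and novel modes; ≤ 3 edits for the
reference-miRNA screen), folding **both strands**, locating the *core
region* (the stem segment aligned with the mature read), deriving the
miRNA\* and trimming the precursor to 10 nt outside the terminal
miRNA/miRNA\* pair before refolding. Overlapping placements on one EST are
deduplicated keeping the highest-count mature read — the most abundant
read is taken as the mature form.

The filter cascade evaluates, in order: (1) mature in the stem, not the
loop; (2) trimmed MFE inside the two-sided 95 % prediction interval of the
MFE-on-length regression; (3) terminal loop of the mature's arm ≤ 15 nt;
(4) ≤ 6 branches; (5) ≤ 1 core bulge of size ≤ 2; (6) ≤ 4 continuous
unpaired residues; (7) no loop or branch inside the core; (8) core
unpaired count within the length staircase (≤17 bp: 1; 18: 2; 19: 3;
20: 4; >20: 5). The verdict records the first failing rule. Each unpaired
core residue is counted once under rule 8 regardless of how rules 5–6
classified it — double-counting residues across rule families would make
the staircase unreachable for ordinary stems. The loop bound is applied to
the hairpin loop terminating the *mature's* helix; in branched structures
other arms' loops are irrelevant to whether the duplex is believable.

The prediction interval uses the standard OLS form
ŷ(L) ± t₁₋α/2,n−2 · s · √(1 + 1/n + (L − L̄)² / Sxx), cross-checked in the
tests against `predict.lm(interval = "prediction")`. A degenerate training
set (zero residual variance) is widened by a configurable ε (default 10⁻⁶)
so exact-line fits remain decidable. The interval is two-sided by default:
both unusually stable and unusually unstable hairpins are rejected; a
one-sided variant can be obtained by widening the confidence and ignoring
one bound, but is intentionally not the default.

The shuffle benchmark (`benchmark_precursor_filter()`) generates one
composition-preserving permutation per positive hairpin, evaluates it at
the same mature coordinates, and reports sensitivity and specificity with
a per-record audit. Shuffles are seeded explicitly and the seed is the
caller's to record.

## Novel miRNA calling

Novel candidates come from reads classified `unmatched` or `noncoding_est`
(20–24 nt, the observed mature size range), placed perfectly on non-coding
ESTs and passed through the full cascade. A call additionally **requires**
miRNA\* evidence: a library read exactly equal to the star sequence
(star start = partner(mature_end − 2), star end = partner(mature_start)+2,
the canonical 2-nt 3′ overhangs; unpaired positions are resolved by
extrapolating from the nearest paired neighbour). The star search default
is exact; a ± shift tolerance exists but is 0 by default, because evidence
standards for duplex support are exactness-based. The star read must be
present in the post-filter read set — i.e. it has itself survived the
total-count filter — which is the stricter and simpler of the two readings
of "found in our libraries". Since a perfect inverted repeat places a read
on both EST strands, calls are deduplicated per (read, EST) locus. Arm
labels (5p/3p) follow the mature's position relative to the terminal loop.

## Target prediction

The complementarity scan enumerates ungapped windows of the miRNA against
the transcript sense strand (miRNAs act on mRNAs; coding ESTs are
oriented). A window qualifies if it contains miRNA positions 2–12 (1-based
from the 5′ end), spans ≥ 17 nt ("over 16"), and opposes the site with
≤ 3 non-Watson–Crick oppositions — G:U wobble counts as a mismatch here,
even though it is a legal structural pair in folding; the two contracts
are intentionally distinct. Windows never end on a mismatch (trimming a
terminal mismatch always improves a local ungapped alignment, so such
windows are not reportable alignments); overlapping qualifying windows are
merged to the best (fewest mismatches, then longest, then leftmost).
Mismatches inside positions 2–12 are not restricted beyond the global cap
by default (`max_mismatches_seed` tightens this for users who want
seed-region stringency). The homology route joins each EST's best
protein-level hit (e ≤ 10⁻³⁰) against a known-target table, restricted to
families observed in the libraries. `merge_methods()` unions both routes
with method flags, and `detect_dual_site_transcripts()` reports
transcripts carrying ≥ 2 non-overlapping sites for one miRNA — the
signature of TAS-like transcripts.

## Expression profiling

RPM divides a count by the post-filter library total × 10⁶. The
specificity measure is computed per tissue; two variants are provided:

* `cosine` (default): SPM_i = x_i / ‖x‖₂ — the cosine between the profile
  and the idealised one-tissue vector;
* `squared`: SPM_i = x_i² / ‖x‖₂².

Both are scale-invariant, bounded in [0, 1] and map one-hot profiles to
one-hot SPM, and both reproduce every >0.9 tissue flag in the packaged
family table. They differ on borderline profiles: under the cosine variant
two unflagged families in that table (miR1318 flower, miR3946 root) also
exceed 0.9, while the squared variant separates flagged from unflagged
rows exactly — evidence that squared-variant computations produced the
flags. The default remains the cosine form, the more common reading of
the measure; users reproducing flag patterns exactly should select
`spm(x, "squared")`.

Fold-change selection uses max/min across libraries with a 0.01-RPM
pseudo-count for zeros (the denominator convention is otherwise
undefined); the same pseudo-count guards the log₂ transform. Clustering
is agglomerative with centroid linkage under the Euclidean metric,
implemented via `stats::hclust` on squared distances with heights
square-rooted back to the Euclidean scale (the Lance–Williams centroid
update is exact on squared Euclidean distances); the tests verify merge
heights against a brute-force greedy recomputation. Percentages are
reported to one decimal.

## Synthetic data: what it shows and what it does not

`simulate_dataset()` emulates the study design: four strand-specific
tissue libraries (root, leaf, flower, seed) of 18–30 nt inserts with a 3′
adapter, drawn from coding and non-coding ESTs, implanted conserved and
novel miRNA hairpins, structural-RNA and contaminant fragments, shuffled
decoy ESTs and random noise. Abundances are log-normal
(median 20, σ_log = 1) with a ×50 home-tissue multiplier, producing the
several-orders-of-magnitude RPM spreads seen in real family tables;
implanted mature and star totals are floored at 4 so implants carry
expression evidence. Implanted matures are drawn with realized GC in
[1/3, 2/3] — the same band as the regression training hairpins — so
implanted stems share the training energy–length relation; a GC-extreme
stem is precisely what the prediction interval is built to reject.
`make_hairpin_est()` verifies each hairpin with the builtin folder against
the full filter cascade and redraws flanks deterministically until
verification succeeds, which is what licenses the end-to-end tests to
demand *100 %* recovery rather than a rate.

Test problem sizes are deliberately modest: libraries of a few thousand
reads, ESTs of 150–400 nt, 8 implants and 3 decoys per dataset, 20
datasets in the recovery suite, 60 training hairpins for the default
regression. These sizes exercise every code path; they are not chosen to
stress throughput.

What passing does **not** show: the builtin energy model is not
thermodynamic, so recovery rates here do not predict recovery under Mfold
or ViennaRNA energies; real decoys are not composition-preserving shuffles
but genomic hairpin-like sequences, a harder negative class; substitution
errors at realistic rates interact with the count filter statistically,
while the recovery tests run error-free; and adapter trimming here is
exact-match, whereas real adapters suffer synthesis errors.

## Degenerate inputs and tie-breaks

Empty read sets, empty reference sets and structures with no pairs are
values, not errors, wherever a sensible value exists (empty tables,
zero-stem metrics); configuration gaps (no library columns, missing
reference sets, zero library totals) are errors. Unique-read ids are
assigned in deterministic sorted order (decreasing total, then sequence),
shuffles and simulations take explicit seeds, and alignment ties prefer
leftmost placements — reruns are byte-identical.

## Known limitations

The folder is O(n³) in sequence length and intended for EST-scale inputs
(≤ a few kb), not chromosomes; multi-branch structures are folded but the
mature arm must form a clean duplex to pass; the homology-transfer route
consumes precomputed tabular best-hit files rather than running protein
search itself; and the category cascade records only the single best
evidence line per read, so multi-family structural reads keep one family
label (the audit retains the recorded non-coding hit alongside).
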