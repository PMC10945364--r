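---
title: "Mapping endoribonuclease cleavage sites and predicting codon-limited targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endoribonuclease cleavage sites and predicting codon-limited targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endocut)
```

## The problem

VapC-family toxins of type II toxin--antitoxin systems are PIN-domain
endoribonucleases that typically cleave specific tRNAs in the anticodon loop.
When such a toxin is overexpressed, every cleavage event leaves a new RNA 5'
end at the cut position. A 5'-end sequencing library (adaptor ligation to
5'-monophosphorylated ends, after polynucleotide-kinase conversion of 5'-OH
ends) therefore shows a pile-up of read starts at exactly one nucleotide in
the toxin condition that is absent from an uninduced control. `endocut`
implements the computational side of that experiment for a bacterium with a
multi-replicon genome (a chromosome plus megaplasmids, as in rhizobia):

1. ingest aligned 5'-end reads into filtered, strand-aware, fractional
   per-position count tracks;
2. score each genomic position against its local background and call
   cleavage sites from the toxin/control score ratio;
3. derive a degenerate consensus around the cuts, scan candidate tRNAs and
   mRNAs for it, and ask whether cuts fall in the anticodon loop;
4. predict which proteins lose translational support when specific
   tRNA^Ser^ isoacceptors are destroyed, from the serine-codon composition
   of zone-specific transcripts.

Because the raw sequencing and nodule transcriptome inputs of such a study
are typically not redistributable, the package ships a first-class synthetic
data generator with planted ground truth; every downstream stage is tested
against what the generator planted.

## Counting rules

Alignment records enter as SAM or an equivalent tabular dialect. Two filters
are applied before counting, mirroring standard practice for 5'-end RNase
mapping:

* any record with a mismatch within the first 30 nucleotides of the read
  (counted from its 5' end; 0-based offsets, so offset 29 is removed and
  offset 30 kept) is discarded — early mismatches make the inferred 5' end
  untrustworthy;
* records whose strand disagrees with every annotated feature overlapping
  their 5' end are discarded; reads outside any feature are kept by default
  (`keep_unannotated = FALSE` drops them). The annotation's strand is the
  only orientation reference the data model carries.

Mismatch offsets are taken from the alignment record (`MD`/`NM` in SAM, an
explicit column in the dialect); no re-alignment is attempted. The filter
necessarily runs after alignment, since mismatches are only knowable then.

The 5' end of a `+` record is its leftmost base; of a `-` record its
rightmost. A read reported at `x` equally-best placements contributes `1/x`
at each placement, so every read carries total mass 1 — this is what lets a
cut in one of two identical duplicated tRNA genes surface in both copies.
`multimap = "primary-only"` instead counts only primary placements with
weight 1, for comparison. Replicates of a condition are combined per
position by the median (absent positions count 0); with two replicates this
equals the mean. A `stat = "sum"` mode exists for the alternative reading of
the replicate-combination step. No library-size normalization is applied
before scoring: the score below is scale-free for uniform depth changes, and
coverage normalization in such experiments serves browser display, not the
statistic.

## The score and the calling rule

For position $i$, with $m_k$ the replicate-median count at position $k$,

$$\mathrm{Score}(i) \;=\; \frac{m_i + 0.5}
  {\sum_{k \in W(i)} m_k + 10 \times 0.5},$$

where $W(i)$ is the 10 positions immediately upstream of $i$ *in transcript
orientation* ($i-1,\dots,i-10$ on `+`; $i+1,\dots,i+10$ on `-`), and the 0.5
pseudocount forbids zeros. A genomic-coordinate window would mis-handle
minus-strand genes, since the defining signature — many read 5' ends at one
nucleotide — lives on the transcribed strand. On a uniform track of depth
$c$ the score is $(c+0.5)/(10c+5) = 0.1$ identically, which the tests assert
exactly; peaks push it toward 1.

The cleavage ratio at $i$ is the toxin score over the control score, and a
site is called where the ratio **strictly exceeds 60** — the fixed
enrichment rule of this assay family, exposed as the `threshold` argument.
Positions whose upstream window crosses a replicon end are skipped rather
than padded (padding with pseudo-zeros inflates scores at ends). No
multiple-testing machinery is involved: the rule is a fixed ratio cutoff,
not a p-value, and no minimum absolute count is applied by default
(`min_median` is available). Called sites are annotated with the same-strand
containing feature (else "intergenic") and the ±10 nt context in transcript
orientation.

```{r calling}
sim <- simulate_genome(genome_spec(n_replicons = 2,
                                   replicon_lengths = c(15000, 15000),
                                   n_trna_genes = 6, n_duplicate_trna_pairs = 1,
                                   n_cds_genes = 24, seed = 1))
sim <- plant_motif_sites(sim, n_sites = 10, enrichment = 300, seed = 2)
aln <- simulate_reads(sim, read_sim_params(seed = 3))
tracks <- lapply(aln[c("toxin", "control")], function(reps)
  summarize_replicates(lapply(seq_along(reps), function(i)
    count_five_prime_ends(filter_reads(reps[[i]], sim$annotation),
                          replicate = i))))
calls <- call_sites(tracks$toxin, tracks$control, sim$annotation, sim$genome)
summary(calls)
all(paste(sim$sites$replicon, sim$sites$position) %in%
      paste(calls$replicon, calls$position))
```

## Consensus motifs and the anticodon loop

The cleavage consensus for this toxin family is written `CU(U/G)G^AA`: the
cut sits after the fourth base, and the called genomic position is the first
nucleotide of the 3' product. `consensus_motif("CUKG^AA")` captures exactly
that (IUPAC `K` = U/G). `build_consensus()` generalises aligned cut windows
column-wise to the smallest covering IUPAC code (`Biostrings::
mergeIUPACLetters`), trimming flanking all-`N` columns; the default
`min_fraction = 1` covers every observed base because the motivating
consensus covers both observed variants exactly, and a frequency threshold
is exposed for larger site sets. `scan_motif()` reports all (including
overlapping) occurrences with their implied cut positions.

Secondary structure is *accepted*, never predicted: a dot-bracket string per
target. A cloverleaf exposes three hairpin loops; the second, in 5'→3'
order, is the anticodon loop. Structures with any other number of hairpins
return "unknown" rather than guessing. Without a structure, a sequence of
tRNA length (60–95 nt) gets the standard-numbering heuristic interval 32–38,
flagged as heuristic. Simultaneous alignment-and-folding homolog search is
out of scope (mature external tools exist for it); instead
`minimal_motif_filter()` implements the exclusion logic that homolog
candidates lacking the minimal `G^AA` site cannot be physiological targets.

## Codon-based target prediction

Loss of a tRNA^Ser^ isoacceptor limits translation of messages rich in the
codons it decodes. Working on a zone-specific transcript universe (for a
nodule: genes specifically overexpressed in the nitrogen-fixation zone,
supplied as input — differential expression calling is upstream and out of
scope), the package counts the six serine codons per CDS in reading frame
and builds threshold lists on *absolute* counts (absolute numbers avoid
penalising short transcripts): at least 4 of a rare codon (UCU, UCA, AGU) or
at least 12 of a frequent one (UCC, UCG, AGC). The lists are named for the
isoacceptor genes they model: `serT` (≥4 UCA), `rare_serX` (≥4 UCU), `serX`
(≥4 UCU or ≥12 UCC), `serU` (≥12 UCG), `serV` (≥4 AGU or ≥12 AGC), plus
`ZIII+`, the highly expressed zone genes. For `ZIII+` the inclusive reading
`zone_reads >= 1500` is used (the boundary gene at 1499 is out, 1500 in),
with the operator configurable, since the two natural phrasings of the
cutoff ("above 1500" vs "n ≥ 1500") disagree at the boundary and the
inclusive form is the more precise statement. Codon-list membership is
computed on the supplied universe and intersected with `ZIII+` *afterwards*,
via exact Venn regions (every gene of the union in exactly one region);
the triple-overlap region is the headline prediction set.

Replicon bias — whether a megaplasmid carries disproportionately many
rare-codon-rich genes — is reported per replicon with a two-sided Fisher
exact test on each replicon pair's 2×2 table, Bonferroni-corrected over the
pairs. No particular test is canonical for this claim; the exact conditional
test was chosen for its validity at small list counts and is labelled as a
package decision in the output. `subset_representativeness()` compares a
subset's protein-length and serine-codon-frequency distributions to the full
universe (two-sample Kolmogorov–Smirnov plus quantiles) — a report, not a
gate.

```{r codons}
ze <- simulate_zone_expression(zone_expression_spec(seed = 4))
gl <- build_lists(ze$records[ze$records$zone_specific, ])
venn(gl, select = c("ZIII+", "serT", "serX"))
```

## What the generator emulates — and what it does not

The synthetic modules define the conditions every test runs under:

* **Genome**: 1–3 replicons (named chr/pSymA/pSymB) of random sequence at
  62% GC, carrying 85-nt tRNA genes and CDS genes of 300–900 nt on random
  strands, non-overlapping. Duplicated tRNA pairs are bit-identical copies
  on one replicon, ≥1 kb apart — far enough that 1/x counting is exercised
  without overlapping-feature ambiguity. Coordinates are 1-based inclusive
  throughout, matching SAM, so no translation happens at I/O boundaries.
* **Planted sites**: a concrete realisation of the motif is written into a
  chosen feature (reverse-complemented on `-`), the recorded coordinate
  being the first base of the 3' product. Planting into a duplicated gene
  mirrors the motif into the partner so the pair stays identical.
  Enrichment is the fold-increase of 5'-end starts at the cut in the toxin
  condition; 5'-end capture chemistry is modelled only as a per-site capture
  probability (default 1), because the scoring pipeline never uses chemistry
  beyond which reads exist.
* **Reads**: 150-nt single-end; per-position background start weights are
  uniform at `background_start_rate` (default 2 per transcribed position),
  so with the default library sizing per-position counts are approximately
  Poisson(2) i.i.d., the simplest background that exercises the
  median-across-replicates step; optional per-replicate scaling models
  library-size heterogeneity. A configurable fraction of reads carries an
  early mismatch (exercising the filter) or comes from duplicated genes
  (reported at both placements, `x = 2`).
* **Zone table**: 900 genes with 220 zone-specific (a tenth-scale analog of
  an 8933/2209-gene nodule study), log-normal normalized counts
  (meanlog = log 500, sdlog = 1.2 for zone genes, so a realistic minority
  clears the 1500-read bar), ~6% serine codons split by a GC-rich
  isoacceptor mix, and replicon labels with an optional rare-codon bias
  factor on one replicon. Ground-truth list labels are recorded from the
  *planted* codon counts, never recounted from sequence, keeping
  generator and analysis independent.

Not emulated: realistic sequencing error profiles, adaptors,
fragment-length effects, paired ends, transcription-start pile-ups,
RNA-structure-dependent capture efficiency, or correlated replicate noise.
Passing the planted-recovery tests therefore shows the statistic and its
implementation are correct under idealised noise, not that threshold 60 has
any particular sensitivity/specificity on real libraries — on real data the
threshold, the mismatch window and the multimap mode remain the analyst's
choices.

## Numerical and design notes

* Scores are computed on dense per-replicon vectors with cumulative-sum
  windows; tests pin them to a literal per-position evaluation of the
  formula at 1e-9, and the uniform-track closed form 0.1 exactly.
* The ratio is scale-free up to the pseudocount; with pseudocounts disabled
  (`pseudo = 0`, a test mode) it is exactly invariant under rescaling both
  conditions.
* Ties in ratio do not merge sites; each position is reported on its own.
  Sites are sorted by replicon then position.
* Windows crossing replicon ends yield undefined scores (skipped), so the
  first/last 10 positions of a replicon are never called.
* Degenerate inputs fail loudly and early: over-full replicons name the
  replicon, fully degenerate consensus columns raise "no informative
  columns", zero serine codons make relative usage an explicit error, an
  empty subset or mixed-condition replicate sets are usage errors.
* Problem sizes in the tests (10–30 kb genomes, 2×2 libraries of 2–10^5
  reads, 900-gene universes, 100-seed null batteries) were chosen so a full
  run completes in well under a minute while leaving every rule with a
  non-trivial number of events; they are stated here as the package's own
  reproducibility conditions.

## Limitations

The caller assumes single-nucleotide cut signatures; processive or ragged
cleavage would spread signal over adjacent positions and lower single-site
ratios. The orientation filter trusts the annotation; antisense transcription
of annotated features is filtered away. The anticodon-loop finder handles
cloverleaf dot-brackets only — tRNAs with long variable arms folded as a
fourth hairpin return "unknown". Codon-based prediction ignores translation
dynamics entirely (no ribosome modelling); it flags compositional
vulnerability, not measured translational loss.
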