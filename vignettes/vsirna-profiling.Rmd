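---
title: "Methods: virus triage, genome annotation and vsiRNA signature profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virus triage, genome annotation and vsiRNA signature profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visirna)
```

# Scope and model

`visirna` covers the computational spine of an insect-virus discovery
study: deciding which assembled contigs are genuinely viral, describing
the genome organisation of the viruses found, and quantifying the
virus-derived small interfering RNA (vsiRNA) population that an antiviral
RNAi response leaves in a small-RNA library. It consumes the standard
text formats produced upstream (FASTA contigs and genomes, FASTQ reads,
12/13-column tabular homology hits) and does not run assemblers or
aligners itself.

The underlying biological model is the canonical arthropod antiviral RNAi
pathway: replicating positive-sense RNA viruses expose double-stranded
RNA, Dicer cleaves it into siRNAs of a characteristic length (21 nt in
many insects), and the resulting vsiRNA population therefore shows (i) a
sharp length mode, (ii) near-equal derivation from both genome strands,
(iii) a 5′-terminal A/U preference, and (iv) uneven coverage with
pronounced hotspots. The profiler measures exactly these four statistics;
none of them presumes a mechanism, so the same statistics also serve as
negative evidence when a candidate virus lacks the signature.

# Contig triage

Candidates are screened with two inclusive thresholds: at least one
viral-reference hit with E-value ≤ 10⁻²⁰ and contig length ≥ 3000 nt.
Both defaults are the field's conventional desk-screen values for
full-length virus recovery from metatranscriptomes; both are
config-exposed. The E-value boundary is taken inclusively for symmetry
with the explicit "no less than" length rule.

Survivors are then classified by their single best hit in a comprehensive
search whose subjects carry a `viral`/`cellular`/`unknown` category. Best
means maximal bitscore, with ties broken by smaller E-value and then
lexicographic subject id — bitscore is the standard ranking and the two
tie-breaks make the verdict deterministic. A contig whose best hit is
`unknown` (or that has no hits) is `unresolved`, not viral: the entire
point of the second search is to remove false positives, so lack of
evidence must not promote a candidate. Because a contig can hit both
insect and virus proteins at similar scores, every verdict carries a
`margin` column (best-viral minus best-cellular bitscore) so borderline
calls are visible rather than silently resolved.

# Genome annotation

An ORF is a maximal ATG-initiated, stop-terminated span in a fixed frame
and strand. Per stop codon only the longest ORF is reported (first ATG
after the previous in-frame stop); nested downstream ATGs are suppressed.
The defaults — minimum protein 100 aa, positive strand only — reflect the
target organisms: positive-sense RNA viruses encode long polyproteins or
a handful of long ORFs on the genomic strand, and a 100-aa floor
suppresses the dense background of short spurious spans in any sequence.
All four criteria are arguments.

Translation uses the standard genetic code; codons containing `N`
translate to `X` rather than erroring, tolerating ambiguous assembly
positions, while an internal stop is an error because it contradicts the
ORF contract. UTR lengths are derived, not predicted: the 5′ UTR is the
start offset of the first (+)-strand ORF and the 3′ UTR the remainder
after the last, which for a single-ORF genome gives the familiar
`utr5 + orf + utr3 = genome length` decomposition. Overlap detection
between ORFs is purely interval arithmetic on half-open coordinates
(adjacent ORFs touching at a boundary do not overlap); whether an overlap
reflects a frameshift element is deliberately out of scope.

Internally every coordinate is 0-based half-open; report writers emit
1-based inclusive coordinates. The conversion happens only at the I/O
boundary, which is the cheapest place to prevent off-by-one drift.

# Zero-mismatch mapping

Reads of 18–30 nt (inclusive) are extracted, reads containing `N` are
dropped (exact matching against `N` is undefined; the count is logged),
and identical sequences are collapsed to (sequence, count) pairs. Mapping
is exact on both strands: a seed-and-verify index hashes every
`min_len`-mer of the genome to its offsets, a query is located through
its `min_len`-nt prefix and verified over its full length, and the
reverse complement of the query is looked up the same way for antisense
placements. Per occurrence the cost is independent of genome length,
which keeps 10⁴–10⁵-read libraries interactive on desk hardware.

Two conventions matter downstream. First, multi-mapped reads are reported
at **all** sites; counting weights each site by the read's count with no
fractional splitting. All-sites is the conservative superset — any other
policy can be recomputed from it, whereas a best-site policy destroys
information. Reports therefore quote both the per-site and the per-read
conventions where they differ. Second, the 5′ position of an antisense
placement is the **rightmost** offset of the matched span: the read's 5′
end in genome coordinates, which is what a mirror coverage plot of
Dicer products should anchor on.

# vsiRNA statistics

Every statistic is computed in two weightings: `unique` (each collapsed
read once per site) and `total` (weighted by read count). The two answer
different questions — sequence diversity versus molar abundance — and
diverge exactly when single species dominate, so both are always
reported. 5′-terminal composition is reported in the RNA alphabet (U for
T) at a configurable analysis length defaulting to 21 nt, the canonical
Dicer product; its A/U bias is `f(A) + f(U)`, with 0.5 the no-bias
baseline under a uniform composition.

Hotspots have no standard quantitative definition, so the caller is a
deliberate, fully exposed choice: smooth the per-offset 5′-start counts
with a centred moving sum of width 21 nt (one Dicer product), call
offsets whose smoothed value is positive and exceeds the 99th percentile
of all smoothed values, and merge calls separated by ≤ 10 nt. A quantile
threshold adapts to library depth without a free scale parameter; the
merge gap bridges the sampling gaps expected at realistic depths. All
three knobs are arguments, and callers comparing strands should hold them
fixed.

# The synthetic-data generators

The generators exist so that every stage can be tested against ground
truth without any external download, and their defaults encode the study
conditions the package is built around: a size distribution with 60 % of
reads at 21 nt (remainder spread evenly over 18–30), balanced strands
(sense probability 0.5), 5′ composition U 0.40 / A 0.35 / C 0.15 /
G 0.10 for 21-nt reads, and uniform start positions unless hotspot
intervals with rate multipliers are planted.

Genome generation plants each requested ORF (ATG start, stop terminus,
stop-free interior) into an i.i.d. background of the requested GC
content, places a stop codon immediately upstream of each planted start
where space allows, and repairs residual conflicts (overlapping ORFs in
different frames constrain shared codons) by randomised codon resampling;
chance ATG-initiated spans of ≥ 100 aa outside the layout are disrupted
with inserted stops. The result is a genome on which (+)-strand ORF
prediction provably returns exactly the planted coordinates. Planting is
implemented for the positive strand — the strand that matters for the
positive-sense viruses modelled here — and same-frame overlapping
layouts are rejected as infeasible (one ORF's terminal stop would sit
in-frame inside the other).

For the 5′-base law the generator stratifies candidate start positions by
the base they would put at the read's 5′ end and samples strata at the
target frequencies, instead of rejection sampling: the result is exact in
expectation, never loops, and fails loudly (advising a longer genome)
only when a genome offers no position at all for a required base.
Host-background reads are i.i.d. random sequences explicitly verified not
to match the genome on either strand, regenerated on collision — using a
real host transcriptome would reintroduce the external-data dependence
the generators exist to remove.

What the generator does **not** emulate: sequencing error and quality
variation (reads are modelled post-trimming), adapter remnants, genome
secondary-structure or Dicer-processivity effects on hotspot shape, host
reads that share k-mers with the virus, and multi-virus mixtures. Tests
passing on synthetic libraries therefore demonstrate algorithmic
correctness and statistical recovery, not robustness to upstream
wet-lab artefacts.

# Numerical and design notes

* Parsers are line-based, tolerate CRLF and missing trailing newlines,
  and map any residue outside `{A,C,G,T,N}` (IUPAC codes included) to `N`
  with a warning, since downstream exact matching treats `N` as
  never-matching.
* Report TSVs render doubles with 6 significant digits; percentages in
  the triage summary are rounded to one decimal, matching how such
  tables are conventionally quoted. An empty candidate set reports `NA`
  rather than 0 % host-derived.
* Degenerate inputs are defined, not errors: empty mapping sets give
  all-zero distributions and `NA` compositions/fractions; an all-zero
  positional profile gives an empty hotspot list.
* All generators draw from a single local RNG stream seeded from their
  spec (`withr::with_seed`), so results are bit-reproducible and the
  caller's RNG state is untouched.
* Problem sizes used by the test suite and the acceptance script —
  50,000-read libraries for parameter recovery, 100 × 20,000 reads for
  hotspot recovery in tests (20 simulations in the script), 200 (tests)
  or 50 (script) random mapper-oracle instances of a 5-kb genome ×
  1,000 reads — were chosen so each check has clear statistical
  resolution (e.g. ±0.01 recovery at n = 50,000 is ≈ 4.5 binomial SDs)
  while the whole suite stays desk-scale.

# Known limitations

* The mapper is exact-match only by design; a single mismatch (a real
  SNV, an RNA edit, a sequencing error) drops a read entirely.
* ORF prediction is ATG-initiated; viruses using non-AUG initiation or
  ribosomal frameshifts (the nidovirus ORF1a/1b junction) need external
  evidence — overlap detection reports the geometry but not the
  mechanism.
* The hotspot caller's quantile threshold always calls *something* on a
  strand with any signal; interpretation should lean on the reported
  peak heights, not the mere presence of calls.
* Triage trusts the subject-category column supplied with the
  comprehensive search; taxonomy lookup is out of scope.
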