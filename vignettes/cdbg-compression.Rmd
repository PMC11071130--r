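---
title: "Compressing colored de Bruijn graphs: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing colored de Bruijn graphs: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbgzip)
```

## The problem and the model

A colored de Bruijn graph is a family $E = \{E_0,\dots,E_{C-1}\}$ of k-mer
sets. Tools that operate on sequence collections — pan-genome analysis,
metagenome profiling, RNA-seq quantification — routinely reduce their input
to this form, and the resulting files are large enough that storage and
transfer dominate practical costs. Indexes over such collections support
membership and color queries but pay for that capability in space; a disk
codec does not answer queries and can therefore be considerably smaller.

`cdbgzip` stores the equivalent information as (i) the union k-mer set
$\bar{E}$ and (ii) for every k-mer its *color vector*, the $C$-bit
membership vector that doubles as the identity of its *color class*. Two
structural facts make this compressible:

* the number $M$ of distinct classes is usually far below $2^C$ (and below
  $|\bar{E}|$), so classes can be dictionary-coded;
* k-mers adjacent in the genome(s) almost always carry the same or a very
  similar class, so a sequence-aware layout turns the class sequence into
  long runs punctuated by small Hamming steps.

The layout is a *spectrum-preserving string set* (SPSS): strings
("simplitigs") whose length-$k$ windows, after canonicalization (a k-mer
and its reverse complement are one object, represented by the
lexicographically smaller string), enumerate $\bar{E}$ exactly once. The
SPSS both compresses the nucleotides — one base per k-mer plus $k-1$ per
simplitig instead of $k$ per k-mer — and fixes the global k-mer order in
which the color matrix is written.

## The codec

**Global class table.** Classes are sorted by numeric value (color 0 is
the most significant bit — a convention this package fixes and applies
everywhere) and assigned canonical Huffman codewords ("global IDs") from
their k-mer frequencies. The table is serialized as a delta stream
$\Delta$ (first class verbatim in $C$ bits; each later class as the
ascending list of differing color indices, one $\lceil\log_2 C\rceil$-bit
field each, floored at 1 bit so a field exists when $C \le 2$), a boundary
bitvector $b$ marking where each class starts in $\Delta$, and the
frequency list as decimal text. Frequencies alone regenerate the identical
codewords at decompression time because the Huffman construction is
deterministic: leaves are processed in (frequency, class value) order, a
leaf beats an internal node on equal weight, and codewords are assigned
canonically (shorter first, then by class value). $M = 1$ is degenerate
for Huffman and receives the empty codeword, so storing such an ID costs
only its type bit.

**Per-simplitig encodings.** The class sequence of a simplitig is emitted
left to right, one of four cases per k-mer:

| case | condition | bits |
|---|---|---|
| skip | interior k-mer, class equals both neighbours | none |
| small difference | $0 < h \le \textit{maxDif}$ vs predecessor | `10`, ($h$-flag when maxDif = 2), $h$ color indices |
| end of run | class equals predecessor; successor differs or simplitig ends | `11` (or `1` when maxDif = 0), run length |
| store ID | otherwise (always the first k-mer) | `0`, global or local ID |

Run lengths count the consecutive same-class *predecessors* of the closing
k-mer and are written as a unary quotient and a fixed-width binary
remainder with respect to `runDivisor`. The decoder emits exactly that
many k-mers at a run marker (the skipped interior plus the closer); the
run's opener was emitted by its own store/difference encoding. This is the
one reading of the run semantics under which the emitted count always
equals the simplitig's window count, so the decoder treats a zero run
length as corruption.

With *UseLocalID*, the simplitig's $\ell$ distinct classes (in
first-appearance order) go into a local table and stored IDs shrink to
$\lceil\log_2\ell\rceil$ bits (zero when $\ell = 1$). On disk the local
table spends $\lceil\log_2 M\rceil$ bits on $\ell - 1$ — storing $\ell$
itself could not represent $\ell = M$ in that width — followed by the
$\ell$ global codewords, which are prefix-free and hence parseable.

**Mode search.** All six combinations of maxDif ∈ {0,1,2} ×
UseLocalID ∈ {false,true} are encoded per simplitig and the cheapest kept
(cost = 3 metadata bits + $|m|$ + local-table bits). Ties go to the
smaller maxDif, then to global IDs, making archives reproducible. The
search is exhaustive rather than predictive because the trade-offs (the
extra run-type bit when maxDif > 0, the table overhead of local IDs)
depend on the simplitig's own class sequence.

## Tunable parameters

* `k` — k-mer length, set by the producing pipeline; every stage is
  generic in `k` (the fast paths assume nothing beyond `k ≥ 2`).
* `a` (abundance) — minimum count for a k-mer to enter a color when
  reading FASTA; 1 keeps everything, 2+ suppresses likely sequencing
  errors in read data. Applied per color across all its files.
* `runDivisor` — power of two splitting run lengths into unary quotient
  and $\log_2$-width remainder; default 16. Small values lengthen the
  encoding of long runs (larger quotient), large values tax short runs
  (wider remainder); 16 is a good middle ground for genomic run-length
  distributions and is recorded in the archive header.

## The greedy SPSS builder

SPSS construction is delegated to external tools by the compression
schemes this package follows; the codec is correct for *any* valid SPSS,
and archives simply differ in size with the decomposition. The built-in
builder is a deterministic greedy: seed with the smallest unused k-mer,
extend right then left, trying bases in `A,C,G,T` order and accepting an
extension iff the new window's canonical form is still unused. Windows may
sit in either orientation; membership is always tested canonically.
Determinism gives reproducible archives and honest size comparisons;
minimum-character decompositions are out of scope.

## The synthetic generator: what it emulates, what it does not

`synth_spec()` models a collection of $C$ related samples as shared random
backbones with per-color backbone dropout and independent per-base
substitutions. Dropout creates the block-structured classes and long
monochrome runs seen in real cohorts (where a sequence region is present
in a subset of samples); substitutions create rare classes and
Hamming-1/2 steps between adjacent k-mers. Defaults — 9 colors, 5
backbones of 2000 bp, substitution rate 0.001, dropout 0.2, k = 31 —
mirror a high-sharing, moderately divergent cohort at desk scale; k = 31
is the field's workhorse k-mer size.

The generator does *not* simulate sequencing reads (no coverage, no error
model — the abundance threshold is exercised with hand-built duplicated
records instead), no indels (substitution-only keeps run structure
interpretable), and no realistic genome composition (backbones are i.i.d.
uniform). A green round-trip over generated instances therefore
establishes losslessness and codec correctness over realistic *class
structure*, not size figures comparable with published benchmarks — those
depend on the exact SPSS and the entropy coder back-end of the original
tools, both deliberately substituted here (see below). Ground truth is
computed by re-counting the emitted sequences rather than by tracking
mutations, so a mutated k-mer colliding with an existing one is classified
correctly by construction. If dropout empties a color by chance the
generator retains one backbone (a color with no k-mers would make its
matrix column unrepresentable); `dropout = 1` is an error.

## Numerical and format choices

* Bit order: MSB-first within bytes everywhere; sections are zero-padded
  to byte boundaries and carry exact bit lengths in the directory.
* Index widths are per-field $\lceil\log_2\rceil$, floored at 1 bit
  (degenerate $C \le 2$, $M = 1$); nothing is amortized fractionally.
* The archive uses unsigned 32-bit header fields (practical desk-scale
  limit $2^{31}-1$ k-mers), CRC32 per section, and DEFLATE as the generic
  byte compressor. A succinct bitvector (RRR-style) back-end would be the
  natural choice if rank/select queries were ever needed; for pure disk
  storage a stream compressor preserves losslessness at comparable size
  and keeps the format dependency-free.
* Decompression validates everything it touches: magic/version, CRCs,
  section lengths, boundary/delta consistency, ascending reconstructed
  classes, run lengths, emitted k-mer counts, and trailing bits. A
  truncated or tampered archive fails loudly rather than yielding partial
  output.
* Sorting of k-mers and classes uses C-locale (radix) order so archives do
  not depend on the session locale.

## Known limitations

* No queries on the compressed form; decompress first.
* Single-threaded; the mode search is exhaustive but cheap relative to
  k-mer counting at desk scale.
* The SPSS is greedy, not minimum-size; archives are a little larger than
  with an optimized decomposition.
* FASTQ input is read as sequences only; qualities are ignored.
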