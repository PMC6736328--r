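---
title: "Assembly methods in rnaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly methods in rnaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaforge)
```

# Overview

rnaforge is a de novo transcriptome assembler for paired-end short-read
RNA-seq. It follows the single-cell-style de Bruijn graph paradigm: RNA-seq
coverage is as uneven as multiple-displacement-amplified single-cell data,
so the assembler never uses global coverage cutoffs to decide what is real.
Instead it relies on graph topology, sequence similarity and *relative*
coverage, and treats every dead-end edge as a potential transcript
terminus rather than an artefact.

The pipeline is: canonical k-mer counting, condensed bidirected de Bruijn
graph construction, RNA-specific simplification, a second graph pass at a
larger k seeded with the first pass's edges, read-pair gap closing,
isoform-aware path extension, and tiered filtration.

# The condensed bidirected graph

Vertices are (k-1)-mers and edges are maximal non-branching paths carrying
their full nucleotide sequence, the mean canonical-k-mer coverage `cov(e)`,
and, for stranded libraries, strand-specific coverages `cov+(e)` and
`cov-(e)`. Every edge has a reverse-complement twin; all operations remove,
split or merge twin pairs together, so twin symmetry is an invariant the
test suite checks after every procedure. k is required to be odd so that no
k-mer is its own reverse complement; palindromic *edges* can still arise
and are stored once, flagged `self_rc`.

# Simplification

Five cleaning procedures run in a fixed order (tips, bulges, chimeric
loops, hairpins, isolated edges), re-condensing after each, iterated to a
fixed point. The order mirrors the narrative order of the procedures; any
order reaching a fixed point would be acceptable, but a fixed one keeps
runs reproducible.

**Tip clipping.** A tip (edge with a dead end) of length `l` and coverage
`c_T` is removed if any of: `l < 2k` and `c_T <= 1`; `l < 4k`,
`c_T < c_A/2` and Hamming distance to the alternative edge at most 3;
or more than 80% A/T content (poly-A artefacts). The alternative edge used
for the similarity rule is the highest-covered other out-edge of the
shared vertex -- it is the presumably correct sequence -- and the Hamming
distance is computed over the aligned prefixes extending from that shared
vertex, which is the natural anchoring when both edges leave the same
(k-1)-mer. Tips that are genuine alternative first/last exons differ from
their alternative by much more than 3 mismatches and survive, which is
what allows isoforms differing only in terminal exons to be recovered.

**Bulge collapsing.** Only *similar-length* parallel edges (relative
difference below 10%, computed as `|l1-l2| / max(l1,l2)`) are collapsed;
no coverage threshold is applied, because exon-skipping isoforms produce
parallel edges of clearly different lengths while sequencing errors and
allelic variants produce near-equal ones. The higher-covered edge wins
(ties break to the lexicographically smaller sequence for determinism) and
absorbs the loser's k-mer mass, so total graph mass is conserved.

At realistic error rates the detour generated by one substitution is a
single edge of length `2k-1`, but the *correct* counterpart is usually
subdivided by the branch points of other nearby detours, so the two-edge
case alone stalls. The package therefore also collapses a single edge that
runs parallel to a *multi-edge path* between the same vertices under the
same 10% length rule, removing the single edge only when its coverage does
not exceed the path's mean coverage and projecting its mass onto the path.
The search is a bounded depth-first walk (candidate edges up to 500 bp,
400 search states), which comfortably covers error detours while keeping
the pass linear in practice.

**Chimeric loops and hairpins.** Template-switching artefacts fall into
two topological classes, detected without using sequence or coverage: a
self-loop at a vertex of total degree three whose single other incident
edge is long (the signature of a junction connecting a transcript end back
into itself), and a hairpin edge connecting a vertex to its own twin
vertex -- equivalently, an edge whose twin shares both of its endpoints --
hanging off real sequence. Both are removed together with their twins. A
self-loop at a vertex with other through-traffic (a genuine tandem
repeat) and an inverted-repeat edge whose endpoints are not twins are
left alone.

**Isolated edges.** Edges with no neighbours at either end are dropped
when coverage is below 2 *and* length is at most the read length: these
are reads whose every k-mer carries an error, or trace contamination.
Both conditions are strict boundaries, tested as such.

# Two-pass construction and k-mer sizes

The main k is the largest odd number not exceeding `read_length/2 - 1`;
the lower k is the largest odd number not exceeding `read_length/3`,
floored at 29 (below that, unrelated transcripts share k-mers too often
and chimeric junctions multiply). For 100 bp reads this gives k = 33 and
49. If the floor collides with the main k the assembler runs single-k.

Pass 1 builds and simplifies the graph at the lower k. Pass 2 rebuilds at
the higher k from the reads *plus* the pass-1 edge sequences: k-mers of
those edges that have no read support at the higher k enter the table with
presence count 1 and are flagged protected. Protected edges are exempt
from the two coverage-based removals (short-low-coverage tips and isolated
edges) -- they are exactly the low-coverage stretches only the smaller k
could bridge -- but coverage itself is always computed from reads, and
similarity- and topology-based cleaning still applies to them.

**Gap closing.** Remaining dead ends are joined when (a) their sequences
share an exact suffix-prefix overlap of at least `L_ov = 8` bp and at
least `N_ov = 1` read pair connects them, or (b) at least `N_min = 5`
pairs connect them regardless of overlap. In case (b) the junction is a
direct concatenation at the median pair-implied offset (the true gap
sequence is unknowable; inserting N runs would only push the problem
downstream); a negative implied gap falls back to a short exact overlap of
at least 4 bp, else the pair is left unglued. A tip with several eligible
partners is never glued, and a tip is never glued to its own twin.

# Isoform reconstruction

Paths are seeded at the longest edge not yet covered by any path and grown
in both directions (the reverse direction by growing the twin path
forward). At each step the candidates are the out-edges of the terminal
vertex, scored by read-pair support: the score of candidate `e` is the
number of read pairs with one mate anchored within one insert-size window
of the path end and the other mate anchored on `e` in consistent
orientation. Every candidate with score above both `theta = 1` and
`max_score / C` with `C = 1.5` is selected; the path forks into one copy
per selected edge, which is what reconstructs several isoforms of one
gene. Because the score is a raw pair count it does not favour
highly-expressed isoforms over rare ones.

Anchoring is exact-k-mer based: every oriented edge that collects unique
k-mer hits of a mate is a placement of that mate. Recording *all*
placements (rather than a single majority vote) matters because junction
edges shorter than the read length would otherwise almost never win a
vote and would starve of pair support.

**Coverage fallback.** When the pair extender is silent and exactly two
extensions compete, the most recent vertex with an off-path incoming
alternative arbitrates: extension `e` (the higher-covered candidate, with
`e'` its competitor and `e2`/`e2'` the on-/off-path incoming pair) is
taken iff `cov(e) > delta*cov(e')`, `cov(e2) > delta*cov(e2')`,
`omega > cov(e2)/cov(e) > 1/omega` and `cov(e) > C_min`, with
`delta = 2`, `omega = 10`, `C_min = 2`. The first two demand a clear
expression difference, the band demands coverage persistence along the
path, and the floor keeps the rule away from noise-level edges.

**Stranded libraries.** Strand-specific coverages are computed by
orienting each mate to the transcript strand (for RF the first mate is
antisense) and mapping positionally. Three mechanisms use them: edges
whose two halves are dominated by opposite strands (dominance ratio at
least 10 with at least 1x support -- the concrete reading of "much
greater") are split into two detached edges; extension candidates whose
strand dominance opposes the path's are rejected, which prevents walks
from leaking into reverse-complement shadow paths where two transcripts
share a long reverse-complement region; and the coverage fallback runs on
forward-strand coverage. Finally each path is emitted in the orientation
with the higher forward-strand coverage. For unstranded data orientation
is the lexicographically smaller of sequence and reverse complement, so
output is deterministic.

**Deduplication** removes only exact duplicate edge lists and contiguous
sub-lists (twin-reversed copies count as duplicates for unstranded data).
Nothing else is trimmed: isoforms that differ by one short exon must both
survive. Forked paths that later reconverge are kept as separate paths and
left to deduplication. Each edge may repeat at most 4 times within one
path, a termination guard for cyclic graphs.

# Filtration

Non-mRNA contamination is mostly short, weakly covered and isolated in
the graph. Three presets trade sensitivity for specificity, and their
outputs always form a chain (hard within normal within soft):

| preset | min length | min coverage | drop isolated below |
|--------|-----------:|-------------:|--------------------:|
| soft   | 0          | 0            | read_length / 2     |
| normal | 0          | 1.0          | read_length + 1     |
| hard   | 200        | 2.0          | 2 x read_length + 1 |

These values are this package's own calibration (configurable per run),
chosen so that `normal` removes the single-read artefact class while
`hard` additionally applies the 200 bp reporting cutoff common in
assembly benchmarking.

# The synthetic-data generator

The generator is first-class, tested code and defines the package's
reference study conditions: 50 genes with two isoforms each (skipped
internal exon, alternative first or alternative last exon; exons 80-250 bp
so every event is longer than any assembly k), log-normal expression
(sdlog 0.5), 2 x 100 bp pairs at 20x mean coverage, insert 200 +/- 20 bp,
0.5% substitution errors, 1% chimeric pairs, and a 15 nt poly-A tail that
exercises the low-complexity tip rule. The insert size follows the
read-length-100 libraries in published benchmark sets (inserts about
170-240 bp), which also means mate pairs nearly abut and short transcripts
are covered through their middles. Fragment placements may overhang the
transcript ends and are clipped, the way real fragmentation produces
shorter terminal fragments; without this the last tens of bases of every
transcript would be systematically unsampled, which is a library artefact
rather than an assembly property.

Chimeras are modelled as template-switching during reverse transcription
of the pair's own fragment, in two classes. Loop chimeras slip a short
distance (20-60 bp) back from the 3' end and re-copy the terminal segment
as a rolling repeat; in the graph this condenses into exactly the
self-loop topology the loop remover targets, and removal costs the
transcript at most the slip distance off its 3' end. Hairpin chimeras
fold back exactly onto the opposite strand, producing a palindromic
junction edge whose removal costs nothing. Fold-backs dominate the
mixture (80%), matching the observation that the polymerase usually jumps
to the opposite strand. Substitutions only, no indels: the tip and bulge
rules target substitution artefacts, and indel-type errors are rare in
Illumina data.

Every stochastic call flows through the single config seed, and the
generator is byte-reproducible (tested). What the simulation does *not*
model: empirical quality profiles, PCR duplicates, intron retention,
positional fragmentation bias, and expression heavier-tailed than
lognormal(0, 0.5). Passing the recovery bar on this data therefore shows
the algorithm's correctness on clean-but-erroneous input, not performance
parity on real libraries.

# Evaluation

Contigs are aligned to the reference by exact 31-mer chaining: hits on a
common diagonal band (40 bp) form segments, segments merged across gaps
up to 1 kb. Each contig is assigned to the reference holding its longest
single segment (an exon-skipping contig tiles the longer isoform in two
abutting segments but its own isoform in one). A reference transcript is
X%-assembled iff a single contig's alignment covers at least X of its
length; database coverage is the covered fraction of all reference bases;
duplication ratio is aligned contig bases over covered reference bases. A
contig is misassembled iff no single colinear chain on one reference and
strand explains at least 90% of its aligned span -- this catches fusions,
fold-backs and repeat expansions while leaving strand flips and
gap-closed contigs alone. Unalignable contigs are counted separately,
never as misassemblies. This alignment is adequate for near-exact
synthetic data; it is not a spliced aligner and the 1 kb / 90% constants
are documented configuration, not tuned values.

# Problem sizes and reproduction

The shipped acceptance computation (`scripts/acceptance.R`) simulates the
50-gene reference conditions (about 7,000 read pairs), assembles with
default parameters and reports the normal-filtration metrics; it runs in
about one minute on one CPU. The test suite builds all of its fixtures in
code at small scale: oracle comparisons use up to ten random sequences of
at most 300 bp at k 15 and 21, property checks use a handful of seeds,
and the end-to-end check runs the same 50-gene simulation once. With the
reference seed the pipeline 95%-assembles 93% of the 100 isoforms with
zero truth-based misassemblies and duplication ratio 1.006.

# Known limitations

- Tips are evaluated against the single best-covered alternative edge;
  a tip that is similar to the *second* alternative is kept.
- The path-bulge pass compares a single edge against one alternative
  path; interlocking detours of two multi-edge paths can survive in
  pathological densities.
- Gap closing concatenates directly in the pair-only case, so the closed
  contig omits the true gap bases.
- Misassembly detection assumes reference transcripts shorter than the
  1 kb colinearity gap are not internally repetitive.
- Unstranded libraries cannot distinguish a transcript walk from a
  twin-symmetric chimeric walk through a shared reverse-complement region
  longer than the insert size; such regions fork and the spurious
  branches surface as misassembled contigs, which is precisely the case
  strand-specific protocols resolve.
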