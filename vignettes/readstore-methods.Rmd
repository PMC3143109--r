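---
title: "readstore: storage model, query guarantees, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{readstore: storage model, query guarantees, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readstore)
```

## The storage model

Sequencing-based assays such as ChIP-Seq, DNase-seq and RNA-Seq produce
tens to hundreds of millions of mapped reads per sample, but many
downstream consumers — peak callers, browsers, coverage summaries —
need only where each read landed, not its bases or qualities. readstore
therefore reduces each mapped read occurrence to a *hit*:

* `chrom` — a non-negative integer chromosome id. Integers keep records
  compact; a two-column sidecar (`chrommap.tsv`) preserves the
  name-to-id assignment per alignment so `chrX` and friends survive
  round trips.
* `pos` — the 1-based 5' coordinate, a 32-bit signed integer. For
  minus-strand reads this is the *rightmost* aligned base; the covered
  interval is `[pos - length + 1, pos]`. The 5' coordinate is the sort
  and index key, and all region selection is by this single coordinate.
* `strand` and `length` — packed into one 16-bit word: bit 15 is the
  strand (0 = forward), bits 0–14 the aligned length (1..32767 bases).
  The length is the reference-consuming span of the alignment, so a
  spliced `10M20N10M` alignment stores length 40; reads whose span
  exceeds the 15-bit field are skipped at import and tallied.
* `weight` — a non-negative 32-bit float, by convention 1/k for a read
  with k alignments, so each read contributes total probability mass 1
  no matter how many places it maps. Import takes k from the `NH` tag
  when present and otherwise counts records per read name.

An *alignment* (one read set mapped to one reference) is a directory of
per-chromosome column files: positions (4 B/record), packed
strand/length (2 B), weights (4 B), each sorted by position and
index-aligned so record *i* of each file is one hit — 10 bytes per
single-end record. Storing each field contiguously means a
positions-only or weights-only query reads exactly one file.

## The block index and the query bound

A fourth file per partition samples the sorted position column every
*B* = 1024 records, storing that record's position and offset in 8
bytes. This is effectively a single B-tree block: binary search over at
most a few thousand entries, then one sequential scan. 1024 records are
4 kb of position column — the dense end of the useful range, since disk
reads much smaller than a few kb are not faster, and the denser index
maximizes how much of the scan the index pays for. The arithmetic is
what makes the design practical: a 64 kb index file (8192 entries)
addresses 8192 × 1024 ≈ 8.4 million records, more than most experiments
place on one chromosome, so a server can keep hundreds of index files
hot in memory while the data columns stay on disk.

A region query `[s, e]` seeks to the last index entry with first
position strictly below `s` (strictly, because a run of equal positions
can straddle a block boundary), scans positions forward, and stops at
the first block whose first position exceeds `e`. The matching records
are a contiguous range, so the other columns are sliced, never scanned.
At most one partial block before the region and one after are decoded:
per-query work is bounded by *m* + 2·1024 records for *m* results,
independent of store size *n* — the testable form of the
*O*(log *n* + *m*) contract, asserted by instrumentation
(`records_decoded` attribute) at 10^5, 10^6 and 10^7 stored hits. The
bound is stated for the position predicate; a strand or weight filter
reduces results without changing the contiguous decode range.

## Writes, pairs, deletes

Writes merge incoming hits with the existing records and rewrite the
partition. Point insertion into sorted columns is O(N) regardless, so
rewriting keeps the format trivial and makes writes *order-insensitive*:
records are sorted by a total key (position, packed attrs, float32
weight, then mate columns), so any permutation of the same multiset —
in one batch or several — yields byte-identical files, which the tests
check literally. Duplicate hits are retained; weights already express
multiplicity, and collapsing would be a lossy policy decision.

Paired-end sets are stored twice: once keyed by the "left" end (smaller
(chromosome, position) key, ties to the forward strand) in that end's
chromosome partition, and once keyed by the "right" end. Twenty bytes
per record, forty per pair, buys interval queries anchored on either
end with the same index machinery; the left- and right-keyed partitions
are exact images of each other under anchor/mate swap, and the mate's
chromosome is stored explicitly so interchromosomal pairs route
correctly. Deletes remove a whole partition (single or paired, per
chromosome or per alignment) and are idempotent; point deletes would
fight the sorted-rewrite design for no identified use case.

Endianness is fixed little-endian and pinned by a golden-byte test, so
files are portable across machines and implementations of this format.

## Aggregates and histograms

`count_hits` and `sum_weights` answer without materializing hits
(weights accumulate in double precision; storage is float32, so values
round to ~7 significant digits on write — the only lossy step).
Histograms bin by start position: a hit at *p* falls in the bin starting
at `start + binwidth * floor((p - start) / binwidth)`. Bins anchor at
the query start rather than coordinate 0, making results independent of
any chromosome-origin convention; only non-empty bins are returned, so a
count histogram sums exactly to the region's count and a weight
histogram to its weight sum (to float accumulation order, tested at
1e-6 relative). Reads are counted in the bin they *start* in, not every
bin they cross — coverage-style semantics belong to pileup formats, and
mixing the two silently inflates totals.

## Protocol, server, client

The server speaks newline-terminated UTF-8 text with tab-separated
payloads (PROTOCOL.md), so any language with a socket can use it. It is
a single-process event loop multiplexing connections with
`socketSelect()`: requests execute one at a time, which serializes
writes and gives readers consistent snapshots without locks, while many
clients keep connections open. Stores are all-or-nothing per request —
every line is validated before anything is persisted. The client
library is a thin typed wrapper, one request and one parsed response
per call, with no cache: the server's in-memory index cache is the
intended performance feature. Error responses carry a code (400/404)
and become typed R conditions client-side; a fuzz test feeds the server
random request lines and asserts it answers every one and stays up.

## The synthetic generator

`gen_spec()`/`gen_hits()` draw hit sets from explicit study conditions:
uniform positions over a stated range (default 1..10^6), a forward-
strand fraction (default 0.5), 36-base reads (a classic short-read
length), and one of three weight regimes — unit weights, uniform(0.1, 2)
float32-rounded weights to exercise weight filters, or a multiplicity
mixture where each read aligns k ~ uniform{1..4} places yielding k hits
of weight 1/k. Paired specs place a forward left end and reverse right
end 100–300 bases apart, a typical fragment-size range. Every draw uses
a named RNG (Mersenne-Twister) under an explicit seed and restores the
caller's RNG state, so fixtures are bit-reproducible. `gen_hits`
bundles a brute-force full-scan oracle that answers any region/filter
query from the in-memory truth — the independent reference for every
indexed query test. `gen_sam`/`gen_bed` emit importable fixtures whose
import reproduces the generated hits exactly (multisets compared after
mapping chromosome names through the sidecar), closing the loop between
generator and importer.

What the generator does *not* emulate: positional clustering (peaks),
chromosome-scale density variation, sequencing error or alignability
structure, and realistic multiplicity distributions. Passing tests
therefore certify the storage and query machinery — sorting, indexing,
bounds, filters, conservation — not robustness to any biological signal
shape, which the machinery is agnostic to anyway: it never inspects
positions beyond ordering them.

## Numerical and degenerate-input choices

* Weight filtering is inclusive (`weight >= minweight`); a strict
  threshold would make the common "weight ≥ 1 means unique" idiom
  awkward.
* Querying an unknown chromosome returns an empty result, not an error:
  a chromosome absent from the store simply has no mapped reads.
* Empty stores, empty regions, and zero-record partitions are valid
  everywhere (empty index, empty results, zero sums).
* `read_records` ranges are 0-based end-exclusive internally; the
  public query surface is entirely 1-based inclusive.
* A packed attrs word with length 0 is rejected as corruption rather
  than silently decoded.
* `verify_alignment` re-checks the invariants (column-size consistency,
  sort order, index entry placement) and the CLI exposes it with a
  distinct exit code, so damaged stores fail loudly.

## Problem sizes

The default test suite runs stores up to 10^6 hits plus one 10^7-hit
store for the decode-bound check, about a thousand randomized
oracle-equivalence cases, 10^4 pairs for the dual-key bijection, and
end-to-end socket round trips of a few thousand hits — sizes chosen so
the whole suite completes in a couple of minutes on one CPU while still
crossing two orders of magnitude in store size, the range over which the
decode bound is claimed. `scripts/acceptance.R` re-measures the same
quantities from scratch at the same sizes.

## Limitations

* Selection is by 5' position only; span-overlap queries are a
  documented non-goal (they would need either post-filtering with a
  maximum-length bound or an interval tree, both foreign to this
  format).
* No compression; the format trades bytes for seek simplicity.
* Single writer at a time per alignment; the server serializes writes,
  and direct-API writers must not race each other.
* No authentication or TLS; deploy behind a trusted network boundary.
* Histograms are computed per query; there are no precomputed
  multi-resolution summaries, so repeated identical histograms cost the
  same each time (server-side binning still keeps network transfer
  small).
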