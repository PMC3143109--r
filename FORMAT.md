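# readstore on-disk format

One **alignment** (a read set mapped to one reference genome) is one
directory. All multi-byte values are **little-endian**. All coordinates
are 1-based inclusive; for a minus-strand hit the stored position is the
5' end, i.e. the highest-coordinate aligned base, and the hit covers
`[pos - length + 1, pos]`.

## Files

Per chromosome id `<c>` (a non-negative integer) and partition
`<p>` ∈ `single` | `pairedL` | `pairedR`:

| file | record size | content |
|---|---|---|
| `<c>.<p>.positions` | 4 B | int32 5' position of the keyed end, sorted non-decreasing |
| `<c>.<p>.attrs` | 2 B | uint16 packed strand/length (below) |
| `<c>.<p>.weights` | 4 B | float32 hit (or pair) weight |
| `<c>.<p>.matechrom` | 4 B | int32 mate chromosome id (paired partitions only) |
| `<c>.<p>.matepos` | 4 B | int32 mate 5' position (paired only) |
| `<c>.<p>.mateattrs` | 2 B | uint16 mate packed strand/length (paired only) |
| `<c>.<p>.index` | 8 B/entry | block index (below) |

Record `i` of each column file describes the same hit: a single-end
record costs 10 bytes, a paired record 20 bytes (and each pair is stored
twice, once left-keyed and once right-keyed).

A sidecar `chrommap.tsv` (two tab-separated columns: chromosome name,
integer id; no header) records the name↔id assignment. It is bijective
and append-only, so re-imports reuse existing ids.

## Packed strand/length word

16-bit unsigned: bit 15 is the strand (0 = `+`, 1 = `-`), bits 0–14 the
aligned length in bases (1..32767). A word whose low 15 bits are zero is
invalid (corrupt record).

## Block index

One entry per 1024 records (= 4 kb of the position column), starting at
record 0:

    entry k: int32 first-position of record k*1024, uint32 record offset k*1024

Entry count is `ceil(N / 1024)`. Strictly increasing record offsets,
non-decreasing first positions. A 64 kb index (8192 entries) therefore
addresses 8192 × 1024 = 8,388,608 records.

## Write semantics

Writes merge incoming hits with existing records and rewrite the whole
chromosome partition in sorted order (ties broken by packed attrs, then
weight, then mate columns), so writing any permutation of the same hit
multiset — in one batch or several — produces byte-identical files.
Duplicate hits are retained, never collapsed. Deletes remove a whole
partition (per chromosome or per alignment) and are idempotent.
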