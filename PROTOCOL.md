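# readstore wire protocol

Line-oriented UTF-8 text over TCP; every line is newline-terminated.
Any language that can open a socket and read lines can use the server.

## Requests

    VERB key=value key=value ...

Parameter values contain no spaces. Verbs and parameters:

| verb | required | optional |
|---|---|---|
| `STORE` | `align`, `chrom`, `count` | — (followed by `count` data lines) |
| `STOREPAIRED` | `align`, `count` | — (followed by `count` data lines) |
| `DELETE` | `align`, `endedness` (`single`\|`paired`) | `chrom` |
| `CHROMS` | `align` | — |
| `COUNT` | `align` | `chrom`, `start`, `end`, filters |
| `WEIGHTSUM` | `align` | `chrom`, `start`, `end`, filters |
| `GETHITS` | `align` | `chrom`, `start`, `end`, filters, `projection` (`full`\|`positions`\|`weights`) |
| `HISTOGRAM` | `align`, `chrom`, `start`, `end`, `binwidth` | `mode` (`count`\|`weight`), filters |
| `SHUTDOWN` | — | — |

Filters (any query verb): `strand=+`\|`-`, `minweight=<float>`
(inclusive, keeps weight ≥ threshold), `endedness=single`\|
`paired-left`\|`paired-right` (selects the partition; region matching is
on the keyed end's position). `chrom` may be an integer id or a name
resolvable through the alignment's `chrommap.tsv`. `start`/`end` are
1-based inclusive; omitting them queries the whole chromosome, omitting
`chrom` queries the whole alignment.

### Store payloads

`STORE` is followed by exactly `count` tab-separated lines:

    pos <TAB> strand <TAB> length <TAB> weight

`STOREPAIRED` lines carry both ends (anchor side first):

    chrom pos strand length matechrom matepos matestrand matelength weight

A store is **all-or-nothing**: if any line fails to parse, the response
is an `ERROR` naming the line and nothing is persisted.

## Responses

Success:

    OK <n>
    <n tab-separated payload lines>

`COUNT`/`WEIGHTSUM` return one line with the number. `CHROMS` lines are
`chrom<TAB>name<TAB>single-count<TAB>paired-count`. `GETHITS` lines are
`chrom pos strand length weight` (plus the four mate fields before
`weight` for paired partitions), or bare positions/weights under a
projection. `HISTOGRAM` lines are `binstart<TAB>value` (non-empty bins
only, bins anchored at `start`).

Failure (connection stays open):

    ERROR <code> <message>

Codes: `400` malformed request / bad parameters / parse failure,
`404` unknown alignment.

## Concurrency

Many clients may hold connections; requests are executed serially by the
server's event loop, so readers always observe a consistent store and
writes need no client-side locking (single-writer-at-a-time,
many-reader contract). The server caches index files in memory across
requests, invalidated by file modification time.
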