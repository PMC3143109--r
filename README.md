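# readstore

A compact, network-accessible column store for genome-aligned short-read
positions, for ChIP-Seq, DNase-seq, DNA-methylation and RNA-Seq analysis
and visualization backends that need read *positions* — not sequences,
qualities or mismatches — across thousands of datasets.

Each stored **hit** is a mapped read occurrence: integer chromosome id,
1-based 5' coordinate (a 32-bit int; for minus-strand reads the
rightmost aligned base), strand and aligned length packed into one
16-bit word, and a 32-bit float **weight**, typically 1/k for a read
with k alignments so every read contributes total mass 1. Hits live in
per-chromosome parallel binary column files sorted by position, with a
sparse block index holding one `(first-position, record-offset)` entry
per 1024 records. A region query binary-searches the index and scans
forward, so its cost is *O*(log *n* + *m*) in stored hits *n* and
returned hits *m* — concretely, at most *m* + 2×1024 records are ever
decoded for a region, regardless of *n*. Paired-end read sets are stored
**dual-keyed**: each pair is written twice, once sorted by the left
end's position and once by the right end's, so interval queries can
anchor on either end. The server answers count, weight-sum, per-hit and
**histogram** queries (counts or weight sums at any caller-chosen bin
width, anchored at the query start) over a line-oriented text protocol;
see `FORMAT.md` and `PROTOCOL.md` for the byte-exact layouts.

## Worked example

```r
library(readstore)

align <- align_open(file.path(tempdir(), "ctcf_rep1"))
hits <- single_hits(chrom = 1,
                    pos = c(10450, 10462, 10471, 11003, 11020),
                    strand = c("+", "+", "-", "+", "-"),
                    length = 36, weight = c(1, 1, 0.5, 1, 1))
store_single(align, hits)

count_hits(align, region(1, 10400, 10500))
#> [1] 3
sum_weights(align, region(1, 10400, 10500))
#> [1] 2.5
histogram_query(align, region(1, 10401, 11100), binwidth = 100)
#>   binstart value
#> 1    10401     3
#> 2    11001     2
get_hits(align, region(1, 10400, 10500), hit_filter(strand = "-"))
#>   chrom   pos strand length weight
#> 1     1 10471      -     36    0.5
```

Three of the five hits have their 5' end inside `[10400, 10500]`; their
weights sum to 2.5 (the 0.5 is a read that mapped twice). The histogram
bins anchor at the region start, and the strand filter returns only the
minus-strand hit — selection is always by stored 5' position, so a
minus-strand read spanning into a region from outside is not returned.

Import real data and serve it:

```sh
inst/cli/readstore import --sam reads.sam --align /data/ctcf_rep1
inst/cli/readstore count --align /data/ctcf_rep1 --region chr1:1-2000000
inst/cli/readstore serve --root /data --port 52734
```

then from any client, `readdb_connect()` / `rdb_count()` /
`rdb_get_hits()` / `rdb_histogram()` mirror the local API over the
socket.

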