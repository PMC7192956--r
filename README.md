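# barcodeprep

Staging DNA-barcode records and their metadata files for upload to
centralized repositories.

## The problem

Reference libraries such as the Barcode of Life Datasystems (BOLD) only
become useful when researchers actually submit their records — the
barcode sequence plus its metadata: specimen images (JPG), Sanger
chromatogram traces (AB1) and FASTA sequence files. In practice those
files are scattered across nested project folders accumulated over
years and collaborators, upload portals cap the size of each submission,
quality filtering leaves name lists of records to keep, and alignment
artifacts (gap characters, multi-line wrapping, duplicated records)
block the sequence files themselves from being accepted. On locked-down
institutional machines the usual shell one-liners for this are often
unavailable.

`barcodeprep` packages the nine file- and sequence-organization steps of
that workflow behind plain functions and a small command-line tool.
Every output carries a deterministic date-stamped name
(`YYYYMMDD_<operation>[_TYP][_#][.ext]`), existing outputs are never
overwritten, and source files are never modified.

| operation | what it does |
|---|---|
| `target_file_list` | list all JPG / AB1 / FASTA-FAS files under a tree into a tab-separated text file |
| `recursive_copy` | flatten every matching file in a tree into one upload folder |
| `max_packs` | partition a flat folder's files into size-capped upload packs (first-fit, order-stable) |
| `copy_by_list` | copy the files named in a one-name-per-line list (non-recursive) |
| `degap` | delete alignment gaps (`-`) from every sequence |
| `rank_seq` | sort records shortest to longest (stable) |
| `head_derep` | keep the first record per distinct header |
| `seq_derep` | keep the first record per distinct sequence (case-insensitive) — a quick haplotype collapse |
| `multi_to_single_fasta` | rewrite wrapped FASTA with each sequence on one line |

Sequence files are held in an S4 `FastaDocument` (headers verbatim,
sequences as a `Biostrings::BStringSet` so case and gaps survive, plus
the detected single-line / multi-line dialect). A seeded fixture
generator (`generateTree()`, `generateFasta()`) produces synthetic
inputs with known ground truth, so the whole toolkit is testable with no
external data.

## Worked example

```r
library(barcodeprep)

# a throwaway tree: two images, one trace, nested folders
root <- tempfile(); dir.create(file.path(root, "a", "deep"), recursive = TRUE)
writeBin(as.raw(1:40), file.path(root, "a", "IMG_001.jpg"))
writeBin(as.raw(1:60), file.path(root, "a", "deep", "IMG_002.JPG"))
writeBin(as.raw(1:99), file.path(root, "trace.ab1"))

d <- as.Date("2020-04-23")
scanTargets(root, "JPG")$name
#> [1] "IMG_002.JPG" "IMG_001.jpg"
basename(recursiveCopy(root, "JPG", d))
#> [1] "20200423_recursive_copy_JPG"

flat <- file.path(root, "20200423_recursive_copy_JPG")
plan <- planPacks(scanTargets(flat, "JPG", recursive = FALSE), maxBytes = 70)
plan
#> PackPlan: 2 pack(s), cap 70 bytes
#>   pack 1: 1 file(s), 60 bytes
#>   pack 2: 1 file(s), 40 bytes
basename(executePacks(plan, flat, "JPG", d))
#> [1] "20200423_max_packs_JPG_1" "20200423_max_packs_JPG_2"

# sequence side: degap and collapse to haplotypes
f <- tempfile(fileext = ".fas")
writeLines(c(">s1", "AC-GT", ">s2", "acgt", ">s3", "TTTT"), f)
doc <- degap(readFasta(f))
seqDerep(doc)
#> FastaDocument with 2 records (single_line dialect)
#>   >s1  [4 nt]
#>   >s3  [4 nt]
```

The scan lists files lexicographically by full path; the two 40- and
60-byte images cannot share a 70-byte pack, so two indexed pack folders
are created; after degapping, `s2` (`acgt`) is the same haplotype as
`s1` and is dropped by the case-insensitive sequence dereplication.

The same operations are available from a shell via the installed
`exec/barcodeprep` script, e.g.
`barcodeprep degap --in seqs.fas --out-dir . --date 20200423`; run a
subcommand with flags omitted at a terminal and it prompts for them
instead.

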