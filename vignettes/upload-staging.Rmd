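---
title: "Staging barcode submissions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging barcode submissions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeprep)
```

## What the package models

Submitting DNA-barcode records to a centralized repository is mostly a
logistics problem: the sequence itself is a few hundred nucleotides,
but it travels with specimen images (JPG), chromatogram traces (AB1)
and FASTA files spread over deep project trees, and the portal imposes
formatting rules (single-line FASTA, no alignment gaps, no duplicate
records) and per-upload size limits. `barcodeprep` treats this as nine
small, composable operations over two kinds of atoms:

* a **file entry** — path, base name, byte size — for the file-level
  operations, which never open the files they move (an AB1 trace is an
  opaque payload here);
* a **FASTA record** — header plus nucleotide sequence — held in a
  `FastaDocument`, for the sequence-level operations.

Every operation derives its output name from an injectable run date
(`renderName()`), so a pipeline run with a fixed `--date` is
reproducible down to the file names, and every writing operation
refuses to overwrite an existing output rather than risk clobbering a
previous run.

## Parameters that matter

* **Target file type** (`JPG`, `AB1`, `FAS`): extension matching is
  case-insensitive, because cameras and sequencers emit `.JPG` and
  `.AB1` as often as the lower-case forms. `FAS` matches `.fasta` and
  `.fas` only; `.fa` / `.fna` are deliberately excluded so the matched
  set corresponds exactly to the advertised type names (the matching
  table is a single internal constant, easy to extend).
* **Pack size cap** (`planPacks(maxBytes)`; `--max-size` in MB on the
  command line, converted as MB × 10⁶ bytes): the per-upload limit of
  the destination portal. The unit choice — megabytes at the CLI,
  bytes in the API — mirrors how portals phrase their limits versus
  how sizes are measured on disk; the CLI help and logs state the unit.
  Packing is first-fit over the deterministic lexicographic scan
  order: files are appended to the current pack until the next file
  would exceed the cap, then a new pack opens. This is not optimal bin
  packing; it is order-stable and reproducible, which matters more
  when a half-finished upload must be resumed. A single file larger
  than the cap cannot be packed at all and is a named error.
* **Run date** (`runDate` / `--date`): defaults to today, injectable
  everywhere. Day granularity only; the naming scheme is fixed, not
  configurable.

## Sequence-side semantics

* **Gap removal** deletes `-` and only `-`. Some alignment formats use
  `.` or `~` for terminal gaps, but those have other meanings in
  nucleotide files, so they pass through untouched.
* **Dereplication keeps the first occurrence** of each key, preserving
  input order. The surviving record is therefore deterministic; which
  duplicate survives is otherwise arbitrary, and first-occurrence
  keeps whatever curation order the input encodes.
* **Header keys are verbatim** (the whole line after `>`, trailing
  whitespace trimmed): specimen identifiers routinely contain pipes
  and spaces with meaning, so tokenizing at the first space would
  merge distinct records.
* **Sequence keys are case-insensitive** (soft-masked lowercase is a
  formatting artifact, not a haplotype difference) but gaps are *not*
  stripped before keying — a gapped and an ungapped copy of one
  haplotype are different strings; run `degap()` first if they should
  collapse. The distinct-sequence count after `seqDerep()` is a quick
  haplotype-diversity estimate for a marker file.
* **Length ranking is a stable sort**: ties keep input order, never
  reordered by header, so repeated runs and partial edits behave
  predictably.
* **Dialects**: `readFasta()` records whether every sequence occupied
  one source line. The four single-line transforms operate on parsed
  documents regardless of dialect at the API level, but the
  command-line tool refuses multi-line input and points at
  `multi_to_single_fasta` — at the shell, silently accepting wrapped
  input would hide the conversion the user is expected to make, and
  keeping the two steps explicit matches how the tools are documented
  to users. Output always uses LF endings and single-line wrapping.

## Filesystem semantics

* Recursive scans use a hand-rolled walk that skips symbolic links to
  directories (cycle safety) and sorts by full path with a radix sort,
  so ordering does not depend on the locale.
* `recursiveCopy()` excludes its own output folder from the scan and
  resolves base-name collisions by suffixing `_1`, `_2`, … before the
  extension with a warning — flattening a tree legitimately brings
  together same-named files, and silent overwrite would lose data.
* `copyByList()` is deliberately non-recursive (flatten first with
  `recursiveCopy()` if needed); names requested but absent are
  returned as a sorted `missing` report rather than an error, since
  reconciling a filter list against a folder is exactly the use case.
* The list-file grammar is one name per line with an optional single
  trailing blank line; CRLF and missing trailing newlines are
  tolerated on read. The written file list uses a tab between path and
  name — tabs are the one separator that cannot appear in either field
  on common filesystems.

## What the generators emulate

`generateTree()` builds nested directories of JPG/AB1/FAS/other files
with controlled type mix, sizes, and base-name duplication; payloads
are random bytes, which is faithful to how the file operations treat
them (never opened). `generateFasta()` writes records with controlled
length, gap fraction, duplicate-header and duplicate-sequence rates,
optional lowercase re-casing of duplicates, and optional column
wrapping, and returns the ground truth the tests assert against
(per-record inserted gap counts, distinct-header and distinct-key
counts). Both are deterministic functions of their arguments and seed.

What they do *not* emulate: real chromatogram or image content,
biologically realistic sequence composition, IUPAC ambiguity codes,
pathological filesystems (permissions, case-insensitive volumes,
non-UTF-8 names). Passing tests demonstrate the organizational logic,
not robustness to every storage backend.

Default test problem sizes — trees of up to four levels with at most
four files per directory, FASTA files of tens of records, 100-replicate
property sweeps — were chosen as desk-scale workloads that exercise
every branch (empty directories, ties, duplicate names, all three
dialect/wrap combinations) while keeping the whole suite interactive.

## Numerical and degenerate-input choices

* Byte sizes are exact integers; no tolerance is involved anywhere.
* Empty inputs are well-defined: an empty scan yields a zero-row
  table, an empty list file is an error (a filter list with no names
  is almost certainly a mistake), an empty `FastaDocument` writes an
  empty file, and a record that becomes empty after degapping is a
  named error (a gap-only record is not uploadable).
* The pack index is 1-based — folder names are user-facing, and
  `_1` is what a bench scientist expects the first pack to be called.
* Prompt mode is disabled when stdin is not a terminal, keeping the
  tool scriptable; prompts ask for the path first, then the file type,
  then the size cap where applicable. Flag mode and prompt mode call
  the identical library functions, so their outputs are byte-identical
  for the same effective parameters.

## Known limitations

* Copying is sequential and unverified beyond the test-suite
  checksums; there is no manifest or resume support.
* Only `-` is a gap; amino-acid FASTA semantics, translation, and
  quality trimming are out of scope.
* `max_packs` plans by file size only; it does not balance counts or
  group related records into the same pack.
* Name-collision suffixing changes base names in the flattened folder;
  downstream tools that key on exact file names should use the file
  list to map back to sources.
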