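---
title: "Verifiable, portable datasets: the model behind dtoolr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifiable, portable datasets: the model behind dtoolr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtoolr)
```

## The dataset model

dtoolr treats a collection of related files plus its metadata as one
portable unit, the *dataset*. The model separates three kinds of metadata,
because they have different owners and different lifecycles:

* **Administrative** (machine-managed): UUID, name, creator, proto/frozen
  state, freeze timestamp, format version. The UUID is assigned at creation
  and never changes — not when the dataset is renamed on disk, not when it is
  copied to another medium. It is the dataset's identity.
* **Structural** (machine-computed): the manifest, mapping each item's
  identifier to its relative path, size in bytes, content hash and
  modification timestamp. The manifest is computed once, at freeze time, and
  is immutable thereafter.
* **Descriptive** (human-owned): a free-form YAML README about the whole
  dataset, and *overlays* — named mappings from item identifiers to scalar
  values — for per-item annotation. Descriptive metadata remains editable
  after freezing: curation continues for as long as the data lives, and a
  README edit must never be able to invalidate an integrity check. The
  package's tests assert exactly that independence.

### Item identifiers

An item's identifier is the SHA-1 hex digest of the UTF-8 encoding of its
relative path: `generate_identifier("U00096.3.fasta")` is
`b445ff5a1e468ab48628a00a944cac2e007fb9bc`, on every machine and every
storage backend. Deriving the identifier from the relpath — rather than from
content, or from a random key — has three consequences that the rest of the
design leans on:

1. Identifiers are computable without touching storage, so processing
   scripts can address items before deciding whether to fetch them.
2. Replacing an item's content (re-adding the same relpath to a proto
   dataset) keeps its identifier stable; last write wins.
3. Two items in one dataset can never collide, because relpaths are unique
   within a dataset by construction.

The identifier is an addressing device, not a cryptographic commitment; the
content hash in the manifest is what fixity checking compares.

### Freezing and the source of truth

`freeze()` enumerates what is *actually in storage*, not what `add_item()`
was called with. A file placed into the data area by other means is
manifested like any other; an item deleted behind the API's back simply is
not. This makes storage the single source of truth and keeps the manifest
honest about the bytes it describes. Each item's `utc_timestamp` is the
stored file's modification time at freeze, kept as decimal UTC epoch
seconds.

Empty datasets freeze successfully into valid zero-item datasets. Pipelines
legitimately produce empty outputs, and nothing in the format forbids them.

### Fixity checking

`verify()` compares storage against the manifest and reports four kinds of
discrepancy: expected items that are absent (*missing*), stored items the
manifest does not know (*unknown*), items whose size differs
(*altered size*), and — only with `full = TRUE` — items whose recomputed
content hash differs (*altered hash*). The default mode reads no item
content, so it is cheap even for large datasets on slow media; the full mode
re-hashes every item and therefore catches size-preserving corruption, which
the default mode by design cannot. Discrepancies are report content, never
errors: an archivist checking a damaged dataset needs the complete list, not
an exception at the first problem.

## Storage brokers

All reads and writes go through a broker contract: initialize the structure
at a URI, store/retrieve item bytes, store/retrieve named text artefacts
(admin record, manifest, README, overlays, structure description), enumerate
stored items with sizes and timestamps, and provide a local readable path
for an item. Dataset logic never touches a medium directly.

Two brokers are included:

* `file://` — the canonical directory layout: `README.yml` at the root,
  items under `data/` at their relative paths, machine metadata under
  `.dtool/` (`dtool` = admin record, `manifest.json`, `structure.json`
  mapping logical artefact names to locations, and a plain-text `README.txt`
  explaining that the directory is a dataset and must not be hand-edited).
  The layout is deliberately auditable with `ls` and `cat` alone, and is
  designed to outlive the software: every file is plain text in a standard
  format (JSON, YAML).
* `mock://` — a local directory that behaves like object storage: datasets
  addressed by UUID (`mock://<store>/<uuid>`), item bytes stored *flat*
  under `data/<identifier>` with no relpath-derived tree, relpaths kept in
  per-item sidecar keys (as object stores keep them in object metadata), and
  item reads served by materializing into a local cache directory
  (idempotently — a second fetch reuses the cached copy, with the relpath's
  extension chain preserved so suffix-sniffing tools keep working).

The second broker exists to keep the abstraction honest. Because its
on-medium representation shares nothing with the directory layout — not even
file names — any test that passes unchanged on both brokers demonstrates
that dataset behaviour really is independent of the medium. The test suite
runs its lifecycle and corruption property suites against both, and asserts
that a dataset copied disk → object store → disk is byte-identical in
manifest, README, overlays and item content.

Copying writes the administrative record last. Its presence is the marker of
a complete dataset, so an interrupted copy leaves a location that fails to
load at all rather than a plausible-looking but broken dataset — a cheap
atomicity signal that needs no transactions.

## Tunable parameters

* `hash_algorithm` (in `freeze()`): manifest label of the content-hash
  algorithm; default `"md5sum_hexdigest"` (MD5). MD5 is the default because
  fixity checking defends against bit rot and operational accidents, not
  adversaries, and MD5 is fast and universally available for spot-checking
  with standard tools (`md5sum`). SHA-1 and SHA-256 variants are registered
  (`sha1sum_hexdigest`, `sha256sum_hexdigest`) and the registry is
  extensible; when reading, the manifest's recorded label is authoritative,
  so datasets frozen with any registered algorithm verify correctly.
* `creator_username`: defaults to the operating-system account, overridable
  via the user configuration file or `DTOOLR_CREATOR_USERNAME`.
* cache root (`DTOOLR_CACHE_ROOT` or the configuration file; default
  `~/.cache/dtoolr`): where non-filesystem brokers materialize item content.
  The cache is per-dataset-UUID and append-only; it is safe to delete.

## Numerical and formatting choices

* **Size formatting** uses binary prefixes (1 KiB = 1024 B), choosing the
  largest unit in which the value is at least 1, printed with exactly one
  decimal place, rounding half *up* on that decimal (`floor(x * 10 + 0.5) /
  10`, since base R's `round()` is half-to-even). A 3,858,445,043-byte
  dataset is 3.593 GiB and prints as `3.6GiB` — rounded, not truncated.
* **Ordering**: identifiers sort byte-wise lexicographically everywhere
  (listings, manifest serialization, overlay keys); dataset listings sort by
  name with URI as tie-break. No ordering depends on locale-sensitive
  collation of anything but `[0-9a-f]` strings.
* **Manifest serialization** is a fixed byte format: top-level keys
  `dtoolcore_version`, `hash_function`, `items`; keys sorted; two-space
  indent; timestamps printed with at least one decimal place
  (`1537805410.0`) and sizes as exact integers, never scientific notation.
  A bespoke serializer guarantees these bytes; generic JSON emitters do not.
* **Timestamps** are UTC epoch seconds throughout storage; the CLI renders
  `frozen_at` as a UTC ISO date (`2018-09-26`).
* **Degenerate inputs**: relpaths may not be absolute or contain `.`/`..`
  segments; dataset and overlay names are restricted to
  `[A-Za-z0-9._-]`; a zero-byte item is legal and hashes to the MD5 of the
  empty string; `format_size(0)` is `"0.0B"`.

## The command-line interface

Every CLI command maps 1:1 onto a package function, and machine-consumed
output (quiet forms, identifiers, fetched paths) is one item per line on
standard output, so commands compose in shell pipelines:
`dtool identifiers` → `dtool item fetch` → `dtool add item` →
`dtool readme write` → `dtool freeze` is the canonical dataset-to-dataset
processing pattern, and the suite runs it end-to-end as an actual Bash
script against both brokers. Exit codes are fixed for scriptability: 0
success, 1 user error, 2 integrity failure from `verify`. The wording of
the `verify` discrepancy lines for unknown and altered items
(`Unknown item: <id>`, `Altered item: <id> <relpath>`) and the non-quiet
`create`/`cp` messages are conventions of this package. `publish`
(cloud access control) is registered but returns a clear "not supported"
error: network backends are out of scope, and the local object-store broker
exists precisely to exercise those code paths without a network.

## What the fixture generator emulates — and what it does not

`make_fixture_dataset()` builds the datasets every test runs against:

* *Content fixtures*: small synthetic items generated deterministically from
  a seed — paired gzipped FASTQ files (`ERR022075_1.fastq.gz` /
  `ERR022075_2.fastq.gz`, 5 reads × 36 bases by default, matching read names
  ending `/1` and `/2`) and a reference-FASTA item (`U00096.3.fasta`,
  280 bases). The gzip container is produced with a zeroed header timestamp,
  so identical seeds yield byte-identical items.
* *Manifest-level fixtures*: datasets whose manifest states declared sizes,
  hashes and timestamps without materializing the bytes. This is how the
  published two-item, 3.6 GiB read dataset is reproduced exactly — summary,
  listing and identifier behaviour are functions of the manifest alone — at
  desk scale. Such items are flagged as not fetchable and are never used in
  operations that read content.

The generator emulates the *structure* of real sequencing data (paired
naming, gzip framing, realistic metadata), not its scale or statistics: item
sizes in content fixtures are tens to hundreds of bytes, not gigabytes, and
sequence content is uniform random. Passing tests therefore demonstrate the
format's logic — identifier stability, manifest fidelity, corruption
detection, broker equivalence — on faithful miniatures; they say nothing
about I/O throughput, large-file streaming performance, or network
behaviour of genuinely remote storage. Streaming hashing (fixed-size-chunk
file digests, memory use independent of file size) is inherited from the
digest layer and asserted for equivalence with in-memory hashing, not
benchmarked.

Problem sizes used by the test and acceptance suites: random lifecycle
datasets of up to 20 items of up to ~220 bytes each, corruption sweeps
exhaustive over 4-item datasets with 2 sampled byte positions per item, and
1,000 random strings for the identifier cross-check against an independent
SHA-1 implementation. These sizes exercise every code path (including empty
datasets and nested relpaths) while keeping the full suite fast enough to
run habitually.

## Known limitations

* Verification establishes *fixity*, not authenticity: anyone who can edit
  both an item and the manifest can make `verify` pass. Tamper-evidence is
  explicitly not a goal.
* Single writer assumed; concurrent mutation of one proto dataset is
  unsynchronized.
* Frozen datasets are immutable but not versioned; deriving a corrected
  dataset means creating a new one (with a new UUID) and recording
  provenance in its README.
* SHA-1 relpath collisions are not handled; for path-length inputs they do
  not occur in practice, and identifiers are addressing, not security.
* The included brokers are both local. Genuinely remote backends (S3,
  iRODS, HTTP) would plug into the same contract — the object-store broker
  models their shape — but credentials, retries and latency are unaddressed
  here.
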