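# dtoolr

Lightweight data management for research groups: package collections of data
files together with their metadata into portable, verifiable **datasets**.

## The problem

Front-line researchers — core-facility staff, embedded bioinformaticians,
students inheriting a predecessor's sequencing runs — rarely have a central
data-management system. Metadata ends up encoded in file names and directory
trees (`repl_2/col0_chitin_leaf_1.tif`), where it is silently lost the moment
files are moved; nobody can say with confidence whether an old archive is
still intact; and every storage technology (POSIX filesystem, object store)
needs its own tooling. dtoolr addresses this at the level where the work
happens: it bundles data files with administrative, structural and
descriptive metadata into a single unit that can be moved between storage
media, understood years later, and checked for integrity at any time.

## The model

A **dataset** consists of:

* **items** — the user's data files, addressed by *identifier*
  `id = SHA1(UTF8(relpath))`, the 40-hex-digit SHA-1 of the item's relative
  path. Identifiers are pure functions of the relpath, so they are identical
  on every storage backend.
* a **manifest** (structural metadata) mapping each identifier to the item's
  relative path, size in bytes, content hash (MD5 by default, recorded under
  the label `md5sum_hexdigest`) and UTC timestamp.
* an **administrative record**: UUID (stable for life, including across
  copies), name, creator, proto/frozen state, freeze time.
* **descriptive metadata**: a free-form YAML README stored byte-for-byte,
  plus named **overlays** mapping item identifiers to scalar values.

Datasets are built as mutable *proto datasets*, then **frozen**: the manifest
is computed from the stored bytes and the dataset becomes immutable.
**Fixity** is then checkable forever after: `verify()` compares presence and
size of every expected item (and, in full mode, recomputed content hashes)
against the manifest. All storage access flows through a pluggable
**storage broker**, with two concrete backends included: a human-auditable
directory layout (`file://`) and a local object-store-like backend
(`mock://`) that stores item bytes flat under identifier keys and serves
reads through a cache — datasets behave identically on both.

## Worked example

```r
library(dtoolr)

proto <- create_proto_dataset("Escherichia-coli-ref-genome", "my_datasets")
add_item(proto, "U00096.3.fasta")
#> [1] "b445ff5a1e468ab48628a00a944cac2e007fb9bc"
write_readme(proto, "---\ndescription: E. coli K-12 MG1655 reference genome\n")
ds <- freeze(proto)

summary(ds)
#> name: Escherichia-coli-ref-genome
#> uuid: 1fd2d311-39b8-465a-84be-a42f6a24b33b
#> creator_username: olssont
#> number_of_items: 1
#> size: 100.0B
#> frozen_at: 2026-10-01
```

The `add_item()` return value is the item's identifier — the SHA-1 of its
relative path. The summary aggregates the manifest: one item, 100 bytes,
frozen today, created by the configured user. Integrity and portability:

```r
verify(ds, full = TRUE)
#> All good :)

dest <- copy_dataset(dataset_uri(ds), "mock:///tmp/object-store")
dest
#> mock:///tmp/object-store/1fd2d311-39b8-465a-84be-a42f6a24b33b
verify(load_dataset(dest), full = TRUE)
#> All good :)
```

The copy keeps the UUID (the object store addresses datasets by it), the
manifest byte-for-byte, the README and all overlays; full verification
recomputes every content hash at the destination. Removing an item from a
dataset is reported with its identifier and relative path:

```r
verify(ds)
#> Missing item: b445ff5a1e468ab48628a00a944cac2e007fb9bc U00096.3.fasta
```

The same operations are available from the shell (`dtool name`, `dtool
summary`, `dtool ls --verbose`, `dtool verify -f`, `dtool cp -q`, `dtool
identifiers`, `dtool item fetch`, `dtool inventory --format=html`, ...), with
quiet forms designed for composition in pipelines:

```sh
LOCAL_URI=`dtool cp -q mock:///tmp/object-store/1fd2d311-... .`
dtool name $LOCAL_URI
```

See `vignettes/dataset-management.Rmd` for the full account of the format,
the design decisions and the limits of what verification can promise.

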