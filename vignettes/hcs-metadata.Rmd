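---
title: "Managing high content screening metadata with hcstore"
author: "hcstore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing high content screening metadata with hcstore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcstore)
```

# The problem

A high content screening (HCS) experiment produces three kinds of
information that must stay linked to be interpretable: experimental
metadata (plate layouts, reagents, imaging parameters, protocol details),
the images themselves, and analytic output (segmented regions of interest
and per-cell feature measurements, often millions of rows per plate). No
single storage technology serves all three well. Strongly typed records
are queryable but rigid; free-form attachments are flexible but opaque;
large numeric arrays need a columnar binary store, not a database table.

`hcstore` puts one API over three storage strategies, each matched to one
of those kinds:

1. a **typed object store** for the containment hierarchy — Screen →
   Plate → Well → Field → Image → Channel, plus Reagents and ROIs — with
   stable integer IDs (`ObjectRef`s) that every other strategy links
   through;
2. **flexible annotations** — ordered key-value *map annotations* with
   optional scientific units, namespaced *file annotations* stored by
   content, and *tags* — attachable to any object;
3. an **HDF5-backed columnar feature store** for analytic output: typed
   columns including object-reference columns, append-only row blocks,
   column-slice reads, a restricted predicate query language, and per-row
   backlinks to the source well/image/ROI.

Around the core sit bulk CSV/TSV import of plate metadata, a token-based
text search index, group-based permissions consulted on every read path,
per-plane pixel statistics with thumbnail rendering, and a seeded
synthetic-screen generator that can populate all of the above without any
external data.

# The data model

## Containment hierarchy

Plates use the standard SBS geometries (96 = 8×12, 384 = 16×24,
1536 = 32×48); an advanced constructor accepts arbitrary grids. All
indices are 0-based internally; user-facing well labels follow the bench
convention of letter row and 1-based column (`"A1"`, `"P24"`), with
bijective base-26 double letters beyond `"Z"`. `parseAddress()` is
tolerant of case and zero padding (`"h012"` is row 7, column 11), because
that is how addresses arrive in spreadsheets.

Images are 5D (x, y, z, channel, time). Pixel data are referenced **in
place**: an image's `pixel_source` is a verbatim path to an external
file; pixel bytes are never copied into the store. This mirrors how
modern screening servers treat multi-terabyte image repositories — the
metadata store holds the linkage, the filesystem holds the bytes.

ROIs delineate objects (typically cells) on an image. Coordinates are
0-based pixel units, x right / y down, with half-open bounding boxes;
mask dimensions must match their bounding box. These conventions are
stated explicitly because off-by-one disagreements between analysis
tools are a classic source of silent feature misalignment.

Deletion is restricted: removing an object that anything still points at
fails unless a cascade is requested. Since linkage is the entire point of
the store, failing loudly is the only safe default. IDs are never reused,
so a stale reference always errors rather than resolving to a stranger.

## Quantities and units

Map annotations may carry units (`"Temperature" : "37" : "°C"`), and
acquisition metadata such as exposure times and emission wavelengths are
unit-bearing quantities. The registry covers SI base plus common
microscopy units (nm, µm, mm, m; µs, ms, s; K, °C, °F; V, mV; Pa, bar;
Hz; rad, deg), each defined by an affine map to its dimension's base
unit: `base = value × factor + offset`, the offset non-zero only for the
absolute temperature scales. Unit symbols are case-sensitive UTF-8 —
`"C"` is deliberately rejected rather than guessed to mean Celsius, to
avoid the Coulomb ambiguity. Molarity and other chemistry units are an
optional extension (`defaultUnitRegistry(chemistry = TRUE)`), off by
default. The registry serialises to a plain tab-separated table so a
deployment can extend it. There is no compound-unit algebra (µm/s and
the like): the model attaches single units to single values, and that is
all the conversion machinery promises.

Temperature conversions are affine and treated as absolute temperatures;
there is no temperature-difference type. Round-trip conversions are exact
to well below 1e-9 relative tolerance, which the test suite asserts.

## Annotations

Map annotations are ordered multimaps: duplicate keys are allowed and
pair order is preserved exactly, because spreadsheet rows and instrument
logs are ordered and a faithful carrier must not canonicalise them. An
annotation is a shared object: the same annotation may be linked to many
targets, but a given (annotation, target) pair only once. `queryMap()`
is exact and case-sensitive; fuzzy matching belongs to the search index,
keeping the typed-query strategy and the indexed-search strategy
separate.

File annotations are stored content-addressed (MD5) under the store's
managed `files/` area, so attaching the same bytes twice stores them
once while remaining two distinct annotations. Ontology references are a
key convention, not a typed feature: a pair `("Ontology Name", x)`
together with `("Ontology ID", y)` carries enough information for an
external lookup.

## Feature tables

A feature table is one HDF5 file: one group, one chunked extensible
dataset per column, schema (names, kinds, string widths, format version)
as group attributes, and an explicit row-count attribute that is advanced
only after all column writes succeed — so a failed append can never
expose a ragged table. Column kinds are `int64`, `float64`, `bool`,
fixed-width NUL-padded UTF-8 `string`, and the reference kinds
`well_ref` / `image_ref` / `roi_ref`. `float64` columns use NaN as the
missing value; the other kinds have no missing representation and the
append rejects one — an explicit contract beats a silent sentinel.

Row indices are 0-based and ranges half-open, matching the on-disk
convention; stating one convention and using it everywhere (reads,
queries, backlinks, CSV export) was judged less error-prone than
translating to R's 1-based indexing at the API boundary of a file format
other tools will read directly.

Queries are deliberately restricted — terms `(column op literal)`
AND-combined, no joins, no SQL — evaluated chunk-wise at 65,536 rows per
chunk (a performance detail that cannot change results). `backlink()` is
exactly the equality query on a reference column, and the test suite
pins the two to a brute-force row scan on randomized tables.

Two canonical layouts are supported for per-cell output, because both
occur in practice: **wide** (one row per ROI, one `float64` column per
feature × channel, plus well/image/ROI reference columns — 78 columns
for 3 channels × 25 features) and **long** (one row per ROI × channel ×
feature with a single value column — 7.2 million rows for a full
384-well plate at 5 fields/well, 50 cells/image). Object time-tracking
is disabled in the HDF5 files so identical write sequences are
byte-identical, which makes seed determinism testable at the file level.

## Bulk annotation

`loadSheet()` turns one sheet row into one map annotation on the matched
well (or image), pairs ordered as the sheet's columns — one annotation
per row rather than one per cell, so a row remains a retrievable unit.
Headers like `"Temperature [°C]"` put the unit into each pair's unit
field. Delimiters follow the extension (`.csv` comma, `.tsv`/`.txt`
tab) with an override flag; encoding is UTF-8 with BOM tolerance, CRLF
and LF both accepted, quoting per RFC 4180. `exportSheet()` writes the
round-trip counterpart and requires a consistent key/unit sequence
within the exported namespace — heterogeneous annotations cannot be
represented in one rectangular sheet without inventing blanks, so the
export refuses instead.

## Search

The index is a full rebuild (`reindex()`): one document per
non-annotation object, containing its own text plus the text of its
linked annotations — tag labels, map keys and values, file-annotation
filenames, and full payload text for text MIME types (text/*, plus
.csv/.tsv/.m by extension). Tokenization splits on non-alphanumeric
characters and lowercases; no stemming, no stop words — the simplest
contract that is exactly reproducible by a brute-force oracle. Queries
require all tokens, rank by total token frequency, and break ties by
object type then ID so results are deterministic. Incremental indexing
is omitted on purpose at desk scale.

## Permissions

Every object carries one (owner, group) record; each group has one
policy on the ladder *private* < *group-read* < *group-read-annotate*,
plus *public-read* which opens reading to everyone. Reading requires
admin, ownership, group membership at group-read or above, or a
public-read policy; annotating requires admin, ownership, or membership
at group-read-annotate. There are no per-object ACLs. Feature tables and
file annotations inherit the permissions of the object they are linked
to; an unlinked table is owner-private. Every read surface —
`objectInfo()`, `getAnnotations()`, `queryMap()`, `getTable()`,
`searchStore()` — consults the same predicate, and the test suite checks
that a private object is invisible through all of them.

Lowering a group's policy after objects exist in it is refused with an
error: data already visible to a group cannot silently "un-escape", and
pretending otherwise would misrepresent what members may have copied.

Ownership reassignment supports the facility workflow (one user imports,
another analyses); annotations keep their own creators across it.

# The synthetic-screen generator

`generateScreen()` emulates the structure of a real screening run: the
full hierarchy, one reagent per well (`compound-0001`, ...), one
rectangular 20×20 ROI per simulated cell on 512×512 images, and Gaussian
feature values. Its defaults are the full-scale conditions the package
is sized for: **one 384-well plate, 5 fields/well, 3 channels, 50
cells/image, 25 features/channel/cell**, giving 1,920 images, 96,000
ROIs and 7,200,000 long-format rows. Cell counts may instead be
Poisson-distributed per image. The RNG is R's Mersenne-Twister with
inversion sampling, seeded once from the mandatory config seed; the draw
order (per image: optional Poisson count, then ROI x positions, then y
positions; finally one vector of feature values) is fixed, so a seed
fully determines the output down to the bytes of the HDF5 files.

What it does **not** emulate: spatial or plate-position effects, channel
correlations, phenotype structure, segmentation errors, or any
biological signal — features are independent Gaussians. Passing tests
therefore demonstrate that the storage, linkage, querying, permission
and import machinery is correct at realistic scale; they say nothing
about analytic methods downstream of storage, which is out of scope for
a metadata-management layer. Pixel planes are generated only on request
(`renderSyntheticPlane()`, Gaussian blobs per ROI) so the full-scale
example stays fast.

# Numerical choices

* Thumbnail windowing is the linear map `clamp((v − min)/(max − min))`
  scaled to 0..255, tinted per channel, **rounded half-up per channel,
  then integer-summed** with saturation at 255. Rounding before the sum
  makes compositing exactly channel-order invariant (integer addition
  commutes; float summation does not).
* Downsampling is block-mean over the largest integer factor, then
  nearest-neighbour to the exact target size, rounding half-up at the
  end — chosen for determinism, not visual optimality.
* Plane medians of even-sized data are the lower–upper midpoint.
* NaN never matches any query comparison, matching IEEE semantics.
* Degenerate inputs error early and loudly: empty planes, empty schemas,
  inverted rendering windows, empty search queries, out-of-bounds reads.

# Persistence

The object store lives in memory backed by an environment (operations
mutate it in place, like a database handle) and persists under a
directory: `store.rds` for the serialized state and `files/` for
content-addressed payloads; feature tables are separate HDF5 files
registered in the store. A serialized single-file image was chosen over
an embedded relational database for a desk-scale library: the store's
query surface (typed lookups, map queries, restricted table predicates)
does not need SQL, and a single serialized state keeps save/open
trivially atomic. The HDF5 files are the only component other tools are
expected to read directly, and their layout (group, per-column datasets,
schema attributes) is documented for that purpose.

# Scale used in the tests

The test suite runs the property suites at modest sizes (100 randomized
tables of up to ~800 rows for the query/brute-force equivalence, 10
randomized annotation stores and sheets for the map-query and round-trip
properties) and runs the full-scale worked example — 7.2 million rows,
78 wide columns — once, end to end. Generation plus append plus count of
the full example takes on the order of ten seconds on a single CPU.

# Known limitations

* No proprietary microscopy format parsing; pixel input is in-memory
  arrays or baseline uncompressed grayscale TIFF.
* No remote access, sessions, or authentication — the permission system
  enforces contracts within one process, not security against a hostile
  actor with filesystem access.
* No SQL, joins, row updates or deletions in feature tables;
  append-only by design.
* Whether a well can belong to two plates is unspecified in the
  underlying data model family; this store forbids it.
* The search index is rebuilt in full; at millions of objects an
  incremental index would be needed.
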