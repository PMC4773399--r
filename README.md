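# hcstore — metadata management for high content screening

High content screening (HCS) experiments combine three kinds of data that
must stay linked to be interpretable: **experimental metadata** (plate
layouts, reagents, cell lines, imaging parameters), **images** (thousands
per plate), and **analytic output** (segmented cell ROIs and per-cell
feature measurements, millions of rows per plate). `hcstore` is an R
package for screening facilities, image-analysis developers and data
curators that puts a single API over three storage strategies matched to
those three kinds:

* a **typed object store** for the containment hierarchy
  Screen → Plate → Well → Field → Image → Channel (plus Reagents and
  ROIs), with stable integer IDs and in-place references to external
  pixel files — pixel bytes are never copied into the store;
* **flexible annotations**: ordered key-value *map annotations* with
  optional scientific units (`"Temperature" : "37" : "°C"`), namespaced
  content-addressed *file annotations*, and *tags*, linkable to any
  object and queryable by exact key/value;
* an **HDF5-backed columnar feature store**: append-only typed columns
  (including well/image/ROI reference columns), column-slice reads, a
  restricted `(column op literal) AND ...` query language, and per-row
  backlinks from measurements to their source objects.

The canonical sizing example is the analytic output of a single 384-well
plate with 5 images/well, 3 channels/image, 50 cells/image and 25
features/channel/cell: a **wide** table of one row per ROI needs 78
columns (3 reference columns + 25 × 3 feature columns), and a **long**
table of one row per (ROI, channel, feature) holds
384 × 5 × 50 × 3 × 25 = **7,200,000 rows**. Both layouts are supported;
a seeded generator reproduces the whole example in seconds.

Around the core: bulk CSV/TSV import of plate metadata keyed by well
address, token-based text search across names, tags, map pairs and text
attachments, group-based permissions (private / group-read /
group-read-annotate / public-read) consulted on every read path,
per-plane pixel statistics and windowed RGB thumbnail rendering, and a
command-line interface (`exec/hcstore`).

## Worked example

```r
library(hcstore)
st <- initStore(file.path(tempdir(), "demo-store"))

# a seeded synthetic screen: 96 wells, 2 fields/well, 2 channels,
# 10 cells/image, 5 features/channel/cell
cfg <- screenConfig(plate_format = 96, fields_per_well = 2, channels = 2,
                    cells = list(kind = "constant", k = 10), n_features = 5,
                    seed = 20)
s <- generateScreen(st, cfg, file.path(tempdir(), "features.h5"))
cat("wells:", s$wells, " images:", s$images, " rois:", s$rois,
    " feature_rows:", s$feature_rows, "\n")
#> wells: 96  images: 192  rois: 1920  feature_rows: 19200

# bulk-annotate the plate from a CSV keyed by well address
sheet <- file.path(tempdir(), "layout.csv")
generateSheet(cfg, sheet)
rep <- loadSheet(st, sheet, s$plates[[1]])
rep$annotations_created
#> [1] 96

# exact typed queries over map annotations
queryMap(st, "Cell line", "U2OS")[1:3, ]
#>   target_otype target_oid annotation_oid
#> 1         well          1              1
#> 2         well          2              2
#> 3         well          3              3

# feature rows link back to their source ROI
tab <- getTable(st, s$table)
rows <- backlink(tab, "roi", objectRef("roi", 1))
length(rows)                      # channels x features rows for this cell
#> [1] 10
readRows(tab, c("channel", "feature", "value"), rows[1], rows[1] + 3)
#> $channel: 1 1 1
#> $feature: 1 2 3
#> $value:   1.381 -2.662 0.868

# token-based search across all annotation text
reindex(st)
head(searchStore(st, "U2OS"), 3)
#>   otype oid score
#> 1  well   1     1
#> 2  well   2     1
#> 3  well   3     1

# unit-bearing quantities convert through the registry
convertQuantity(quantity(37, "°C"), "K")
#> 310.15 K (temperature)
```

The `feature_rows` count is the long-layout closed form
wells × fields × cells × channels × features; `backlink()` finds exactly
the channels × features = 10 measurement rows of one segmented cell; the
search hits are the wells whose bulk annotations mention the queried
cell line.

## Command line

```sh
exec/hcstore init --store /tmp/screen
exec/hcstore gen --store /tmp/screen --seed 7 --table /tmp/features.h5
exec/hcstore query-map --store /tmp/screen --key "Cell line" --value U2OS
exec/hcstore table-query --table /tmp/features.h5 --where 'value > 0.5 AND channel == 1'
exec/hcstore search --store /tmp/screen --query "mitotic"
```

See the vignette (`vignettes/hcs-metadata.Rmd`) for the data model, the
permission rules, the numerical conventions and the design rationale.
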