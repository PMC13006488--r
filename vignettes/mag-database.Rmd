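---
title: "Design and methods: a local relational database for MAG workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and methods: a local relational database for MAG workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`magdb` integrates the file outputs of a prokaryotic metagenome-assembled
genome (MAG) workflow into one queryable relational database. This
vignette explains the data model, the parsing dialects, the population
pipeline and the synthetic test project, including the design decisions
that were genuinely open and how they were resolved.

## The data model

The schema holds 28 tables in three categories. *Project-management
entities* record provenance: a `project` contains `sample`s and
`assembly`s; every ingested input is tied to a `run` that names the
`tool` (name + version) and the `source` (the configured file or
directory) that produced it; `plugin_registration` snapshots the
annotation plugins and their enabled state. *File entities* store what
each file literally said — one row per FASTA record, GFF feature line,
taxonomy row, cluster row, quality row or annotation line, each file with
its path and SHA-256 digest. *Biological entities* are the integrated
layer: `genome`, `contig`, `gene`, `protein`, `taxon`,
`genome_cluster`, `taxonomy_assignment`, `protein_annotation` and
`genome_quality`, every row carrying a foreign key back to the file row
it came from.

The design is third normal form: a fact lives in exactly one table and
is referenced by key everywhere else. Taxonomy names appear only in
`taxon`; a gene knows its contig by key, not by repeating the seqid; the
only stored lengths (`contig.length_bp`, `protein.sequence_length_aa`)
are attributes of the entity itself. All keys are surrogate integers,
with a natural-key uniqueness index per table (for example
`(assembly, name)` for genomes, or the sextuple
`(protein, tool, type, accession, coords)` for annotations, with `NULL`
coordinates coalesced to a sentinel inside the index so they deduplicate
like values). The schema version is stored in SQLite's `user_version`
pragma rather than a metadata table, so the catalog contains exactly the
28 user tables; a target holding foreign tables or a different version is
refused rather than migrated.

The backend is any DBI connection in principle, but the supported and
tested target is embedded SQLite — a deliberate desk-scale choice: tests
and analyses need no server, and one file *is* the database.

## Validation and insertion

Every record passes `validate_record()` before touching the store: field
presence, scalar types, enumerated values (strands, ranks, annotation
types) and per-table invariants (coordinate ordering, positive lengths,
percentage ranges). The same rules are compiled into SQL `CHECK`
constraints, so even out-of-band writes are constrained.

`insert_if_absent()` is the single write path. It memoizes natural keys
in an in-memory cache primed from the table on first use, so a key is
looked up in the database at most once per session, and it commits in
transactions of `batch_size` rows (default 1000, configurable; the
default balances transaction overhead against rollback granularity at
desk scale). The consequence used throughout is idempotency: re-running
any stage, or the whole pipeline, adds zero rows.

`integrity_check()` audits the declared foreign-key graph for orphans and
re-evaluates all invariants over stored rows, including two rules a
single-table constraint cannot express: a gene must end within its
contig, and a taxon's parent must sit exactly one rank above it.

## Population and assembly order

`populate()` drives ingestion from a TOML configuration (project name,
per-assembly input paths, optional tool names/versions, options). Stages
run serially in fixed dependency order per assembly: bin FASTA ingestion,
genomes + contigs, GFF ingestion, genes, protein FASTA ingestion,
proteins, annotation plugins, dereplication clusters, taxonomy, quality.
Parents are always written before children, so an interruption at any
point leaves a referentially closed (if incomplete) database; a re-run
completes it. Each stage refuses to run if its prerequisite stage has
not, without partial writes.

Cross-file identity resolution follows fixed rules:

* genome names are bin-file stems with one recognized FASTA extension
  (`.fa`/`.fasta`/`.fna`) stripped; every other file joins on that stem;
* a gene is a GFF `CDS` feature; its identifier is the `ID` attribute,
  falling back to `locus_tag` (Prokka emits both, and `ID` matches the
  `.faa` headers); other feature types (tRNA, rRNA) remain file entities
  — the biological layer models genes and proteins only;
* coordinates are stored exactly as GFF3 states them: 1-based,
  inclusive, forward-axis regardless of strand;
* a protein joins the gene whose identifier equals its FASTA record id
  within the same genome; a trailing `*` stop mark is excluded from the
  stored length;
* matching is strict by default — any unresolved identifier aborts the
  assembly with the offending key named; lenient mode records unmatched
  keys in the stage report instead.

Run bookkeeping is content-based: one `run` row per (project, tool,
source), with the wall-clock timestamp recorded on first ingest but
excluded from the run's identity. A timestamp-keyed run row would make
every re-run insert new rows, defeating end-to-end idempotency; under
the content-based key a repeated `populate()` is a strict no-op. Tool
names and versions come from the configuration when supplied and are
recorded as `unknown` otherwise. Every file is digested (SHA-256) into
the audit trail; a path whose digest changed since first ingest is
treated as a new file version, which this version refuses in strict mode
rather than silently re-ingesting.

## Annotation plugins and their dialects

A plugin is a descriptor plus a parser from a file path to a tibble of
unified annotations: protein key, source tool, annotation type (family,
subfamily, domain, EC number, GO term or description), accession, and
optional description, score and coordinates. Plugins only ever populate
existing tables — nothing in the plugin path can create or alter schema
objects. Discovery covers the four built-in reference plugins plus any
installed package following the `magdb.plugin.<name>` convention;
installation from package indexes is distribution, not computation, and
is out of scope.

Dialect decisions, where upstream formats vary or are undocumented:

* **dbCAN**: reading is header-driven; the consensus column is
  `Recommend Results` when present, otherwise the `HMMER` column. The
  consensus is authoritative: per-tool columns are retained verbatim in
  the annotation-entry file rows but not expanded into annotations, which
  avoids double-counting families in queries. Consensus units split on
  `+`; `GH5_2(31-330)` yields a family annotation `GH5` with coordinates
  and a subfamily annotation `GH5_2` (accession only); the `#ofTools`
  agreement count rides along as the score. A row whose family token
  lacks a CAZy class code (GH, GT, PL, CE, AA, CBM) is skipped with a
  warning and counted. The `EC#` column stays verbatim in the file
  entity; expanding it would duplicate what CLEAN/ProteInfer assert with
  scores.
* **InterProScan**: headerless TSV, ≥ 11 columns; each line yields a
  domain annotation for the member-database signature (source
  `interproscan:<analysis>`, e-value as score, coordinates), plus a
  domain annotation for the InterPro accession and one GO-term annotation
  per id in the GO column.
* **CLEAN** and **ProteInfer** have no single published output layout,
  so the package fixes one concrete contract each (documented in the
  parser help pages) and the synthetic generator writes exactly those
  dialects: CLEAN as `protein,EC:a.b.c.d/score;...` and ProteInfer as a
  `sequence_name / predicted_label / confidence` TSV with `GO:`/`EC:`
  prefixes selecting the annotation type.

## Taxonomy and the definition of novelty

GTDB-style classification strings split on `;` into the seven canonical
ranks (`d__` … `s__`). An empty suffix is an unassigned rank;
`Unclassified` or truncated strings leave all missing ranks unassigned
rather than erroring, because real classifier output contains them. A
taxon row is created per assigned (rank, name), unique across genomes,
with the parent pointer set only when the immediately higher rank is
assigned. Each genome gets one assignment row pointing at its most
specific assigned taxon.

"Taxonomic novelty" is operationalized as *species rank unassigned*,
recorded as a flag at ingest time. Because the classifier itself states
no formal rule, the query layer exposes the threshold as a parameter:
`novelty_rank = "genus"` selects genomes unassigned at genus or deeper,
and so on. The two named queries — CAZymes of novel taxa, and per-genome
distinct-protein counts for one exact family accession — consider only
family/subfamily annotations from the dbCAN source; domain annotations
from other tools are not CAZyme calls.

## The read-only API

The HTTP/JSON API exposes entity listings (with limit/offset pagination)
and the named queries. It is strictly read-only: only `GET` is accepted,
and the test suite asserts that no endpoint changes any table's row
count. Where the surrounding design could be read as allowing
manipulation over HTTP, the conservative reading wins — mutation goes
through the ingestion pipeline, where validation and idempotency live.

## The synthetic study project

`generate_project_fixture()` writes a complete project tree and the TOML
configuration that ingests it, plus a `manifest.json` of ground-truth
counts, derived from the in-memory truth the files are rendered from —
including the expected post-ingest row count of all 28 tables. Its
defaults are the standard study conditions used throughout the tests:
5 genomes × 4 contigs × 6 genes (120 proteins), novel fraction 0.4
(2 species-unassigned genomes), CAZyme density 0.2 (24 annotated
proteins), ⌈5/2⌉ = 3 dereplication clusters. These sizes exercise every
code path (multi-unit consensus strings, subfamilies, shared genera,
winners, a tRNA per genome, a trailing `##FASTA` block in each GFF)
while keeping a full generate–ingest–query cycle around two seconds, so
properties can be checked across many seeds (the query-oracle test runs
20).

Determinism: one RNG stream per file type, each derived from the master
seed, so the same seed reproduces a byte-identical tree and adding a file
type never perturbs existing files. Gene placement is sequential
non-overlapping windows with a fixed 50 bp gap, which guarantees the
coordinate invariants by construction; protein sequences have
⌊gene length / 3⌋ residues plus a `*` stop.

What the generator deliberately does **not** emulate: realistic sequence
composition (codon usage, GC skew), fragmented or contaminated bins,
proteins whose ids disagree with gene identifiers, malformed or
version-skewed annotation files beyond the dialects above, and
multi-sample/multi-assembly projects. Passing tests therefore demonstrate
the correctness of parsing, assembly, storage and querying under
well-formed inputs of the declared dialects — not robustness to every
format variant in the wild.

## Degenerate inputs and numerical choices

Empty FASTA files yield genomes with zero contigs plus a warning; a
zero-length contig is a validation error; header-only annotation files
yield empty annotation sets; an empty database answers queries with empty
results, not errors. Scores are stored as given (CLEAN scores above 1 are
legal). E-values parse as plain doubles; `-` means absent. Ties do not
arise in the query layer (results are ordered by name), and no floating
comparison enters any key.

## Known limitations

* Only the SQLite target is exercised; the access layer is DBI-generic
  but a client-server backend is untested here.
* File-to-assembly scoping inside the database goes through the project;
  in a multi-assembly project the standalone assembly stages should be
  given explicit file ids (as `populate()` does) rather than relying on
  project-wide defaults.
* No schema migrations: a version mismatch aborts.
* No transparent gzip; inputs are plain text.
* Annotation plugins for eggNOG/KOfam, dbCAN substrate/CGC outputs, and
  promotion of tRNA/rRNA features to biological entities are natural
  extensions under the same contracts.
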