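# Declarative definition of the 28-table schema and its DDL.

#' Canonical taxonomic ranks, highest to lowest
#'
#' The seven-rank lineage used by GTDB-style classifications, ordered from
#' domain down to species.
#'
#' @return Character vector of length 7.
#' @export
taxonomic_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' CAZyme family class codes
#' @return Character vector of the six CAZy class prefixes.
#' @export
cazyme_classes <- function() {
  c("GH", "GT", "PL", "CE", "AA", "CBM")
}

annotation_types <- function() {
  c("family", "subfamily", "domain", "ec_number", "go_term", "description")
}

strand_values <- function() c("+", "-", ".", "?")

MAGDB_SCHEMA_VERSION <- 1L

# A column spec: type in {"integer","text","real","bool"}; nullable flag;
# enum restricts text values; fk = c(parent_table, parent_column).
col_def <- function(type, nullable = FALSE, enum = NULL, fk = NULL) {
  list(type = type, nullable = nullable, enum = enum, fk = fk)
}

# Each table: category, pk, columns, natural_key, checks (named list of
# R predicates over a one-row record, also rendered as SQL CHECKs where
# expressible in one table).
magdb_schema_def <- function() {
  ranks <- taxonomic_ranks()
  list(
    # -- project management -------------------------------------------------
    project = list(
      category = "project_management", pk = "project_id",
      columns = list(name = col_def("text")),
      natural_key = "name", checks = list()
    ),
    sample = list(
      category = "project_management", pk = "sample_id",
      columns = list(
        project_id = col_def("integer", fk = c("project", "project_id")),
        name = col_def("text")
      ),
      natural_key = c("project_id", "name"), checks = list()
    ),
    assembly = list(
      category = "project_management", pk = "assembly_id",
      columns = list(
        project_id = col_def("integer", fk = c("project", "project_id")),
        name = col_def("text")
      ),
      natural_key = c("project_id", "name"), checks = list()
    ),
    tool = list(
      category = "project_management", pk = "tool_id",
      columns = list(name = col_def("text"), version = col_def("text")),
      natural_key = c("name", "version"), checks = list()
    ),
    source = list(
      category = "project_management", pk = "source_id",
      columns = list(label = col_def("text")),
      natural_key = "label", checks = list()
    ),
    run = list(
      category = "project_management", pk = "run_id",
      columns = list(
        project_id = col_def("integer", fk = c("project", "project_id")),
        tool_id = col_def("integer", fk = c("tool", "tool_id")),
        source_id = col_def("integer", fk = c("source", "source_id")),
        started_at = col_def("text")
      ),
      natural_key = c("project_id", "tool_id", "source_id"), checks = list()
    ),
    plugin_registration = list(
      category = "project_management", pk = "plugin_registration_id",
      columns = list(
        name = col_def("text"),
        target_tool = col_def("text"),
        version = col_def("text"),
        enabled = col_def("bool")
      ),
      natural_key = "name", checks = list()
    ),
    # -- file entities ------------------------------------------------------
    fasta_file = list(
      category = "file", pk = "fasta_file_id",
      columns = list(
        run_id = col_def("integer", fk = c("run", "run_id")),
        path = col_def("text"),
        sha256 = col_def("text"),
        file_kind = col_def("text", enum = c("bin", "protein"))
      ),
      natural_key = "path", checks = list()
    ),
    fasta_entry = list(
      category = "file", pk = "fasta_entry_id",
      columns = list(
        fasta_file_id = col_def("integer", fk = c("fasta_file", "fasta_file_id")),
        record_id = col_def("text"),
        description = col_def("text", nullable = TRUE),
        sequence = col_def("text", nullable = TRUE)
      ),
      natural_key = c("fasta_file_id", "record_id"), checks = list()
    ),
    gff_file = list(
      category = "file", pk = "gff_file_id",
      columns = list(
        run_id = col_def("integer", fk = c("run", "run_id")),
        path = col_def("text"),
        sha256 = col_def("text")
      ),
      natural_key = "path", checks = list()
    ),
    gff_entry = list(
      category = "file", pk = "gff_entry_id",
      columns = list(
        gff_file_id = col_def("integer", fk = c("gff_file", "gff_file_id")),
        line_number = col_def("integer"),
        seqid = col_def("text"),
        source = col_def("text"),
        feature_type = col_def("text"),
        start = col_def("integer"),
        end = col_def("integer"),
        score = col_def("real", nullable = TRUE),
        strand = col_def("text", enum = strand_values()),
        frame = col_def("integer", nullable = TRUE),
        attributes = col_def("text", nullable = TRUE)
      ),
      natural_key = c("gff_file_id", "line_number"),
      checks = list(
        start_positive = list(
          sql = '"start" >= 1',
          fn = function(r) isTRUE(r$start >= 1),
          message = "start must be >= 1"
        ),
        start_le_end = list(
          sql = '"start" <= "end"',
          fn = function(r) isTRUE(r$start <= r$end),
          message = "start must be <= end"
        )
      )
    ),
    dereplication_file = list(
      category = "file", pk = "dereplication_file_id",
      columns = list(
        run_id = col_def("integer", fk = c("run", "run_id")),
        path = col_def("text"),
        sha256 = col_def("text"),
        table_role = col_def("text", enum = c("clusters", "winners"))
      ),
      natural_key = "path", checks = list()
    ),
    dereplication_entry = list(
      category = "file", pk = "dereplication_entry_id",
      columns = list(
        dereplication_file_id = col_def(
          "integer", fk = c("dereplication_file", "dereplication_file_id")
        ),
        genome_name = col_def("text"),
        cluster_label = col_def("text"),
        is_winner = col_def("bool")
      ),
      natural_key = c("dereplication_file_id", "genome_name"),
      checks = list(
        cluster_label_nonempty = list(
          sql = "length(cluster_label) > 0",
          fn = function(r) isTRUE(nzchar(r$cluster_label)),
          message = "cluster_label must be non-empty"
        )
      )
    ),
    taxonomy_file = list(
      category = "file", pk = "taxonomy_file_id",
      columns = list(
        run_id = col_def("integer", fk = c("run", "run_id")),
        path = col_def("text"),
        sha256 = col_def("text")
      ),
      natural_key = "path", checks = list()
    ),
    taxonomy_entry = list(
      category = "file", pk = "taxonomy_entry_id",
      columns = list(
        taxonomy_file_id = col_def("integer", fk = c("taxonomy_file", "taxonomy_file_id")),
        user_genome = col_def("text"),
        classification = col_def("text")
      ),
      natural_key = c("taxonomy_file_id", "user_genome"), checks = list()
    ),
    quality_file = list(
      category = "file", pk = "quality_file_id",
      columns = list(
        run_id = col_def("integer", fk = c("run", "run_id")),
        path = col_def("text"),
        sha256 = col_def("text")
      ),
      natural_key = "path", checks = list()
    ),
    quality_entry = list(
      category = "file", pk = "quality_entry_id",
      columns = list(
        quality_file_id = col_def("integer", fk = c("quality_file", "quality_file_id")),
        genome_name = col_def("text"),
        completeness_pct = col_def("real"),
        contamination_pct = col_def("real")
      ),
      natural_key = c("quality_file_id", "genome_name"),
      checks = list(
        completeness_range = list(
          sql = "completeness_pct >= 0 AND completeness_pct <= 100",
          fn = function(r) isTRUE(r$completeness_pct >= 0 && r$completeness_pct <= 100),
          message = "completeness_pct must be in [0, 100]"
        ),
        contamination_nonneg = list(
          sql = "contamination_pct >= 0",
          fn = function(r) isTRUE(r$contamination_pct >= 0),
          message = "contamination_pct must be >= 0"
        )
      )
    ),
    protein_annotation_file = list(
      category = "file", pk = "protein_annotation_file_id",
      columns = list(
        run_id = col_def("integer", fk = c("run", "run_id")),
        path = col_def("text"),
        sha256 = col_def("text"),
        plugin_name = col_def("text")
      ),
      natural_key = "path", checks = list()
    ),
    protein_annotation_entry = list(
      category = "file", pk = "protein_annotation_entry_id",
      columns = list(
        protein_annotation_file_id = col_def(
          "integer", fk = c("protein_annotation_file", "protein_annotation_file_id")
        ),
        line_number = col_def("integer"),
        raw_line = col_def("text", nullable = TRUE)
      ),
      natural_key = c("protein_annotation_file_id", "line_number"), checks = list()
    ),
    # -- biological entities ------------------------------------------------
    genome = list(
      category = "biological", pk = "genome_id",
      columns = list(
        assembly_id = col_def("integer", fk = c("assembly", "assembly_id")),
        name = col_def("text"),
        genome_cluster_id = col_def(
          "integer", nullable = TRUE, fk = c("genome_cluster", "genome_cluster_id")
        ),
        fasta_file_id = col_def("integer", fk = c("fasta_file", "fasta_file_id"))
      ),
      natural_key = c("assembly_id", "name"), checks = list()
    ),
    genome_cluster = list(
      category = "biological", pk = "genome_cluster_id",
      columns = list(
        assembly_id = col_def("integer", fk = c("assembly", "assembly_id")),
        label = col_def("text"),
        representative_genome_id = col_def(
          "integer", nullable = TRUE, fk = c("genome", "genome_id")
        )
      ),
      natural_key = c("assembly_id", "label"), checks = list()
    ),
    contig = list(
      category = "biological", pk = "contig_id",
      columns = list(
        genome_id = col_def("integer", fk = c("genome", "genome_id")),
        name = col_def("text"),
        length_bp = col_def("integer"),
        fasta_entry_id = col_def("integer", fk = c("fasta_entry", "fasta_entry_id"))
      ),
      natural_key = c("genome_id", "name"),
      checks = list(
        length_positive = list(
          sql = "length_bp >= 1",
          fn = function(r) isTRUE(r$length_bp >= 1),
          message = "length_bp must be >= 1"
        )
      )
    ),
    gene = list(
      category = "biological", pk = "gene_id",
      columns = list(
        contig_id = col_def("integer", fk = c("contig", "contig_id")),
        identifier = col_def("text"),
        start_1based = col_def("integer"),
        end_1based = col_def("integer"),
        strand = col_def("text", enum = strand_values()),
        gff_entry_id = col_def("integer", fk = c("gff_entry", "gff_entry_id"))
      ),
      natural_key = c("contig_id", "identifier"),
      checks = list(
        start_positive = list(
          sql = "start_1based >= 1",
          fn = function(r) isTRUE(r$start_1based >= 1),
          message = "start_1based must be >= 1"
        ),
        start_le_end = list(
          sql = "start_1based <= end_1based",
          fn = function(r) isTRUE(r$start_1based <= r$end_1based),
          message = "start_1based must be <= end_1based"
        )
      )
    ),
    protein = list(
      category = "biological", pk = "protein_id",
      columns = list(
        gene_id = col_def("integer", fk = c("gene", "gene_id")),
        name = col_def("text"),
        sequence_length_aa = col_def("integer"),
        fasta_entry_id = col_def("integer", fk = c("fasta_entry", "fasta_entry_id"))
      ),
      natural_key = "gene_id",
      checks = list(
        length_positive = list(
          sql = "sequence_length_aa >= 1",
          fn = function(r) isTRUE(r$sequence_length_aa >= 1),
          message = "sequence_length_aa must be >= 1"
        )
      )
    ),
    taxon = list(
      category = "biological", pk = "taxon_id",
      columns = list(
        rank = col_def("text", enum = ranks),
        name = col_def("text"),
        parent_id = col_def("integer", nullable = TRUE, fk = c("taxon", "taxon_id"))
      ),
      natural_key = c("rank", "name"), checks = list()
    ),
    taxonomy_assignment = list(
      category = "biological", pk = "taxonomy_assignment_id",
      columns = list(
        genome_id = col_def("integer", fk = c("genome", "genome_id")),
        taxon_id = col_def("integer", nullable = TRUE, fk = c("taxon", "taxon_id")),
        lowest_assigned_rank = col_def("text", nullable = TRUE, enum = ranks),
        is_novel_species = col_def("bool"),
        taxonomy_entry_id = col_def("integer", fk = c("taxonomy_entry", "taxonomy_entry_id"))
      ),
      natural_key = "genome_id", checks = list()
    ),
    protein_annotation = list(
      category = "biological", pk = "protein_annotation_id",
      columns = list(
        protein_id = col_def("integer", fk = c("protein", "protein_id")),
        protein_annotation_entry_id = col_def(
          "integer", fk = c("protein_annotation_entry", "protein_annotation_entry_id")
        ),
        source_tool = col_def("text"),
        annotation_type = col_def("text", enum = annotation_types()),
        accession = col_def("text"),
        description = col_def("text", nullable = TRUE),
        score = col_def("real", nullable = TRUE),
        coord_start = col_def("integer", nullable = TRUE),
        coord_stop = col_def("integer", nullable = TRUE)
      ),
      natural_key = c(
        "protein_id", "source_tool", "annotation_type", "accession",
        "coord_start", "coord_stop"
      ),
      checks = list(
        accession_nonempty = list(
          sql = "length(accession) > 0",
          fn = function(r) isTRUE(nzchar(r$accession)),
          message = "accession must be non-empty"
        ),
        coord_order = list(
          sql = "coord_start IS NULL OR coord_stop IS NULL OR coord_start <= coord_stop",
          fn = function(r) {
            if (is.null(r$coord_start) || is.null(r$coord_stop) ||
                is.na(r$coord_start) || is.na(r$coord_stop)) return(TRUE)
            isTRUE(r$coord_start <= r$coord_stop)
          },
          message = "coord_start must be <= coord_stop"
        ),
        coord_start_positive = list(
          sql = "coord_start IS NULL OR coord_start >= 1",
          fn = function(r) {
            if (is.null(r$coord_start) || is.na(r$coord_start)) return(TRUE)
            isTRUE(r$coord_start >= 1)
          },
          message = "coord_start must be >= 1"
        )
      )
    ),
    genome_quality = list(
      category = "biological", pk = "genome_quality_id",
      columns = list(
        genome_id = col_def("integer", fk = c("genome", "genome_id")),
        completeness_pct = col_def("real"),
        contamination_pct = col_def("real"),
        quality_entry_id = col_def("integer", fk = c("quality_entry", "quality_entry_id"))
      ),
      natural_key = "genome_id",
      checks = list(
        completeness_range = list(
          sql = "completeness_pct >= 0 AND completeness_pct <= 100",
          fn = function(r) isTRUE(r$completeness_pct >= 0 && r$completeness_pct <= 100),
          message = "completeness_pct must be in [0, 100]"
        ),
        contamination_nonneg = list(
          sql = "contamination_pct >= 0",
          fn = function(r) isTRUE(r$contamination_pct >= 0),
          message = "contamination_pct must be >= 0"
        )
      )
    )
  )
}

# Memoized copy: the definition is consulted constantly during ingestion.
schema_cache <- new.env(parent = emptyenv())

magdb_schema <- function() {
  if (is.null(schema_cache$def)) schema_cache$def <- magdb_schema_def()
  schema_cache$def
}

#' Inventory of the database tables
#'
#' The relational model organizes its 28 tables into three categories:
#' project-management entities (workflow runs, tools, sources), file
#' entities (rows parsed verbatim from workflow output files) and
#' biological entities (genomes, contigs, genes, proteins and their
#' annotations, assembled across files by foreign keys).
#'
#' @return A tibble with columns `table_name` and `category`.
#' @export
#' @examples
#' table_inventory()
#' dplyr::count(table_inventory(), category)
table_inventory <- function() {
  def <- magdb_schema()
  tibble::tibble(
    table_name = names(def),
    category = purrr::map_chr(def, "category")
  )
}

sql_type <- function(type) {
  switch(type,
    integer = "INTEGER", bool = "INTEGER", real = "REAL", text = "TEXT",
    rlang::abort(paste0("unknown column type: ", type))
  )
}

quote_id <- function(x) paste0('"', x, '"')

# Render one CREATE TABLE statement plus its unique index.
table_ddl <- function(table_name, def) {
  cols <- c(sprintf("%s INTEGER PRIMARY KEY", quote_id(def$pk)))
  for (cn in names(def$columns)) {
    cd <- def$columns[[cn]]
    decl <- sprintf("%s %s", quote_id(cn), sql_type(cd$type))
    if (!cd$nullable) decl <- paste(decl, "NOT NULL")
    if (!is.null(cd$enum)) {
      decl <- paste0(
        decl, " CHECK (", quote_id(cn), " IN (",
        paste(sprintf("'%s'", cd$enum), collapse = ", "), "))"
      )
    }
    if (!is.null(cd$fk)) {
      decl <- paste0(
        decl, sprintf(" REFERENCES %s(%s)", quote_id(cd$fk[[1]]), quote_id(cd$fk[[2]]))
      )
    }
    cols <- c(cols, decl)
  }
  for (ck in def$checks) cols <- c(cols, paste0("CHECK (", ck$sql, ")"))
  create <- sprintf(
    "CREATE TABLE %s (\n  %s\n)", quote_id(table_name), paste(cols, collapse = ",\n  ")
  )
  # Unique index over the natural key; nullable key parts are coalesced to a
  # sentinel so NULL coordinates do not defeat deduplication.
  key_exprs <- purrr::map_chr(def$natural_key, function(k) {
    if (isTRUE(def$columns[[k]]$nullable)) {
      sprintf("IFNULL(%s, -1)", quote_id(k))
    } else {
      quote_id(k)
    }
  })
  index <- sprintf(
    "CREATE UNIQUE INDEX %s ON %s (%s)",
    quote_id(paste0("uq_", table_name)), quote_id(table_name),
    paste(key_exprs, collapse = ", ")
  )
  c(create, index)
}

# Foreign-key relationships declared in the schema, one row each.
schema_relationships <- function() {
  def <- magdb_schema()
  purrr::map_dfr(names(def), function(tn) {
    cols <- def[[tn]]$columns
    purrr::map_dfr(names(cols), function(cn) {
      fk <- cols[[cn]]$fk
      if (is.null(fk)) return(NULL)
      tibble::tibble(
        child_table = tn, child_column = cn,
        parent_table = fk[[1]], parent_column = fk[[2]]
      )
    })
  })
}

n_schema_constraints <- function() {
  def <- magdb_schema()
  n_unique <- length(def)                    # one natural-key index per table
  n_fk <- nrow(schema_relationships())
  n_check <- sum(purrr::map_int(def, function(d) {
    length(d$checks) + sum(purrr::map_lgl(d$columns, ~ !is.null(.x$enum)))
  }))
  n_pk <- length(def)
  n_unique + n_fk + n_check + n_pk
}
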