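# Connection handling, schema creation, record validation, memoized batch
# insertion and referential-integrity auditing over the embedded store.

magdb_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "magdb_error"), ...)
}

#' Open a MAG database
#'
#' Connects to an embedded single-file SQLite database (created if absent)
#' or to an in-memory database when `target = ":memory:"`. Foreign-key
#' enforcement is switched on for the connection.
#'
#' @param target Path to the database file, or `":memory:"`.
#' @return An object of class `magdb` wrapping the DBI connection.
#' @export
#' @examples
#' db <- magdb_connect(":memory:")
#' initialize_schema(db)
#' magdb_disconnect(db)
magdb_connect <- function(target = ":memory:") {
  con <- tryCatch(
    DBI::dbConnect(RSQLite::SQLite(), target),
    error = function(e) {
      magdb_abort(
        paste0("cannot connect to database target '", target, "': ",
               conditionMessage(e)),
        "magdb_connection_error"
      )
    }
  )
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  structure(list(con = con, target = target), class = "magdb")
}

#' Close a MAG database connection
#' @param db A `magdb` object from [magdb_connect()].
#' @return Invisibly `TRUE`.
#' @export
magdb_disconnect <- function(db) {
  DBI::dbDisconnect(db_con(db))
  invisible(TRUE)
}

db_con <- function(db) {
  if (inherits(db, "magdb")) return(db$con)
  if (inherits(db, "DBIConnection")) return(db)
  magdb_abort("`db` must be a magdb object from magdb_connect()",
              "magdb_type_error")
}

#' @export
print.magdb <- function(x, ...) {
  cat("<magdb> target:", x$target, "\n")
  tabs <- user_tables(x)
  cat("  tables:", length(tabs), "\n")
  invisible(x)
}

user_tables <- function(db) {
  setdiff(DBI::dbListTables(db_con(db)), "sqlite_sequence")
}

schema_version_of <- function(db) {
  as.integer(DBI::dbGetQuery(db_con(db), "PRAGMA user_version")[[1]])
}

#' Create the relational schema
#'
#' Creates all 28 tables with their primary keys, foreign keys, natural-key
#' uniqueness indexes and check constraints. Idempotent: calling it against
#' a database that already holds an identical schema version is a no-op.
#' A database containing tables from a different schema version aborts.
#'
#' @param db A `magdb` connection.
#' @return A `magdb_schema_report`: list with `total_tables`, `categories`,
#'   `tables_per_category` (tibble) and `n_constraints`.
#' @export
#' @examples
#' db <- magdb_connect(":memory:")
#' initialize_schema(db)$total_tables
#' magdb_disconnect(db)
initialize_schema <- function(db) {
  con <- db_con(db)
  def <- magdb_schema()
  existing <- user_tables(db)
  if (length(existing) > 0) {
    same <- setequal(existing, names(def)) &&
      schema_version_of(db) == MAGDB_SCHEMA_VERSION
    if (!same) {
      magdb_abort(
        paste0(
          "database target already contains tables from a different schema ",
          "version (found version ", schema_version_of(db), ", expected ",
          MAGDB_SCHEMA_VERSION, ")"
        ),
        "magdb_schema_conflict"
      )
    }
  } else {
    for (tn in names(def)) {
      for (stmt in table_ddl(tn, def[[tn]])) DBI::dbExecute(con, stmt)
    }
    DBI::dbExecute(con, sprintf("PRAGMA user_version = %d", MAGDB_SCHEMA_VERSION))
  }
  inv <- table_inventory()
  per_cat <- dplyr::count(inv, .data$category, name = "n_tables")
  structure(
    list(
      total_tables = length(user_tables(db)),
      categories = nrow(per_cat),
      tables_per_category = per_cat,
      n_constraints = n_schema_constraints()
    ),
    class = "magdb_schema_report"
  )
}

#' @export
print.magdb_schema_report <- function(x, ...) {
  cat("Schema:", x$total_tables, "tables in", x$categories, "categories;",
      x$n_constraints, "declared constraints\n")
  print(x$tables_per_category)
  invisible(x)
}

#' Count rows in every table
#'
#' @param db A `magdb` connection.
#' @return A tibble with columns `table_name`, `category`, `n_rows`.
#' @export
table_counts <- function(db) {
  con <- db_con(db)
  inv <- table_inventory()
  inv$n_rows <- purrr::map_int(inv$table_name, function(tn) {
    as.integer(DBI::dbGetQuery(
      con, sprintf("SELECT COUNT(*) FROM %s", quote_id(tn))
    )[[1]])
  })
  inv
}

# -- validation --------------------------------------------------------------

coerce_scalar <- function(value, type, field, table) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return(NA)
  if (length(value) != 1) {
    magdb_abort(
      sprintf("field '%s' of %s must be a scalar", field, table),
      "magdb_validation_error"
    )
  }
  ok <- switch(type,
    integer = is.numeric(value) && (is.na(value) || value == trunc(value)),
    real = is.numeric(value),
    text = is.character(value),
    bool = is.logical(value) || (is.numeric(value) && value %in% c(0, 1))
  )
  if (!isTRUE(ok)) {
    magdb_abort(
      sprintf("field '%s' of %s must have type %s", field, table, type),
      "magdb_validation_error"
    )
  }
  switch(type,
    integer = as.integer(value),
    real = as.numeric(value),
    text = value,
    bool = as.integer(as.logical(value))
  )
}

#' Validate a candidate record against its table's contract
#'
#' Checks field presence, scalar types, enumerated values and the table's
#' invariants (coordinate ordering, positivity, percentage ranges, ...).
#' A record is returned, normalized for storage, only if every rule holds;
#' otherwise a classed validation error names the offending field and rule.
#'
#' @param record Named list (or one-row data frame) of field values.
#' @param table Name of one of the 28 tables.
#' @return The validated record as a named list, with missing nullable
#'   fields filled with `NA`.
#' @export
#' @examples
#' validate_record(list(genome_id = 1, name = "c1", length_bp = 150,
#'                      fasta_entry_id = 1), "contig")
validate_record <- function(record, table) {
  def <- magdb_schema()[[table]]
  if (is.null(def)) {
    magdb_abort(paste0("unknown table: ", table), "magdb_validation_error")
  }
  if (is.data.frame(record)) record <- as.list(record)
  cols <- def$columns
  extra <- setdiff(names(record), c(names(cols), def$pk))
  if (length(extra) > 0) {
    magdb_abort(
      sprintf("unknown field(s) for %s: %s", table, paste(extra, collapse = ", ")),
      "magdb_validation_error"
    )
  }
  out <- list()
  for (cn in names(cols)) {
    cd <- cols[[cn]]
    value <- record[[cn]]
    if (is.null(value) || (length(value) == 1 && is.na(value))) {
      if (!cd$nullable) {
        magdb_abort(
          sprintf("field '%s' of %s is required", cn, table),
          "magdb_validation_error"
        )
      }
      out[[cn]] <- NA
      next
    }
    value <- coerce_scalar(value, cd$type, cn, table)
    if (!is.null(cd$enum) && !is.na(value) && cd$type == "text" &&
        !value %in% cd$enum) {
      magdb_abort(
        sprintf("field '%s' of %s must be one of {%s}, got '%s'",
                cn, table, paste(cd$enum, collapse = ", "), value),
        "magdb_validation_error"
      )
    }
    out[[cn]] <- value
  }
  for (rule in names(def$checks)) {
    ck <- def$checks[[rule]]
    if (!isTRUE(ck$fn(out))) {
      magdb_abort(
        sprintf("record for %s violates rule '%s': %s", table, rule, ck$message),
        "magdb_validation_error"
      )
    }
  }
  out
}

# -- memoized batch insertion ------------------------------------------------

#' Create a natural-key cache
#'
#' An in-memory map from (table, natural key) to surrogate id, shared across
#' [insert_if_absent()] calls so repeated keys never touch the database
#' twice.
#'
#' @return An environment usable as the `cache` argument of
#'   [insert_if_absent()].
#' @export
magdb_cache <- function() new.env(parent = emptyenv())

nk_string <- function(values) {
  parts <- purrr::map_chr(values, function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) "\x01NULL" else as.character(v)
  })
  paste(parts, collapse = "\x1f")
}

cache_key <- function(table, key) paste0(table, "\x1f", key)

preload_cache <- function(db, table, cache) {
  flag <- paste0(".loaded\x1f", table)
  if (isTRUE(cache[[flag]])) return(invisible())
  def <- magdb_schema()[[table]]
  sel <- sprintf(
    "SELECT %s, %s FROM %s",
    quote_id(def$pk),
    paste(quote_id(def$natural_key), collapse = ", "),
    quote_id(table)
  )
  rows <- DBI::dbGetQuery(db_con(db), sel)
  if (nrow(rows) > 0) {
    for (i in seq_len(nrow(rows))) {
      key <- nk_string(as.list(rows[i, def$natural_key, drop = FALSE]))
      cache[[cache_key(table, key)]] <- as.integer(rows[[def$pk]][i])
    }
  }
  cache[[flag]] <- TRUE
  invisible()
}

#' Insert validated records, skipping natural-key duplicates
#'
#' Inserts a batch of records into one table, committing one transaction per
#' `batch_size` rows. A record whose natural key is already present (in the
#' memo cache or the table) is not inserted again; its existing surrogate id
#' is returned. The cache is primed from the table on first use and updated
#' as rows are inserted, so re-submitting the same records is a no-op on row
#' counts.
#'
#' @param db A `magdb` connection.
#' @param table Target table name.
#' @param records A data frame (or tibble) of records; rows are validated
#'   unless `validated = TRUE`.
#' @param cache A natural-key cache from [magdb_cache()]; created ad hoc
#'   when `NULL`.
#' @param batch_size Rows per transaction (default 1000).
#' @param validated Set to `TRUE` when rows already passed
#'   [validate_record()] to skip re-validation.
#' @return A tibble with one row per input record: `outcome`
#'   (`"inserted"` or `"already_present"`) and `id` (surrogate key). The
#'   number of transactions used is attached as attribute `"transactions"`.
#' @export
insert_if_absent <- function(db, table, records, cache = NULL,
                             batch_size = 1000, validated = FALSE) {
  con <- db_con(db)
  def <- magdb_schema()[[table]]
  if (is.null(def)) magdb_abort(paste0("unknown table: ", table), "magdb_validation_error")
  if (is.null(cache)) cache <- magdb_cache()
  stopifnot(batch_size >= 1)
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n == 0) {
    out <- tibble::tibble(outcome = character(), id = integer())
    attr(out, "transactions") <- 0L
    return(out)
  }
  if (is.data.frame(records)) {
    records <- purrr::map(seq_len(n), function(i) as.list(records[i, , drop = FALSE]))
  }
  preload_cache(db, table, cache)
  cols <- names(def$columns)
  insert_sql <- sprintf(
    "INSERT INTO %s (%s) VALUES (%s)",
    quote_id(table),
    paste(quote_id(cols), collapse = ", "),
    paste(rep("?", length(cols)), collapse = ", ")
  )
  outcome <- character(n)
  ids <- integer(n)
  n_tx <- 0L
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (chunk in chunks) {
    DBI::dbBegin(con)
    n_tx <- n_tx + 1L
    ok <- tryCatch({
      for (i in chunk) {
        rec <- if (validated) {
          r <- records[[i]]
          for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
          r[cols]
        } else {
          validate_record(records[[i]], table)
        }
        key <- nk_string(rec[def$natural_key])
        ck <- cache_key(table, key)
        hit <- cache[[ck]]
        if (!is.null(hit)) {
          outcome[i] <- "already_present"
          ids[i] <- hit
        } else {
          params <- unname(purrr::map(rec[cols], function(v) {
            if (length(v) == 1 && is.na(v)) NA else v
          }))
          tryCatch(
            DBI::dbExecute(con, insert_sql, params = params),
            error = function(e) {
              msg <- conditionMessage(e)
              if (grepl("FOREIGN KEY", msg, ignore.case = TRUE)) {
                fks <- names(def$columns)[!purrr::map_lgl(def$columns, ~ is.null(.x$fk))]
                vals <- paste(fks, "=", purrr::map_chr(rec[fks], ~ as.character(.x %||% NA)),
                              collapse = ", ")
                magdb_abort(
                  sprintf("unresolved reference inserting into %s (%s)", table, vals),
                  "magdb_unresolved_reference"
                )
              }
              stop(e)
            }
          )
          id <- as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid()")[[1]])
          cache[[ck]] <- id
          outcome[i] <- "inserted"
          ids[i] <- id
        }
      }
      TRUE
    }, error = function(e) {
      DBI::dbRollback(con)
      stop(e)
    })
    if (isTRUE(ok)) DBI::dbCommit(con)
  }
  out <- tibble::tibble(outcome = outcome, id = ids)
  attr(out, "transactions") <- n_tx
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# -- integrity audit ---------------------------------------------------------

#' Audit referential integrity and stored invariants
#'
#' Scans every declared foreign-key relationship for orphans (child rows
#' whose reference resolves to no parent) and re-evaluates each table's
#' invariants over its stored rows, including the cross-table rules that a
#' single-table CHECK cannot express: gene coordinates within the contig
#' length, and each taxon's parent sitting exactly one rank above it.
#'
#' @param db A `magdb` connection.
#' @return A `magdb_integrity_report`: list with tibbles `orphans`
#'   (`relationship`, `n`) and `violations` (`table`, `rule`, `n`), plus a
#'   logical `ok` that is `TRUE` iff every count is zero.
#' @export
integrity_check <- function(db) {
  con <- db_con(db)
  rel <- schema_relationships()
  rel$relationship <- paste0(rel$child_table, ".", rel$child_column,
                             " -> ", rel$parent_table)
  rel$n <- purrr::pmap_int(rel, function(child_table, child_column,
                                         parent_table, parent_column, ...) {
    sql <- sprintf(
      "SELECT COUNT(*) FROM %s c LEFT JOIN %s p ON c.%s = p.%s
       WHERE c.%s IS NOT NULL AND p.%s IS NULL",
      quote_id(child_table), quote_id(parent_table),
      quote_id(child_column), quote_id(parent_column),
      quote_id(child_column), quote_id(parent_column)
    )
    as.integer(DBI::dbGetQuery(con, sql)[[1]])
  })
  orphans <- tibble::tibble(relationship = rel$relationship, n = rel$n)

  def <- magdb_schema()
  violations <- purrr::map_dfr(names(def), function(tn) {
    purrr::map_dfr(names(def[[tn]]$checks), function(rule) {
      sql <- sprintf(
        "SELECT COUNT(*) FROM %s WHERE NOT (%s)",
        quote_id(tn), def[[tn]]$checks[[rule]]$sql
      )
      tibble::tibble(table = tn, rule = rule,
                     n = as.integer(DBI::dbGetQuery(con, sql)[[1]]))
    })
  })
  # Cross-table invariants.
  gene_bounds <- as.integer(DBI::dbGetQuery(con,
    'SELECT COUNT(*) FROM gene g JOIN contig c ON g.contig_id = c.contig_id
     WHERE g.end_1based > c.length_bp')[[1]])
  ranks <- taxonomic_ranks()
  rank_case <- paste(
    sprintf("WHEN '%s' THEN %d", ranks, seq_along(ranks)), collapse = " "
  )
  parent_rank <- as.integer(DBI::dbGetQuery(con, sprintf(
    "SELECT COUNT(*) FROM taxon t JOIN taxon p ON t.parent_id = p.taxon_id
     WHERE (CASE t.rank %s END) - (CASE p.rank %s END) != 1",
    rank_case, rank_case))[[1]])
  violations <- dplyr::bind_rows(
    violations,
    tibble::tibble(table = "gene", rule = "end_within_contig", n = gene_bounds),
    tibble::tibble(table = "taxon", rule = "parent_immediate_rank", n = parent_rank)
  )
  structure(
    list(
      orphans = orphans,
      violations = violations,
      ok = sum(orphans$n) + sum(violations$n) == 0
    ),
    class = "magdb_integrity_report"
  )
}

#' @export
print.magdb_integrity_report <- function(x, ...) {
  cat("Integrity:", if (x$ok) "OK" else "VIOLATIONS FOUND", "\n")
  cat("  orphan foreign keys:", sum(x$orphans$n), "\n")
  cat("  invariant violations:", sum(x$violations$n), "\n")
  if (!x$ok) {
    print(dplyr::filter(x$orphans, .data$n > 0))
    print(dplyr::filter(x$violations, .data$n > 0))
  }
  invisible(x)
}
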