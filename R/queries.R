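# Named, parameterized biological queries over the populated database.
# "CAZyme" here means any family/subfamily annotation emitted by the dbCAN
# plugin; other sources' domain annotations are excluded. "Taxonomic
# novelty" defaults to species-rank unassigned in the GTDB-style
# classification, with the rank threshold exposed as a parameter so
# stricter definitions (e.g. genus-level novelty) are selectable.

rank_index_case <- function(column) {
  ranks <- taxonomic_ranks()
  paste0("CASE ", column, " ",
         paste(sprintf("WHEN '%s' THEN %d", ranks, seq_along(ranks)),
               collapse = " "),
         " ELSE 0 END")
}

# SQL predicate: genome unassigned at `rank` or deeper.
novelty_predicate <- function(rank) {
  if (!rank %in% taxonomic_ranks()) {
    magdb_abort(
      paste0("novelty_rank must be one of ",
             paste(taxonomic_ranks(), collapse = ", ")),
      "magdb_validation_error"
    )
  }
  threshold <- match(rank, taxonomic_ranks())
  sprintf("(ta.lowest_assigned_rank IS NULL OR %s < %d)",
          rank_index_case("ta.lowest_assigned_rank"), threshold)
}

cazyme_join_sql <- "
  FROM protein_annotation pa
  JOIN protein p        ON pa.protein_id = p.protein_id
  JOIN gene ge          ON p.gene_id = ge.gene_id
  JOIN contig c         ON ge.contig_id = c.contig_id
  JOIN genome g         ON c.genome_id = g.genome_id
  JOIN assembly a       ON g.assembly_id = a.assembly_id
  JOIN project pr       ON a.project_id = pr.project_id
  JOIN taxonomy_assignment ta ON ta.genome_id = g.genome_id
  WHERE pa.source_tool = 'dbcan'
    AND pa.annotation_type IN ('family', 'subfamily')
"

#' CAZymes restricted to taxonomically novel MAGs
#'
#' Returns every distinct (genome, protein, family) triple where the
#' protein carries at least one family or subfamily annotation from the
#' dbCAN source and the genome's taxonomy assignment is a taxonomic
#' novelty: unassigned at `novelty_rank` (default species) or deeper.
#' Spans all projects unless `project` is given.
#'
#' @param db A `magdb` connection.
#' @param project Optional project name restricting the scope.
#' @param novelty_rank Rank at which an unassigned classification counts
#'   as novel (default `"species"`).
#' @return A tibble with columns `project_name`, `genome_name`,
#'   `protein_name`, `family_accession`, `lowest_assigned_rank`.
#' @export
query_cazymes_novel_taxa <- function(db, project = NULL,
                                     novelty_rank = "species") {
  sql <- paste0(
    "SELECT DISTINCT pr.name AS project_name, g.name AS genome_name,
            p.name AS protein_name, pa.accession AS family_accession,
            ta.lowest_assigned_rank",
    cazyme_join_sql,
    " AND ", novelty_predicate(novelty_rank)
  )
  params <- list()
  if (!is.null(project)) {
    sql <- paste0(sql, " AND pr.name = ?")
    params <- list(project)
  }
  sql <- paste0(sql, " ORDER BY pr.name, g.name, p.name, pa.accession")
  out <- db_tbl(db, sql, params = params)
  class(out) <- c("magdb_cazyme_hits", class(out))
  out
}

#' Per-genome protein counts for one CAZyme family
#'
#' Counts, for each genome, the distinct proteins annotated with exactly
#' the given family accession by the dbCAN source. Genomes with zero
#' matching proteins are omitted; `novel_only = TRUE` restricts the rows
#' to taxonomically novel genomes.
#'
#' @param db A `magdb` connection.
#' @param family_accession Exact family accession, e.g. `"GH5"`.
#' @param novel_only Restrict to novel genomes (default `TRUE`).
#' @param project Optional project name restricting the scope.
#' @param novelty_rank Rank threshold for novelty (default `"species"`).
#' @return A tibble with columns `project_name`, `genome_name`,
#'   `family_accession`, `protein_count`.
#' @export
query_family_counts_per_genome <- function(db, family_accession,
                                           novel_only = TRUE,
                                           project = NULL,
                                           novelty_rank = "species") {
  if (!is.character(family_accession) || length(family_accession) != 1 ||
      !nzchar(family_accession)) {
    magdb_abort("family_accession must be a single non-empty string",
                "magdb_validation_error")
  }
  sql <- paste0(
    "SELECT pr.name AS project_name, g.name AS genome_name,
            pa.accession AS family_accession,
            COUNT(DISTINCT p.protein_id) AS protein_count",
    cazyme_join_sql,
    " AND pa.accession = ?"
  )
  params <- list(family_accession)
  if (isTRUE(novel_only)) {
    sql <- paste0(sql, " AND ", novelty_predicate(novelty_rank))
  }
  if (!is.null(project)) {
    sql <- paste0(sql, " AND pr.name = ?")
    params <- c(params, list(project))
  }
  sql <- paste0(sql, " GROUP BY pr.name, g.name, pa.accession
                       ORDER BY pr.name, g.name")
  out <- db_tbl(db, sql, params = params)
  out$protein_count <- as.integer(out$protein_count)
  class(out) <- c("magdb_family_counts", class(out))
  out
}

query_registry <- function() {
  list(
    "cazymes-novel-taxa" = list(
      fn = query_cazymes_novel_taxa,
      params = c("project", "novelty_rank")
    ),
    "family-counts" = list(
      fn = query_family_counts_per_genome,
      params = c("family_accession", "novel_only", "project", "novelty_rank")
    )
  )
}

#' List the registered named queries
#' @return Character vector of query names.
#' @export
named_queries <- function() names(query_registry())

#' Run a registered named query
#'
#' Dispatches to a named query with validated parameters and optional
#' serialization.
#'
#' @param db A `magdb` connection.
#' @param name Query name (see [named_queries()]).
#' @param params Named list of query parameters.
#' @param output_format `"tibble"` (default), `"tsv"` (a single string,
#'   header row plus one tab-separated line per hit) or `"json"`.
#' @return A tibble, or a serialized string for `"tsv"`/`"json"`.
#' @export
run_named_query <- function(db, name, params = list(),
                            output_format = c("tibble", "tsv", "json")) {
  output_format <- match.arg(output_format)
  reg <- query_registry()
  entry <- reg[[name]]
  if (is.null(entry)) {
    magdb_abort(
      paste0("unknown query '", name, "'; registered queries: ",
             paste(names(reg), collapse = ", ")),
      "magdb_lookup_error"
    )
  }
  bad <- setdiff(names(params), entry$params)
  if (length(bad) > 0) {
    magdb_abort(
      paste0("unknown parameter(s) for query '", name, "': ",
             paste(bad, collapse = ", ")),
      "magdb_validation_error"
    )
  }
  if ("novel_only" %in% names(params)) {
    v <- params$novel_only
    if (is.character(v)) v <- tolower(v) %in% c("true", "1", "yes")
    if (!is.logical(v)) {
      magdb_abort("parameter novel_only must be logical",
                  "magdb_validation_error")
    }
    params$novel_only <- v
  }
  result <- do.call(entry$fn, c(list(db), params))
  switch(output_format,
    tibble = result,
    tsv = {
      tab <- as.data.frame(result)
      paste(c(
        paste(names(tab), collapse = "\t"),
        if (nrow(tab) > 0) {
          apply(tab, 1, function(r) paste(ifelse(is.na(r), "", r), collapse = "\t"))
        }
      ), collapse = "\n")
    },
    json = as.character(jsonlite::toJSON(result, dataframe = "rows",
                                         auto_unbox = TRUE, na = "null"))
  )
}

#' Plot per-genome family counts
#'
#' Horizontal bar chart of the distinct-protein counts returned by
#' [query_family_counts_per_genome()].
#'
#' @param object A `magdb_family_counts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.magdb_family_counts <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$protein_count,
                 y = stats::reorder(.data$genome_name, .data$protein_count))
  ) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = "proteins annotated",
      y = NULL,
      title = paste0("CAZyme family ", unique(object$family_accession),
                     " per genome")
    ) +
    ggplot2::theme_minimal()
}

#' Plot CAZyme family repertoire of novel genomes
#'
#' Tile plot of family hits per genome from
#' [query_cazymes_novel_taxa()].
#'
#' @param object A `magdb_cazyme_hits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.magdb_cazyme_hits <- function(object, ...) {
  counts <- dplyr::count(object, .data$genome_name, .data$family_accession)
  ggplot2::ggplot(
    counts,
    ggplot2::aes(x = .data$family_accession, y = .data$genome_name,
                 fill = .data$n)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "proteins") +
    ggplot2::labs(x = "CAZyme family", y = NULL,
                  title = "CAZyme repertoire of taxonomically novel MAGs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
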