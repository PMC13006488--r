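# Read-only HTTP/JSON API over the populated database: entity listings
# with limit/offset pagination plus the named queries. No mutating verbs;
# every handler only ever reads.

api_paginate <- function(sql, query) {
  limit <- suppressWarnings(as.integer(query$limit %||% 100L))
  offset <- suppressWarnings(as.integer(query$offset %||% 0L))
  if (is.na(limit) || limit < 1) limit <- 100L
  if (is.na(offset) || offset < 0) offset <- 0L
  sprintf("%s LIMIT %d OFFSET %d", sql, limit, offset)
}

api_error <- function(status, message) {
  list(status = status, body = list(error = message))
}

#' Handle one API request in-process
#'
#' The request router behind [db_serve()]: resolves a method and path to
#' a read-only handler and returns the response as an R object. Useful
#' directly for programmatic access without a running server.
#'
#' Routes: `GET /projects`, `/projects/{id}/genomes`, `/genomes/{id}`,
#' `/genomes/{id}/proteins`, `/proteins/{id}/annotations`,
#' `/queries/cazymes-novel-taxa`, `/queries/family-counts`. List routes
#' accept `limit` and `offset`.
#'
#' @param db A `magdb` connection.
#' @param method HTTP verb; anything but `GET` is rejected with 405.
#' @param path Request path.
#' @param query Named list of query-string parameters.
#' @return A list with elements `status` (integer) and `body` (R object,
#'   serializable to JSON).
#' @export
#' @examples
#' db <- magdb_connect(":memory:")
#' initialize_schema(db)
#' api_request(db, "GET", "/projects")$status
#' magdb_disconnect(db)
api_request <- function(db, method, path, query = list()) {
  if (!identical(toupper(method), "GET")) {
    return(api_error(405L, "read-only API: only GET is supported"))
  }
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  tab <- function(sql, params = list()) db_tbl(db, sql, params = params)
  int_id <- function(x) {
    id <- suppressWarnings(as.integer(x))
    if (is.na(id)) NULL else id
  }
  ok <- function(body) list(status = 200L, body = body)

  tryCatch({
    if (length(parts) == 1 && parts[1] == "projects") {
      return(ok(tab(api_paginate(
        "SELECT project_id, name FROM project ORDER BY project_id", query))))
    }
    if (length(parts) == 3 && parts[1] == "projects" && parts[3] == "genomes") {
      id <- int_id(parts[2])
      if (is.null(id)) return(api_error(404L, "invalid project id"))
      return(ok(tab(api_paginate(
        "SELECT g.genome_id, g.name, g.assembly_id, g.genome_cluster_id
         FROM genome g JOIN assembly a ON g.assembly_id = a.assembly_id
         WHERE a.project_id = ? ORDER BY g.genome_id", query),
        params = list(id))))
    }
    if (length(parts) == 2 && parts[1] == "genomes") {
      id <- int_id(parts[2])
      if (is.null(id)) return(api_error(404L, "invalid genome id"))
      g <- tab("SELECT g.genome_id, g.name, g.assembly_id, g.genome_cluster_id,
                       ta.is_novel_species, ta.lowest_assigned_rank,
                       gq.completeness_pct, gq.contamination_pct
                FROM genome g
                LEFT JOIN taxonomy_assignment ta ON ta.genome_id = g.genome_id
                LEFT JOIN genome_quality gq ON gq.genome_id = g.genome_id
                WHERE g.genome_id = ?", params = list(id))
      if (nrow(g) == 0) return(api_error(404L, "genome not found"))
      return(ok(as.list(g[1, ])))
    }
    if (length(parts) == 3 && parts[1] == "genomes" && parts[3] == "proteins") {
      id <- int_id(parts[2])
      if (is.null(id)) return(api_error(404L, "invalid genome id"))
      return(ok(tab(api_paginate(
        "SELECT p.protein_id, p.name, p.sequence_length_aa
         FROM protein p
         JOIN gene ge ON p.gene_id = ge.gene_id
         JOIN contig c ON ge.contig_id = c.contig_id
         WHERE c.genome_id = ? ORDER BY p.protein_id", query),
        params = list(id))))
    }
    if (length(parts) == 3 && parts[1] == "proteins" &&
        parts[3] == "annotations") {
      id <- int_id(parts[2])
      if (is.null(id)) return(api_error(404L, "invalid protein id"))
      return(ok(tab(api_paginate(
        "SELECT protein_annotation_id, source_tool, annotation_type,
                accession, description, score, coord_start, coord_stop
         FROM protein_annotation WHERE protein_id = ?
         ORDER BY protein_annotation_id", query),
        params = list(id))))
    }
    if (length(parts) == 2 && parts[1] == "queries") {
      name <- parts[2]
      if (!name %in% named_queries()) {
        return(api_error(404L, paste0(
          "unknown query; registered: ",
          paste(named_queries(), collapse = ", "))))
      }
      params <- query[setdiff(names(query), c("limit", "offset"))]
      if ("family" %in% names(params)) {
        params$family_accession <- params$family
        params$family <- NULL
      }
      return(ok(run_named_query(db, name, params)))
    }
    api_error(404L, "no such route")
  }, magdb_error = function(e) api_error(400L, conditionMessage(e)))
}

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs %||% "")
  if (!nzchar(qs)) return(list())
  pairs <- strsplit(qs, "&", fixed = TRUE)[[1]]
  keys <- sub("=.*$", "", pairs)
  values <- ifelse(grepl("=", pairs, fixed = TRUE),
                   sub("^[^=]*=", "", pairs), "")
  stats::setNames(as.list(purrr::map_chr(values, utils::URLdecode)), keys)
}

#' Serve the read-only HTTP API
#'
#' Starts an HTTP server exposing [api_request()] routes as JSON on
#' localhost. The server runs on httpuv's background I/O thread; call
#' [httpuv::service()] (or run inside an interactive session) to process
#' requests, and [api_stop()] to shut down.
#'
#' @param db A `magdb` connection.
#' @param port TCP port.
#' @param host Interface to bind (default loopback).
#' @return The httpuv server handle.
#' @export
db_serve <- function(db, port = 8642, host = "127.0.0.1") {
  httpuv::startServer(host, port, list(
    call = function(req) {
      res <- api_request(
        db, req$REQUEST_METHOD, req$PATH_INFO,
        parse_query_string(req$QUERY_STRING)
      )
      list(
        status = res$status,
        headers = list("Content-Type" = "application/json"),
        body = as.character(jsonlite::toJSON(
          res$body, dataframe = "rows", auto_unbox = TRUE, na = "null"
        ))
      )
    }
  ))
}

#' Stop a running API server
#' @param server Handle returned by [db_serve()].
#' @return Invisibly `TRUE`.
#' @export
api_stop <- function(server) {
  httpuv::stopServer(server)
  invisible(TRUE)
}
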