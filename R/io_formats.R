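#' Write an embedding to a .mds coordinate file
#'
#' The .mds dialect is a headerless tab-separated table with the cell ID in
#' the first column followed by the 3 spatial coordinates; when velocity
#' targets are present the file has 7 columns (ID, x, y, z, tx, ty, tz).
#' Coordinates are serialized with 17 significant digits so a write/read
#' round-trip is bit-identical. 2D embeddings are padded with a constant
#' z = 0 and a sidecar note `<path>.2d-padded.txt` records the padding.
#'
#' @param embedding an [embedding_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mds <- function(embedding, path) {
  stopifnot(inherits(embedding, "EmbeddingTable"))
  coords <- embedding$coords
  padded <- FALSE
  if (ncol(coords) == 2L) {
    coords <- cbind(coords, 0)
    padded <- TRUE
  }
  cols <- cbind(embedding$cell_ids,
                apply(coords, 2, format_coord))
  if (!is.null(embedding$velocity_targets)) {
    cols <- cbind(cols, apply(embedding$velocity_targets, 2, format_coord))
  }
  lines <- do.call(paste, c(split(cols, col(cols)), sep = "\t"))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) stop_input("cannot write .mds file: ", conditionMessage(e)))
  if (padded) {
    writeLines(c("source embedding was 2D; third coordinate padded with 0",
                 paste0("embedding: ", embedding$name)),
               paste0(path, ".2d-padded.txt"))
  }
  invisible(path)
}

#' Read a .mds coordinate file
#'
#' Accepts 4- or 7-column whitespace-delimited rows (tab or runs of spaces);
#' the 7-column variant populates `velocity_targets`.
#'
#' @param path file path.
#' @param name embedding label; defaults to the file name without extension.
#' @return an [embedding_table()] with 3D coordinates.
#' @export
read_mds <- function(path, name = sub("\\.mds$", "", basename(path))) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_input("parse error: ", path, " is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (!all(ncols %in% c(4L, 7L))) {
    bad <- which(!ncols %in% c(4L, 7L))[1]
    stop_input("parse error at line ", bad, ": expected 4 or 7 columns, got ",
               ncols[bad])
  }
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[1])[1]
    stop_input("parse error at line ", bad, ": ragged rows (",
               ncols[bad], " vs ", ncols[1], " columns)")
  }
  m <- do.call(rbind, fields)
  ids <- m[, 1]
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1]
    stop_input("parse error at line ", bad, ": duplicate cell ID '", ids[bad], "'")
  }
  num <- suppressWarnings(apply(m[, -1, drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (any(!is.finite(num))) {
    bad <- which(apply(num, 1, function(r) any(!is.finite(r))))[1]
    stop_input("parse error at line ", bad, ": non-numeric coordinate")
  }
  vel <- if (ncols[1] == 7L) num[, 4:6, drop = FALSE] else NULL
  embedding_table(num[, 1:3, drop = FALSE], cell_ids = ids, name = name,
                  velocity_targets = vel)
}

DB_SCHEMA_VERSION <- "1"

#' Build the sparse SQLite expression database
#'
#' Stores only non-zero values as (gene_id, cell_id, value) triples, indexed
#' on gene so per-gene colouring queries are fast. The schema (tables
#' `genes`, `cells`, `expr`, `meta`) is this package's own documented dialect;
#' the schema version is recorded in `meta`.
#'
#' @param expr an [expression_matrix()].
#' @param path output database path.
#' @param overwrite replace an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
build_expression_db <- function(expr, path, overwrite = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (file.exists(path) && !overwrite) {
    stop_input("refusing to overwrite existing database: ", path,
               " (use overwrite = TRUE)")
  }
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "CREATE TABLE genes (id INTEGER PRIMARY KEY, name TEXT UNIQUE NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE cells (id INTEGER PRIMARY KEY, name TEXT UNIQUE NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE expr (gene_id INTEGER NOT NULL, cell_id INTEGER NOT NULL, value REAL NOT NULL)")
  DBI::dbWriteTable(con, "meta",
                    data.frame(key = "schema_version", value = DB_SCHEMA_VERSION),
                    append = TRUE)
  DBI::dbWriteTable(con, "genes",
                    data.frame(id = seq_len(nrow(expr)), name = rownames(expr)),
                    append = TRUE)
  DBI::dbWriteTable(con, "cells",
                    data.frame(id = seq_len(ncol(expr)), name = colnames(expr)),
                    append = TRUE)
  nz <- which(expr != 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    DBI::dbWriteTable(con, "expr",
                      data.frame(gene_id = nz[, 1], cell_id = nz[, 2],
                                 value = expr[nz]),
                      append = TRUE)
  }
  DBI::dbExecute(con, "CREATE INDEX idx_expr_gene ON expr (gene_id)")
  invisible(path)
}

#' Query per-cell expression of one gene from the database
#'
#' @param db path to a database written by [build_expression_db()].
#' @param gene gene name.
#' @return named numeric vector over all cells in stored order; cells with no
#'   stored value receive 0.
#' @export
query_expression <- function(db, gene) {
  if (!file.exists(db)) stop_input("database not found: ", db)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  g <- DBI::dbGetQuery(con, "SELECT id FROM genes WHERE name = ?",
                       params = list(gene))
  if (nrow(g) == 0) {
    all_genes <- DBI::dbGetQuery(con, "SELECT name FROM genes")$name
    near <- agrep(gene, all_genes, max.distance = 0.3,
                  ignore.case = TRUE, value = TRUE)
    stop_input("unknown gene '", gene, "'",
               if (length(near)) paste0("; did you mean: ",
                                        paste(head(near, 5), collapse = ", "))
               else "")
  }
  cells <- DBI::dbGetQuery(con, "SELECT id, name FROM cells ORDER BY id")
  out <- stats::setNames(numeric(nrow(cells)), cells$name)
  vals <- DBI::dbGetQuery(con,
                          "SELECT cell_id, value FROM expr WHERE gene_id = ?",
                          params = list(g$id[1]))
  if (nrow(vals) > 0) out[vals$cell_id] <- vals$value
  out
}

#' List genes stored in an expression database
#' @param db database path.
#' @return character vector of gene names in stored order.
#' @export
db_gene_names <- function(db) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbGetQuery(con, "SELECT name FROM genes ORDER BY id")$name
}

#' Read a full expression matrix back from a database
#' @param db database path.
#' @return an [expression_matrix()].
#' @export
read_expression_db <- function(db) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  genes <- DBI::dbGetQuery(con, "SELECT id, name FROM genes ORDER BY id")
  cells <- DBI::dbGetQuery(con, "SELECT id, name FROM cells ORDER BY id")
  vals <- DBI::dbGetQuery(con, "SELECT gene_id, cell_id, value FROM expr")
  m <- matrix(0, nrow(genes), nrow(cells),
              dimnames = list(genes$name, cells$name))
  if (nrow(vals) > 0) m[cbind(vals$gene_id, vals$cell_id)] <- vals$value
  expression_matrix(m)
}

#' Write / read the one-hot cell-type table
#'
#' Tab-separated with a header row of type names; the first column (`CellID`)
#' holds the cell identifier and body entries are strictly 0 or 1.
#'
#' @param table a [celltype_table()].
#' @param path file path.
#' @return `path` (writer) or a `CellTypeTable` (reader).
#' @export
write_celltype_table <- function(table, path) {
  stopifnot(inherits(table, "CellTypeTable"))
  df <- data.frame(CellID = table$cell_ids, table$membership,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_celltype_table
#' @export
read_celltype_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop_input("cell-type table needs >= 1 type column")
  ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  if (!all(body %in% c("0", "1"))) {
    bad <- body[!body %in% c("0", "1")][1]
    stop_input("validation error: cell-type entries must be 0 or 1, found '",
               bad, "'")
  }
  storage.mode(body) <- "integer"
  celltype_table(body, cell_ids = ids, type_names = colnames(df)[-1])
}

#' Write / read categorical metadata tables
#' @param table a [metadata_table()].
#' @param path file path.
#' @param id_column header name of the identifier column.
#' @return `path` (writer) or a `MetadataTable` (reader).
#' @export
write_metadata_table <- function(table, path, id_column = "ID") {
  stopifnot(inherits(table, "MetadataTable"))
  df <- data.frame(table$row_ids, table$columns, check.names = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_table
#' @export
read_metadata_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  metadata_table(df[, -1, drop = FALSE], row_ids = df[[1]])
}

#' Write / read surface-marker intensity tables
#' @param table a [surface_marker_table()].
#' @param path file path.
#' @return `path` (writer) or a `SurfaceMarkerTable` (reader).
#' @export
write_marker_table <- function(table, path) {
  stopifnot(inherits(table, "SurfaceMarkerTable"))
  df <- data.frame(CellID = table$cell_ids,
                   apply(table$intensities, 2, format_coord),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  surface_marker_table(m, cell_ids = as.character(df[[1]]),
                       marker_names = colnames(df)[-1])
}

#' Export a complete interchange bundle
#'
#' Writes one `.mds` file per embedding, the sparse SQLite expression
#' database, the cell-type and metadata tables, plus a JSON manifest listing
#' every file with its row/column counts. All inputs must cover exactly the
#' same cell set; tables are reordered to the expression matrix's cell order.
#'
#' @param expr an [expression_matrix()].
#' @param embeddings a single [embedding_table()] or list of them.
#' @param celltypes optional [celltype_table()].
#' @param cell_metadata,gene_metadata optional [metadata_table()]s.
#' @param markers optional [surface_marker_table()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_bundle <- function(expr, embeddings, celltypes = NULL,
                          cell_metadata = NULL, gene_metadata = NULL,
                          markers = NULL, out_dir) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (inherits(embeddings, "EmbeddingTable")) embeddings <- list(embeddings)
  if (length(embeddings) == 0) stop_input("at least one embedding is required")
  ref_ids <- colnames(expr)
  check_ids <- function(ids, what) {
    missing_ids <- setdiff(ref_ids, ids)
    extra <- setdiff(ids, ref_ids)
    if (length(missing_ids) || length(extra)) {
      stop_input("cell-ID mismatch in ", what, ": ",
                 if (length(missing_ids)) paste0("missing ",
                   paste(head(missing_ids, 3), collapse = ", ")) else "",
                 if (length(extra)) paste0(" extra ",
                   paste(head(extra, 3), collapse = ", ")) else "")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  db_path <- file.path(out_dir, "expression.db")
  build_expression_db(expr, db_path, overwrite = TRUE)
  files$expression_db <- list(file = "expression.db", genes = nrow(expr),
                              cells = ncol(expr))

  mds_files <- list()
  for (emb in embeddings) {
    check_ids(emb$cell_ids, paste0("embedding '", emb$name, "'"))
    ord <- match(ref_ids, emb$cell_ids)
    emb2 <- embedding_table(emb$coords[ord, , drop = FALSE],
                            cell_ids = ref_ids, name = emb$name,
                            velocity_targets =
                              if (is.null(emb$velocity_targets)) NULL
                              else emb$velocity_targets[ord, , drop = FALSE])
    fn <- paste0(emb$name, ".mds")
    write_mds(emb2, file.path(out_dir, fn))
    mds_files[[emb$name]] <- list(file = fn, cells = length(ref_ids),
                                  dims = ncol(emb$coords))
  }
  files$embeddings <- mds_files

  if (!is.null(celltypes)) {
    check_ids(celltypes$cell_ids, "cell-type table")
    ord <- match(ref_ids, celltypes$cell_ids)
    ct <- celltype_table(celltypes$membership[ord, , drop = FALSE],
                         cell_ids = ref_ids,
                         type_names = celltypes$type_names)
    write_celltype_table(ct, file.path(out_dir, "celltypes.txt"))
    files$celltypes <- list(file = "celltypes.txt",
                            cells = length(ref_ids),
                            types = length(ct$type_names))
  }
  if (!is.null(cell_metadata)) {
    check_ids(cell_metadata$row_ids, "cell metadata")
    ord <- match(ref_ids, cell_metadata$row_ids)
    md <- metadata_table(cell_metadata$columns[ord, , drop = FALSE],
                         row_ids = ref_ids)
    write_metadata_table(md, file.path(out_dir, "cell_metadata.txt"),
                         id_column = "CellID")
    files$cell_metadata <- list(file = "cell_metadata.txt",
                                rows = length(ref_ids),
                                columns = ncol(md$columns))
  }
  if (!is.null(gene_metadata)) {
    write_metadata_table(gene_metadata, file.path(out_dir, "gene_metadata.txt"),
                         id_column = "Gene")
    files$gene_metadata <- list(file = "gene_metadata.txt",
                                rows = length(gene_metadata$row_ids),
                                columns = ncol(gene_metadata$columns))
  }
  if (!is.null(markers)) {
    check_ids(markers$cell_ids, "surface-marker table")
    ord <- match(ref_ids, markers$cell_ids)
    mk <- surface_marker_table(markers$intensities[ord, , drop = FALSE],
                               cell_ids = ref_ids,
                               marker_names = markers$marker_names)
    write_marker_table(mk, file.path(out_dir, "markers.txt"))
    files$markers <- list(file = "markers.txt", cells = length(ref_ids),
                          markers = length(mk$marker_names))
  }

  manifest <- list(format = "embedsep-bundle", schema_version = DB_SCHEMA_VERSION,
                   n_cells = length(ref_ids), files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read an exported bundle back into memory
#'
#' @param dir bundle directory written by [export_bundle()].
#' @param load_expression read the full expression matrix (default `TRUE`);
#'   when `FALSE` only the database path is returned.
#' @return list with `expr` (or `db`), `embeddings` (named list), `celltypes`,
#'   `cell_metadata`, `markers`, and the parsed `manifest`.
#' @export
read_bundle <- function(dir, load_expression = TRUE) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_input("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path)
  db <- file.path(dir, manifest$files$expression_db$file)
  out <- list(manifest = manifest, db = db)
  if (load_expression) out$expr <- read_expression_db(db)
  out$embeddings <- lapply(manifest$files$embeddings, function(e) {
    read_mds(file.path(dir, e$file))
  })
  if (!is.null(manifest$files$celltypes)) {
    out$celltypes <- read_celltype_table(
      file.path(dir, manifest$files$celltypes$file))
  }
  if (!is.null(manifest$files$cell_metadata)) {
    out$cell_metadata <- read_metadata_table(
      file.path(dir, manifest$files$cell_metadata$file))
  }
  if (!is.null(manifest$files$markers)) {
    out$markers <- read_marker_table(file.path(dir, manifest$files$markers$file))
  }
  out
}
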