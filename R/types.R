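#' Per-cell embedding coordinates
#'
#' Container for one dimension-reduction result: an ordered set of cell IDs
#' with their 2D or 3D coordinates, optionally carrying RNA-velocity
#' destination coordinates (one 3D target per cell).
#'
#' @param coords numeric matrix, cells x dimensions (2 or 3 columns).
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `rownames(coords)`.
#' @param name label of the dimension-reduction method (e.g. `"umap3d"`).
#' @param velocity_targets optional cells x 3 numeric matrix of per-cell
#'   destination coordinates; only allowed for 3D embeddings.
#' @return an object of class `EmbeddingTable`.
#' @examples
#' emb <- embedding_table(matrix(rnorm(30), 10, 3),
#'                        cell_ids = sprintf("cell_%02d", 1:10))
#' @export
embedding_table <- function(coords, cell_ids = rownames(coords),
                            name = "embedding", velocity_targets = NULL) {
  coords <- as.matrix(coords)
  check_finite_matrix(coords, "coords")
  d <- ncol(coords)
  if (!d %in% c(2L, 3L)) stop_input("coords must have 2 or 3 columns, got ", d)
  if (is.null(cell_ids)) stop_input("cell_ids missing and coords has no rownames")
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(coords)) {
    stop_input("length(cell_ids) != nrow(coords)")
  }
  if (anyDuplicated(cell_ids)) {
    dup <- unique(cell_ids[duplicated(cell_ids)])
    stop_input("duplicate cell IDs: ", paste(head(dup, 5), collapse = ", "))
  }
  if (!is.null(velocity_targets)) {
    velocity_targets <- as.matrix(velocity_targets)
    check_finite_matrix(velocity_targets, "velocity_targets")
    if (d != 3L) stop_input("velocity_targets only allowed for 3D embeddings")
    if (nrow(velocity_targets) != nrow(coords) || ncol(velocity_targets) != 3L) {
      stop_input("velocity_targets must be a cells x 3 matrix")
    }
  }
  dimnames(coords) <- NULL
  structure(list(name = name, cell_ids = cell_ids, coords = coords,
                 velocity_targets = velocity_targets),
            class = "EmbeddingTable")
}

#' @export
print.EmbeddingTable <- function(x, ...) {
  cat(sprintf("EmbeddingTable '%s': %d cells x %dD%s\n", x$name,
              nrow(x$coords), ncol(x$coords),
              if (is.null(x$velocity_targets)) "" else " (+velocity targets)"))
  invisible(x)
}

#' Number of spatial dimensions of an embedding
#' @param x an `EmbeddingTable`.
#' @return 2 or 3.
#' @export
embedding_dim <- function(x) {
  stopifnot(inherits(x, "EmbeddingTable"))
  ncol(x$coords)
}

#' Genes x cells expression matrix
#'
#' Non-negative normalized expression values with unique gene and cell
#' identifiers. Backs the sparse SQLite export.
#'
#' @param values numeric genes x cells matrix, all values finite and >= 0.
#' @param gene_names,cell_ids identifiers; default to the dimnames.
#' @return an object of class `ExpressionMatrix` (a matrix with dimnames).
#' @export
expression_matrix <- function(values, gene_names = rownames(values),
                              cell_ids = colnames(values)) {
  values <- as.matrix(values)
  check_finite_matrix(values, "values")
  if (any(values < 0)) stop_input("expression values must be non-negative")
  if (is.null(gene_names) || is.null(cell_ids)) {
    stop_input("gene_names and cell_ids are required")
  }
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_names)) stop_input("duplicate gene names")
  if (anyDuplicated(cell_ids)) stop_input("duplicate cell IDs")
  if (length(gene_names) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop_input("dimnames lengths do not match matrix dimensions")
  }
  dimnames(values) <- list(gene_names, cell_ids)
  class(values) <- c("ExpressionMatrix", class(matrix()))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells, %.1f%% non-zero\n",
              nrow(x), ncol(x), 100 * mean(x != 0)))
  invisible(x)
}

#' One-hot cell-type membership table
#'
#' Binary cells x types membership: a cell is marked as belonging to a type
#' with 1, or 0 otherwise. A cell may carry zero or several type labels.
#'
#' @param membership cells x types matrix with entries in `{0, 1}`.
#' @param cell_ids,type_names identifiers; default to the dimnames.
#' @return an object of class `CellTypeTable`.
#' @export
celltype_table <- function(membership, cell_ids = rownames(membership),
                           type_names = colnames(membership)) {
  membership <- as.matrix(membership)
  if (!all(membership %in% c(0, 1))) {
    stop_input("membership entries must be exactly 0 or 1")
  }
  storage.mode(membership) <- "integer"
  if (is.null(cell_ids) || is.null(type_names)) {
    stop_input("cell_ids and type_names are required")
  }
  cell_ids <- as.character(cell_ids)
  type_names <- as.character(type_names)
  if (anyDuplicated(cell_ids)) stop_input("duplicate cell IDs")
  if (anyDuplicated(type_names)) stop_input("duplicate type names")
  if (length(cell_ids) != nrow(membership) ||
      length(type_names) != ncol(membership)) {
    stop_input("identifier lengths do not match membership dimensions")
  }
  dimnames(membership) <- list(cell_ids, type_names)
  structure(list(cell_ids = cell_ids, type_names = type_names,
                 membership = membership),
            class = "CellTypeTable")
}

#' @export
print.CellTypeTable <- function(x, ...) {
  cat(sprintf("CellTypeTable: %d cells x %d types\n",
              length(x$cell_ids), length(x$type_names)))
  invisible(x)
}

#' Categorical metadata for cells or genes
#'
#' @param df data.frame of text labels; one row per cell or gene.
#' @param row_ids unique identifiers, default `rownames(df)`.
#' @return an object of class `MetadataTable`.
#' @export
metadata_table <- function(df, row_ids = rownames(df)) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(row_ids)) stop_input("row_ids are required")
  row_ids <- as.character(row_ids)
  if (anyDuplicated(row_ids)) stop_input("duplicate row IDs")
  if (length(row_ids) != nrow(df)) stop_input("row_ids length != nrow(df)")
  df[] <- lapply(df, as.character)
  rownames(df) <- NULL
  structure(list(row_ids = row_ids, columns = df), class = "MetadataTable")
}

#' Surface-marker intensity table
#'
#' Index-sorting / CITE-seq antibody intensities, cells x markers.
#'
#' @param intensities cells x markers matrix, finite and >= 0.
#' @param cell_ids,marker_names identifiers; default to the dimnames.
#' @return an object of class `SurfaceMarkerTable`.
#' @export
surface_marker_table <- function(intensities, cell_ids = rownames(intensities),
                                 marker_names = colnames(intensities)) {
  intensities <- as.matrix(intensities)
  check_finite_matrix(intensities, "intensities")
  if (any(intensities < 0)) stop_input("intensities must be non-negative")
  cell_ids <- as.character(cell_ids)
  marker_names <- as.character(marker_names)
  if (anyDuplicated(cell_ids)) stop_input("duplicate cell IDs")
  dimnames(intensities) <- list(cell_ids, marker_names)
  structure(list(cell_ids = cell_ids, marker_names = marker_names,
                 intensities = intensities),
            class = "SurfaceMarkerTable")
}

#' Disjoint user-selected cell groups
#'
#' Represents the colour groups a user captures with the selection tool: at
#' least two disjoint, non-empty sets of cells.
#'
#' @param cell_ids character vector of cell identifiers.
#' @param group per-cell group label (colour), same length as `cell_ids`.
#' @return an object of class `SelectionGroups`.
#' @export
selection_groups <- function(cell_ids, group) {
  cell_ids <- as.character(cell_ids)
  group <- as.character(group)
  if (length(cell_ids) != length(group)) {
    stop_input("cell_ids and group must have equal length")
  }
  if (anyDuplicated(cell_ids)) {
    stop_input("a cell may appear in one group only (duplicate cell IDs)")
  }
  tab <- table(group)
  if (length(tab) < 2) stop_input("at least 2 groups are required")
  structure(list(cell_ids = cell_ids, group = group,
                 group_names = names(tab)),
            class = "SelectionGroups")
}
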