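#' Read and write the pipeline's tab-separated tables
#'
#' All tables are plain TSV with a header line and missing values encoded as
#' `NA`. Density tables carry their processing stage in a `stage` column on
#' disk and as an attribute in memory.
#'
#' @param table Data frame to write.
#' @param path File path.
#' @return `read_density_table()` returns the density table with its stage
#'   attribute restored; `write_*` return the path invisibly.
#' @export
write_density_table <- function(table, path) {
  out <- table
  out$stage <- attr(table, "stage") %||% "raw"
  write_tsv(out, path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stage <- if ("stage" %in% names(tab)) unique(tab$stage)[1] else "raw"
  tab$stage <- NULL
  attr(tab, "stage") <- stage
  tab
}

#' @rdname write_density_table
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_density_table
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write plate images
#'
#' Images are numeric matrices in raw intensity units (0..65535). TIFF files
#' are written as 16-bit grayscale; PNG files are read through the png
#' package. On reading, the [0, 1] scale of both readers is mapped back to
#' 16-bit counts.
#'
#' @param image Numeric matrix (rows = y).
#' @param path File path ending in .tif/.tiff or .png.
#' @return `read_plate_image()` returns the intensity matrix; the writer
#'   returns the path invisibly.
#' @export
write_plate_image <- function(image, path) {
  scaled <- pmin(pmax(image / 65535, 0), 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(scaled, path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' @rdname write_plate_image
#' @export
read_plate_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else stop("unsupported image format: ", path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 65535
}

#' Read and write GMT gene-set files
#'
#' Reading goes through `fgsea::gmtPathways`; writing emits the standard
#' three-plus columns (set name, description, genes).
#'
#' @param path GMT file path.
#' @param sets Named list of gene sets.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology from edge-list and annotation TSVs
#'
#' @param edge_path TSV with columns child, parent.
#' @param annot_path TSV with columns term_id, gene_id.
#' @return An [ontology_dag()].
#' @export
read_ontology <- function(edge_path, annot_path) {
  ontology_dag(read_tsv(edge_path), read_tsv(annot_path))
}

#' Export an enrichment map as edge TSV and GraphML
#'
#' @param edges Edge data frame from [enrichment_map()].
#' @param tsv_path Path for the edge TSV (term_a, term_b, jaccard).
#' @param graphml_path Optional path for a GraphML export (via igraph) with
#'   the Jaccard coefficient as edge weight.
#' @return The TSV path, invisibly.
#' @export
write_enrichment_map <- function(edges, tsv_path, graphml_path = NULL) {
  write_tsv(edges, tsv_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::E(g)$weight <- edges$jaccard
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(tsv_path)
}
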