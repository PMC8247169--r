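#' Write a count matrix as an MTX bundle
#'
#' Writes Matrix Market coordinate format (1-based indices) alongside
#' `genes.tsv` (gene_id plus any annotation columns) and `barcodes.tsv`.
#' The matrix is stored genes x cells on disk, the 10x convention.
#' For a [spot_matrix()], spot coordinates go to `coords.tsv`
#' (spot_id, x, y, layer).
#'
#' @param m A `count_matrix` or `spot_matrix`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir, "matrix.mtx"))
  genes <- if (is.null(m$gene_meta)) tibble::tibble(gene_id = gene_ids(m)) else m$gene_meta
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  if (inherits(m, "spot_matrix"))
    utils::write.table(m$coords, file.path(dir, "coords.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an MTX bundle written by [write_mtx()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `coords.tsv`.
#' @return A `count_matrix`, or a `spot_matrix` when coordinates are present.
#' @export
read_mtx <- function(dir) {
  mm <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- if (ncol(genes) > 1) genes else NULL
  coords_path <- file.path(dir, "coords.tsv")
  if (file.exists(coords_path)) {
    coords <- utils::read.delim(coords_path, sep = "\t", stringsAsFactors = FALSE)
    spot_matrix(mm, coords, cell_ids = barcodes, gene_ids = genes$gene_id,
                gene_meta = meta)
  } else {
    count_matrix(mm, cell_ids = barcodes, gene_ids = genes$gene_id,
                 gene_meta = meta)
  }
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "gnstates") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, ds, genes) {
    paste(c(nm, ds, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}
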