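# Readers and writers for every external representation the pipeline touches.
# All tables are UTF-8, tab-delimited, with a header; MTX orientation is
# declared in a YAML sidecar, never guessed.

#' Construct a cell-by-gene count matrix with per-cell metadata
#'
#' The central in-memory container: sparse non-negative integer counts with
#' cells in rows and genes in columns, plus per-cell labels at two cluster
#' granularities (subclass, optional subtype).
#'
#' @param counts Matrix or sparse Matrix, cells x genes, non-negative integers.
#' @param gene_ids Character vector of unique gene identifiers (columns).
#' @param cell_meta Data frame with one row per cell and columns
#'   `cell_id`, `species`, `individual`, `subclass` and optionally `subtype`.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, gene_ids, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!"subtype" %in% names(cell_meta)) cell_meta$subtype <- NA_character_
  validate_cell_matrix(counts, gene_ids, cell_meta)
  dimnames(counts) <- list(cell_meta$cell_id, gene_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_meta = cell_meta),
    class = "cell_matrix"
  )
}

validate_cell_matrix <- function(counts, gene_ids, cell_meta) {
  if (ncol(counts) != length(gene_ids)) {
    stop_named("celltempo_dim_mismatch",
               "counts has ", ncol(counts), " columns but ",
               length(gene_ids), " gene ids were given")
  }
  if (nrow(counts) != nrow(cell_meta)) {
    stop_named("celltempo_dim_mismatch",
               "counts has ", nrow(counts), " rows but cell_meta has ",
               nrow(cell_meta), " rows")
  }
  if (anyDuplicated(gene_ids)) {
    stop_named("celltempo_duplicate_genes", "gene ids are not unique")
  }
  required <- c("cell_id", "species", "individual", "subclass")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols)) {
    stop_named("celltempo_missing_metadata",
               "cell_meta lacks required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (anyNA(cell_meta$species) || anyNA(cell_meta$subclass)) {
    stop_named("celltempo_missing_metadata",
               "every cell must have species and subclass labels")
  }
  if (any(counts@x < 0)) {
    stop_named("celltempo_negative_counts", "counts contain negative entries")
  }
  invisible(TRUE)
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      length(unique(x$cell_meta$species)), "species,",
      length(unique(x$cell_meta$subclass)), "subclasses\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a cell-by-gene count matrix from disk
#'
#' Reads the MatrixMarket dialect: `matrix.mtx` plus `genes.tsv` and
#' `cells.tsv` sidecars and a `config.yaml` declaring the matrix orientation
#' (`cells_in_rows: true/false`). Output is normalized to cells x genes with
#' genes sorted by identifier and cells sorted by cell id, so reader output
#' order is deterministic regardless of input order.
#'
#' @param path Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`,
#'   `config.yaml`.
#' @param dialect Only `"mtx+tsv"` is supported on this install; requesting
#'   `"hdf5"` raises a named error.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(path, dialect = c("mtx+tsv", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5") {
    stop_named("celltempo_unsupported_dialect",
               "the hdf5 container dialect requires an HDF5 reader, ",
               "which this package does not bundle; use mtx+tsv")
  }
  mtx_file <- file.path(path, "matrix.mtx")
  genes_file <- file.path(path, "genes.tsv")
  cells_file <- file.path(path, "cells.tsv")
  cfg_file <- file.path(path, "config.yaml")
  for (f in c(mtx_file, genes_file, cells_file, cfg_file)) {
    if (!file.exists(f)) {
      stop_named("celltempo_missing_file", "expected file not found: ", f)
    }
  }
  cfg <- yaml::read_yaml(cfg_file)
  if (is.null(cfg$cells_in_rows)) {
    stop_named("celltempo_missing_metadata",
               "config.yaml must declare cells_in_rows")
  }
  m <- Matrix::readMM(mtx_file)
  if (!isTRUE(cfg$cells_in_rows)) m <- Matrix::t(m)
  genes <- read.delim(genes_file, stringsAsFactors = FALSE)
  cells <- read.delim(cells_file, stringsAsFactors = FALSE)
  if (nrow(genes) != ncol(m)) {
    stop_named("celltempo_dim_mismatch",
               "genes.tsv has ", nrow(genes), " rows but the matrix has ",
               ncol(m), " gene columns")
  }
  if (nrow(cells) != nrow(m)) {
    stop_named("celltempo_dim_mismatch",
               "cells.tsv has ", nrow(cells), " rows but the matrix has ",
               nrow(m), " cell rows")
  }
  gene_order <- order(genes$gene_id)
  cell_order <- order(cells$cell_id)
  cm <- cell_matrix(m[cell_order, gene_order, drop = FALSE],
                    genes$gene_id[gene_order],
                    cells[cell_order, , drop = FALSE])
  cm
}

#' Write a cell_matrix in the mtx+tsv dialect
#'
#' @param cm A [cell_matrix()].
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_cell_matrix <- function(cm, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cm$counts, file.path(path, "matrix.mtx"))
  write.table(data.frame(gene_id = cm$gene_ids),
              file.path(path, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$cell_meta, file.path(path, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  yaml::write_yaml(list(cells_in_rows = TRUE, format = "mtx+tsv"),
                   file.path(path, "config.yaml"))
  invisible(path)
}

#' Read a one-to-one ortholog map
#'
#' A tab-delimited table with one gene-identifier column per species and
#' optional logical columns `protein_coding` and `mitochondrial`. Records
#' violating the one-to-one requirement (a gene id appearing in more than one
#' record within any species column) are dropped with a message reporting the
#' count; downstream analyses join species through this map only.
#'
#' @param path TSV file.
#' @param species Optional character vector of species columns that must be
#'   present; an absent column raises a named error.
#' @return Data frame of class `ortholog_map`, rows sorted by the first
#'   species column, with attribute `n_dropped`.
#' @export
read_ortholog_map <- function(path, species = NULL) {
  if (!file.exists(path)) {
    stop_named("celltempo_missing_file", "file not found: ", path)
  }
  info <- file.info(path)
  if (info$size == 0) {
    warning("empty ortholog map: ", path)
    out <- data.frame()
    class(out) <- c("ortholog_map", "data.frame")
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  map <- read.delim(path, stringsAsFactors = FALSE)
  ortholog_map(map, species = species)
}

#' Build an ortholog map from a data frame
#' @param map Data frame with one gene-id column per species.
#' @param species Optional required species columns.
#' @return Data frame of class `ortholog_map` with attribute `n_dropped`.
#' @export
ortholog_map <- function(map, species = NULL) {
  flag_cols <- intersect(c("protein_coding", "mitochondrial"), names(map))
  sp_cols <- setdiff(names(map), flag_cols)
  if (!is.null(species)) {
    missing_sp <- setdiff(species, sp_cols)
    if (length(missing_sp)) {
      stop_named("celltempo_unknown_species",
                 "ortholog map lacks species column(s): ",
                 paste(missing_sp, collapse = ", "))
    }
  }
  keep <- rep(TRUE, nrow(map))
  for (sc in sp_cols) {
    dup_ids <- unique(map[[sc]][duplicated(map[[sc]])])
    keep <- keep & !(map[[sc]] %in% dup_ids)
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("read_ortholog_map: dropped ", n_dropped,
            " record(s) violating one-to-one mapping")
  }
  out <- map[keep, , drop = FALSE]
  if (nrow(out)) out <- out[order(out[[sp_cols[1]]]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  attr(out, "species_cols") <- sp_cols
  out
}

#' Genes usable for cross-species comparison
#'
#' Protein-coding, non-mitochondrial one-to-one orthologs for one species.
#' @param map An `ortholog_map`.
#' @param species Species column to extract.
#' @return Character vector of gene ids.
#' @export
ortholog_genes <- function(map, species) {
  sp_cols <- attr(map, "species_cols") %||% names(map)
  if (!species %in% sp_cols) {
    stop_named("celltempo_unknown_species", "unknown species: ", species)
  }
  keep <- rep(TRUE, nrow(map))
  if ("protein_coding" %in% names(map)) keep <- keep & map$protein_coding
  if ("mitochondrial" %in% names(map)) keep <- keep & !map$mitochondrial
  map[[species]][keep]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Sets with fewer than `min_size` members are excluded, mirroring the
#' restriction of phenotype collections to sets with at least 100 genes.
#'
#' @param path GMT file.
#' @param min_size Minimum member count for a set to be retained.
#' @return Named list of character vectors, class `gene_set_collection`.
#' @export
read_gene_sets <- function(path, min_size = 0L) {
  if (!file.exists(path)) {
    stop_named("celltempo_missing_file", "file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_named("celltempo_malformed_gmt",
                 "malformed GMT line ", i, ": fewer than 3 fields")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!nzchar(fields[[1]])) {
      stop_named("celltempo_malformed_gmt",
                 "malformed GMT line ", i, ": empty set name")
    }
    sets[[fields[[1]]]] <- members
  }
  if (anyDuplicated(names(sets))) {
    stop_named("celltempo_malformed_gmt", "duplicate set names in GMT")
  }
  sets <- sets[vapply(sets, length, 1L) >= min_size]
  sets <- sets[order(names(sets))]
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an allele-specific expression count table
#'
#' Per (gene, sample): read counts assigned to each parental allele of an
#' interspecies hybrid, with the hybrid line each sample derives from and an
#' optional timepoint label.
#'
#' @param path TSV with columns `gene_id`, `sample`, `line`,
#'   `allele1_count`, `allele2_count` and optionally `timepoint`.
#' @return Data frame of class `ase_table`, sorted by (gene_id, sample).
#' @export
read_ase_table <- function(path) {
  if (!file.exists(path)) {
    stop_named("celltempo_missing_file", "file not found: ", path)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  ase_table(tab)
}

#' Validate and normalize an ASE count table
#' @param tab Data frame with the `ase_table` columns.
#' @return Data frame of class `ase_table`.
#' @export
ase_table <- function(tab) {
  required <- c("gene_id", "sample", "line", "allele1_count", "allele2_count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_named("celltempo_missing_metadata",
               "ASE table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (any(tab$allele1_count < 0) || any(tab$allele2_count < 0)) {
    stop_named("celltempo_negative_counts", "ASE counts must be non-negative")
  }
  key <- paste(tab$gene_id, tab$sample, sep = "\r")
  if (anyDuplicated(key)) {
    stop_named("celltempo_duplicate_records",
               "duplicate (gene, sample) record(s) in ASE table")
  }
  tab <- tab[order(tab$gene_id, tab$sample), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ase_table", "data.frame")
  tab
}

#' Write an ASE table
#' @param tab An `ase_table`.
#' @param path Output TSV.
#' @export
write_ase_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ortholog map
#' @param map An `ortholog_map` or data frame.
#' @param path Output TSV.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read per-gene annotations (constraint, categories)
#'
#' @param path TSV with column `gene_id` and any of `s_het`, `pLI`,
#'   `dnds_lineage1`, `dnds_lineage2`, `synaptic`, `tf_cr`,
#'   `haploinsufficient`.
#' @return Data frame of class `gene_annotation`, sorted by gene id.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) {
    stop_named("celltempo_missing_file", "file not found: ", path)
  }
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(ann)) {
    stop_named("celltempo_missing_metadata",
               "gene annotation lacks gene_id column")
  }
  if ("pLI" %in% names(ann)) {
    ok <- is.na(ann$pLI) | (ann$pLI >= 0 & ann$pLI <= 1)
    if (!all(ok)) {
      stop_named("celltempo_invalid_annotation", "pLI outside [0, 1]")
    }
  }
  if ("s_het" %in% names(ann)) {
    ok <- is.na(ann$s_het) | ann$s_het >= 0
    if (!all(ok)) {
      stop_named("celltempo_invalid_annotation", "negative s_het")
    }
  }
  ann <- ann[order(ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
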