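#' Ordinal immunohistochemistry detection levels
#'
#' The four-category ordinal scale used by Human Protein Atlas style IHC
#' annotation, from no detection to strong staining.
#'
#' @format Character vector of length 4, ordered weakest to strongest.
#' @export
IHC_LEVELS <- c("Not detected", "Low", "Medium", "High")

# ---- expression table -------------------------------------------------------

#' Construct an expression table
#'
#' An expression table holds non-negative, FPKM-like expression values on a
#' gene-by-tissue grid. It is stored in long (tidy) form: one row per
#' *observed* (gene, tissue) cell. Grid cells with no row are *missing*,
#' which is deliberately distinct from an observed zero -- the downstream
#' fold-change computation treats a missing measurement as "assume not
#' expressed" (contributes 0) while still recording that no measurement was
#' made.
#'
#' @param data A data frame with columns `gene`, `tissue`, `value`.
#' @param genes,tissues Optional character vectors fixing the full grid
#'   (and its order). Default: unique values observed in `data`, in order of
#'   appearance.
#' @return A tibble of class `expr_table` with columns `gene`, `tissue`,
#'   `value`, plus `genes` and `tissues` attributes describing the grid.
#' @examples
#' expression_table(tibble::tibble(
#'   gene = c("G1", "G1", "G2"),
#'   tissue = c("liver", "lung", "liver"),
#'   value = c(10, 0, 3.2)
#' ))
#' @export
expression_table <- function(data, genes = NULL, tissues = NULL) {
  data <- as_tibble(data)
  req <- c("gene", "tissue", "value")
  if (!all(req %in% names(data))) {
    abort(paste0(
      "expression data must have columns gene, tissue, value; missing: ",
      paste(setdiff(req, names(data)), collapse = ", ")
    ))
  }
  data <- data[req]
  data$gene <- trimws(as.character(data$gene))
  data$tissue <- trimws(as.character(data$tissue))
  data$value <- as.numeric(data$value)
  if (anyNA(data$value)) {
    abort("expression values must be non-missing; encode missing cells by omitting the row")
  }
  if (any(data$value < 0)) {
    abort("expression values must be non-negative")
  }
  if (anyDuplicated(data[c("gene", "tissue")])) {
    dup <- data[duplicated(data[c("gene", "tissue")]), , drop = FALSE]
    abort(paste0(
      "duplicated (gene, tissue) pairs in expression data, e.g. (",
      dup$gene[1], ", ", dup$tissue[1], ")"
    ))
  }
  genes <- genes %||% unique(data$gene)
  tissues <- tissues %||% unique(data$tissue)
  stopifnot(!anyDuplicated(genes), !anyDuplicated(tissues))
  if (!all(data$gene %in% genes) || !all(data$tissue %in% tissues)) {
    abort("expression rows refer to genes/tissues outside the declared grid")
  }
  structure(
    data,
    genes = as.character(genes),
    tissues = as.character(tissues),
    class = c("expr_table", class(tibble()))
  )
}

#' Grid accessors for expression tables and weight objects
#'
#' @param x An object carrying a gene-by-tissue grid.
#' @return Character vector of gene identifiers or tissue names.
#' @export
expr_genes <- function(x) attr(x, "genes")

#' @rdname expr_genes
#' @export
expr_tissues <- function(x) attr(x, "tissues")

#' Expression table as a dense matrix
#'
#' @param x An `expr_table`.
#' @param missing_as Value to place in missing cells (default `NA`; the
#'   fold-change step uses 0).
#' @return Numeric matrix, genes in rows, tissues in columns.
#' @export
expr_matrix <- function(x, missing_as = NA_real_) {
  genes <- expr_genes(x)
  tissues <- expr_tissues(x)
  m <- matrix(missing_as, nrow = length(genes), ncol = length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(x$gene, x$tissue)] <- x$value
  m
}

# ---- IHC table --------------------------------------------------------------

#' Construct an IHC annotation table
#'
#' Holds immunohistochemistry protein detection calls: one row per
#' (gene, tissue, cell type) with an ordinal detection `level`. Multiple
#' cell types per tissue are allowed; activity derivation collapses them by
#' maximum level (detection in any cell type counts).
#'
#' @param data A data frame with columns `gene`, `tissue`, `level`, and
#'   optionally `cell_type` and `reliability`.
#' @return A tibble of class `ihc_table`.
#' @export
ihc_table <- function(data) {
  data <- as_tibble(data)
  req <- c("gene", "tissue", "level")
  if (!all(req %in% names(data))) {
    abort(paste0(
      "IHC data must have columns gene, tissue, level; missing: ",
      paste(setdiff(req, names(data)), collapse = ", ")
    ))
  }
  if (!"cell_type" %in% names(data)) data$cell_type <- NA_character_
  if (!"reliability" %in% names(data)) data$reliability <- NA_character_
  data <- data[c("gene", "tissue", "cell_type", "level", "reliability")]
  data$gene <- trimws(as.character(data$gene))
  data$tissue <- trimws(as.character(data$tissue))
  data$level <- match_ihc_level(data$level)
  if (anyDuplicated(data[c("gene", "tissue", "cell_type")])) {
    dup <- data[duplicated(data[c("gene", "tissue", "cell_type")]), , drop = FALSE]
    abort(paste0(
      "duplicated (gene, tissue, cell type) triples in IHC data, e.g. (",
      dup$gene[1], ", ", dup$tissue[1], ")"
    ))
  }
  structure(data, class = c("ihc_table", class(tibble())))
}

# Case-insensitive mapping of level strings onto the canonical four-category
# scale; unknown strings are a hard error listing the offenders.
match_ihc_level <- function(level) {
  level <- trimws(as.character(level))
  idx <- match(tolower(level), tolower(IHC_LEVELS))
  if (anyNA(idx)) {
    bad <- unique(level[is.na(idx)])
    abort(paste0(
      "unrecognized IHC level(s): ", paste(shQuote(bad), collapse = ", "),
      "; expected one of ", paste(shQuote(IHC_LEVELS), collapse = ", ")
    ))
  }
  IHC_LEVELS[idx]
}

# ---- gene set collection ----------------------------------------------------

#' Construct a gene set collection
#'
#' A named collection of gene sets over a gene universe, equivalent to the
#' g x p set-by-gene indicator matrix used by competitive gene set tests.
#'
#' @param sets A data frame with columns `set`, `description`, and a
#'   list-column `genes` of character vectors, or a named list of character
#'   vectors (descriptions default to `""`).
#' @return A tibble of class `gene_set_collection` with columns `set`,
#'   `description`, `genes` (list), `n_genes`.
#' @export
gene_set_collection <- function(sets) {
  if (is.list(sets) && !is.data.frame(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("a list of gene sets must have unique names")
    }
    sets <- tibble(
      set = names(sets),
      description = "",
      genes = lapply(sets, as.character)
    )
  }
  sets <- as_tibble(sets)
  if (!all(c("set", "genes") %in% names(sets))) {
    abort("gene set data must have columns set and genes")
  }
  if (!"description" %in% names(sets)) sets$description <- ""
  sets <- sets[c("set", "description", "genes")]
  sets$set <- trimws(as.character(sets$set))
  if (anyDuplicated(sets$set)) {
    abort(paste0(
      "duplicate gene set name(s): ",
      paste(unique(sets$set[duplicated(sets$set)]), collapse = ", ")
    ))
  }
  sets$genes <- lapply(sets$genes, function(g) {
    g <- trimws(as.character(g))
    unique(g[nzchar(g)])
  })
  if (any(lengths(sets$genes) == 0)) {
    abort("every gene set must contain at least one gene")
  }
  sets$n_genes <- lengths(sets$genes)
  structure(sets, class = c("gene_set_collection", class(tibble())))
}

#' Gene universe of a collection
#'
#' The union of all member genes across the sets, in first-appearance order.
#'
#' @param gsc A `gene_set_collection`.
#' @return Character vector of gene identifiers.
#' @export
gs_universe <- function(gsc) {
  unique(unlist(gsc$genes, use.names = FALSE))
}

#' Collection as a set-by-gene indicator matrix
#'
#' @param gsc A `gene_set_collection`.
#' @param universe Optional gene universe defining the columns; defaults to
#'   [gs_universe()].
#' @return 0/1 integer matrix, sets in rows, genes in columns.
#' @export
gs_indicator_matrix <- function(gsc, universe = NULL) {
  universe <- universe %||% gs_universe(gsc)
  m <- matrix(0L, nrow = nrow(gsc), ncol = length(universe),
              dimnames = list(gsc$set, universe))
  for (j in seq_len(nrow(gsc))) {
    members <- intersect(gsc$genes[[j]], universe)
    m[j, members] <- 1L
  }
  m
}

# ---- GMT --------------------------------------------------------------------

#' Read a gene set collection in GMT format
#'
#' Parses the tab-separated MSigDB exchange format: one set per line, fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are removed with a warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @param toupper_genes Upper-case gene identifiers after reading (guards
#'   against case mismatches when mixing symbol sources). Default `FALSE`.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, toupper_genes = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(paste0(
      "GMT parse error: line ", short[1], " has ",
      lengths(fields)[short[1]], " field(s); need name, description, >=1 gene"
    ))
  }
  name <- vapply(fields, `[[`, "", 1)
  description <- vapply(fields, `[[`, "", 2)
  genes <- lapply(fields, function(f) trimws(f[-(1:2)]))
  if (toupper_genes) genes <- lapply(genes, toupper)
  n_dup <- sum(vapply(genes, function(g) sum(duplicated(g)), 0L))
  if (n_dup > 0) {
    warn(paste0("removed ", n_dup, " duplicated gene(s) within GMT lines"))
  }
  gene_set_collection(tibble(
    set = name, description = description,
    genes = lapply(genes, unique)
  ))
}

#' Write a gene set collection in GMT format
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(seq_len(nrow(gsc)), function(j) {
    paste(c(gsc$set[j], gsc$description[j], gsc$genes[[j]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- RNA / IHC readers ------------------------------------------------------

#' Read an HPA-style RNA expression table
#'
#' Reads a long-format tab-separated file with one row per (gene, tissue)
#' measurement and pivots it onto the gene-by-tissue grid. (gene, tissue)
#' pairs absent from the file are marked missing -- distinct from zero.
#' Default column names follow the HPA normal-tissue RNA download
#' (`Gene`, `Sample`, `Value`) but are overridable since they have changed
#' across HPA releases.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param gene_col,tissue_col,value_col Column names in the file.
#' @param toupper_genes Upper-case gene identifiers after reading.
#' @return An [expression_table()].
#' @export
read_rna_table <- function(path, gene_col = "Gene", tissue_col = "Sample",
                           value_col = "Value", toupper_genes = FALSE) {
  df <- read_tsv_checked(path, c(gene_col, tissue_col, value_col))
  out <- tibble(
    gene = as.character(df[[gene_col]]),
    tissue = as.character(df[[tissue_col]]),
    value = as.numeric(df[[value_col]])
  )
  if (toupper_genes) out$gene <- toupper(out$gene)
  expression_table(out)
}

#' Read an HPA-style IHC annotation table
#'
#' Reads a tab-separated file of IHC detection calls. Level strings are
#' matched case-insensitively against the four-category scale
#' (`Not detected`, `Low`, `Medium`, `High`); anything else is an error.
#' Default column names follow the HPA `normal_tissue.tsv` download.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param gene_col,tissue_col,level_col Required column names in the file.
#' @param cell_type_col,reliability_col Optional column names; silently
#'   skipped when absent from the file.
#' @param toupper_genes Upper-case gene identifiers after reading.
#' @return An [ihc_table()]; empty (zero rows) if the file has only a header.
#' @export
read_ihc_table <- function(path, gene_col = "Gene", tissue_col = "Tissue",
                           level_col = "Level", cell_type_col = "Cell type",
                           reliability_col = "Reliability",
                           toupper_genes = FALSE) {
  df <- read_tsv_checked(path, c(gene_col, tissue_col, level_col))
  out <- tibble(
    gene = as.character(df[[gene_col]]),
    tissue = as.character(df[[tissue_col]]),
    level = as.character(df[[level_col]])
  )
  out$cell_type <- if (cell_type_col %in% names(df)) {
    as.character(df[[cell_type_col]])
  } else {
    NA_character_
  }
  out$reliability <- if (reliability_col %in% names(df)) {
    as.character(df[[reliability_col]])
  } else {
    NA_character_
  }
  if (toupper_genes) out$gene <- toupper(out$gene)
  ihc_table(out)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "column(s) not found in ", path, ": ",
      paste(shQuote(missing), collapse = ", "),
      "; available: ", paste(shQuote(names(df)), collapse = ", ")
    ))
  }
  df
}

# ---- gene identifier mapping ------------------------------------------------

#' Apply a two-column identifier mapping to a gene set collection
#'
#' Gene identifiers are matched between collections and expression/IHC
#' tables by exact string equality (after whitespace trimming); there is no
#' built-in identifier conversion. When the two sides use different
#' identifier spaces (MSigDB symbols vs. HPA Ensembl genes), supply an
#' explicit mapping file: tab-separated, two columns, `from<TAB>to`, with a
#' header. Unmapped genes are dropped from the sets with an informative
#' count; one-to-many mappings expand.
#'
#' @param gsc A `gene_set_collection`.
#' @param mapping A data frame whose first two columns are (from, to), or a
#'   path to such a tab-separated file.
#' @return A remapped `gene_set_collection` (sets that lose every member are
#'   dropped, with a warning).
#' @export
map_gene_ids <- function(gsc, mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- readr::read_tsv(mapping, show_col_types = FALSE, progress = FALSE)
  }
  mapping <- as_tibble(mapping)
  if (ncol(mapping) < 2) abort("identifier mapping needs two columns (from, to)")
  from <- trimws(as.character(mapping[[1]]))
  to <- trimws(as.character(mapping[[2]]))
  lut <- split(to, from)
  n_unmapped <- 0L
  new_genes <- lapply(gsc$genes, function(g) {
    hits <- lut[g]
    n_unmapped <<- n_unmapped + sum(vapply(hits, is.null, TRUE))
    unique(unlist(hits, use.names = FALSE))
  })
  if (n_unmapped > 0) {
    inform(paste0(n_unmapped, " gene membership(s) had no identifier mapping and were dropped"))
  }
  keep <- lengths(new_genes) > 0
  if (!all(keep)) {
    warn(paste0(sum(!keep), " set(s) lost all members under the mapping and were dropped"))
  }
  gene_set_collection(tibble(
    set = gsc$set[keep],
    description = gsc$description[keep],
    genes = new_genes[keep]
  ))
}

# ---- weight matrix I/O ------------------------------------------------------

#' Write a weight matrix to a tab-separated file
#'
#' Writes gene or set weights as a wide matrix: first column `name`
#' (genes or sets), one column per tissue, full floating-point precision so
#' that a write/read round-trip is lossless. Undefined weights are written
#' as `NA`.
#'
#' @param x A `gene_weights` or `set_weights` object (long form), or any
#'   data frame with columns (`gene`|`set`), `tissue`, `weight`.
#' @param path Output path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(x, path) {
  if (!dir.exists(dirname(path))) {
    abort(paste0("directory does not exist: ", dirname(path)))
  }
  df <- as_tibble(x)
  id_col <- intersect(c("gene", "set", "name"), names(df))[1]
  if (is.na(id_col) || !all(c("tissue", "weight") %in% names(df))) {
    abort("expected long-form weights with columns (gene|set|name), tissue, weight")
  }
  wide <- tidyr::pivot_wider(
    df[c(id_col, "tissue", "weight")],
    names_from = "tissue", values_from = "weight"
  )
  names(wide)[1] <- "name"
  # %.17g guarantees the printed decimal parses back to the identical double
  wide[-1] <- lapply(wide[-1], function(col) {
    ifelse(is.na(col), NA_character_, sprintf("%.17g", col))
  })
  readr::write_tsv(wide, path, progress = FALSE, na = "NA")
  invisible(path)
}

#' Read a weight matrix written by [write_weight_table()]
#'
#' @param path Path to a tab-separated weight matrix with a `name` column.
#' @return Long tibble with columns `name`, `tissue`, `weight`.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # read as character and convert through base strtod, which recovers the
  # written %.17g representation bit-exactly
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (names(df)[1] != "name") {
    abort(paste0("expected first column 'name' in ", path))
  }
  df[-1] <- lapply(df[-1], as.numeric)
  tidyr::pivot_longer(df, -"name", names_to = "tissue", values_to = "weight")
}
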