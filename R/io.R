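#' Expression matrix container
#'
#' A genes-by-samples numeric matrix with a declared scale. Every downstream
#' stage of the classification pipeline consumes this type. `scale` records
#' whether the values are raw counts or log2-normalised expression; counts
#' must be non-negative and are converted by [normalize_housekeeping()].
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene and sample identifiers unless `gene_ids`
#'   / `sample_ids` are given.
#' @param scale `"counts"` or `"log2norm"`.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (named matrix), `scale`.
#' @export
expression_matrix <- function(values, scale = c("counts", "log2norm"),
                              gene_ids = NULL, sample_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_ic("'values' must be a numeric matrix")
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ic("gene and sample identifiers are required")
  if (anyNA(values)) stop_ic("expression matrix contains missing values")
  if (anyDuplicated(rownames(values)))
    stop_ic("duplicate gene ids: %s",
            paste(unique(rownames(values)[duplicated(rownames(values))]),
                  collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_ic("duplicate sample ids: %s",
            paste(unique(colnames(values)[duplicated(colnames(values))]),
                  collapse = ", "))
  if (scale == "counts" && any(values < 0))
    stop_ic("scale 'counts' requires non-negative values")
  structure(list(values = values, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an ExpressionMatrix or ScoreMatrix
#' @param x an `ExpressionMatrix` or `ScoreMatrix`.
#' @export
sample_ids <- function(x) colnames(x$values)

#' A named gene set
#'
#' @param name signature name, unique within its category.
#' @param category one of `cell_type`, `function`, `immune_estimate`,
#'   `hallmark`, `pathway`.
#' @param genes character vector of gene ids (duplicates removed).
#' @return a `GeneSignature` list.
#' @export
gene_signature <- function(name, category, genes) {
  category <- match.arg(category,
                        c("cell_type", "function", "immune_estimate",
                          "hallmark", "pathway"))
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop_ic("signature '%s' has no genes", name)
  structure(list(name = name, category = category, genes = genes),
            class = "GeneSignature")
}

#' A collection of gene signatures
#'
#' Signature names must be unique within each category.
#'
#' @param signatures list of [gene_signature()] objects.
#' @return a `SignatureCollection`.
#' @export
signature_collection <- function(signatures) {
  stopifnot(all(vapply(signatures, inherits, logical(1), "GeneSignature")))
  key <- vapply(signatures, function(s) paste(s$category, s$name), "")
  if (anyDuplicated(key))
    stop_ic("duplicate signature name within a category: %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(list(signatures = signatures), class = "SignatureCollection")
}

#' @export
length.SignatureCollection <- function(x) length(x$signatures)

#' @export
print.SignatureCollection <- function(x, ...) {
  cats <- table(vapply(x$signatures, `[[`, "", "category"))
  cat(sprintf("SignatureCollection: %d signatures (%s)\n", length(x),
              paste(names(cats), cats, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Subset a SignatureCollection by category
#' @param collection a `SignatureCollection`.
#' @param category category to keep.
#' @export
filter_signatures <- function(collection, category) {
  keep <- vapply(collection$signatures, function(s) s$category == category,
                 logical(1))
  signature_collection(collection$signatures[keep])
}

#' Names of the signatures in a collection
#' @param collection a `SignatureCollection`.
#' @export
signature_names <- function(collection)
  vapply(collection$signatures, `[[`, "", "name")

# ---------------------------------------------------------------------------
# readers / writers

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  # tie broken toward tab
  if (lengths(regmatches(first, gregexpr(",", first))) >
      lengths(regmatches(first, gregexpr("\t", first)))) "," else "\t"
}

#' Read a delimited gene-by-sample expression table
#'
#' First column gene ids, header row sample ids; delimiter auto-detected
#' (tab or comma, ties to tab). Duplicate gene rows are collapsed: summed for
#' counts, averaged for log2-normalised values, with a warning. Gene matching
#' downstream is by exact, case-sensitive string equality.
#'
#' @param path path to a TSV/CSV file.
#' @param scale_hint `"counts"` or `"log2norm"`.
#' @param transpose set `TRUE` for files with samples in rows.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, scale_hint = c("counts", "log2norm"),
                                  transpose = FALSE) {
  scale_hint <- match.arg(scale_hint)
  if (!file.exists(path)) stop_ic("file not found: %s", path)
  if (file.size(path) == 0) stop_ic("empty expression file: %s", path)
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop_ic("expression file has no data cells: %s", path)
  ids <- df[[1]]
  num <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_ic("non-numeric value at gene '%s', sample '%s'",
            ids[bad[1]], colnames(num)[bad[2]])
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  if (anyDuplicated(rownames(num))) {
    dup <- unique(rownames(num)[duplicated(rownames(num))])
    warn_ic("collapsing %d duplicated gene id(s) by %s: %s",
            length(dup), if (scale_hint == "counts") "sum" else "mean",
            paste(utils::head(dup, 5), collapse = ", "))
    f <- factor(rownames(num), levels = unique(rownames(num)))
    agg <- if (scale_hint == "counts") {
      rowsum(num, f)
    } else {
      rowsum(num, f) / as.vector(table(f))
    }
    num <- agg[levels(f), , drop = FALSE]
  }
  expression_matrix(num, scale = scale_hint)
}

#' Write an ExpressionMatrix as TSV
#' @param expr an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(gene_id = gene_ids(expr), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Broad-dialect GMT: one set per line, fields tab-separated —
#' name, description (discarded), then gene ids. Trailing empty fields are
#' stripped.
#'
#' @param path path to a .gmt file.
#' @param category category tag assigned to every set in the file.
#' @return a [signature_collection()].
#' @export
read_gmt <- function(path, category = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_ic("empty GMT file: %s", path)
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3)
      stop_ic("GMT line %d has fewer than 3 fields", i)
    gene_signature(fields[1], category, fields[-(1:2)])
  })
  signature_collection(sigs)
}

#' Read a mixed-category GMT written by [write_gmt()]
#'
#' [write_gmt()] stores each signature's category in the GMT description
#' field; this reader restores it, so a whole collection round-trips through
#' one file.
#'
#' @param path path to a .gmt file whose description fields hold categories.
#' @return a [signature_collection()].
#' @export
read_gmt_by_category <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_ic("empty GMT file: %s", path)
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3)
      stop_ic("GMT line %d has fewer than 3 fields", i)
    gene_signature(fields[1], fields[2], fields[-(1:2)])
  })
  signature_collection(sigs)
}

#' Write a SignatureCollection as GMT
#' @param collection a `SignatureCollection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$signatures, function(s) {
    paste(c(s$name, s$category, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Delimited text with a required `sample_id` column. Recognised columns:
#' `cps` (PD-L1 combined positive score, non-negative), `subtype`
#' (CIN/GS/EBV/MSI), `pfs_time` (months), `pfs_event` (0/1 or TRUE/FALSE),
#' `response` (responder/non_responder), `batch`, `il18` (plasma IL-18,
#' pg/mL). Unrecognised columns are preserved. Missing optional fields are
#' returned as `NA`/`"unknown"`.
#'
#' @param path path to a TSV/CSV file.
#' @return a data.frame with one row per sample, typed columns.
#' @export
read_sample_annotations <- function(path) {
  if (!file.exists(path)) stop_ic("file not found: %s", path)
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (!"sample_id" %in% names(df)) stop_ic("missing 'sample_id' column")
  validate_annotations(df)
}

#' Validate (and type) a sample-annotation data.frame
#' @param df data.frame with at least a `sample_id` column.
#' @return the validated data.frame with canonical column types.
#' @export
validate_annotations <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_ic("duplicate sample_id: %s",
            paste(unique(df$sample_id[duplicated(df$sample_id)]),
                  collapse = ", "))
  if ("cps" %in% names(df)) {
    df$cps <- as.numeric(df$cps)
    if (any(df$cps < 0, na.rm = TRUE)) stop_ic("cps must be non-negative")
  }
  if ("subtype" %in% names(df)) {
    ok <- c("CIN", "GS", "EBV", "MSI", "unknown", NA)
    if (!all(df$subtype %in% ok))
      stop_ic("unknown subtype value(s): %s",
              paste(setdiff(df$subtype, ok), collapse = ", "))
    df$subtype[is.na(df$subtype)] <- "unknown"
  }
  if ("pfs_time" %in% names(df)) {
    df$pfs_time <- as.numeric(df$pfs_time)
    if (any(df$pfs_time <= 0, na.rm = TRUE))
      stop_ic("pfs_time must be positive")
  }
  if ("pfs_event" %in% names(df)) {
    ev <- df$pfs_event
    if (is.character(ev)) ev <- ev %in% c("TRUE", "true", "1", "yes")
    df$pfs_event <- as.logical(ev)
    if (!"pfs_time" %in% names(df) ||
        any(!is.na(df$pfs_event) & is.na(df$pfs_time)))
      stop_ic("pfs_event defined without pfs_time")
  }
  if ("response" %in% names(df)) {
    ok <- c("responder", "non_responder", "unknown", NA)
    if (!all(df$response %in% ok))
      stop_ic("response must be responder/non_responder/unknown")
    df$response[is.na(df$response)] <- "unknown"
  }
  if ("il18" %in% names(df)) {
    df$il18 <- as.numeric(df$il18)
    if (any(df$il18 < 0, na.rm = TRUE)) stop_ic("il18 must be non-negative")
  }
  df
}
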