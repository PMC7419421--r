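#' Construct a gene-level CNA matrix
#'
#' The central container of the package: discrete gene-level copy-number
#' calls for a cohort, with samples as rows and genes as columns. Entries
#' follow the GISTIC thresholded convention: -2 homozygous deletion,
#' -1 heterozygous loss, 0 diploid, 1 one-copy gain, 2 high-level
#' amplification. Other integers are accepted with a warning, since some
#' GISTIC dialects emit them.
#'
#' @param values integer matrix, samples x genes.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to rownames of `values`).
#' @param gene_ids character vector of unique gene identifiers
#'   (defaults to colnames of `values`).
#' @param labels optional named character vector mapping every sample_id to
#'   a class name (tissue of origin).
#' @return an object of class `cna_matrix` with elements `values`
#'   (integer matrix with dimnames), and optionally `labels`.
#' @export
cna_matrix <- function(values, sample_ids = rownames(values),
                       gene_ids = colnames(values), labels = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(gene_ids))
    stop("sample_ids and gene_ids are required (or provide dimnames)")
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(sample_ids) || ncol(values) != length(gene_ids))
    stop(sprintf("matrix is %d x %d but %d sample ids and %d gene ids given",
                 nrow(values), ncol(values), length(sample_ids), length(gene_ids)))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  if (anyNA(values)) stop("CNA matrix contains missing values")
  if (any(values != round(values)))
    stop("CNA matrix entries must be integers")
  storage.mode(values) <- "integer"
  if (any(values < -2L | values > 2L))
    warning("CNA values outside {-2,...,2} present; accepted as-is")
  dimnames(values) <- list(sample_ids, gene_ids)
  if (!is.null(labels)) {
    labels <- vapply(labels, as.character, character(1))
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("labels missing for samples: ", paste(utils::head(missing, 5), collapse = ", "))
    labels <- labels[sample_ids]
  }
  structure(list(values = values, labels = labels), class = "cna_matrix")
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat(sprintf("cna_matrix: %d samples x %d genes\n", nrow(x$values), ncol(x$values)))
  rng <- range(x$values)
  cat(sprintf("  value range: [%d, %d]\n", rng[1], rng[2]))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cna_matrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
gene_ids <- function(x) colnames(x$values)

#' Subset a CNA matrix by samples and/or genes
#'
#' @param x a [cna_matrix()].
#' @param samples,genes index or name vectors; missing keeps all.
#' @return a `cna_matrix`.
#' @export
subset_cna <- function(x, samples = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  lab <- if (is.null(x$labels)) NULL else x$labels[rownames(v)]
  cna_matrix(v, labels = lab)
}

#' Read a GISTIC-style gene-level CNA matrix
#'
#' Parses tab-separated gene-level thresholded copy-number tables such as
#' GISTIC's `all_thresholded.by_genes` (one gene per row, one sample per
#' column, plus annotation columns like "Locus ID" and "Cytoband"), or the
#' transposed dialect with one sample per row. The returned matrix always
#' has samples as rows.
#'
#' @param path path to a tab-separated text file whose first column holds
#'   identifiers and first row holds the header.
#' @param orientation `"genes_as_rows"` (GISTIC convention, default) or
#'   `"samples_as_rows"`.
#' @param annotation_columns columns dropped before parsing values;
#'   default covers the usual GISTIC annotations.
#' @return a [cna_matrix()] (without labels).
#' @export
read_cna_matrix <- function(path,
                            orientation = c("genes_as_rows", "samples_as_rows"),
                            annotation_columns = c("Locus ID", "Cytoband")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty or malformed CNA matrix file: ", path)
  ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  drop <- intersect(annotation_columns, colnames(df))
  if (length(drop)) df <- df[, setdiff(colnames(df), drop), drop = FALSE]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate row identifiers in ", path, ": ", paste(dup, collapse = ", "))
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(df)))
  bad <- which(is.na(num) & !is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 df[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(df)[bad[1, 2]], path))
  rownames(num) <- ids
  if (orientation == "genes_as_rows") num <- t(num)
  cna_matrix(num)
}

#' Write a CNA matrix as a GISTIC-style TSV
#'
#' @param x a [cna_matrix()].
#' @param path output path.
#' @param orientation file layout; `"genes_as_rows"` matches GISTIC.
#' @param id_column header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_cna_matrix <- function(x, path, orientation = c("genes_as_rows", "samples_as_rows"),
                             id_column = NULL) {
  orientation <- match.arg(orientation)
  v <- x$values
  if (orientation == "genes_as_rows") {
    v <- t(v)
    if (is.null(id_column)) id_column <- "Gene Symbol"
  } else if (is.null(id_column)) id_column <- "Sample"
  df <- data.frame(id = rownames(v), v, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-class label table
#'
#' Two tab-separated columns, `sample_id<TAB>class`, header optional
#' (recognized when the first line reads like `sample.../class|label|tissue...`).
#' A sample listed twice with the same class is deduplicated with a warning;
#' conflicting classes are an error.
#'
#' @param path path to the label TSV.
#' @return named character vector: `names` are sample ids, values class names.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("label file must have two tab-separated columns: ", path)
  first <- tolower(trimws(as.character(df[1, 1:2])))
  if (first[1] %in% c("sample", "sample_id", "sampleid", "id") &&
      first[2] %in% c("class", "label", "tissue", "type"))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("label file has no data rows: ", path)
  ids <- trimws(df[[1]]); cls <- trimws(df[[2]])
  agg <- tapply(cls, ids, unique, simplify = FALSE)
  conflict <- names(agg)[lengths(agg) > 1]
  if (length(conflict))
    stop("conflicting labels for sample(s): ", paste(conflict, collapse = ", "))
  if (anyDuplicated(ids))
    warning("duplicated sample entries with identical labels were deduplicated")
  out <- vapply(agg, `[[`, character(1), 1)
  out <- out[unique(ids)]  # preserve file order
  message(sprintf("read %d samples across %d classes: %s", length(out),
                  length(unique(out)), paste(sort(unique(out)), collapse = ", ")))
  out
}

#' Write a label table
#' @param labels named character vector (names = sample ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(names(labels), unname(labels)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Harmonize a training and an independent cohort
#'
#' Restricts both matrices to the genes they share (identical order) and
#' removes from `test` any sample whose id also occurs in `train`, so the
#' independent cohort stays independent.
#'
#' @param train,test [cna_matrix()] objects.
#' @return list with elements `train` and `test`.
#' @export
harmonize <- function(train, test) {
  stopifnot(inherits(train, "cna_matrix"), inherits(test, "cna_matrix"))
  common <- intersect(gene_ids(train), gene_ids(test))
  if (length(common) == 0) stop("no genes shared between the two cohorts")
  dropped_train <- ncol(train$values) - length(common)
  dropped_test <- ncol(test$values) - length(common)
  shared_samples <- intersect(sample_ids(test), sample_ids(train))
  keep <- setdiff(sample_ids(test), shared_samples)
  if (length(keep) == 0) stop("no test samples remain after removing overlap with train")
  message(sprintf(
    "harmonize: %d common genes (dropped %d from train, %d from test); removed %d overlapping test sample(s)",
    length(common), dropped_train, dropped_test, length(shared_samples)))
  list(train = subset_cna(train, genes = common),
       test = subset_cna(test, samples = keep, genes = common))
}

#' Scale a CNA matrix to [-1, 1] by its maximum absolute value
#'
#' Divides every entry by a single positive divisor so the result lies in
#' `[-1, 1]`: `x' = x / |x|_max`. With the default policy the divisor is
#' the global maximum absolute entry of the matrix (for GISTIC thresholded
#' data this is 2, so the map is x/2). The divisor is recorded so held-out
#' data can be scaled identically via [apply_scaling()].
#'
#' @param m a [cna_matrix()].
#' @param divisor_policy `"global_max_abs"` (default) or a fixed positive
#'   number supplied through `divisor`.
#' @param divisor positive numeric; required when
#'   `divisor_policy = "fixed"`.
#' @return object of class `scaled_matrix`: `values` (real matrix, same
#'   dimnames), `scale_divisor`, and the input's `labels`.
#' @export
scale_cna <- function(m, divisor_policy = c("global_max_abs", "fixed"), divisor = NULL) {
  stopifnot(inherits(m, "cna_matrix"))
  divisor_policy <- match.arg(divisor_policy)
  if (divisor_policy == "global_max_abs") {
    divisor <- max(abs(m$values))
    if (divisor == 0)
      stop("all-zero matrix: global max-abs divisor would divide by zero")
  } else {
    if (is.null(divisor) || !is.finite(divisor) || divisor <= 0)
      stop("fixed policy requires a positive finite divisor")
  }
  vals <- m$values / divisor
  structure(list(values = vals, scale_divisor = divisor, labels = m$labels),
            class = "scaled_matrix")
}

#' Apply a previously fitted scaling to new data
#'
#' Reuses the divisor fitted on training data, avoiding leakage. Warns if
#' any scaled entry falls outside [-1, 1] (possible when the new cohort
#' contains larger alterations than the training data).
#'
#' @param m a [cna_matrix()].
#' @param divisor positive divisor, typically `scaled$scale_divisor` from
#'   a training-set [scale_cna()] call.
#' @return a `scaled_matrix`.
#' @export
apply_scaling <- function(m, divisor) {
  stopifnot(inherits(m, "cna_matrix"), is.numeric(divisor), divisor > 0)
  vals <- m$values / divisor
  if (any(abs(vals) > 1))
    warning("scaled values outside [-1, 1]: new data exceed the training divisor")
  structure(list(values = vals, scale_divisor = divisor, labels = m$labels),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("scaled_matrix: %d samples x %d genes, divisor %g, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$scale_divisor,
              min(x$values), max(x$values)))
  invisible(x)
}
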