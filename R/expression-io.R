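#' Expression dataset container
#'
#' A minimal container for a genes x samples intensity matrix with optional
#' binary class labels (0 = normal, 1 = cancer). Values are stored as a
#' numeric matrix with gene ids as rownames and sample ids as colnames;
#' labels are an integer vector named by sample id and aligned to the
#' matrix columns.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). No missing values.
#' @param labels optional vector of 0/1 labels. Either named by sample id
#'   (any order; must cover every sample exactly) or unnamed of length N in
#'   column order.
#' @return an object of class `expression_dataset` with elements
#'   `gene_ids`, `sample_ids`, `values`, `labels`.
#' @export
expression_dataset <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  if (!is.null(labels)) labels <- align_labels(labels, colnames(values))
  structure(
    list(
      gene_ids = rownames(values),
      sample_ids = colnames(values),
      values = values,
      labels = labels
    ),
    class = "expression_dataset"
  )
}

align_labels <- function(labels, sample_ids) {
  lab <- as.integer(labels)
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
    stop("labels must all be 0 or 1")
  }
  if (!is.null(names(labels))) {
    extra <- setdiff(names(labels), sample_ids)
    if (length(extra)) {
      stop("labels given for unknown sample ids: ", paste(extra, collapse = ", "))
    }
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) {
      stop("labels missing for sample ids: ", paste(missing, collapse = ", "))
    }
    lab <- lab[match(sample_ids, names(labels))]
  } else if (length(lab) != length(sample_ids)) {
    stop(sprintf(
      "unnamed labels of length %d do not match %d samples",
      length(lab), length(sample_ids)
    ))
  }
  names(lab) <- sample_ids
  lab
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d samples%s\n",
    length(x$gene_ids), length(x$sample_ids),
    if (is.null(x$labels)) " (unlabeled)"
    else sprintf(" (%d normal / %d cancer)", sum(x$labels == 0L), sum(x$labels == 1L))
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

split_fields <- function(line) {
  sep <- if (grepl("\t", line, fixed = TRUE)) "\t" else ","
  strsplit(line, sep, fixed = TRUE)[[1]]
}

parse_numeric_cells <- function(fields, line_no, path) {
  vals <- suppressWarnings(as.numeric(fields))
  bad <- is.na(vals) & !(toupper(trimws(fields)) %in% c("NA", ""))
  if (anyNA(vals)) {
    offending <- fields[is.na(vals)][1]
    stop(sprintf(
      "non-numeric or missing cell '%s' at line %d of '%s'",
      offending, line_no, path
    ))
  }
  vals
}

#' Read a gene expression matrix
#'
#' Reads either a plain delimited matrix (tab or comma; header row of sample
#' ids, first column of gene ids) or a GCT v1.2 file. The historical RES
#' format is deliberately not supported.
#'
#' @param path file path.
#' @param format `"delimited"` or `"gct"`.
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`;
#'   for the latter the delimited file has gene ids in the header and sample
#'   ids in the first column, and the matrix is transposed on load. GCT files
#'   are always genes x samples.
#' @param labels optional labels passed through to [expression_dataset()].
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path,
                            format = c("delimited", "gct"),
                            orientation = c("genes_by_samples", "samples_by_genes"),
                            labels = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  mat <- if (format == "gct") {
    if (orientation != "genes_by_samples") {
      stop("GCT files are genes x samples by definition; do not set orientation")
    }
    read_gct_matrix(path)
  } else {
    read_delimited_matrix(path, orientation)
  }
  expression_dataset(mat, labels = labels)
}

read_delimited_matrix <- function(path, orientation) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop(sprintf("'%s': need a header line plus at least one data row", path))
  }
  header <- split_fields(lines[1])
  if (length(header) < 2L) {
    stop(sprintf("malformed header at line 1 of '%s': '%s'", path, lines[1]))
  }
  # header may or may not carry a stub for the id column
  col_ids <- header[-1]
  n_col <- length(col_ids)
  row_ids <- character(length(lines) - 1L)
  mat <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = n_col)
  for (i in seq_along(row_ids)) {
    fields <- split_fields(lines[i + 1L])
    if (length(fields) != n_col + 1L) {
      stop(sprintf(
        "line %d of '%s' has %d fields, expected %d (id + %d values)",
        i + 1L, path, length(fields), n_col + 1L, n_col
      ))
    }
    row_ids[i] <- fields[1]
    mat[i, ] <- parse_numeric_cells(fields[-1], i + 1L, path)
  }
  dimnames(mat) <- list(row_ids, col_ids)
  if (orientation == "samples_by_genes") mat <- t(mat)
  mat
}

read_gct_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "#1.2") {
    stop(sprintf("'%s' is not a GCT v1.2 file (first line must be '#1.2')", path))
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (length(dims) != 2L || anyNA(dims)) {
    stop(sprintf("malformed GCT dimensions line 2 of '%s': '%s'", path, lines[2]))
  }
  g_decl <- dims[1]; n_decl <- dims[2]
  header <- split_fields(lines[3])
  if (length(header) < 3L || toupper(header[1]) != "NAME") {
    stop(sprintf("malformed GCT header at line 3 of '%s': '%s'", path, lines[3]))
  }
  sample_ids <- header[-(1:2)]
  if (length(sample_ids) != n_decl) {
    stop(sprintf(
      "GCT '%s' declares %d samples but header has %d",
      path, n_decl, length(sample_ids)
    ))
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != g_decl) {
    stop(sprintf(
      "GCT '%s' declares %d genes but contains %d data rows",
      path, g_decl, length(body)
    ))
  }
  gene_ids <- character(g_decl)
  mat <- matrix(NA_real_, nrow = g_decl, ncol = n_decl)
  for (i in seq_len(g_decl)) {
    fields <- split_fields(body[i])
    if (length(fields) != n_decl + 2L) {
      stop(sprintf(
        "GCT '%s' declares %d samples but line %d has %d value columns",
        path, n_decl, i + 3L, length(fields) - 2L
      ))
    }
    gene_ids[i] <- fields[1]
    mat[i, ] <- parse_numeric_cells(fields[-(1:2)], i + 3L, path)
  }
  dimnames(mat) <- list(gene_ids, sample_ids)
  mat
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; round trips are lossless to the 15
#' significant digits written.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @param format `"delimited"` (tab separated) or `"gct"`.
#' @export
write_expression <- function(dataset, path, format = c("delimited", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], if (format == "gct") "na", fmt(v[i, ])), collapse = "\t")
  }, character(1))
  header <- if (format == "gct") {
    c("#1.2",
      paste(nrow(v), ncol(v), sep = "\t"),
      paste(c("Name", "Description", colnames(v)), collapse = "\t"))
  } else {
    paste(c("gene_id", colnames(v)), collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a two-column sample label file
#'
#' @param path delimited file (tab, comma or whitespace) with columns
#'   (sample id, label in 0/1); an optional header line is skipped when its
#'   second field is not a 0/1 label.
#' @return named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("'%s' is empty", path))
  split2 <- function(line) {
    f <- if (grepl("[\t,]", line)) strsplit(line, "[\t,]")[[1]]
         else strsplit(trimws(line), "\\s+")[[1]]
    trimws(f)
  }
  start <- 1L
  first <- split2(lines[1])
  if (length(first) == 2L && !first[2] %in% c("0", "1")) start <- 2L
  if (start > length(lines)) stop(sprintf("'%s' has a header but no data", path))
  ids <- character(0); labs <- integer(0)
  for (i in seq(start, length(lines))) {
    f <- split2(lines[i])
    if (length(f) != 2L) {
      stop(sprintf("line %d of '%s' has %d fields, expected 2", i, path, length(f)))
    }
    if (!f[2] %in% c("0", "1")) {
      stop(sprintf("line %d of '%s': label '%s' is not 0 or 1", i, path, f[2]))
    }
    ids <- c(ids, f[1]); labs <- c(labs, as.integer(f[2]))
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample ids in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(labs) <- ids
  labs
}

predictions_table <- function(predictions) {
  if (!length(predictions)) stop("empty prediction list")
  one <- function(p, id) {
    if (inherits(p, "minimax_prediction")) {
      data.frame(
        sample_id = id, F = p$f_reported, rho = p$rmse_bound,
        ci_low = p$ci_low, ci_high = p$ci_high,
        class_call = p$class_call, cp_flag = p$cp_flag,
        i_star = p$fit$i, sigma = p$fit$sigma,
        stringsAsFactors = FALSE
      )
    } else if (inherits(p, "knn_prediction")) {
      data.frame(
        sample_id = id, F = NA_real_, rho = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        class_call = p$class_call, cp_flag = p$cp_flag,
        i_star = NA_integer_, sigma = NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      stop("unsupported prediction object of class ", paste(class(p), collapse = "/"))
    }
  }
  ids <- names(predictions)
  if (is.null(ids)) ids <- as.character(seq_along(predictions))
  do.call(rbind, Map(one, predictions, ids))
}

#' Write a per-patient prediction report
#'
#' TSV output has one row per patient with columns (sample_id, F, rho,
#' ci_low, ci_high, class_call, cp_flag, i_star, sigma); JSON output nests
#' the same rows plus the cohort summary. Numbers are written with at least
#' six significant digits.
#'
#' @param predictions non-empty named list of predictions
#'   (from [minimax_estimate()] or [knn_predict()]).
#' @param summary optional [summarize_cohort()] result (required for JSON).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(predictions, summary = NULL, path,
                         format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- predictions_table(predictions)
  if (format == "tsv") {
    num <- vapply(tab, is.numeric, logical(1)) &
      !vapply(tab, is.integer, logical(1))
    tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 8, format = "g"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(patients = tab)
    if (!is.null(summary)) payload$summary <- unclass(summary)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
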