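#' Construct a validated Cq dataset
#'
#' A Cq dataset holds quantification-cycle (Cq) values for a two-group qPCR
#' experiment in wide form: one row per sample x gene x plate, with technical
#' replicates in columns \code{cq_rep1..cq_repK}. Validation is total --
#' malformed input raises a typed error rather than returning a partial
#' object.
#'
#' @param df data frame with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{plate} and at least one \code{cq_rep*} column.
#' @param control label of the control (calibrator-side) group. Defaults to
#'   the alphabetically first group label, with a message.
#' @return a \code{cq_dataset}: the validated data frame with attributes
#'   \code{groups}, \code{genes}, \code{control} and \code{rep_cols}.
#' @export
cq_dataset <- function(df, control = NULL) {
  required <- c("sample_id", "group", "gene", "plate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    ns_format_error("missing required column(s): %s",
                    paste(missing_cols, collapse = ", "))
  rep_cols <- grep("^cq_rep[0-9]+$", names(df), value = TRUE)
  if (!length(rep_cols))
    ns_format_error("no replicate Cq columns (cq_rep1..cq_repK) found")
  rep_cols <- rep_cols[order(as.integer(sub("^cq_rep", "", rep_cols)))]

  for (col in rep_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(as.character(raw)))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad))
      ns_parse_error("non-numeric Cq value '%s' in column %s, row %d",
                     as.character(raw[bad[1]]), col, bad[1])
    df[[col]] <- val
  }
  cq <- as.matrix(df[rep_cols])
  if (anyNA(cq))
    ns_validation_error("missing Cq replicate value in row %d",
                        which(rowSums(is.na(cq)) > 0)[1])
  out_of_range <- which(cq <= 0 | cq > 45, arr.ind = TRUE)
  if (nrow(out_of_range))
    ns_validation_error("Cq value %.3f out of (0, 45] in row %d",
                        cq[out_of_range[1, , drop = FALSE]],
                        out_of_range[1, 1])

  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$gene <- as.character(df$gene)
  df$plate <- as.character(df$plate)

  groups <- sort(unique(df$group))
  if (length(groups) != 2L)
    ns_validation_error("exactly two group labels required, found %d (%s)",
                        length(groups), paste(groups, collapse = ", "))

  key <- paste(df$sample_id, df$gene, df$plate, sep = "\r")
  if (anyDuplicated(key))
    ns_validation_error("duplicate (sample, gene) entry on one plate: %s",
                        gsub("\r", " / ", key[duplicated(key)][1]))

  # complete design: every sample quantified on every gene of the panel
  tab <- table(df$sample_id, df$gene)
  if (any(tab == 0))
    ns_validation_error("incomplete design: sample '%s' has no record for gene '%s'",
                        rownames(tab)[which(tab == 0, arr.ind = TRUE)[1, 1]],
                        colnames(tab)[which(tab == 0, arr.ind = TRUE)[1, 2]])

  # balanced plates: equal numbers of samples from each group on every plate
  smp <- unique(df[c("sample_id", "group", "plate")])
  bal <- table(smp$plate, smp$group)
  if (any(bal[, 1] != bal[, 2]))
    ns_validation_error("plate '%s' is unbalanced: %d vs %d samples per group",
                        rownames(bal)[which(bal[, 1] != bal[, 2])[1]],
                        bal[which(bal[, 1] != bal[, 2])[1], 1],
                        bal[which(bal[, 1] != bal[, 2])[1], 2])

  if (is.null(control)) {
    control <- groups[1]
    message("control group not declared; using '", control, "'")
  } else if (!control %in% groups) {
    ns_validation_error("declared control group '%s' not among group labels (%s)",
                        control, paste(groups, collapse = ", "))
  }

  structure(df,
            class = c("cq_dataset", "data.frame"),
            groups = groups, genes = sort(unique(df$gene)),
            control = control, rep_cols = rep_cols)
}

#' Read a Cq table
#'
#' Reads a CSV of raw quantification cycles. The wide dialect has columns
#' \code{sample_id, group, gene, plate, cq_rep1..cq_repK}; the long dialect
#' has one row per replicate with columns \code{sample_id, group, gene,
#' plate, replicate, cq} and is pivoted to wide on load.
#'
#' @param path CSV file path.
#' @param control control-group label (calibrator side); see
#'   \code{\link{cq_dataset}}.
#' @param format \code{"wide"} (default) or \code{"long"}.
#' @return a validated \code{\link{cq_dataset}}.
#' @export
read_cq_table <- function(path, control = NULL, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) ns_io_error("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  if (format == "long") {
    req <- c("sample_id", "group", "gene", "plate", "replicate", "cq")
    if (length(setdiff(req, names(df))))
      ns_format_error("long dialect requires columns: %s",
                      paste(req, collapse = ", "))
    df$replicate <- as.integer(df$replicate)
    wide <- stats::reshape(df[req], direction = "wide",
                           idvar = c("sample_id", "group", "gene", "plate"),
                           timevar = "replicate", v.names = "cq")
    names(wide) <- sub("^cq\\.", "cq_rep", names(wide))
    rownames(wide) <- NULL
    df <- wide
  }
  cq_dataset(df, control = control)
}

#' Write a Cq table
#'
#' @param ds a \code{cq_dataset}.
#' @param path output CSV path.
#' @export
write_cq_table <- function(ds, path) {
  stopifnot(inherits(ds, "cq_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE,
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a log2 expression matrix
#'
#' Series-matrix-style TSV: first column row identifiers (genes or
#' probesets), header line sample identifiers. Rows containing empty or
#' non-numeric cells are dropped with a message; the count of dropped rows
#' is attached as attribute \code{n_dropped}.
#'
#' @param path TSV file path.
#' @param log2 whether the stored values are on the log2 scale (metadata
#'   flag consumed by downstream stages).
#' @return numeric matrix of class \code{expression_matrix} with attributes
#'   \code{log2} and \code{n_dropped}.
#' @export
read_expression_matrix <- function(path, log2 = TRUE) {
  if (!file.exists(path)) ns_io_error("file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(nf)) != 1L)
    ns_format_error("ragged table: rows have %s fields",
                    paste(sort(unique(nf)), collapse = "/"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
  if (ncol(df) < 2L) ns_format_error("expected row ids plus >=1 sample column")
  ids <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, names(df)[-1]))
  keep <- rowSums(is.na(vals)) == 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " row(s) with missing values: ",
            paste(utils::head(ids[!keep], 5), collapse = ", "))
  expression_matrix(vals[keep, , drop = FALSE], log2 = log2,
                    n_dropped = n_dropped)
}

#' Construct an expression matrix
#'
#' @param x numeric matrix, genes/probesets in rows, samples in columns.
#' @param log2 metadata flag: values are log2-scale signal intensities.
#' @param n_dropped rows dropped on loading (bookkeeping).
#' @export
expression_matrix <- function(x, log2 = TRUE, n_dropped = 0L) {
  if (!is.matrix(x) || !is.numeric(x))
    ns_validation_error("expression matrix must be a numeric matrix")
  if (anyNA(x)) ns_validation_error("expression matrix contains missing values")
  structure(x, class = c("expression_matrix", class(matrix())),
            log2 = log2, n_dropped = as.integer(n_dropped))
}

#' Write an expression matrix as TSV
#'
#' @param mat matrix with row and column names.
#' @param path output TSV path.
#' @param id_column header name of the row-identifier column.
#' @export
write_expression_matrix <- function(mat, path, id_column = "id") {
  df <- data.frame(id = rownames(mat),
                   format(unclass(mat), digits = 12, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column sample label file
#'
#' TSV with columns \code{sample_id} and \code{group}; returns a named
#' character vector of group labels.
#' @param path TSV file path.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) ns_io_error("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (length(setdiff(c("sample_id", "group"), names(df))))
    ns_format_error("label file requires columns sample_id, group")
  stats::setNames(as.character(df$group), as.character(df$sample_id))
}

#' Read a probeset-to-gene annotation
#'
#' Two-column TSV (\code{probeset_id}, \code{gene_symbol}); many-to-one
#' probeset-to-gene mappings are allowed.
#' @param path TSV file path.
#' @export
read_probeset_annotation <- function(path) {
  if (!file.exists(path)) ns_io_error("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (length(setdiff(c("probeset_id", "gene_symbol"), names(df))))
    ns_format_error("annotation requires columns probeset_id, gene_symbol")
  if (anyDuplicated(df$probeset_id))
    ns_validation_error("probeset '%s' annotated more than once",
                        df$probeset_id[duplicated(df$probeset_id)][1])
  df
}

#' Write a results table
#'
#' Serializes analysis results as a UTF-8, LF-terminated TSV with a fixed,
#' deterministic column order. Differential-expression results use the
#' conventional header (logFC, AveExpr, t, p-value, Adjusted p-value, B);
#' any other data frame is written with its own columns.
#'
#' @param results non-empty data frame (e.g. from \code{\link{run_de}}).
#' @param path output TSV path.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || !nrow(as.data.frame(results)))
    ns_validation_error("refusing to write an empty results table")
  df <- as.data.frame(results)
  if (inherits(results, "de_results")) {
    df <- data.frame(probeset = df$probeset_id, gene = df$gene_symbol,
                     logFC = df$logFC, AveExpr = df$AveExpr, t = df$t,
                     `p-value` = df$p_value, `Adjusted p-value` = df$adj_p_value,
                     B = df$B, check.names = FALSE)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 12, trim = TRUE,
                                                scientific = FALSE))
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) ns_io_error("cannot open '%s' for writing", path))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}
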