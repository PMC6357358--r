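#' Read a GMT gene-set file
#'
#' Broad/MSigDB dialect: one set per line, tab-separated fields
#' `name TAB description TAB gene TAB gene ...`. Lines with fewer than three
#' fields are a parse error; duplicate members within a line are removed with
#' a warning; duplicate set names are an error. Ordering is preserved.
#'
#' @param path path to a GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(sets = stats::setNames(list(), character(0)),
                          desc = stats::setNames(character(0), character(0))),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                 which(nf < 3L)[1L]))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  gene_sets(stats::setNames(members, nm), desc)
}

#' Write a gene-set collection as GMT
#'
#' Canonical form: one set per line, `name TAB description TAB genes...`,
#' members in stored order. Tabs inside names, descriptions or gene ids are
#' an error because the tab is the field separator.
#'
#' @param x a `gene_set_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  all_tok <- c(names(x$sets), x$desc, unlist(x$sets, use.names = FALSE))
  if (any(grepl("\t", all_tok, fixed = TRUE))) {
    stop("tab characters are not allowed inside GMT fields")
  }
  lines <- vapply(seq_along(x$sets), function(i) {
    paste(c(names(x$sets)[i], x$desc[[i]], x$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.read_table_matrix <- function(path, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), comment.char = "")
  if (ncol(df) < 2L) stop(what, ": expected an id column plus data columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(what, ": duplicate row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols)) {
    stop(what, ": duplicate column ids: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  # an all-missing column is read as logical NA; treat it as numeric
  num_ok <- vapply(df[-1L], function(col) {
    is.numeric(col) || all(is.na(col))
  }, logical(1))
  if (any(!num_ok)) {
    stop(what, ": non-numeric values in column(s): ",
         paste(cols[!num_ok], collapse = ", "))
  }
  m <- vapply(df[-1L], as.numeric, numeric(nrow(df)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, cols))
  rownames(m) <- ids
  m
}

#' Read a log-scale expression matrix
#'
#' Tab-delimited text: header row of sample ids, first column gene ids,
#' numeric cells. Values are taken as already log-scale; no transformation is
#' applied. Missing or non-numeric cells and duplicate ids are errors.
#'
#' @param path path to a tab-delimited matrix.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path) {
  m <- .read_table_matrix(path, "expression")
  if (anyNA(m)) stop("expression: missing values are not allowed")
  m
}

#' Read a drug-response table
#'
#' Tab-delimited text: header row of drug ids, first column sample ids,
#' numeric log-IC50 cells. Missing entries (empty or `NA`) are allowed:
#' not every sample has response data for every drug.
#'
#' @param path path to a tab-delimited table.
#' @return Numeric matrix, samples x drugs, possibly containing `NA`.
#' @export
read_response <- function(path) {
  .read_table_matrix(path, "response")
}

#' Write a matrix in the package's tab-delimited dialect
#'
#' UTF-8, tab separators, `.` decimal point, `NA` for missing cells, numbers
#' at full double precision (`%.17g`) so a write/read round trip reproduces
#' the values exactly.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_label header label for the id column (first cell).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, id_label = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_label, colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a drug-gene annotation table
#'
#' Three tab-separated columns: drug id, gene id, role. Roles must be one of
#' `target`, `transporter`, `enzyme`. A header line `drug TAB gene TAB role`
#' is optional. Duplicate (drug, gene) pairs within a role are collapsed.
#'
#' @param path path to the annotation file.
#' @return A named list (class `drug_annotation`): per drug, a list with
#'   character vectors `target`, `transporter` and `enzyme`.
#' @export
read_drug_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1L]]),
                                  c("drug", "gene", "role"))) {
    fields <- fields[-1L]
  }
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop(sprintf("annotation line %d: expected 3 tab-separated fields",
                 which(nf != 3L)[1L]))
  }
  drug <- vapply(fields, `[[`, character(1), 1L)
  gene <- vapply(fields, `[[`, character(1), 2L)
  role <- vapply(fields, `[[`, character(1), 3L)
  ok <- role %in% c("target", "transporter", "enzyme")
  if (any(!ok)) {
    stop("unknown role token(s): ", paste(unique(role[!ok]), collapse = ", "))
  }
  drug_annotation(data.frame(drug = drug, gene = gene, role = role,
                             stringsAsFactors = FALSE))
}

#' Build a drug-gene annotation from a data frame
#'
#' @param df data frame with columns `drug`, `gene`, `role` (role in
#'   `target`/`transporter`/`enzyme`). The same gene may appear under several
#'   roles; duplicates within one role are collapsed.
#' @return Object of class `drug_annotation`: named list per drug with
#'   `target`, `transporter` and `enzyme` character vectors.
#' @export
drug_annotation <- function(df) {
  stopifnot(all(c("drug", "gene", "role") %in% names(df)))
  ok <- df$role %in% c("target", "transporter", "enzyme")
  if (any(!ok)) {
    stop("unknown role token(s): ",
         paste(unique(df$role[!ok]), collapse = ", "))
  }
  out <- lapply(split(df, df$drug), function(d) {
    list(target = unique(d$gene[d$role == "target"]),
         transporter = unique(d$gene[d$role == "transporter"]),
         enzyme = unique(d$gene[d$role == "enzyme"]))
  })
  structure(out, class = "drug_annotation")
}

#' Serialize a fitted elastic-net model to key-value text
#'
#' Plain-text format: comment header, then `key TAB value` lines for
#' `alpha`, `lambda`, `intercept`, `min_cv_mse`, `n_samples`, followed by one
#' `coef TAB feature TAB value` line per feature (zeros included so the
#' feature space round-trips). The CV surface is not serialized.
#'
#' @param model a [fit_elastic_net_cv()] fit of class `pd_enet`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pd_enet"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# pathdrive elastic-net model", con)
  kv <- c(alpha = model$alpha, lambda = model$lambda,
          intercept = model$intercept, min_cv_mse = model$min_cv_mse,
          n_samples = model$n_samples)
  writeLines(sprintf("%s\t%.17g", names(kv), kv), con)
  writeLines(sprintf("coef\t%s\t%.17g", names(model$coefficients),
                     model$coefficients), con)
  invisible(path)
}

#' Read a fitted model written by [write_model()]
#'
#' @param path path to a model file.
#' @return A `pd_enet` object (without the CV surface or fold assignment).
#' @export
read_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_coef <- vapply(fields, `[[`, character(1), 1L) == "coef"
  kv <- fields[!is_coef]
  vals <- stats::setNames(as.numeric(vapply(kv, `[[`, character(1), 2L)),
                          vapply(kv, `[[`, character(1), 1L))
  cf <- fields[is_coef]
  coefs <- stats::setNames(as.numeric(vapply(cf, `[[`, character(1), 3L)),
                           vapply(cf, `[[`, character(1), 2L))
  structure(list(feature_names = names(coefs),
                 intercept = unname(vals[["intercept"]]),
                 coefficients = coefs,
                 alpha = unname(vals[["alpha"]]),
                 lambda = unname(vals[["lambda"]]),
                 cv_mse = NULL,
                 min_cv_mse = unname(vals[["min_cv_mse"]]),
                 n_samples = as.integer(vals[["n_samples"]]),
                 config = NULL),
            class = "pd_enet")
}
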