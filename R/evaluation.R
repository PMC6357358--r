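#' Categorize a pathway by its drug-related genes
#'
#' Applies the waterfall-plot color rules relating a pathway's members to a
#' drug's annotated genes: `target_plus` if the pathway holds a target gene
#' and at least one transporter or metabolic enzyme; `target_only` if it
#' holds targets only; `enzyme_only` if it holds enzymes but no targets and
#' no transporters; `transporter_only` if it holds transporters but no
#' targets and no enzymes; otherwise `none`. A non-target pathway containing
#' both an enzyme and a transporter falls outside the four rules and is
#' assigned `enzyme_only` with a warning. Every (pathway, drug) pair maps to
#' exactly one category.
#'
#' @param members character vector of member gene ids.
#' @param annotation a `drug_annotation` (see [drug_annotation()]).
#' @param drug drug id present in `annotation`.
#' @return Length-1 factor with levels `target_plus`, `target_only`,
#'   `enzyme_only`, `transporter_only`, `none`.
#' @export
categorize_pathway <- function(members, annotation, drug) {
  stopifnot(inherits(annotation, "drug_annotation"))
  if (!drug %in% names(annotation)) stop("unknown drug: ", drug)
  ann <- annotation[[drug]]
  has_t <- any(members %in% ann$target)
  has_x <- any(members %in% ann$transporter)
  has_e <- any(members %in% ann$enzyme)
  cat_ <- if (has_t && (has_x || has_e)) {
    "target_plus"
  } else if (has_t) {
    "target_only"
  } else if (has_e && has_x) {
    warning("non-target pathway with both enzyme and transporter genes; ",
            "assigned enzyme_only")
    "enzyme_only"
  } else if (has_e) {
    "enzyme_only"
  } else if (has_x) {
    "transporter_only"
  } else {
    "none"
  }
  factor(cat_, levels = c("target_plus", "target_only", "enzyme_only",
                          "transporter_only", "none"))
}

#' Count selected pathways involving drug-related genes
#'
#' For each drug, counts how many of the pathways selected by a model (its
#' nonzero-coefficient features) involve at least one annotated drug-related
#' gene, i.e. categorize to anything but `none`.
#'
#' @param selected named list: drug id -> character vector of selected
#'   pathway names (e.g. the `feature` column of [nonzero_features()]).
#' @param genesets a `gene_set_collection` holding all selectable pathways.
#' @param annotation a `drug_annotation`.
#' @return Data frame with columns `drug`, `n_selected`, `n_drug_related`;
#'   attribute `"n_drugs_with_hit"` gives the number of drugs with at least
#'   one drug-related pathway selected.
#' @export
count_drug_related_pathways <- function(selected, genesets, annotation) {
  stopifnot(is.list(selected), inherits(genesets, "gene_set_collection"))
  rows <- lapply(names(selected), function(d) {
    pws <- selected[[d]]
    missing <- setdiff(pws, names(genesets$sets))
    if (length(missing)) {
      stop("selected pathway(s) not in collection: ",
           paste(missing, collapse = ", "))
    }
    cats <- vapply(pws, function(p) {
      as.character(categorize_pathway(genesets$sets[[p]], annotation, d))
    }, character(1))
    data.frame(drug = d, n_selected = length(pws),
               n_drug_related = sum(cats != "none"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "n_drugs_with_hit") <- sum(out$n_drug_related >= 1L)
  out
}

#' Compare sensitive and resistant samples on a pathway's activity
#'
#' The `k` samples with the lowest IC50 form the sensitive group and the `k`
#' with the highest IC50 the resistant group (ties broken by stable sample-id
#' order); a two-sample t-test contrasts the pathway activity between the
#' groups. The t statistic is oriented sensitive minus resistant.
#'
#' @param activity named numeric vector of one pathway's activity scores.
#' @param ic50 named numeric vector of log-IC50 values; names matched against
#'   `activity` (unnamed vectors are matched positionally).
#' @param k group size (default 20; needs at least `2k` complete samples).
#' @param variant `"welch"` (unequal variances, default) or `"student"`.
#' @return Object of class `group_ttest`: `t_statistic`, `p_value`, `k`,
#'   group means, `variant`.
#' @export
sensitivity_group_ttest <- function(activity, ic50, k = 20L,
                                    variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (k < 2L) stop("k must be >= 2")
  if (!is.null(names(activity)) && !is.null(names(ic50))) {
    ids <- intersect(names(activity), names(ic50))
    activity <- activity[ids]
    ic50 <- ic50[ids]
  } else {
    stopifnot(length(activity) == length(ic50))
    ids <- if (!is.null(names(activity))) names(activity) else
      sprintf("s%06d", seq_along(activity))
  }
  keep <- !is.na(activity) & !is.na(ic50)
  activity <- activity[keep]
  ic50 <- ic50[keep]
  ids <- ids[keep]
  if (length(ic50) < 2L * k) {
    stop("need at least 2k = ", 2L * k, " complete samples, have ",
         length(ic50))
  }
  ord <- order(ic50, ids)
  sens <- ord[seq_len(k)]
  res <- ord[seq.int(length(ord) - k + 1L, length(ord))]
  tt <- stats::t.test(activity[sens], activity[res],
                      var.equal = (variant == "student"))
  structure(list(t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, k = k,
                 mean_sensitive = mean(activity[sens]),
                 mean_resistant = mean(activity[res]),
                 sensitive_ids = ids[sens], resistant_ids = ids[res],
                 variant = variant),
            class = "group_ttest")
}

#' @export
print.group_ttest <- function(x, ...) {
  cat(sprintf(
    "sensitive vs resistant activity t-test (%s, k = %d)\n  t = %.4f, p = %.4g\n  mean sensitive = %.4f, mean resistant = %.4f\n",
    x$variant, x$k, x$t_statistic, x$p_value, x$mean_sensitive,
    x$mean_resistant))
  invisible(x)
}

#' Rank scoring methods by per-drug cross-validated MSE
#'
#' Per drug, methods are ranked by ascending CV MSE (rank 1 = best). Methods
#' whose MSEs agree to within 1e-12 share the better rank (logged). Counts of
#' rank-1 ("best") and rank-2 ("second best") occurrences are aggregated per
#' method.
#'
#' @param mse_table numeric matrix, drugs x methods, with dimnames and no
#'   missing values.
#' @return Object of class `method_comparison`: the input table, the per-drug
#'   rank matrix, and named `best` / `second` count vectors.
#' @export
compare_methods <- function(mse_table) {
  stopifnot(is.matrix(mse_table), !is.null(colnames(mse_table)))
  if (anyNA(mse_table)) stop("mse_table contains missing values")
  tol <- 1e-12
  ranks <- t(apply(mse_table, 1L, function(v) {
    vapply(v, function(x) sum(v < x - tol) + 1L, integer(1))
  }))
  dimnames(ranks) <- dimnames(mse_table)
  n_ties <- sum(apply(ranks, 1L, anyDuplicated) > 0L)
  if (n_ties > 0L) message(n_ties, " drug(s) with tied MSE ranks")
  best <- colSums(ranks == 1L)
  second <- colSums(ranks == 2L)
  structure(list(mse = mse_table, ranks = ranks, best = best,
                 second = second),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method comparison over %d drug(s)\n", nrow(x$mse)))
  print(data.frame(method = colnames(x$mse), best = unname(x$best),
                   second_best = unname(x$second)), row.names = FALSE)
  invisible(x)
}
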