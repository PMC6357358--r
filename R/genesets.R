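#' Construct a gene-set collection
#'
#' A gene-set collection is an ordered, named list of pathways, each holding a
#' character vector of member gene ids. Duplicate members within a set are
#' removed (with a warning); duplicate set names are an error.
#'
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled to the number of sets; defaults to empty strings.
#' @return An object of class `gene_set_collection` with elements `sets`
#'   (named list) and `desc` (named character vector).
#' @examples
#' gs <- gene_sets(list(pwA = c("g1", "g2", "g3"), pwB = c("g2", "g4")))
#' geneset_sizes(gs)
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop("`sets` must be a list of character vectors")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("every gene set must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    if (length(m) == 0L) stop("gene sets must be non-empty")
    m
  })
  ndup <- vapply(sets, function(m) sum(duplicated(m)), integer(1))
  if (any(ndup > 0L)) {
    warning("removed duplicate members in set(s): ",
            paste(nm[ndup > 0L], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- nm
  structure(list(sets = sets, desc = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- geneset_sizes(x)
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x$sets)))
  if (length(sz)) {
    cat(sprintf("  sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
    show <- utils::head(names(x$sets), 5L)
    cat("  ", paste(show, collapse = ", "),
        if (length(x$sets) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' Subset a gene-set collection
#' @param x a `gene_set_collection`.
#' @param i index vector (names, positions or logical).
#' @param ... ignored.
#' @export
`[.gene_set_collection` <- function(x, i, ...) {
  gene_sets(x$sets[i], x$desc[i])
}

#' Sizes of the sets in a collection
#' @param x a `gene_set_collection`.
#' @return Named integer vector of member counts.
#' @export
geneset_sizes <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  vapply(x$sets, length, integer(1))
}

#' Filter a gene-set collection by size
#'
#' Retains the sets whose member count falls inside `[size_min, size_max]`
#' (bounds inclusive). By default sizes are counted on the stored (database)
#' membership; with `restrict_to_universe = TRUE` members are first
#' intersected with `universe` and the effective sizes are used, and retained
#' sets keep only their in-universe members.
#'
#' @param x a `gene_set_collection`.
#' @param universe character vector of gene ids (e.g. the rownames of an
#'   expression matrix); required when `restrict_to_universe = TRUE`.
#' @param size_min,size_max inclusive size bounds (defaults 5 and 200).
#' @param restrict_to_universe intersect members with `universe` before
#'   measuring sizes.
#' @return A filtered `gene_set_collection`; the attribute `"dropped"` holds a
#'   data frame of removed sets with their effective size and reason.
#' @examples
#' gs <- gene_sets(list(a = paste0("g", 1:3), b = paste0("g", 1:10)))
#' filter_genesets(gs, size_min = 5, size_max = 200)
#' @export
filter_genesets <- function(x, universe = NULL, size_min = 5L,
                            size_max = 200L, restrict_to_universe = FALSE) {
  stopifnot(inherits(x, "gene_set_collection"))
  if (size_min < 1L) stop("size_min must be >= 1")
  if (size_max < size_min) stop("size_max must be >= size_min")
  if (restrict_to_universe) {
    if (is.null(universe) || length(universe) == 0L) {
      stop("restrict_to_universe = TRUE requires a non-empty universe")
    }
    eff <- lapply(x$sets, function(m) m[m %in% universe])
  } else {
    eff <- x$sets
  }
  sz <- vapply(eff, length, integer(1))
  keep <- sz >= size_min & sz <= size_max
  dropped <- data.frame(
    name = names(x$sets)[!keep],
    size = sz[!keep],
    reason = ifelse(sz[!keep] < size_min, "below size_min", "above size_max"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  members <- if (restrict_to_universe) eff[keep] else x$sets[keep]
  out <- if (any(keep)) {
    gene_sets(members, x$desc[keep])
  } else {
    structure(list(sets = stats::setNames(list(), character(0)),
                   desc = stats::setNames(character(0), character(0))),
              class = "gene_set_collection")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Pairwise Jaccard overlap of a gene-set collection
#'
#' J(A, B) = |A intersect B| / |A union B|. The result is a symmetric matrix
#' with unit diagonal and values in `[0, 1]`; identical sets score 1 and
#' disjoint sets score 0.
#'
#' @param x a `gene_set_collection` with at least one set.
#' @return A symmetric numeric matrix, sets x sets.
#' @examples
#' gs <- gene_sets(list(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4")))
#' jaccard_matrix(gs)
#' @export
jaccard_matrix <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  if (length(x$sets) < 1L) stop("collection is empty")
  genes <- unique(unlist(x$sets, use.names = FALSE))
  inc <- vapply(x$sets, function(m) genes %in% m,
                logical(length(genes)))
  inc <- matrix(as.numeric(inc), nrow = length(genes),
                dimnames = list(NULL, names(x$sets)))
  inter <- crossprod(inc)
  sz <- diag(inter)
  uni <- outer(sz, sz, "+") - inter
  J <- inter / uni
  diag(J) <- 1
  J
}
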