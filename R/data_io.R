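#' @importFrom stats complete.cases
NULL

ALLOWED_EDGE_TYPES <- data.frame(
  regulator_type = c("TF", "TF", "miRNA"),
  target_type    = c("gene", "miRNA", "gene"),
  stringsAsFactors = FALSE
)

#' Construct an expression matrix
#'
#' An `ExpressionMatrix` is a numeric matrix of expression values with
#' features in rows and samples in columns, tagged with the feature type
#' (`"gene"` or `"miRNA"`). Row and column names must be unique and
#' non-empty; the matrix must be complete (no `NA`).
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param feature_type `"gene"` or `"miRNA"`.
#' @return the matrix with class `ExpressionMatrix` and a `feature_type`
#'   attribute.
#' @export
expression_matrix <- function(values, feature_type = c("gene", "miRNA")) {
  feature_type <- match.arg(feature_type)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  structure(values, feature_type = feature_type,
            class = c("ExpressionMatrix", class(values)))
}

#' Load an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids, the first
#' column holding feature ids, and a numeric body in which an empty cell
#' denotes a missing value.
#'
#' @param path file path.
#' @param feature_type `"gene"` or `"miRNA"`.
#' @param missing_policy `"drop_feature"` drops any feature with a missing
#'   value; `"impute_feature_mean"` fills missing cells with the feature's
#'   mean over the remaining samples.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path,
                            feature_type = c("gene", "miRNA"),
                            missing_policy = c("drop_feature", "impute_feature_mean")) {
  feature_type <- match.arg(feature_type)
  missing_policy <- match.arg(missing_policy)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("expression TSV needs a feature-id column plus >= 1 sample column")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(ifelse(body == "", NA, body)),
                                 nrow = nrow(body), dimnames = dimnames(body)))
  bad <- which(is.na(num) & body != "" & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], colnames(body)[bad[1, 2]]))
  rownames(num) <- ids
  if (missing_policy == "drop_feature") {
    num <- num[stats::complete.cases(num), , drop = FALSE]
  } else {
    for (i in which(!stats::complete.cases(num))) {
      mu <- mean(num[i, ], na.rm = TRUE)
      num[i, is.na(num[i, ])] <- mu
    }
    num <- num[stats::complete.cases(num), , drop = FALSE]  # all-NA rows
  }
  expression_matrix(num, feature_type)
}

#' Construct a prior interaction catalog
#'
#' A `PriorCatalog` is a typed directed candidate edge list with columns
#' `regulator_type`, `regulator_id`, `target_type`, `target_id`,
#' `source_tag`. Only TF->gene, TF->miRNA and miRNA->gene pairs are allowed
#' (miRNA->TF regulation is represented as a miRNA->gene edge whose target
#' sits in the TF roster). Exact duplicate (regulator, target) pairs are
#' merged and self-edges rejected.
#'
#' @param edges data frame with the columns above (`source_tag` optional).
#' @return data frame of class `PriorCatalog`.
#' @export
prior_catalog <- function(edges) {
  need <- c("regulator_type", "regulator_id", "target_type", "target_id")
  if (!all(need %in% names(edges)))
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  if (is.null(edges$source_tag)) edges$source_tag <- NA_character_
  edges <- edges[, c(need, "source_tag")]
  for (col in names(edges)) edges[[col]] <- as.character(edges[[col]])
  tags <- c("TF", "miRNA", "gene")
  unknown <- setdiff(unique(c(edges$regulator_type, edges$target_type)), tags)
  if (length(unknown) > 0)
    stop("unknown type tag(s): ", paste(unknown, collapse = ", "))
  if (any(edges$regulator_id == edges$target_id))
    stop("self-edges are not allowed")
  key <- paste(edges$regulator_type, edges$regulator_id,
               edges$target_type, edges$target_id, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("PriorCatalog", "data.frame")
  edges
}

#' Load a prior interaction catalog from TSV
#'
#' Rows whose (regulator_type, target_type) pair is not one of the three
#' allowed kinds are dropped and reported in the `rejected` attribute of the
#' result; rows carrying a type tag outside \{TF, miRNA, gene\} raise an
#' error.
#'
#' @param path TSV with columns `regulator_type`, `regulator_id`,
#'   `target_type`, `target_id`, `source_tag`.
#' @param tf_roster optional character vector of TF gene ids; when given,
#'   TF regulator ids not in the roster are also rejected.
#' @return a [prior_catalog()]; `attr(x, "rejected")` holds the dropped rows.
#' @export
load_prior_catalog <- function(path, tf_roster = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  if (is.null(raw$source_tag)) raw$source_tag <- NA_character_
  tags <- c("TF", "miRNA", "gene")
  unknown <- setdiff(unique(c(raw$regulator_type, raw$target_type)), tags)
  if (length(unknown) > 0)
    stop("unknown type tag(s) in ", path, ": ", paste(unknown, collapse = ", "))
  ok <- mapply(function(r, t) any(ALLOWED_EDGE_TYPES$regulator_type == r &
                                    ALLOWED_EDGE_TYPES$target_type == t),
               raw$regulator_type, raw$target_type)
  ok <- ok & raw$regulator_id != raw$target_id
  if (!is.null(tf_roster))
    ok <- ok & (raw$regulator_type != "TF" | raw$regulator_id %in% tf_roster)
  rejected <- raw[!ok, , drop = FALSE]
  cat_df <- prior_catalog(raw[ok, , drop = FALSE])
  attr(cat_df, "rejected") <- rejected
  cat_df
}

#' Write a typed edge list to TSV
#'
#' Works for prior catalogs and identified edge sets (extra columns such as
#' `beta` and `f_pvalue` are preserved).
#'
#' @param edges data frame of edges.
#' @param path output path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load sample class labels
#'
#' @param path two-column TSV (`sample_id`, `class`), with header.
#' @return named character vector of classes keyed by sample id.
#' @export
load_labels <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("label TSV needs sample_id and class columns")
  if (anyDuplicated(raw[[1]])) stop("duplicate sample ids in label file")
  stats::setNames(raw[[2]], raw[[1]])
}

#' Pair mRNA and miRNA expression matrices over shared samples
#'
#' Parallel expression data are gene and miRNA abundances measured on the
#' same samples. Both matrices are restricted and reordered to their common
#' samples: when the sample sets are identical the mRNA ordering is kept,
#' otherwise the intersection is taken in sorted order for reproducibility.
#'
#' @param mrna,mirna [expression_matrix()] objects of type gene and miRNA.
#' @param labels optional named class vector covering the shared samples.
#' @return list of class `ParallelDataset` with elements `mrna`, `mirna`,
#'   `labels`, `dropped_samples`.
#' @export
align_parallel <- function(mrna, mirna, labels = NULL) {
  if (!identical(attr(mrna, "feature_type"), "gene"))
    stop("mrna must be an ExpressionMatrix of feature_type 'gene'")
  if (!identical(attr(mirna, "feature_type"), "miRNA"))
    stop("mirna must be an ExpressionMatrix of feature_type 'miRNA'")
  common <- intersect(colnames(mrna), colnames(mirna))
  if (length(common) == 0) stop("no shared samples between mRNA and miRNA matrices")
  if (setequal(colnames(mrna), colnames(mirna))) {
    ord <- colnames(mrna)
  } else {
    ord <- sort(common)
  }
  dropped <- length(union(colnames(mrna), colnames(mirna))) - length(ord)
  if (dropped > 0)
    warning(dropped, " sample(s) dropped when aligning parallel matrices")
  mrna2 <- expression_matrix(unclass(mrna)[, ord, drop = FALSE], "gene")
  mirna2 <- expression_matrix(unclass(mirna)[, ord, drop = FALSE], "miRNA")
  if (!is.null(labels)) {
    missing <- setdiff(ord, names(labels))
    if (length(missing) > 0)
      stop("labels missing for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[ord]
  }
  structure(list(mrna = mrna2, mirna = mirna2, labels = labels,
                 dropped_samples = dropped),
            class = "ParallelDataset")
}

#' @export
print.ParallelDataset <- function(x, ...) {
  cat("ParallelDataset:", nrow(x$mrna), "genes x", nrow(x$mirna), "miRNAs x",
      ncol(x$mrna), "samples\n")
  if (!is.null(x$labels))
    cat("labels:", paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                         collapse = ", "), "\n")
  invisible(x)
}

# look up one feature's profile across the two layers; NULL when unmeasured
feature_profile <- function(dataset, id) {
  if (id %in% rownames(dataset$mrna)) return(unclass(dataset$mrna)[id, ])
  if (id %in% rownames(dataset$mirna)) return(unclass(dataset$mirna)[id, ])
  NULL
}
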