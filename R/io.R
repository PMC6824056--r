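# File formats: plain TSV throughout. Associations are two-column edge
# lists, similarity matrices are square tables with an id header row and
# column written at full double precision, DAG files are three-column
# (disease, child, parent) edge lists covering many diseases per file.

fmt_full <- function(x) sprintf("%.17g", x)

#' Read a disease-microbe association list
#'
#' Two tab-separated columns, `disease<TAB>microbe`, optional header line
#' (recognized when the first line is `disease`/`microbe`, case
#' insensitive). Labels are ordered by first appearance. Duplicate pairs
#' are rejected with their line numbers.
#'
#' @param path file path.
#' @return an [association_matrix()].
#' @export
read_associations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) stop("empty association file: ", path)
  fields <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    bad <- lines_keep[lengths(fields) != 2L]
    stop("malformed line(s) ", paste(bad, collapse = ", "), " in ", path)
  }
  first <- tolower(trimws(fields[[1]]))
  if (identical(first, c("disease", "microbe"))) {
    fields <- fields[-1]
    lines_keep <- lines_keep[-1]
    if (length(fields) == 0) stop("association file has a header but no entries: ", path)
  }
  d <- vapply(fields, `[`, "", 1L)
  m <- vapply(fields, `[`, "", 2L)
  key <- paste(d, m, sep = "\t")
  if (anyDuplicated(key)) {
    dup_lines <- lines_keep[duplicated(key) | duplicated(key, fromLast = TRUE)]
    stop("duplicate disease-microbe pair(s) at line(s) ",
         paste(dup_lines, collapse = ", "), " in ", path)
  }
  disease_ids <- unique(d)
  microbe_ids <- unique(m)
  A <- matrix(0, length(disease_ids), length(microbe_ids),
              dimnames = list(disease_ids, microbe_ids))
  A[cbind(d, m)] <- 1
  association_matrix(A)
}

#' @rdname read_associations
#' @param A association matrix to write.
#' @export
write_associations <- function(A, path) {
  validate_association_matrix(A)
  idx <- which(A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- paste(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]], sep = "\t")
  writeLines(c("disease\tmicrobe", out), path)
  invisible(path)
}

#' Read or write a square similarity matrix
#'
#' Square TSV with the node ids as both header row and first column.
#' Written at full double precision so round trips are exact. Loading
#' rejects matrices asymmetric beyond `tol` and, when `labels` is given,
#' any id not in `labels`.
#'
#' @param path file path.
#' @param labels optional allowed node ids.
#' @param tol symmetry tolerance (default 1e-10).
#' @return numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path, labels = NULL, tol = 1e-10) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(tab)
  if (nrow(S) != ncol(S) || !identical(rownames(S), colnames(S))) {
    stop("similarity matrix must be square with matching row/column ids: ", path)
  }
  if (!is.null(labels)) {
    unknown <- setdiff(rownames(S), labels)
    if (length(unknown) > 0) {
      stop("unknown node id(s) in ", path, ": ", paste(unknown, collapse = ", "))
    }
  }
  if (max(abs(S - t(S))) > tol) {
    stop("similarity matrix asymmetric beyond tolerance ", tol, ": ", path)
  }
  check_similarity_matrix(symmetrize(S))
}

#' @rdname read_similarity_matrix
#' @param S matrix to write.
#' @export
write_similarity_matrix <- function(S, path) {
  stopifnot(is.matrix(S), !is.null(rownames(S)))
  header <- paste(c("", colnames(S)), collapse = "\t")
  rows <- vapply(seq_len(nrow(S)), function(i) {
    paste(c(rownames(S)[i], fmt_full(S[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read or write disease DAG files
#'
#' Three tab-separated columns `disease_id<TAB>child_term<TAB>parent_term`;
#' one file holds the DAGs of many diseases. A disease whose DAG is a
#' single node is recorded as one line with empty child and parent fields.
#'
#' @param path file path.
#' @param decay semantic decay factor for the constructed DAGs.
#' @return named list of [disease_dag()] objects.
#' @export
read_dags <- function(path, decay = 0.5) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("disease", "child", "parent"),
                           stringsAsFactors = FALSE, na.strings = character(0),
                           colClasses = "character", fill = TRUE)
  out <- list()
  for (id in unique(tab$disease)) {
    rows <- tab[tab$disease == id & nzchar(tab$child) & nzchar(tab$parent), ,
                drop = FALSE]
    out[[id]] <- if (nrow(rows) == 0) {
      disease_dag(id, decay = decay)
    } else {
      disease_dag(id, rows[, c("child", "parent")], decay = decay)
    }
  }
  out
}

#' @rdname read_dags
#' @param dags named list of [disease_dag()] objects to write.
#' @export
write_dags <- function(dags, path) {
  lines <- character(0)
  for (g in dags) {
    stopifnot(inherits(g, "disease_dag"))
    lines <- c(lines, if (nrow(g$edges) == 0) {
      paste(g$disease_id, "", "", sep = "\t")
    } else {
      paste(g$disease_id, g$edges[, "child"], g$edges[, "parent"], sep = "\t")
    })
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-pair gene-family network files
#'
#' Six tab-separated columns `microbe_a microbe_b family_u family_v
#' membership_u membership_v` with memberships in `A`/`B`/`both`; rows
#' sharing a microbe pair form that pair's network.
#'
#' @param path file path.
#' @return named list (keys `"ma|mb"`) of [gene_family_network()] objects.
#' @export
read_gene_family_networks <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("microbe_a", "microbe_b", "family_u",
                                         "family_v", "membership_u", "membership_v"),
                           stringsAsFactors = FALSE, colClasses = "character")
  out <- list()
  key <- paste(tab$microbe_a, tab$microbe_b, sep = "|")
  for (k in unique(key)) {
    rows <- tab[key == k, , drop = FALSE]
    fams <- c(stats::setNames(rows$membership_u, rows$family_u),
              stats::setNames(rows$membership_v, rows$family_v))
    fams <- fams[!duplicated(names(fams))]
    conflicting <- tapply(c(rows$membership_u, rows$membership_v),
                          c(rows$family_u, rows$family_v),
                          function(x) length(unique(x)) > 1)
    if (any(conflicting)) {
      stop("inconsistent membership for family(ies) ",
           paste(names(conflicting)[conflicting], collapse = ", "),
           " in pair ", k)
    }
    out[[k]] <- gene_family_network(fams, rows[, c("family_u", "family_v")])
  }
  out
}

#' Write a prediction table
#'
#' One row per disease-microbe pair with its propagation score, its
#' within-disease rank (descending score, ties by microbe index) and a
#' flag marking known associations.
#'
#' @param P a `prediction_matrix` or score matrix.
#' @param A the association matrix supplying the known flags.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_predictions <- function(P, A, path) {
  scores <- if (inherits(P, "prediction_matrix")) P$scores else P
  validate_association_matrix(A)
  stopifnot(all(dim(scores) == dim(A)))
  lines <- "disease\tmicrobe\tscore\trank\tknown_flag"
  for (i in seq_len(nrow(scores))) {
    ord <- order(-scores[i, ], seq_len(ncol(scores)))
    lines <- c(lines, paste(rownames(A)[i], colnames(A)[ord],
                            fmt_full(scores[i, ord]), seq_along(ord),
                            A[i, ord], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an evaluation result as JSON
#'
#' Serializes AUC, AUC standard deviation, the precision/recall/F1 table
#' and the recovery table of an `eval_result`, plus the resolved parameter
#' set when supplied (provenance).
#'
#' @param result an `eval_result` from [global_loocv()] or [kfold_cv()].
#' @param path output file.
#' @param params optional [wmg_params()] recorded alongside the metrics.
#' @return the path, invisibly.
#' @export
write_metrics <- function(result, path, params = NULL) {
  stopifnot(inherits(result, "eval_result"))
  payload <- list(
    auc = result$auc,
    auc_std = if (is.null(result$auc_std)) NA else result$auc_std,
    prf_at_k = result$prf_at_k,
    recovery_at_k = result$recovery_at_k
  )
  if (!is.null(params)) payload$params <- unclass(params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Write the ROC polyline as TSV
#'
#' @param result an `eval_result`.
#' @param path output file with columns `fpr`, `tpr`.
#' @return the path, invisibly.
#' @export
write_roc <- function(result, path) {
  stopifnot(inherits(result, "eval_result"))
  utils::write.table(result$roc_points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `assoc.tsv`, `dags.tsv`, `fs.tsv` and a `manifest.json` holding
#' the generating spec (including the seed) so the run is reproducible.
#'
#' @param spec a [planted_spec()].
#' @param outdir output directory (created if needed).
#' @param decay DAG semantic decay factor.
#' @return the generated [mda_dataset()], invisibly.
#' @export
write_synthetic_dataset <- function(spec, outdir, decay = 0.5) {
  stopifnot(inherits(spec, "planted_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- planted_dataset(spec, decay = decay)
  write_associations(ds$A, file.path(outdir, "assoc.tsv"))
  write_dags(ds$dags, file.path(outdir, "dags.tsv"))
  write_similarity_matrix(ds$FS, file.path(outdir, "fs.tsv"))
  jsonlite::write_json(c(unclass(spec), list(decay = decay)),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}
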