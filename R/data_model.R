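#' Construct a survival dataset
#'
#' The universal input record: an expression matrix (samples in rows, genes in
#' columns) paired with an observed time and an event indicator per sample.
#'
#' @param X numeric n x p matrix, no missing values.
#' @param time positive observed times, length n.
#' @param status event indicators in {0, 1} (1 = event/labelled,
#'   0 = censored), length n.
#' @param sample_ids,gene_ids character identifiers; default from dimnames or
#'   generated.
#' @param promoted optional logical length n: provenance flag for samples
#'   whose labelled time is a pipeline pseudo-label rather than an observation.
#' @return An object of class `survival_dataset` with fields `X`, `time`,
#'   `status`, `sample_ids`, `gene_ids`, `promoted`.
#' @export
survival_dataset <- function(X, time, status, sample_ids = NULL,
                             gene_ids = NULL, promoted = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  sample_ids <- sample_ids %||% rownames(X) %||% paste0("S", seq_len(n))
  gene_ids <- gene_ids %||% colnames(X) %||% paste0("g", seq_len(p))
  time <- as.numeric(time)
  if (anyNA(X) || any(!is.finite(X)))
    stop_validation("expression matrix contains missing or non-finite values")
  if (length(time) != n || length(status) != n)
    stop_validation("time/status length (", length(time), "/", length(status),
                    ") does not match number of samples (", n, ")")
  if (length(sample_ids) != n) stop_validation("sample_ids length mismatch")
  if (length(gene_ids) != p) stop_validation("gene_ids length mismatch")
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t))
    stop_validation("non-positive or non-finite time at row ", bad_t[1])
  if (!all(status %in% c(0, 1)))
    stop_validation("non-binary status at row ",
                    which(!(status %in% c(0, 1)))[1])
  status <- as.integer(status)
  promoted <- promoted %||% rep(FALSE, n)
  dimnames(X) <- list(sample_ids, gene_ids)
  structure(list(X = X, time = time, status = status,
                 sample_ids = as.character(sample_ids),
                 gene_ids = as.character(gene_ids),
                 promoted = as.logical(promoted)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "<survival_dataset> %d samples x %d genes; %d events, %d censored\n",
    nrow(x$X), ncol(x$X), sum(x$status == 1), sum(x$status == 0)))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) dim(x$X)

#' Subset a survival dataset by samples (i) and/or genes (j)
#' @param x a `survival_dataset`.
#' @param i sample index (integer/logical/character).
#' @param j gene index.
#' @param ... unused.
#' @export
`[.survival_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  if (is.character(i)) i <- match(i, x$sample_ids)
  survival_dataset(x$X[i, j, drop = FALSE], x$time[i], x$status[i],
                   sample_ids = x$sample_ids[i],
                   gene_ids = x$gene_ids[if (is.character(j))
                     match(j, x$gene_ids) else j],
                   promoted = x$promoted[i])
}

detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read a dataset from delimited expression and survival tables
#'
#' The expression file must have a header row of gene ids and sample ids in
#' the first column; the survival file columns `sample_id`, `time`, `status`.
#' The delimiter (tab or comma) is auto-detected from each header line.
#' Samples are matched by id; the survival file's row order governs the
#' resulting row order.
#'
#' @param expression_path,survival_path paths to the two delimited files.
#' @param genes_as_rows set `TRUE` when the expression file stores genes as
#'   rows; it is transposed on read.
#' @return a validated [survival_dataset()].
#' @export
read_dataset <- function(expression_path, survival_path,
                         genes_as_rows = FALSE) {
  for (p in c(expression_path, survival_path)) {
    if (!file.exists(p)) stop_validation("input file not found: ", p)
  }
  expr <- utils::read.table(expression_path, header = TRUE,
                            sep = detect_sep(expression_path),
                            row.names = 1, check.names = FALSE)
  X <- as.matrix(expr)
  if (genes_as_rows) X <- t(X)
  surv <- utils::read.table(survival_path, header = TRUE,
                            sep = detect_sep(survival_path),
                            check.names = FALSE,
                            colClasses = c("character", NA, NA))
  need <- c("sample_id", "time", "status")
  if (!all(need %in% names(surv)))
    stop_validation("survival table must have columns ",
                    paste(need, collapse = ", "))
  if (!is.numeric(surv$status))
    stop_validation("status column must be numeric 0/1; found '",
                    surv$status[1], "'")
  idx <- match(surv$sample_id, rownames(X))
  if (anyNA(idx))
    stop_validation("sample id not found in expression matrix: ",
                    surv$sample_id[which(is.na(idx))[1]])
  X <- X[idx, , drop = FALSE]
  survival_dataset(X, surv$time, surv$status,
                   sample_ids = surv$sample_id, gene_ids = colnames(X))
}

#' Write a dataset as delimited expression and survival tables
#'
#' Inverse of [read_dataset()]: round-tripping reproduces `X`, `time` and
#' `status` (times/values written at full precision).
#'
#' @param data a `survival_dataset`.
#' @param expression_path,survival_path output paths.
#' @param sep field separator, tab by default.
#' @export
write_dataset <- function(data, expression_path, survival_path, sep = "\t") {
  df <- data.frame(sample_id = data$sample_ids,
                   format(data$X, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  names(df) <- c("sample_id", data$gene_ids)
  utils::write.table(df, expression_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  sdf <- data.frame(sample_id = data$sample_ids,
                    time = format(data$time, digits = 17, trim = TRUE,
                                  scientific = TRUE),
                    status = data$status)
  utils::write.table(sdf, survival_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression_path, survival_path))
}

#' Standardize each gene to mean zero and unit sample standard deviation
#'
#' Zero-variance genes are uninformative for any penalized fit and are dropped
#' with a warning. Returns the transformed dataset and a record sufficient to
#' invert the transform (see [unstandardize()]) or to apply it to new data
#' (see [apply_standardization()]).
#'
#' @param data a `survival_dataset`.
#' @return list with elements `data` (standardized `survival_dataset`) and
#'   `record` (class `standardization_record`: per-gene `center`, `scale`,
#'   `gene_ids`).
#' @export
standardize <- function(data) {
  ctr <- colMeans(data$X)
  scl <- apply(data$X, 2, stats::sd)
  keep <- which(scl > 0)
  if (!length(keep)) stop_validation("all genes have zero variance")
  if (length(keep) < ncol(data$X)) {
    warning(sprintf("dropping %d zero-variance gene(s)",
                    ncol(data$X) - length(keep)))
  }
  Xs <- sweep(sweep(data$X[, keep, drop = FALSE], 2, ctr[keep]), 2,
              scl[keep], "/")
  rec <- structure(list(center = ctr[keep], scale = scl[keep],
                        gene_ids = data$gene_ids[keep]),
                   class = "standardization_record")
  list(data = survival_dataset(Xs, data$time, data$status,
                               sample_ids = data$sample_ids,
                               gene_ids = data$gene_ids[keep],
                               promoted = data$promoted),
       record = rec)
}

#' Apply a stored standardization to a new expression matrix
#' @param X matrix with the record's genes as (a superset of) its columns.
#' @param record a `standardization_record` from [standardize()].
#' @export
apply_standardization <- function(X, record) {
  X <- as.matrix(X)[, record$gene_ids, drop = FALSE]
  sweep(sweep(X, 2, record$center), 2, record$scale, "/")
}

#' Invert a standardization
#' @param data standardized `survival_dataset`.
#' @param record the matching `standardization_record`.
#' @export
unstandardize <- function(data, record) {
  X <- sweep(sweep(data$X, 2, record$scale, "*"), 2, record$center, "+")
  survival_dataset(X, data$time, data$status, sample_ids = data$sample_ids,
                   gene_ids = data$gene_ids, promoted = data$promoted)
}

#' Split a dataset into disjoint train and test parts
#'
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param data a `survival_dataset`.
#' @param n_train number of training samples, 0 < n_train < n.
#' @param seed integer seed.
#' @return list with `train` and `test` datasets.
#' @export
split_train_test <- function(data, n_train, seed) {
  n <- nrow(data$X)
  if (!(n_train > 0 && n_train < n))
    stop_validation("n_train must satisfy 0 < n_train < n = ", n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = data[idx, ], test = data[setdiff(seq_len(n), idx), ])
}
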