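#' Read a miRNA-disease association edge list
#'
#' Parses a delimited two-column edge list (miRNA name, disease name) into an
#' indexed binary association matrix. Rows of the matrix are miRNAs, columns
#' are diseases; this orientation is fixed throughout the package. Names are
#' trimmed and matched case-insensitively but stored as first seen; row and
#' column order is first appearance in the file. Duplicate edges collapse to a
#' single 1 (the number collapsed is recorded in the `n_duplicates` attribute).
#'
#' @param path Path to the edge-list file.
#' @param sep Field delimiter (default tab).
#' @param header Logical; if `TRUE` the first line is skipped.
#' @return An object of class `association_dataset`: a list with elements
#'   `mirna_names`, `disease_names` and the binary matrix `Y`
#'   (miRNA x disease), with attributes `n_edges` (unique edges) and
#'   `n_duplicates`.
#' @examples
#' f <- tempfile()
#' writeLines(c("mir-1\tlung neoplasms", "mir-1\tbreast neoplasms",
#'              "mir-2\tbreast neoplasms"), f)
#' d <- read_associations(f)
#' d$Y
#' @export
read_associations <- function(path, sep = "\t", header = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines_keep <- nzchar(trimws(lines))
  line_no <- which(lines_keep) + if (header) 1L else 0L
  lines <- lines[lines_keep]
  if (length(lines) == 0L) stop("empty association file: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed association row (need >= 2 fields) at line ", line_no[bad[1L]])
  }
  mir_raw <- trimws(vapply(parts, `[[`, "", 1L))
  dis_raw <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(mir_raw)) || any(!nzchar(dis_raw))) {
    stop("malformed association row (empty name) at line ",
         line_no[which(!nzchar(mir_raw) | !nzchar(dis_raw))[1L]])
  }
  association_dataset(mir_raw, dis_raw)
}

#' Construct an association dataset from paired name vectors
#'
#' @param mirna Character vector of miRNA names, one per known association.
#' @param disease Character vector of disease names, parallel to `mirna`.
#' @return An `association_dataset` (see [read_associations()]).
#' @export
association_dataset <- function(mirna, disease) {
  stopifnot(length(mirna) == length(disease))
  mir_key <- tolower(trimws(mirna))
  dis_key <- tolower(trimws(disease))
  mirna_names <- trimws(mirna)[!duplicated(mir_key)]
  disease_names <- trimws(disease)[!duplicated(dis_key)]
  i <- match(mir_key, tolower(mirna_names))
  j <- match(dis_key, tolower(disease_names))
  dup <- duplicated(cbind(i, j))
  Y <- matrix(0L, length(mirna_names), length(disease_names),
              dimnames = list(mirna_names, disease_names))
  Y[cbind(i[!dup], j[!dup])] <- 1L
  out <- list(mirna_names = mirna_names, disease_names = disease_names, Y = Y)
  attr(out, "n_edges") <- sum(!dup)
  attr(out, "n_duplicates") <- sum(dup)
  class(out) <- "association_dataset"
  out
}

#' @export
print.association_dataset <- function(x, ...) {
  cat("miRNA-disease association dataset\n")
  cat(sprintf("  %d miRNAs x %d diseases, %d known associations (density %.4f)\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y), mean(x$Y)))
  invisible(x)
}

#' Read a disease-to-MeSH-tree-number table
#'
#' Two delimited columns: disease name, MeSH tree number (e.g. `C04.588.945`).
#' A disease may appear on several rows (one per tree number); multiplicity is
#' preserved. Rows whose tree number does not match the MeSH pattern (a letter,
#' digits, then dot-separated 3-digit groups) are skipped with a warning; the
#' number skipped is stored in the `n_skipped` attribute.
#'
#' @param path Path to the table.
#' @param sep Field delimiter (default tab).
#' @param header Logical; skip the first line if `TRUE`.
#' @return A data frame of class `mesh_table` with columns `disease`,
#'   `tree_number`.
#' @export
read_mesh_table <- function(path, sep = "\t", header = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty MeSH table: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L)) {
    stop("malformed MeSH table row (need 2 fields) at line ",
         which(vapply(parts, length, 1L) < 2L)[1L])
  }
  disease <- trimws(vapply(parts, `[[`, "", 1L))
  tree <- trimws(vapply(parts, `[[`, "", 2L))
  ok <- grepl("^[A-Za-z][0-9]+(\\.[0-9]{3})*$", tree)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with malformed tree numbers skipped")
  }
  out <- data.frame(disease = disease[ok], tree_number = tree[ok],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no valid MeSH rows in ", path)
  attr(out, "n_skipped") <- sum(!ok)
  class(out) <- c("mesh_table", "data.frame")
  out
}

#' Read a labelled square similarity matrix
#'
#' Reads a delimited square numeric matrix whose header row and first column
#' carry matching entity labels (e.g. a precomputed miRNA functional-similarity
#' matrix). The matrix is symmetrized by averaging when the asymmetry exceeds
#' `1e-8`, and values are clipped to `[0, 1]`; the number of clipped entries is
#' stored in the `n_clipped` attribute.
#'
#' @param path Path to the matrix file.
#' @param sep Field delimiter (default tab).
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    stop("similarity matrix is not square: ", nrow(M), " x ", ncol(M))
  }
  if (!identical(trimws(rownames(M)), trimws(colnames(M)))) {
    stop("similarity matrix row/column labels do not match")
  }
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("similarity matrix contains missing values")
  M <- (M + t(M)) / 2
  n_clip <- sum(M < 0 | M > 1)
  M[M < 0] <- 0
  M[M > 1] <- 1
  attr(M, "n_clipped") <- n_clip
  M
}

#' Write a prediction score matrix as a long table
#'
#' Emits one row per (miRNA, disease) pair with columns `mirna`, `disease`,
#' `score`, `known`, sorted by descending score within each disease (ties
#' broken by miRNA index, i.e. row order of the dataset).
#'
#' @param Ystar Numeric score matrix, same shape as `dataset$Y`.
#' @param dataset An `association_dataset` supplying names and known flags.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return Invisibly, the data frame written.
#' @export
write_predictions <- function(Ystar, dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "association_dataset"),
            all(dim(Ystar) == dim(dataset$Y)))
  n_m <- nrow(Ystar); n_d <- ncol(Ystar)
  rows <- lapply(seq_len(n_d), function(j) {
    ord <- order(-Ystar[, j], seq_len(n_m))
    data.frame(mirna = dataset$mirna_names[ord],
               disease = dataset$disease_names[j],
               score = Ystar[ord, j],
               known = dataset$Y[ord, j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read back a prediction table written by [write_predictions()]
#'
#' @param path Path to the predictions file.
#' @param sep Field delimiter.
#' @return A data frame with columns `mirna`, `disease`, `score`, `known`.
#' @export
read_predictions <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
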