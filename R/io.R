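# On-disk formats: triplet TSV (with a metadata comment line), NIfTI label
# volumes and tensors via RNifti, ROI-to-subnetwork maps and connectivity
# matrices as TSV.

#' Read and write coordinate triplet files
#'
#' Triplet files are TSV with header columns `i`, `j`, `value` (optionally
#' `dvalue`) preceded by a metadata comment line
#' `# origin=<0|1> n_rows=<d1> n_cols=<d2>`.  Indices are converted to the
#' internal 1-based convention on read and coordinates are re-normalized
#' from the declared extents.
#'
#' @param dataset a `triplet_dataset`.
#' @param path file path.
#' @return `write_triplets()` returns `path` invisibly; `read_triplets()`
#'   returns a `triplet_dataset`.
#' @export
write_triplets <- function(dataset, path) {
  stopifnot(inherits(dataset, "triplet_dataset"))
  rec <- dataset$records
  out <- data.frame(i = rec$i, j = rec$j, value = rec$y)
  if (!is.null(rec$dy)) out$dvalue <- rec$dy
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin=1 n_rows=%d n_cols=%d",
                     dataset$n_rows, dataset$n_cols), con)
  write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(origin = 1L, n_rows = NA_integer_, n_cols = NA_integer_)
  if (startsWith(first, "#")) {
    for (kv in strsplit(sub("^#\\s*", "", first), "\\s+")[[1]]) {
      parts <- strsplit(kv, "=")[[1]]
      if (length(parts) == 2L) meta[[parts[1]]] <- as.integer(parts[2])
    }
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("i", "j", "value")
  if (!all(need %in% names(df))) {
    stop("triplet file must have columns i, j, value", call. = FALSE)
  }
  i <- df$i + (1L - meta$origin)
  j <- df$j + (1L - meta$origin)
  nr <- if (is.na(meta$n_rows)) max(i) else meta$n_rows
  nc <- if (is.na(meta$n_cols)) max(j) else meta$n_cols
  if (anyDuplicated(cbind(i, j))) stop("duplicate (i, j) pairs", call. = FALSE)
  if (any(i < 1L | i > nr | j < 1L | j > nc)) {
    stop("indices outside the declared extents", call. = FALSE)
  }
  rec <- data.frame(i = i, j = j,
                    X1 = .normalize_index(i, nr), X2 = .normalize_index(j, nc),
                    y = df$value)
  has_dy <- "dvalue" %in% names(df)
  if (has_dy) rec$dy <- df$dvalue
  structure(list(records = rec, n_rows = nr, n_cols = nc,
                 has_derivative = has_dy),
            class = "triplet_dataset")
}

#' Read and write parcellations
#'
#' The label volume travels as an integer NIfTI image and the
#' ROI-to-subnetwork map as a TSV with columns `roi_id`, `roi_name`,
#' `subnetwork`.
#'
#' @param parcellation a `parcellation`.
#' @param labels_path NIfTI path for the label volume.
#' @param map_path TSV path for the subnetwork map.
#' @return `write_parcellation()` returns the paths invisibly;
#'   `read_parcellation()` returns a `parcellation`.
#' @export
write_parcellation <- function(parcellation, labels_path, map_path) {
  stopifnot(inherits(parcellation, "parcellation"))
  RNifti::writeNifti(parcellation$labels, labels_path)
  write.table(parcellation$map, map_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(labels = labels_path, map = map_path))
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(labels_path, map_path) {
  img <- RNifti::readNifti(labels_path)
  labels <- array(as.integer(round(img)), dim(img))
  map <- read.table(map_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("roi_id", "roi_name", "subnetwork")
  if (!all(need %in% names(map))) {
    stop("map file must have columns roi_id, roi_name, subnetwork", call. = FALSE)
  }
  R <- max(map$roi_id)
  present <- sort(unique(labels[labels > 0L]))
  if (any(!present %in% map$roi_id)) {
    stop("label volume contains ROI ids missing from the map", call. = FALSE)
  }
  structure(list(labels = labels, map = map[order(map$roi_id), ],
                 n_rois = R), class = "parcellation")
}

#' Write / read a 4D tensor as NIfTI
#' @param tensor a 3- or 4-way array.
#' @param path NIfTI file path.
#' @return The path (write) or an array (read).
#' @export
write_tensor_nifti <- function(tensor, path) {
  RNifti::writeNifti(tensor, path)
  invisible(path)
}

#' @rdname write_tensor_nifti
#' @export
read_tensor_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write / read a connectivity matrix as TSV
#'
#' Plain numeric TSV; the bin count used is recorded in a leading comment.
#'
#' @param matrix a `connectivity_matrix`.
#' @param path file path.
#' @return The path (write) or a `connectivity_matrix` (read).
#' @export
write_connectivity <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bins=%d", attr(matrix, "bins") %||% NA_integer_), con)
  write.table(unclass(matrix), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  first <- readLines(path, n = 1L)
  bins <- if (grepl("bins=", first)) {
    as.integer(sub(".*bins=(\\d+).*", "\\1", first))
  } else {
    NA_integer_
  }
  M <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  dimnames(M) <- NULL
  attr(M, "bins") <- bins
  class(M) <- c("connectivity_matrix", class(M))
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
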