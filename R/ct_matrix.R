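#' Construct a Ct matrix object
#'
#' The entry object of the qPCR pipeline: a samples-by-miRNAs matrix of raw
#' cycle-threshold (Ct) values, a plate label per sample, and an optional
#' per-observation amplification-validity flag (modelling the quality score /
#' exponential-curve check applied to each qPCR reaction). Non-detects are
#' stored as `NA`; the missingness mask is `is.na(values)`.
#'
#' @param values numeric matrix, samples x miRNAs, with `NA` for non-detects.
#'   Row names are sample ids, column names miRNA ids.
#' @param plate character or factor of plate labels, one per sample.
#' @param valid optional logical matrix, same dimensions as `values`; `FALSE`
#'   marks observations whose amplification curve failed QC.
#' @param provenance character vector of processing steps already applied
#'   (maintained by the pipeline functions).
#' @return An object of class `ct_matrix`.
#' @examples
#' ct <- ct_matrix(matrix(c(20, 21, NA, 23), 2,
#'                        dimnames = list(c("s1", "s2"), c("mA", "mB"))),
#'                 plate = c("P1", "P1"))
#' ct
#' @export
ct_matrix <- function(values, plate, valid = NULL, provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x miRNAs)", call. = FALSE)
  }
  if (is.null(rownames(values)) && nrow(values) > 0) {
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    colnames(values) <- paste0("mir", seq_len(ncol(values)))
  }
  plate <- as.character(plate)
  if (length(plate) != nrow(values)) {
    stop("`plate` must have one label per sample", call. = FALSE)
  }
  if (any(is.na(plate) | !nzchar(plate))) {
    stop("plate labels must be non-empty", call. = FALSE)
  }
  if (!is.null(valid)) {
    if (!is.logical(valid) || !identical(dim(valid), dim(values))) {
      stop("`valid` must be a logical matrix with the dimensions of `values`",
           call. = FALSE)
    }
    dimnames(valid) <- dimnames(values)
  }
  structure(
    list(values = values, plate = plate, valid = valid,
         provenance = provenance),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  nd <- mean(is.na(x$values))
  cat(sprintf("ct_matrix: %d samples x %d miRNAs, %d plates, %.1f%% non-detect\n",
              nrow(x$values), ncol(x$values), length(unique(x$plate)),
              100 * nd))
  if (length(x$provenance)) {
    cat("processing: ", paste(x$provenance, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' Missingness mask of a Ct matrix
#' @param ct a [ct_matrix].
#' @return Logical matrix, `TRUE` where the Ct value is a non-detect.
#' @export
missing_mask <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  is.na(ct$values)
}

#' Write / read the wide Ct exchange format
#'
#' Wide tab-separated table: first column `sample_id`, then one column per
#' miRNA; an empty cell encodes a non-detect. Plate labels travel in the
#' sample metadata table, so `read_ct_table` needs the metadata (or an
#' explicit plate vector) to rebuild the object.
#'
#' @param ct a [ct_matrix].
#' @param path file path.
#' @return `write_ct_table` returns `path` invisibly; `read_ct_table` returns
#'   a [ct_matrix].
#' @export
write_ct_table <- function(ct, path) {
  stopifnot(inherits(ct, "ct_matrix"))
  df <- data.frame(sample_id = rownames(ct$values), ct$values,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_ct_table
#' @param plate plate labels, one per sample (or a metadata data frame with
#'   `sample_id` and `plate` columns).
#' @export
read_ct_table <- function(path, plate) {
  df <- read_tsv(path)
  values <- as.matrix(df[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- df$sample_id
  if (is.data.frame(plate)) {
    plate <- plate$plate[match(df$sample_id, plate$sample_id)]
  }
  ct_matrix(values, plate)
}

# replace the value matrix, keeping bookkeeping consistent and appending a
# provenance step
update_ct <- function(ct, values = ct$values, plate = ct$plate,
                      valid = ct$valid, step = NULL) {
  out <- ct_matrix(values, plate, valid,
                   provenance = c(ct$provenance, step))
  out
}
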