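#' Construct a count matrix object
#'
#' Container for a genes x samples matrix of non-negative integer read
#' counts, together with per-sample library sizes and scale-normalization
#' factors. Library sizes default to column sums of the counts and are
#' frozen at construction: subsequent gene filtering does not change them,
#' because the sequencing depth of a library is a property of the sample,
#' not of the genes retained for analysis.
#'
#' @param counts numeric matrix of non-negative integer-valued counts with
#'   gene IDs as rownames and sample names as colnames (assigned
#'   automatically when absent).
#' @param lib_sizes optional positive numeric vector of library sizes
#'   (total mapped reads per sample); defaults to `colSums(counts)`.
#' @param norm_factors optional positive numeric vector of scale
#'   normalization factors; defaults to 1 for every sample. The effective
#'   library size of sample i is `lib_sizes[i] * norm_factors[i]`.
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts`, `lib_sizes`, `norm_factors`.
#' @examples
#' cm <- count_matrix(matrix(c(1, 3, 2, 4), 2, 2))
#' cm$lib_sizes
#' @export
count_matrix <- function(counts, lib_sizes = NULL, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts) | !is.finite(counts))
  if (length(bad)) {
    g <- ((bad[1] - 1L) %% nrow(counts)) + 1L
    i <- ((bad[1] - 1L) %/% nrow(counts)) + 1L
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: row %d ('%s'), column %d ('%s'), value %s",
      g, rownames(counts)[g] %||% g, i, colnames(counts)[i] %||% i,
      format(counts[g, i])
    ))
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  n <- ncol(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lib_sizes) != n || any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
    stop("lib_sizes must be ", n, " positive finite values")
  if (is.null(norm_factors)) norm_factors <- rep(1, n)
  norm_factors <- as.numeric(norm_factors)
  if (length(norm_factors) != n || any(!is.finite(norm_factors)) || any(norm_factors <= 0))
    stop("norm_factors must be ", n, " positive finite values")
  names(lib_sizes) <- names(norm_factors) <- colnames(counts)
  structure(
    list(counts = counts, lib_sizes = lib_sizes, norm_factors = norm_factors),
    class = "count_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat("library sizes: ", paste(format(x$lib_sizes, big.mark = ","), collapse = ", "), "\n")
  if (any(x$norm_factors != 1))
    cat("norm factors:  ", paste(format(round(x$norm_factors, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' Effective library sizes
#'
#' Library sizes multiplied by the scale normalization factors.
#' @param cm a [count_matrix()].
#' @return numeric vector of effective library sizes.
#' @export
effective_lib_sizes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  cm$lib_sizes * cm$norm_factors
}

#' Read a count matrix from disk
#'
#' Reads either a tab-delimited table (header row of sample names, first
#' column of gene IDs) or a MatrixMarket `.mtx` file accompanied by sidecar
#' row and column label files (`<path>.rownames` / `<path>.colnames`, one
#' label per line).
#'
#' @param path path to the counts file.
#' @param format `"tsv"` or `"mtx"`.
#' @return A [count_matrix()] with `lib_sizes` set to column sums.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             row.names = NULL, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L || ncol(tab) < 2L)
      stop("empty or malformed count table: ", path)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("the Matrix package is required to read .mtx files")
    m <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames")
    cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn))
      stop("mtx input requires sidecar files ", rn, " and ", cn)
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
    if (length(rownames(m)) != nrow(m) || length(colnames(m)) != ncol(m))
      stop("sidecar label length does not match matrix dimensions")
  }
  count_matrix(m)
}

#' Filter genes by total read count
#'
#' Keeps genes whose total count across all samples is at least
#' `min_total`. The conventional preprocessing step for the simulation
#' benchmark removes genes with fewer than ten reads in total, i.e.
#' `min_total = 10`. Library sizes are not recomputed.
#'
#' @param cm a [count_matrix()].
#' @param min_total minimum row sum (inclusive) for a gene to be retained.
#' @return the filtered [count_matrix()].
#' @export
filter_by_total <- function(cm, min_total = 10) {
  stopifnot(inherits(cm, "count_matrix"), min_total >= 1)
  keep <- rowSums(cm$counts) >= min_total
  if (!any(keep))
    stop("all genes removed; reduce min_total (currently ", min_total, ")")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$lib_sizes, cm$norm_factors)
}

#' Filter genes by counts-per-million
#'
#' Keeps genes achieving a cpm of at least `cpm_threshold` in at least
#' `min_samples` samples. cpm is computed from the raw counts as
#' `r / R * 1e6` with no offset: the 0.5 count offset belongs to the log
#' transform, not to filtering.
#'
#' @param cm a [count_matrix()].
#' @param cpm_threshold cpm cutoff (typically 1).
#' @param min_samples number of samples that must reach the cutoff.
#' @return the filtered [count_matrix()].
#' @export
filter_by_cpm <- function(cm, cpm_threshold = 1, min_samples = 1) {
  stopifnot(inherits(cm, "count_matrix"),
            cpm_threshold >= 0, min_samples >= 1,
            min_samples <= ncol(cm$counts))
  cpm <- sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
  keep <- rowSums(cpm >= cpm_threshold) >= min_samples
  if (!any(keep))
    stop("all genes removed; reduce cpm_threshold or min_samples")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$lib_sizes, cm$norm_factors)
}

#' Write library sizes and normalization factors as a two-column table
#'
#' @param cm a [count_matrix()].
#' @param path output path; a tab-delimited file with columns `sample`,
#'   `lib_size`, `norm_factor`, `effective_lib_size`.
#' @return invisibly, the data frame written.
#' @export
write_lib_sizes <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  d <- data.frame(sample = colnames(cm$counts),
                  lib_size = cm$lib_sizes,
                  norm_factor = cm$norm_factors,
                  effective_lib_size = effective_lib_sizes(cm))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
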