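# Transcript-by-lane count container and its TSV serialisation.

#' Transcript-by-lane count matrix
#'
#' Lightweight container for an RNA-Seq count table: an integer matrix with
#' transcripts as rows and sequencing lanes (samples) as columns, plus an
#' optional per-lane condition assignment for two-group comparisons.
#'
#' @param counts Numeric matrix of non-negative integer counts. Row names are
#'   transcript ids, column names lane ids; defaults are generated when
#'   missing.
#' @param condition Optional per-lane labels, values `"control"` /
#'   `"treatment"`.
#' @return An object of class `"count_matrix"` with elements `counts`
#'   (matrix) and `condition` (factor or `NULL`).
#' @export
#' @examples
#' cm <- count_matrix(matrix(0:5, 3, 2))
#' dim(cm)
count_matrix <- function(counts, condition = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (length(counts) == 0L) stop_input("`counts` must be a non-empty matrix")
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop_input("`counts` contains missing or non-finite values")
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop_input("`counts` must contain non-negative integers")
  }
  counts <- round(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("tx%06d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("lane%03d", seq_len(ncol(counts)))
  }
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != ncol(counts)) {
      stop_input("`condition` must have one entry per lane")
    }
    if (!all(condition %in% c("control", "treatment"))) {
      stop_input("`condition` values must be 'control' or 'treatment'")
    }
    condition <- factor(condition, levels = c("control", "treatment"))
  }
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d transcripts x %d lanes\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$condition)) {
    tb <- table(x$condition)
    cat(sprintf("  condition: %s\n",
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  cat(sprintf("  lane totals: %s%s\n",
              paste(format(head(colSums(x$counts), 6), trim = TRUE),
                    collapse = ", "),
              if (ncol(x$counts) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  counts <- x$counts[i, j, drop = FALSE]
  condition <- x$condition
  if (!is.null(condition) && !missing(j)) condition <- condition[j]
  count_matrix(counts, condition = as.character(condition))
}

lane_totals <- function(x) colSums(x$counts)

as_count_matrix <- function(counts, condition = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (!is.null(condition)) {
      return(count_matrix(counts$counts, condition = condition))
    }
    return(counts)
  }
  count_matrix(counts, condition = condition)
}

# split by condition, erroring when two groups are required but absent
require_two_conditions <- function(x) {
  if (is.null(x$condition) || nlevels(x$condition) != 2L ||
      !all(c("control", "treatment") %in% as.character(unique(x$condition)))) {
    stop_input("a two-condition (control/treatment) assignment is required")
  }
  invisible(x)
}

#' Read / write count matrices as TSV
#'
#' The on-disk format is a tab-separated table whose first column
#' (`transcript_id`) holds transcript ids and whose remaining columns are
#' lanes; an optional two-column TSV (`lane_id`, `condition`) carries the
#' condition map.
#'
#' @param path Path to the counts TSV.
#' @param condition_path Optional path to the condition-map TSV.
#' @return For `read_count_matrix`, a [count_matrix()]; `write_count_matrix`
#'   invisibly returns `path`.
#' @export
read_count_matrix <- function(path, condition_path = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_input("counts TSV needs transcript_id plus >= 1 lane")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  condition <- NULL
  if (!is.null(condition_path)) {
    cmap <- read.delim(condition_path, stringsAsFactors = FALSE)
    idx <- match(colnames(counts), as.character(cmap[[1]]))
    if (anyNA(idx)) stop_input("condition map is missing some lane ids")
    condition <- as.character(cmap[[2]])[idx]
  }
  count_matrix(counts, condition = condition)
}

#' @param x A [count_matrix()].
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(x, path, condition_path = NULL) {
  x <- as_count_matrix(x)
  tab <- data.frame(transcript_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(condition_path)) {
    if (is.null(x$condition)) {
      stop_input("no condition assignment to write")
    }
    cmap <- data.frame(lane_id = colnames(x$counts),
                       condition = as.character(x$condition),
                       stringsAsFactors = FALSE)
    write.table(cmap, condition_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
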