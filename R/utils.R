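#' @keywords internal
"_PACKAGE"

# Classical module colour vocabulary, ordered by module size rank.
# "grey" is reserved for unassigned genes and never appears here.
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
  "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
  "brown4", "bisque4", "darkslateblue", "plum2", "thistle2"
)

#' Map module size ranks to colour labels
#'
#' @param n number of modules (size rank 1 = largest)
#' @return character vector of n unique labels
#' @keywords internal
module_color_labels <- function(n) {
  if (n <= length(.module_colors)) return(.module_colors[seq_len(n)])
  c(.module_colors, paste0("module", seq.int(length(.module_colors) + 1L, n)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    .stopf("%s must be a numeric matrix", what)
  if (any(!is.finite(x)))
    .stopf("%s contains non-finite values", what)
  invisible(x)
}

# symmetrize and clamp a square matrix into [lo, hi]
.symmetrize <- function(x, lo = -Inf, hi = Inf) {
  x <- (x + t(x)) / 2
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used for planted-module recovery checks. Labels may be any atomic type;
#' unassigned ("grey"/0) is treated as an ordinary cluster.
#'
#' @param a,b vectors of equal length with cluster labels
#' @return numeric scalar in [-1, 1]; 1 means identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) .stopf("partitions differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Read a TSV file with check.names disabled
#' @param path file path
#' @param row_names logical or column index passed to row.names
#' @return data.frame
#' @keywords internal
read_tsv_file <- function(path, row_names = NULL) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = row_names,
                    comment.char = "", quote = "")
}

#' Write a data.frame or matrix as TSV
#' @param x object to write
#' @param path file path
#' @param row_label if non-NULL, row names are written as a first column
#'   with this header
#' @keywords internal
write_tsv_file <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- data.frame(setNames(list(rownames(x)), row_label),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
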