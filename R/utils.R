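# shared small utilities

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @examples
#' revcomp("ACGTT")  # "AACGT"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  up <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# row-wise log-sum-exp of a matrix
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Hamming distance between binary genotype vectors
#'
#' Number of positions at which two 0/1 vectors differ.
#'
#' @param a,b binary vectors of equal length.
#' @return non-negative integer.
#' @export
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a != b)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same
#' items; 1 for identical partitions (up to relabeling), about 0 for random
#' agreement.
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(NaN)
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

# validate a DNA alphabet, returning TRUE or a message
is_dna <- function(x) {
  grepl("^[ACGT]*$", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
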