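# independent oracles used across tests

# naive per-read exact-substring scan via Biostrings (independent of the
# implementation's base-R fixed-pattern matching)
oracle_count_junction <- function(reads, junction, both_strands = TRUE) {
  if (length(reads) == 0L) return(0L)
  ss <- Biostrings::DNAStringSet(reads)
  hit <- Biostrings::vcountPattern(junction, ss, fixed = TRUE) > 0
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(junction)))
    hit <- hit | Biostrings::vcountPattern(rc, ss, fixed = TRUE) > 0
  }
  sum(hit)
}

# random read sets with a known number of junction-bearing reads
random_reads <- function(n_with, n_without, junction, read_len = 120L) {
  emb <- vapply(seq_len(n_with), function(i) {
    off <- sample.int(read_len - nchar(junction) + 1L, 1L) - 1L
    paste0(rand_seq(off), junction,
           rand_seq(read_len - nchar(junction) - off))
  }, character(1))
  bg <- vapply(seq_len(n_without), function(i) rand_seq(read_len),
               character(1))
  # make sure background really is junction-free on both strands
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(junction)))
  bad <- grepl(junction, bg, fixed = TRUE) | grepl(rc, bg, fixed = TRUE)
  while (any(bad)) {
    bg[bad] <- vapply(seq_len(sum(bad)), function(i) rand_seq(read_len),
                      character(1))
    bad <- grepl(junction, bg, fixed = TRUE) | grepl(rc, bg, fixed = TRUE)
  }
  sample(c(emb, bg))
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# best hard-partition EM objective over all 2-colorings: parameters are the
# partition's smoothed estimates, scored on the same objective EM maximizes
# (mixture log-likelihood plus the Beta(a+1, b+1) log-prior kernel)
brute_best_objective_k2 <- function(X, a = 0.5, b = 0.5) {
  n <- nrow(X)
  best <- -Inf
  for (code in 0:(2^n - 1)) {
    z <- as.integer(intToBits(code))[seq_len(n)] + 1L
    n1 <- sum(z == 1L); n2 <- n - n1
    pi_k <- c(n1, n2) / n
    theta <- rbind(
      (colSums(X[z == 1L, , drop = FALSE]) + a) / (n1 + a + b),
      (colSums(X[z == 2L, , drop = FALSE]) + a) / (n2 + a + b))
    L <- X %*% t(log(theta)) + (1 - X) %*% t(log1p(-theta))
    L <- sweep(L, 2L, log(pmax(pi_k, 1e-300)), `+`)
    mx <- apply(L, 1L, max)
    obj <- sum(mx + log(rowSums(exp(L - mx)))) +
      sum(a * log(theta) + b * log1p(-theta))
    best <- max(best, obj)
  }
  best
}

# exhaustive minimum spanning-tree weight over all (n-1)-edge subsets
enum_min_spanning_weight <- function(G, distance = "hamming") {
  m <- nrow(G)
  pairs <- combn(m, 2L)
  w <- vapply(seq_len(ncol(pairs)), function(p) {
    a <- G[pairs[1, p], ]; bb <- G[pairs[2, p], ]
    if (distance == "hamming") sum(a != bb) else {
      u <- sum(a == 1 | bb == 1)
      if (u == 0) 0 else 1 - sum(a == 1 & bb == 1) / u
    }
  }, numeric(1))
  best <- Inf
  for (sel in combn(ncol(pairs), m - 1L, simplify = FALSE)) {
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    spanning <- TRUE
    for (e in sel) {
      ra <- find(pairs[1, e]); rb <- find(pairs[2, e])
      if (ra == rb) { spanning <- FALSE; break }
      parent[ra] <- rb
    }
    if (spanning) best <- min(best, sum(w[sel]))
  }
  best
}

# two-block binary matrix with optional bit flips
block_matrix <- function(n_per_block = 10L, J = 12L, noise = 0) {
  pat <- rbind(rep(c(1L, 0L), c(J %/% 2, J - J %/% 2)),
               rep(c(0L, 1L), c(J %/% 2, J - J %/% 2)))
  X <- pat[rep(1:2, each = n_per_block), ]
  if (noise > 0) {
    flip <- matrix(runif(length(X)) < noise, nrow(X), ncol(X))
    X[flip] <- 1L - X[flip]
  }
  rownames(X) <- sprintf("cell_%02d", seq_len(nrow(X)))
  colnames(X) <- sprintf("assay_%02d", seq_len(ncol(X)))
  X
}
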