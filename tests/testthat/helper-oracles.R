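# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take different algorithmic routes from the package.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Longest common substring by the classic dynamic program over the
# character-match matrix (row-vectorised); returns length and one witness.
lcs_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  prev <- integer(nb)
  best_len <- 0L; best_end_a <- 0L
  for (i in seq_len(na)) {
    cur <- ifelse(cb == ca[i], c(0L, prev[-nb]) + 1L, 0L)
    m <- max(cur)
    if (m > best_len) {
      best_len <- m
      best_end_a <- i
    }
    prev <- cur
  }
  list(length = best_len,
       substring = if (best_len > 0)
         substr(a, best_end_a - best_len + 1, best_end_a) else "")
}

# Exhaustive crossover search: every k for which attR-prefix + attL-suffix
# reproduces attP.
crossover_oracle <- function(attL, attR, attP) {
  n <- nchar(attL)
  which(vapply(0:n, function(k) {
    paste0(substr(attR, 1, k), substr(attL, k + 1, n)) == attP
  }, logical(1))) - 1L
}

# Sort-based median (no stats::median).
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# Naive per-split scan for the two-segment step fit: returns the split
# minimising total squared error, computing each SSE from scratch.
stepfit_oracle <- function(x) {
  n <- length(x)
  sse <- vapply(1:(n - 1), function(s) {
    left <- x[1:s]; right <- x[(s + 1):n]
    sum((left - mean(left))^2) + sum((right - mean(right))^2)
  }, numeric(1))
  which.min(sse)
}

# Exact Jaccard index of canonical k-mer sets, computed with plain R
# string handling (independent of the C++ hashing).
jaccard_oracle <- function(a, b, k) {
  canon_set <- function(s) {
    kmers <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rcs <- vapply(kmers, prophagekit::revcomp, "", USE.NAMES = FALSE)
    unique(pmin(kmers, rcs))
  }
  sa <- canon_set(a); sb <- canon_set(b)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# Textbook agglomerative clustering with average linkage, recomputing the
# inter-cluster mean distance from the original matrix at every merge.
# Returns merge heights in order, for comparison with hclust()$height.
average_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Point mutations at a fixed per-base rate, never mutating to the same base.
mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}
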