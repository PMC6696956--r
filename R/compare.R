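#' MinHash bottom sketch of a DNA sequence
#'
#' Hashes every distinct canonical k-mer (lexicographic minimum of the
#' k-mer and its reverse complement) with a fixed 64-bit
#' FNV-1a/splitmix64 hash and keeps the `s` smallest values. Identical
#' parameters give identical sketches across runs and platforms.
#'
#' @param sequence a [genome_record()] or DNA string, length >= k.
#' @param k k-mer length (default 21).
#' @param s sketch size (default 1000).
#' @return An object of class `mash_sketch`: `k`, `s`, `hashes` (sorted
#'   ascending, `min(s, n_kmers)` of them) and `n_kmers` (distinct
#'   canonical k-mers in the sequence).
#' @export
sketch <- function(sequence, k = 21L, s = 1000L) {
  seq <- if (inherits(sequence, "genome_record")) sequence$sequence else
    sequence
  assert_dna_string(seq, "sequence")
  if (nchar(seq) < k) stop2("sequence shorter than k (", k, ")")
  assert_scalar_number(s, "s", min = 1)
  hashes <- sort(.canonical_kmer_hashes(seq, as.integer(k)))
  structure(list(k = as.integer(k), s = as.integer(s),
                 hashes = utils::head(hashes, s),
                 n_kmers = length(hashes)),
            class = "mash_sketch")
}

#' @export
print.mash_sketch <- function(x, ...) {
  cat(sprintf("<mash_sketch> k=%d s=%d: %d hashes of %d distinct k-mers\n",
              x$k, x$s, length(x$hashes), x$n_kmers))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated from the bottom-s sketch of the merged
#' hash union (the fraction of those hashes present in both sketches) and
#' converted to a mutation-rate distance
#' `d = -ln(2j / (1 + j)) / k`, capped to `[0, 1]`; `j = 0` gives
#' `d = 1`.
#'
#' @param sketch_a,sketch_b [sketch()] objects with equal `k`.
#' @return Distance d in `[0, 1]`, with the Jaccard estimate attached as
#'   attribute `jaccard`.
#' @export
mash_distance <- function(sketch_a, sketch_b) {
  stopifnot(inherits(sketch_a, "mash_sketch"),
            inherits(sketch_b, "mash_sketch"))
  if (sketch_a$k != sketch_b$k) {
    stop2("k mismatch: ", sketch_a$k, " vs ", sketch_b$k)
  }
  s_use <- min(length(sketch_a$hashes), length(sketch_b$hashes),
               sketch_a$s, sketch_b$s)
  merged <- utils::head(sort(unique(c(sketch_a$hashes, sketch_b$hashes))),
                        s_use)
  shared <- sum(merged %in% sketch_a$hashes & merged %in% sketch_b$hashes)
  j <- shared / s_use
  d <- if (j <= 0) 1 else min(1, max(0, -log(2 * j / (1 + j)) / sketch_a$k))
  structure(d, jaccard = j)
}

#' Mash similarity and hit calling
#'
#' Similarity is defined as `100 * (1 - d)` percent; a sequence is a hit
#' when its similarity reaches the threshold (inclusive; default 70%).
#'
#' @param d Mash distance in `[0, 1]`.
#' @return `similarity_percent`: similarity in percent.
#' @export
similarity_percent <- function(d) {
  100 * (1 - as.numeric(d))
}

#' @rdname similarity_percent
#' @param similarity similarity in percent.
#' @param threshold hit threshold in percent (default 70).
#' @return `is_hit`: logical.
#' @export
is_hit <- function(similarity, threshold = 70) {
  as.numeric(similarity) >= threshold
}

#' Pairwise Mash distance matrix
#'
#' @param sequences named list of [genome_record()]s or DNA strings.
#' @param k,s sketch parameters (see [sketch()]).
#' @return A symmetric labelled distance matrix with zero diagonal.
#' @export
mash_distance_matrix <- function(sequences, k = 21L, s = 1000L) {
  labels <- names(sequences) %||%
    vapply(sequences, function(x)
      if (inherits(x, "genome_record")) x$id else NA_character_, "")
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop2("sequences must be named (list names or record ids)")
  }
  sk <- lapply(sequences, sketch, k = k, s = s)
  n <- length(sk)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- as.numeric(mash_distance(sk[[i]], sk[[j]]))
    }
  }
  m
}

#' Fragment-based average nucleotide identity
#'
#' Chops sequence `a` into consecutive non-overlapping fragments of
#' `fragment_len` bp (a trailing partial fragment is dropped) and aligns
#' each locally against `b` on both strands (match +1, mismatch -1, gap
#' open -5, gap extend -2). Fragments whose best alignment reaches both
#' the identity and the coverage filter contribute their identity; ANI is
#' the mean passing identity in percent. When no fragment passes, the ANI
#' is undefined (`NA`).
#'
#' @param seq_a,seq_b [genome_record()]s or DNA strings, each at least
#'   `fragment_len` long.
#' @param fragment_len fragment length in bp (default 1020).
#' @param min_identity per-fragment identity filter in `[0, 1]` (default
#'   0.7).
#' @param min_coverage fraction of the fragment that must align (default
#'   0.7).
#' @return ANI in percent, or `NA` if undefined; the number of passing
#'   fragments is attached as attribute `n_fragments`.
#' @export
ani <- function(seq_a, seq_b, fragment_len = 1020L, min_identity = 0.7,
                min_coverage = 0.7) {
  a <- if (inherits(seq_a, "genome_record")) seq_a$sequence else seq_a
  b <- if (inherits(seq_b, "genome_record")) seq_b$sequence else seq_b
  assert_dna_string(a, "seq_a"); assert_dna_string(b, "seq_b")
  if (nchar(a) < fragment_len || nchar(b) < fragment_len) {
    stop2("sequences must be at least fragment_len (", fragment_len, ") bp")
  }
  n_frag <- nchar(a) %/% fragment_len
  starts <- (seq_len(n_frag) - 1) * fragment_len + 1
  subjects <- list(Biostrings::DNAString(b),
                   Biostrings::reverseComplement(Biostrings::DNAString(b)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  idents <- vapply(starts, function(st) {
    frag <- substr(a, st, st + fragment_len - 1)
    best <- NULL
    for (subj in subjects) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(frag), subj, type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) {
        best <- aln
      }
    }
    width <- Biostrings::nchar(best)              # alignment length
    identity <- Biostrings::nmatch(best) / width
    coverage <- width / fragment_len
    if (identity >= min_identity && coverage >= min_coverage) identity
    else NA_real_
  }, numeric(1))
  passing <- idents[!is.na(idents)]
  if (length(passing) == 0L) {
    return(structure(NA_real_, n_fragments = 0L))
  }
  structure(100 * mean(passing), n_fragments = length(passing))
}

#' Species assignment from an ANI value
#'
#' Two phages with an ANI below the threshold (default 85%) are, by
#' current standards, different species; an undefined ANI (no alignable
#' fragment) is classified as different with attribute
#' `undefined = TRUE`.
#'
#' @param ani_value ANI in percent, or `NA`.
#' @param threshold species threshold in percent (default 85).
#' @return `"same"` or `"different"`.
#' @export
classify_species <- function(ani_value, threshold = 85) {
  if (is.na(ani_value)) {
    return(structure("different", undefined = TRUE))
  }
  if (as.numeric(ani_value) < threshold) "different" else "same"
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (average linkage by default) of a symmetric
#' zero-diagonal distance matrix, as used to group related prophages.
#'
#' @param matrix symmetric distance matrix with labels and zero diagonal.
#' @param method linkage, passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An [stats::hclust()] dendrogram.
#' @export
cluster_phages <- function(matrix, method = "average") {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop2("need a square matrix")
  }
  if (max(abs(matrix - t(matrix))) > 1e-9) stop2("matrix is not symmetric")
  if (max(abs(diag(matrix))) > 1e-9) stop2("diagonal must be zero")
  stats::hclust(stats::as.dist(matrix), method = method)
}
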