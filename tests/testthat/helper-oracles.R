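# Independent reference implementations used as oracles. They share the
# package's stated conventions (match +1 / mismatch 0 / gap -1, traceback
# preference diagonal > up > left) but are written as plain-R dynamic
# programming, separate from the compiled path they check.

oracle_align <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  S <- matrix(0L, la + 1, lb + 1)
  S[, 1] <- -(0:la)
  S[1, ] <- -(0:lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + (ca[i] == cb[j]),
        S[i, j + 1] - 1L,
        S[i + 1, j] - 1L
      )
    }
  }
  i <- la; j <- lb; matches <- 0L; pairs <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (ca[i] == cb[j])) {
      matches <- matches + (ca[i] == cb[j])
      pairs <- pairs + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(matches = matches, pairs = pairs, columns = la + lb - pairs,
       score = S[la + 1, lb + 1])
}

# Brute-force greedy clustering: compute the full pairwise identity and
# coverage matrix up front, then apply the same greedy rule (longest
# first, lexicographic id tie-break, first qualifying centroid wins).
oracle_cluster_greedy <- function(seqs, params) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  n <- length(seqs)
  idm <- matrix(0, n, n); covm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      st <- pairwise_identity(seqs[[i]], seqs[[j]], params$coverage_mode)
      idm[i, j] <- st[["identity"]]
      covm[i, j] <- st[["coverage"]]
    }
  }
  centroid <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- centroid[idm[i, centroid] >= params$min_identity &
                      covm[i, centroid] >= params$coverage_fraction]
    if (length(hit) > 0) {
      assign[i] <- hit[1]
    } else {
      centroid <- c(centroid, i)
      assign[i] <- i
    }
  }
  setNames(names(seqs)[assign], names(seqs))
}

# Partition comparison helpers.
partition_of <- function(assignment) {
  tidy(assignment) |> dplyr::arrange(seq_id)
}

same_partition <- function(a, b) {
  # identical groupings regardless of cluster naming
  ga <- split(names(a), unname(a))
  gb <- split(names(b), unname(b))
  setequal(lapply(ga, sort), lapply(gb, sort))
}

adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

random_seqs <- function(n, len_range = c(20, 60)) {
  setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   sample(len_range[1]:len_range[2], 1), replace = TRUE),
            collapse = "")
    }, character(1)),
    sprintf("s%03d", seq_len(n))
  )
}
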