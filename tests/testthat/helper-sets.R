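# shared fixture builders

uniform_freqs <- function() {
  f <- rep(1 / 20, 20)
  names(f) <- AA_ALPHABET
  f
}

# frequency vector with one residue raised to `value`, rest uniform
shifted_freqs <- function(residue, value) {
  f <- rep((1 - value) / 19, 20)
  names(f) <- AA_ALPHABET
  f[residue] <- value
  f
}

tiny_set <- function() {
  protein_set(c("p1", "p2", "p3"),
              c("GGGGRRRRAAAA", "RGRGRGRGRGRG", "ACDEFGHIKLMNPQRSTVWY"))
}

# brute-force UPGMA oracle: O(n^3) agglomeration over an explicit distance
# matrix, merging the pair with minimal mean inter-cluster distance.
# Returns the sorted leaf sets of all internal nodes with their heights.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  active <- rep(TRUE, n + (n - 1))
  merges <- list()
  cd <- matrix(NA_real_, n + n - 1, n + n - 1)
  cd[1:n, 1:n] <- d
  sizes <- c(rep(1, n), rep(NA, n - 1))
  for (step in seq_len(n - 1)) {
    act <- which(active[seq_along(clusters)])
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(act)) for (jj in seq_len(ii - 1L)) {
      a <- act[jj]; b <- act[ii]
      if (cd[a, b] < best_d) { best_d <- cd[a, b]; best <- c(a, b) }
    }
    new_id <- n + step
    members <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[new_id]] <- members
    merges[[step]] <- list(leaves = members, height = best_d)
    active[best] <- FALSE
    active[new_id] <- TRUE
    sizes[new_id] <- sizes[best[1]] + sizes[best[2]]
    for (a in which(active[seq_len(new_id - 1L)])) {
      cd[a, new_id] <- cd[new_id, a] <-
        (sizes[best[1]] * cd[a, best[1]] + sizes[best[2]] * cd[a, best[2]]) /
        sizes[new_id]
    }
  }
  merges
}
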