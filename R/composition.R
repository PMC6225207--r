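#' Amino-acid composition of a single sequence
#'
#' Fraction of each canonical residue among the canonical residues of the
#' sequence. Ambiguity codes (X, B, Z, U, O) are excluded from both the
#' numerator and the denominator, so the returned 20-vector always sums to 1.
#'
#' @param sequence Protein sequence string (uppercase or lowercase).
#' @return Named numeric vector of length 20 (names = [AA_ALPHABET]) summing
#'   to 1.
#' @examples
#' aa_composition("GGGG")["G"]          # 1
#' aa_composition("ACDEFGHIKLMNPQRSTVWY")  # all 0.05
#' @export
aa_composition <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  total <- sum(counts)
  if (total == 0L)
    stop("sequence contains no canonical residues")
  out <- as.numeric(counts) / total
  names(out) <- AA_ALPHABET
  out
}

#' Composition matrix of a protein set
#'
#' One row per protein, one column per canonical residue; each row is that
#' protein's [aa_composition()]. Column means give the set's mean composition.
#'
#' @param set A non-empty [protein_set()].
#' @return A `CompositionMatrix`: numeric matrix (proteins x 20) with row
#'   names = protein ids, rows summing to 1.
#' @export
composition_matrix <- function(set) {
  stopifnot(inherits(set, "ProteinSet"))
  if (length(set$ids) == 0L) stop("empty ProteinSet")
  rows <- lapply(seq_along(set$ids), function(i) {
    tryCatch(aa_composition(set$sequences[[i]]),
             error = function(e) stop("protein '", set$ids[[i]], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(set$ids, AA_ALPHABET)
  class(m) <- c("CompositionMatrix", class(m))
  m
}

#' Boxplot statistics per residue column
#'
#' Five-number summaries of a composition matrix using quartiles (type 7) and
#' the 1.5 x IQR whisker rule: whiskers extend to the most extreme values
#' within 1.5 interquartile ranges of the box, and values beyond the fences
#' are reported as outliers together with their protein ids.
#'
#' @param matrix A `CompositionMatrix` with at least 2 proteins.
#' @return A list with `summary`, a data frame (residue, median, q1, q3,
#'   whisker_low, whisker_high, n_outliers), and `outliers`, a data frame
#'   (residue, protein, value).
#' @export
boxplot_stats <- function(matrix) {
  stopifnot(inherits(matrix, "CompositionMatrix"), nrow(matrix) >= 2L)
  res <- lapply(colnames(matrix), function(a) {
    x <- matrix[, a]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x >= lo_fence & x <= hi_fence
    out <- which(!inside)
    list(
      summary = data.frame(
        residue = a, median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = min(x[inside]), whisker_high = max(x[inside]),
        n_outliers = length(out), stringsAsFactors = FALSE),
      outliers = if (length(out))
        data.frame(residue = a, protein = rownames(matrix)[out],
                   value = unname(x[out]), stringsAsFactors = FALSE)
      else NULL)
  })
  list(summary = do.call(rbind, lapply(res, `[[`, "summary")),
       outliers = do.call(rbind, lapply(res, `[[`, "outliers")))
}

#' Relative enrichment or depletion against a reference fraction
#'
#' `(sample_mean - reference) / reference`, with values whose magnitude
#' exceeds `threshold` classified as enriched (positive) or depleted
#' (negative).
#'
#' @param sample_mean Observed mean fraction(s).
#' @param reference Reference fraction(s), strictly positive.
#' @param threshold Classification threshold on |relative change|
#'   (default 0.10).
#' @return Data frame with columns `relative_change` and `classification`
#'   (`"enriched"`, `"depleted"` or `"-"`). Row names follow the input names.
#' @export
relative_change <- function(sample_mean, reference, threshold = 0.10) {
  if (any(reference <= 0)) stop("reference fractions must be > 0")
  rc <- (sample_mean - reference) / reference
  cls <- ifelse(rc > threshold, "enriched",
                ifelse(rc < -threshold, "depleted", "-"))
  data.frame(relative_change = rc, classification = cls,
             row.names = names(rc), stringsAsFactors = FALSE)
}

.kmers_of <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' k-mer composition of a protein set
#'
#' Overlapping k-mers are counted per protein; windows containing ambiguity
#' codes are excluded from both numerator and denominator, so each protein's
#' frequencies sum to 1 over its observed k-mers. Proteins shorter than `k`
#' are skipped with a warning.
#'
#' @param set A [protein_set()].
#' @param k Word length (>= 1).
#' @return A list with `freq`, a proteins x k-mers frequency matrix over the
#'   union of observed k-mers (absent = 0), and `mean`, the set-wide mean
#'   frequency per k-mer sorted decreasingly.
#' @export
kmer_composition <- function(set, k) {
  stopifnot(inherits(set, "ProteinSet"), k >= 1L)
  amb <- paste0("[", paste(AA_AMBIGUITY, collapse = ""), "]")
  per <- list()
  kept <- character()
  for (i in seq_along(set$ids)) {
    words <- .kmers_of(set$sequences[[i]], k)
    words <- words[!grepl(amb, words)]
    if (!length(words)) {
      warning("protein '", set$ids[[i]],
              "' shorter than k or all-ambiguous; skipped")
      next
    }
    tab <- table(words)
    per[[length(per) + 1L]] <- tab / sum(tab)
    kept <- c(kept, set$ids[[i]])
  }
  if (!length(per)) stop("no protein long enough for k = ", k)
  all_k <- sort(unique(unlist(lapply(per, names))))
  freq <- matrix(0, nrow = length(per), ncol = length(all_k),
                 dimnames = list(kept, all_k))
  for (i in seq_along(per))
    freq[i, names(per[[i]])] <- as.numeric(per[[i]])
  list(freq = freq, mean = sort(colMeans(freq), decreasing = TRUE))
}

#' k-mers shared by every protein in a set
#'
#' Exact substring presence in all records; an empty result means no k-mer is
#' universal.
#'
#' @param set A [protein_set()].
#' @param k Word length (>= 1).
#' @return Character vector (possibly empty) of k-mers present in every
#'   protein, sorted.
#' @export
shared_kmer_search <- function(set, k) {
  stopifnot(inherits(set, "ProteinSet"), k >= 1L)
  if (length(set$ids) == 0L) return(character())
  shared <- unique(.kmers_of(set$sequences[[1L]], k))
  for (i in seq_along(set$ids)[-1L]) {
    if (!length(shared)) break
    shared <- shared[vapply(shared, grepl, TRUE,
                            x = set$sequences[[i]], fixed = TRUE)]
  }
  sort(shared)
}

#' Read a reference residue-frequency table
#'
#' Two-column TSV (residue, fraction) covering all 20 canonical residues and
#' summing to 1 within 1e-6.
#'
#' @param path Path to the TSV file (header optional; lines starting with
#'   `#` ignored).
#' @return Named numeric 20-vector in [AA_ALPHABET] order.
#' @export
read_reference_frequencies <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!is.numeric(tab[[2L]])) tab <- tab[-1L, , drop = FALSE]  # header row
  freq <- as.numeric(tab[[2L]])
  names(freq) <- toupper(trimws(as.character(tab[[1L]])))
  missing <- setdiff(AA_ALPHABET, names(freq))
  if (length(missing))
    stop("reference table lacks residues: ", paste(missing, collapse = ", "))
  freq <- freq[AA_ALPHABET]
  if (any(freq <= 0) || any(freq >= 1))
    stop("reference frequencies must lie in (0,1)")
  if (abs(sum(freq) - 1) > 1e-6)
    stop("reference frequencies must sum to 1 (got ", sum(freq), ")")
  freq
}

#' Derive reference frequencies from a proteome set
#'
#' Pools all canonical residues of the set and returns their overall
#' frequencies — the standard way to build a background table from a supplied
#' proteome FASTA.
#'
#' @param set A [protein_set()].
#' @return Named numeric 20-vector summing to 1.
#' @export
reference_frequencies_from_set <- function(set) {
  stopifnot(inherits(set, "ProteinSet"), length(set$ids) > 0L)
  counts <- .pooled_counts(set)
  counts / sum(counts)
}

# pooled canonical-residue counts of a set (20-vector)
.pooled_counts <- function(set) {
  chars <- strsplit(paste(set$sequences, collapse = ""), "", fixed = TRUE)[[1]]
  tab <- table(factor(chars, levels = AA_ALPHABET))
  out <- as.numeric(tab)
  names(out) <- AA_ALPHABET
  out
}
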