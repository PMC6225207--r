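#' Build a position weight matrix from a peptide
#'
#' Converts a peptide into a probability matrix in which position i assigns
#' probability `1 - pseudo_total` to the peptide residue plus
#' `pseudo_total * background(a)` to every residue a (so the observed residue
#' receives `1 - pseudo_total + pseudo_total * background`). With
#' `pseudo_total = 0` the matrix is the indicator of the peptide.
#'
#' @param peptide Peptide string over the canonical alphabet (no ambiguity
#'   codes).
#' @param background Named 20-vector of background residue probabilities
#'   (default uniform 0.05); must be strictly positive and sum to 1.
#' @param pseudo_total Total pseudo-probability mass per position in `[0, 1)`
#'   (default 0.01).
#' @param name Motif name (defaults to the peptide itself).
#' @return A `MotifModel`: list with `name`, `length`, `prob` (L x 20, rows
#'   sum to 1), `background`, and `log_odds` (`log2(prob / background)`,
#'   bits).
#' @export
peptide_to_pwm <- function(peptide, background = NULL, pseudo_total = 0.01,
                           name = peptide) {
  peptide <- toupper(peptide)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (!length(chars)) stop("empty peptide")
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("peptide contains non-canonical character(s): ",
         paste(bad, collapse = ", "))
  stopifnot(pseudo_total >= 0, pseudo_total < 1)
  background <- .check_background(background)
  L <- length(chars)
  prob <- matrix(rep(pseudo_total * background, each = L), nrow = L,
                 dimnames = list(NULL, AA_ALPHABET))
  idx <- cbind(seq_len(L), match(chars, AA_ALPHABET))
  prob[idx] <- prob[idx] + (1 - pseudo_total)
  .motif_model(name, prob, background)
}

.check_background <- function(background) {
  if (is.null(background)) {
    background <- rep(1 / 20, 20)
    names(background) <- AA_ALPHABET
  }
  if (is.null(names(background))) names(background) <- AA_ALPHABET
  background <- background[AA_ALPHABET]
  if (any(is.na(background)) || any(background <= 0))
    stop("background must be strictly positive over all 20 residues")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  background
}

.motif_model <- function(name, prob, background) {
  stopifnot(all(abs(rowSums(prob) - 1) < 1e-9))
  structure(list(name = name, length = nrow(prob), prob = prob,
                 background = background,
                 log_odds = log2(sweep(prob, 2L, background, "/"))),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat("MotifModel '", x$name, "': length ", x$length,
      ", consensus ", consensus(x), "\n", sep = "")
  invisible(x)
}

# integer-binned log-odds matrix (bins of `granularity` bits); zero motif
# probabilities give -Inf log-odds, clamped at -20 bits (ratio 1e-6, far
# below any p-value of interest) to keep the score support finite
.discretize <- function(motif, granularity) {
  stopifnot(granularity > 0)
  lo <- pmax(motif$log_odds, -20)
  round(lo / granularity)
}

#' Exact p-values of PWM window scores under the background model
#'
#' Discretizes the log-odds matrix to integer bins of width `granularity`
#' bits, then runs dynamic programming over motif positions to accumulate the
#' exact distribution of total window scores for a random window drawn from
#' the background. `p(s) = P(score >= s)` is non-increasing in s and equals 1
#' at the minimum achievable score.
#'
#' @param motif A `MotifModel`.
#' @param granularity Score bin width in bits (default 0.001).
#' @return A `ScorePvalueTable`: list with `granularity`, `min_score` /
#'   `max_score` (integer bins), `prob` (exact bin probabilities) and
#'   `pvalue` (upper-tail probabilities, aligned with
#'   `min_score:max_score`).
#' @export
score_pvalue_table <- function(motif, granularity = 0.001) {
  stopifnot(inherits(motif, "MotifModel"))
  S <- .discretize(motif, granularity)
  bg <- motif$background
  cmin <- cumsum(apply(S, 1L, min))
  cmax <- cumsum(apply(S, 1L, max))
  dist <- 1    # score distribution; bin `base` = first entry
  base <- 0L
  for (i in seq_len(motif$length)) {
    lo <- cmin[i]; hi <- cmax[i]
    new <- numeric(hi - lo + 1L)
    for (a in seq_len(20L)) {
      start <- base + S[i, a] - lo + 1L
      rng <- start:(start + length(dist) - 1L)
      new[rng] <- new[rng] + bg[a] * dist
    }
    dist <- new; base <- lo
  }
  pv <- rev(cumsum(rev(dist)))
  pv <- pmin(pv, 1)    # guard fp drift
  structure(list(granularity = granularity, min_score = base,
                 max_score = base + length(dist) - 1L,
                 prob = dist, pvalue = pv),
            class = "ScorePvalueTable")
}

# p-values for integer bin scores; scores below support -> 1, above -> the
# smallest positive tail (scores above the canonical-window maximum can only
# arise from ambiguity-neutral windows)
.pvalue_at <- function(table, scores) {
  idx <- scores - table$min_score + 1L
  n <- length(table$pvalue)
  p <- rep(NA_real_, length(scores))
  p[idx < 1L] <- 1
  p[idx > n] <- table$pvalue[n]
  inb <- idx >= 1L & idx <= n
  p[inb] <- table$pvalue[idx[inb]]
  p
}

#' Scan a protein set with a motif
#'
#' Scores every window of motif length in every protein by the discretized
#' log-odds sum (positions holding ambiguity codes contribute 0, i.e. are
#' background-neutral), attaches exact p-values from [score_pvalue_table()],
#' and computes Benjamini-Hochberg q-values over **all** tested windows of
#' the scan (not only the reported hits). Hits are windows with
#' `p < p_threshold`. Sequences shorter than the motif are skipped with a
#' warning. Coordinates are 1-based inclusive.
#'
#' @param set A [protein_set()].
#' @param motif A `MotifModel`.
#' @param p_threshold Hit threshold on the exact p-value (default 0.01).
#' @param granularity Score bin width in bits (default 0.001).
#' @return A `ScanResult`: list with `motif` (name), `n_windows` (windows
#'   tested), `hits` (data frame: protein, start, stop, matched, score bits,
#'   p_value, q_value, ordered by protein then start) and `per_protein`
#'   (data frame: protein, n_hits, best_p, best_q, positions list-column).
#' @export
scan_set <- function(set, motif, p_threshold = 0.01, granularity = 0.001) {
  stopifnot(inherits(set, "ProteinSet"), inherits(motif, "MotifModel"),
            p_threshold > 0, p_threshold <= 1)
  if (length(set$ids) == 0L)
    return(.scan_result(motif$name, 0L, NULL, set))
  S <- .discretize(motif, granularity)
  tbl <- score_pvalue_table(motif, granularity)
  L <- motif$length
  rows <- list()
  n_windows <- 0L
  for (i in seq_along(set$ids)) {
    seqstr <- set$sequences[[i]]
    W <- nchar(seqstr) - L + 1L
    if (W < 1L) {
      warning("protein '", set$ids[[i]], "' shorter than motif; skipped")
      next
    }
    codes <- match(strsplit(seqstr, "", fixed = TRUE)[[1]], AA_ALPHABET)
    sc <- integer(W)
    for (j in seq_len(L)) {
      add <- S[j, codes[j:(j + W - 1L)]]
      add[is.na(add)] <- 0L
      sc <- sc + add
    }
    n_windows <- n_windows + W
    rows[[length(rows) + 1L]] <- data.frame(
      protein = set$ids[[i]], start = seq_len(W), stop = seq_len(W) + L - 1L,
      score_int = sc, p_value = .pvalue_at(tbl, sc),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.scan_result(motif$name, 0L, NULL, set))
  all_win <- do.call(rbind, rows)
  all_win$q_value <- stats::p.adjust(all_win$p_value, method = "BH")
  hits <- all_win[all_win$p_value < p_threshold, , drop = FALSE]
  if (nrow(hits)) {
    hits$matched <- substring(set$sequences[hits$protein], hits$start,
                              hits$stop)
    hits$score <- hits$score_int * granularity
  } else {
    hits$matched <- character(0)
    hits$score <- numeric(0)
  }
  hits <- hits[order(match(hits$protein, set$ids), hits$start),
               c("protein", "start", "stop", "matched", "score",
                 "p_value", "q_value")]
  rownames(hits) <- NULL
  .scan_result(motif$name, n_windows, hits, set)
}

.scan_result <- function(motif_name, n_windows, hits, set) {
  if (is.null(hits))
    hits <- data.frame(protein = character(), start = integer(),
                       stop = integer(), matched = character(),
                       score = numeric(), p_value = numeric(),
                       q_value = numeric(), stringsAsFactors = FALSE)
  per <- data.frame(protein = set$ids, stringsAsFactors = FALSE)
  per$n_hits <- vapply(set$ids, function(id) sum(hits$protein == id), 0L)
  per$best_p <- vapply(set$ids, function(id) {
    p <- hits$p_value[hits$protein == id]
    if (length(p)) min(p) else NA_real_
  }, 0)
  per$best_q <- vapply(set$ids, function(id) {
    q <- hits$q_value[hits$protein == id]
    if (length(q)) min(q) else NA_real_
  }, 0)
  per$positions <- I(lapply(set$ids, function(id)
    sort(hits$start[hits$protein == id])))
  rownames(per) <- NULL
  structure(list(motif = motif_name, n_windows = n_windows,
                 hits = hits, per_protein = per),
            class = "ScanResult")
}

#' @export
print.ScanResult <- function(x, ...) {
  cat("ScanResult for motif '", x$motif, "': ", nrow(x$hits), " hits in ",
      sum(x$per_protein$n_hits > 0), "/", nrow(x$per_protein),
      " proteins (", x$n_windows, " windows tested)\n", sep = "")
  invisible(x)
}

#' Partition proteins by best q-value
#'
#' Bins every protein of a scan by its best (minimal) hit q-value:
#' `q <= thresholds[1]`, `thresholds[1] < q <= thresholds[2]`, and
#' `q > thresholds[2]` or no hit at all.
#'
#' @param result A `ScanResult`.
#' @param thresholds Two increasing q cut-offs (default `c(0.05, 0.1)`).
#' @return List with `counts` (named integer 3-vector summing to the set
#'   size) and `assignment` (data frame protein, best_q, bin).
#' @export
classify_by_q <- function(result, thresholds = c(0.05, 0.1)) {
  stopifnot(inherits(result, "ScanResult"), length(thresholds) == 2L,
            thresholds[1] < thresholds[2])
  q <- result$per_protein$best_q
  bin <- ifelse(!is.na(q) & q <= thresholds[1], 1L,
                ifelse(!is.na(q) & q <= thresholds[2], 2L, 3L))
  labs <- c(sprintf("q<=%g", thresholds[1]),
            sprintf("%g<q<=%g", thresholds[1], thresholds[2]),
            sprintf("q>%g", thresholds[2]))
  counts <- vapply(1:3, function(b) sum(bin == b), 0L)
  names(counts) <- labs
  list(counts = counts,
       assignment = data.frame(protein = result$per_protein$protein,
                               best_q = q, bin = labs[bin],
                               stringsAsFactors = FALSE))
}

#' Proteins carrying multiple motif occurrences
#'
#' @param result A `ScanResult`.
#' @param min_hits Minimum number of hits (default 2).
#' @return Data frame (protein, n_hits, positions list-column of ascending
#'   1-based starts), proteins in input order.
#' @export
multi_hit_proteins <- function(result, min_hits = 2L) {
  stopifnot(inherits(result, "ScanResult"), min_hits >= 1L)
  per <- result$per_protein
  out <- per[per$n_hits >= min_hits,
             c("protein", "n_hits", "positions"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate motif-carrying proteins
#'
#' Scans a target set and ranks proteins by best hit: ascending p-value, ties
#' by descending score then id; truncates to the `top_n` best. Proteins
#' listed in `exclude` (e.g. already-known binders) are removed before
#' ranking.
#'
#' @param targets A [protein_set()] to search.
#' @param motif A `MotifModel`.
#' @param p_threshold Hit threshold (default 0.1).
#' @param top_n Number of candidates to keep (default 100).
#' @param exclude Optional `ProteinSet` or character vector of ids to drop.
#' @param granularity Score bin width in bits.
#' @return Data frame (rank, protein, best_p, best_q, best_score, start,
#'   matched) with at most `top_n` rows.
#' @export
predict_candidates <- function(targets, motif, p_threshold = 0.1,
                               top_n = 100L, exclude = NULL,
                               granularity = 0.001) {
  stopifnot(inherits(targets, "ProteinSet"))
  if (length(targets$ids) == 0L)
    return(data.frame(rank = integer(), protein = character(),
                      best_p = numeric(), best_q = numeric(),
                      best_score = numeric(), start = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  drop <- if (inherits(exclude, "ProteinSet")) exclude$ids
          else as.character(exclude)
  res <- scan_set(targets, motif, p_threshold = p_threshold,
                  granularity = granularity)
  hits <- res$hits[!(res$hits$protein %in% drop), , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(rank = integer(), protein = character(),
                      best_p = numeric(), best_q = numeric(),
                      best_score = numeric(), start = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  # best hit per protein: min p, ties by max score then smallest start
  hits <- hits[order(hits$protein, hits$p_value, -hits$score, hits$start), ]
  best <- hits[!duplicated(hits$protein), , drop = FALSE]
  best <- best[order(best$p_value, -best$score, best$protein), , drop = FALSE]
  best <- utils::head(best, top_n)
  data.frame(rank = seq_len(nrow(best)), protein = best$protein,
             best_p = best$p_value, best_q = best$q_value,
             best_score = best$score, start = best$start,
             matched = best$matched, stringsAsFactors = FALSE)
}

#' Write a motif in MEME minimal format
#'
#' @param motif A `MotifModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motif, path) {
  stopifnot(inherits(motif, "MotifModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(AA_ALPHABET, collapse = "")), "",
               "Background letter frequencies",
               paste(AA_ALPHABET,
                     formatC(motif$background, format = "g", digits = 6),
                     collapse = " "), "",
               paste("MOTIF", motif$name),
               sprintf("letter-probability matrix: alength= 20 w= %d nsites= 20 E= 0",
                       motif$length)), con)
  utils::write.table(format(motif$prob, digits = 6, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a MEME minimal format motif file
#'
#' Reads the first motif of a MEME minimal file over the 20-letter protein
#' alphabet.
#'
#' @param path Path to a MEME minimal format file.
#' @return A `MotifModel`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  background <- NULL
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    background <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(background) <- toks[seq(1, length(toks), by = 2)]
  }
  background <- .check_background(background)
  m_i <- grep("^MOTIF\\s", lines)[1]
  if (is.na(m_i)) stop("no MOTIF block found in ", path)
  name <- strsplit(lines[m_i], "\\s+")[[1]][2]
  lp_i <- grep("^letter-probability matrix", lines)
  lp_i <- lp_i[lp_i > m_i][1]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp_i]))
  rows <- lines[(lp_i + 1L):(lp_i + w)]
  prob <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  colnames(prob) <- AA_ALPHABET
  prob <- prob / rowSums(prob)   # renormalise printed precision
  .motif_model(name, prob, background)
}
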