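#' Specification for synthetic protein sets
#'
#' Describes a background set of i.i.d.-residue protein sequences; used by
#' [gen_background()] and [gen_grouped()] to produce the inputs the analysis
#' stages are tested on.
#'
#' @param n_proteins Number of sequences.
#' @param length Sequence length: a single value, or `c(min, max)` for a
#'   uniform integer range.
#' @param freqs Named 20-vector of residue probabilities (default uniform);
#'   entries >= 0 and summing to 1 within 1e-9.
#' @param seed Integer seed.
#' @param name Set name.
#' @return A list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_proteins, length = 300L, freqs = NULL,
                           seed = 1L, name = "synthetic") {
  if (is.null(freqs)) {
    freqs <- rep(1 / 20, 20)
    names(freqs) <- AA_ALPHABET
  }
  if (is.null(names(freqs))) names(freqs) <- AA_ALPHABET
  freqs <- freqs[AA_ALPHABET]
  if (any(is.na(freqs)) || any(freqs < 0))
    stop("freqs must be a non-negative 20-vector over the canonical alphabet")
  if (abs(sum(freqs) - 1) > 1e-9) stop("freqs must sum to 1")
  if (all(freqs == 0)) stop("degenerate all-zero frequency vector")
  stopifnot(n_proteins >= 1L, all(length >= 1L), length(length) <= 2L)
  structure(list(n_proteins = as.integer(n_proteins),
                 length = as.integer(length), freqs = freqs,
                 seed = as.integer(seed), name = name),
            class = "SyntheticSpec")
}

.draw_sequences <- function(n, length, freqs) {
  lens <- if (base::length(length) == 2L)
    sample(length[1]:length[2], n, replace = TRUE)
  else rep(length, n)
  vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = freqs),
          collapse = ""), "")
}

#' Generate a background protein set
#'
#' Sequences of i.i.d. residues drawn from the spec's frequency vector;
#' byte-reproducible given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [protein_set()] with ids `<name>0001`, `<name>0002`, ...
#' @export
gen_background <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  seqs <- .draw_sequences(spec$n_proteins, spec$length, spec$freqs)
  ids <- sprintf("%s%04d", spec$name, seq_len(spec$n_proteins))
  protein_set(ids, seqs, name = spec$name)
}

#' Plant motif copies into a protein set
#'
#' Overwrites (does not insert, so sequence lengths are preserved) `copies`
#' non-overlapping occurrences of `peptide` at uniformly chosen positions in
#' every protein; each planted residue is independently replaced by a draw
#' from `freqs` with probability `substitution_rate`. The true planting
#' positions are returned as ground truth and never encoded in the sequences
#' themselves.
#'
#' @param set A [protein_set()].
#' @param peptide Motif string over the canonical alphabet.
#' @param copies Copies per protein (0 leaves the set unchanged).
#' @param substitution_rate Per-residue substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param freqs Background frequencies for substitutions (default uniform).
#' @return List with `set` (the modified [protein_set()]) and `truth`
#'   (data frame: protein, start, planted — the possibly-mutated planted
#'   subsequence).
#' @export
plant_motif <- function(set, peptide, copies = 1L, substitution_rate = 0,
                        seed = 1L, freqs = NULL) {
  stopifnot(inherits(set, "ProteinSet"), copies >= 0L,
            substitution_rate >= 0, substitution_rate <= 1)
  peptide <- toupper(peptide)
  if (copies == 0L)
    return(list(set = set, truth = data.frame(protein = character(),
                                              start = integer(),
                                              planted = character())))
  if (is.null(freqs)) { freqs <- rep(1 / 20, 20); names(freqs) <- AA_ALPHABET }
  k <- nchar(peptide)
  lens <- nchar(set$sequences)
  if (any(lens < copies * k))
    stop("protein(s) too short for ", copies, " non-overlapping copies: ",
         paste(set$ids[lens < copies * k], collapse = ", "))
  set.seed(seed)
  pep_chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  truth <- vector("list", length(set$ids))
  seqs <- set$sequences
  for (i in seq_along(seqs)) {
    L <- lens[i]
    # non-overlapping uniform starts via the gap construction: distribute the
    # spare length among copies + 1 gaps
    spare <- L - copies * k
    cuts <- sort(sample.int(spare + copies, copies))  # stars-and-bars
    starts <- cuts + (seq_len(copies) - 1L) * (k - 1L)
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    planted <- character(copies)
    for (cpy in seq_len(copies)) {
      ins <- pep_chars
      mut <- stats::runif(k) < substitution_rate
      if (any(mut))
        ins[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE,
                           prob = freqs)
      chars[starts[cpy]:(starts[cpy] + k - 1L)] <- ins
      planted[cpy] <- paste(ins, collapse = "")
    }
    seqs[[i]] <- paste(chars, collapse = "")
    truth[[i]] <- data.frame(protein = set$ids[[i]], start = starts,
                             planted = planted, stringsAsFactors = FALSE)
  }
  out <- protein_set(set$ids, seqs, name = set$name,
                     descriptions = set$descriptions,
                     binding_class = set$binding_class)
  list(set = out, truth = do.call(rbind, truth))
}

#' Generate composition-shifted protein groups
#'
#' Draws each group from the base frequency vector plus a per-group offset
#' (clipped at 0 and renormalized), recording group labels for recovery
#' scoring. Emulates protein families whose residue usage differs by a known
#' amount, e.g. a glycine-enriched subset.
#'
#' @param spec A [synthetic_spec()]; `spec$n_proteins` is the size of *each*
#'   group.
#' @param offsets List of named numeric offset vectors, one per group
#'   (residues not named are unshifted; an offset pushing a frequency below
#'   0 is an error).
#' @return List with `set` (a [protein_set()] of all groups, ids carrying a
#'   group prefix) and `labels` (named integer group index per protein).
#' @export
gen_grouped <- function(spec, offsets) {
  stopifnot(inherits(spec, "SyntheticSpec"), is.list(offsets),
            length(offsets) >= 1L)
  set.seed(spec$seed)
  all_ids <- character(); all_seqs <- character(); labels <- integer()
  for (g in seq_along(offsets)) {
    off <- offsets[[g]]
    f <- spec$freqs
    if (length(off)) {
      if (is.null(names(off))) stop("offsets must be named by residue")
      f[names(off)] <- f[names(off)] + off
      if (any(f < 0))
        stop("offset for group ", g, " drives frequencies below 0")
      f <- f / sum(f)
    }
    seqs <- .draw_sequences(spec$n_proteins, spec$length, f)
    ids <- sprintf("g%d_%s%04d", g, spec$name, seq_len(spec$n_proteins))
    all_ids <- c(all_ids, ids); all_seqs <- c(all_seqs, seqs)
    labels <- c(labels, rep(g, spec$n_proteins))
  }
  names(labels) <- all_ids
  list(set = protein_set(all_ids, all_seqs, name = spec$name),
       labels = labels)
}
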