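#' Configuration for the Gibbs motif sampler
#'
#' @param width Motif width (default 20, the length of the RG-rich consensus
#'   reported for quadruplex binding proteins).
#' @param n_restarts Independent random restarts (default 10).
#' @param iterations Gibbs sweeps per restart (default 500).
#' @param seed Integer seed.
#' @param model Occurrence model: `"zoops"` (zero or one occurrence per
#'   sequence, default) or `"oops"` (exactly one).
#' @param pseudo_weight Dirichlet pseudocount weight; per-residue pseudocount
#'   is `pseudo_weight * 20 * background(a)` (total mass
#'   `20 * pseudo_weight`).
#' @param site_prior Prior probability that a sequence carries a site under
#'   zoops (default 0.9).
#' @param patience Stop a restart early after this many sweeps without
#'   improvement of the best score (default 50).
#' @return A list of class `SamplerConfig`.
#' @export
sampler_config <- function(width = 20L, n_restarts = 10L, iterations = 500L,
                           seed = 1L, model = c("zoops", "oops"),
                           pseudo_weight = 0.1, site_prior = 0.9,
                           patience = 50L) {
  stopifnot(width >= 2L, iterations >= 1L, n_restarts >= 1L,
            pseudo_weight > 0, site_prior > 0, site_prior < 1)
  structure(list(width = as.integer(width),
                 n_restarts = as.integer(n_restarts),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), model = match.arg(model),
                 pseudo_weight = pseudo_weight, site_prior = site_prior,
                 patience = as.integer(patience)),
            class = "SamplerConfig")
}

# counts (width x 20) contributed by one site window; NA codes skipped
.site_counts <- function(codes, start, width) {
  m <- matrix(0, width, 20L)
  idx <- codes[start:(start + width - 1L)]
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# log2 likelihood-ratio scores of all windows of one sequence
.window_scores <- function(codes, llr, width) {
  W <- length(codes) - width + 1L
  sc <- numeric(W)
  for (j in seq_len(width)) {
    add <- llr[j, codes[j:(j + W - 1L)]]
    add[is.na(add)] <- 0
    sc <- sc + add
  }
  sc
}

#' De novo ungapped motif discovery by Gibbs site sampling
#'
#' Searches a protein set for a shared fixed-width motif with a site-sampling
#' Gibbs sampler: each sweep re-estimates the position weight matrix from all
#' sites except the held-out sequence's (with Dirichlet pseudocounts
#' proportional to the background) and re-samples that sequence's site from
#' the posterior over windows. Under the zoops model a "no site" option with
#' prior `site_prior` is included. The best-scoring alignment across all
#' sweeps and restarts is tracked and returned; the run is deterministic
#' given `cfg$seed`. The alignment score is the total log2 likelihood ratio
#' (bits) of the aligned windows under the motif versus the background.
#'
#' @param set A [protein_set()] with >= 2 proteins, each at least
#'   `cfg$width` long (shorter proteins are an error).
#' @param cfg A [sampler_config()].
#' @param background Background residue probabilities (default: pooled
#'   frequencies of `set`).
#' @return A `DiscoveryResult`: list with `motif` (a `MotifModel` estimated
#'   from the best alignment), `consensus`, `positions` (named integer
#'   vector of 1-based site starts, NA = no site), `score` (bits) and
#'   `score_trace` (best score after each sweep of the best restart;
#'   non-decreasing).
#' @export
gibbs_discover <- function(set, cfg = sampler_config(), background = NULL) {
  stopifnot(inherits(set, "ProteinSet"), inherits(cfg, "SamplerConfig"),
            length(set$ids) >= 2L)
  width <- cfg$width
  lens <- nchar(set$sequences)
  if (all(lens < width)) stop("all sequences shorter than motif width")
  if (any(lens < width))
    stop("sequence(s) shorter than width: ",
         paste(set$ids[lens < width], collapse = ", "))
  if (is.null(background)) background <- reference_frequencies_from_set(set)
  background <- .check_background(background)
  n <- length(set$ids)
  codes <- lapply(set$sequences, function(s)
    match(strsplit(s, "", fixed = TRUE)[[1]], AA_ALPHABET))
  Wn <- lens - width + 1L
  pseudo <- cfg$pseudo_weight * 20 * background   # width-independent row
  zoops <- cfg$model == "zoops"

  score_state <- function(sites) {
    # total log2 LR of aligned windows under PWM estimated from all sites
    used <- which(!is.na(sites))
    if (length(used) < 2L) return(-Inf)
    counts <- matrix(rep(pseudo, each = width), width, 20L)
    for (i in used)
      counts <- counts + .site_counts(codes[[i]], sites[i], width)
    p <- counts / rowSums(counts)
    llr <- log2(sweep(p, 2L, background, "/"))
    sum(vapply(used, function(i) {
      idx <- codes[[i]][sites[i]:(sites[i] + width - 1L)]
      ok <- !is.na(idx)
      sum(llr[cbind(which(ok), idx[ok])])
    }, 0))
  }

  set.seed(cfg$seed)
  best <- list(score = -Inf, sites = NULL, trace = numeric())
  for (r in seq_len(cfg$n_restarts)) {
    sites <- vapply(Wn, function(w) sample.int(w, 1L), 0L)
    counts <- matrix(rep(pseudo, each = width), width, 20L)
    for (i in seq_len(n))
      counts <- counts + .site_counts(codes[[i]], sites[i], width)
    r_best <- -Inf
    r_trace <- numeric(cfg$iterations)
    stale <- 0L
    for (it in seq_len(cfg$iterations)) {
      for (i in seq_len(n)) {
        if (!is.na(sites[i]))
          counts <- counts - .site_counts(codes[[i]], sites[i], width)
        p <- counts / rowSums(counts)
        llr <- log2(sweep(p, 2L, background, "/"))
        sc <- .window_scores(codes[[i]], llr, width)
        if (zoops) {
          w_no <- log2(Wn[i] * (1 - cfg$site_prior) / cfg$site_prior)
          all_sc <- c(sc, w_no)
          pr <- exp(log(2) * (all_sc - max(all_sc)))
          pick <- sample.int(length(pr), 1L, prob = pr)
          sites[i] <- if (pick > Wn[i]) NA_integer_ else pick
        } else {
          pr <- exp(log(2) * (sc - max(sc)))
          sites[i] <- sample.int(Wn[i], 1L, prob = pr)
        }
        if (!is.na(sites[i]))
          counts <- counts + .site_counts(codes[[i]], sites[i], width)
      }
      # phase-shift move: translating every site by the same offset leaves a
      # locally optimal but misregistered alignment; accept the best shift
      s0 <- score_state(sites)
      for (delta in c(-2L, -1L, 1L, 2L)) {
        shifted <- sites + delta
        bad <- !is.na(shifted) & (shifted < 1L | shifted > Wn)
        shifted[bad] <- NA_integer_
        s_sh <- score_state(shifted)
        if (s_sh > s0) {
          sites <- shifted
          s0 <- s_sh
          counts <- matrix(rep(pseudo, each = width), width, 20L)
          for (i in which(!is.na(sites)))
            counts <- counts + .site_counts(codes[[i]], sites[i], width)
        }
      }
      s <- s0
      if (s > r_best) {
        r_best <- s
        stale <- 0L
        if (s > best$score) best <- list(score = s, sites = sites,
                                         trace = NULL)
      } else stale <- stale + 1L
      r_trace[it] <- r_best
      if (stale >= cfg$patience) { r_trace <- r_trace[seq_len(it)]; break }
    }
    if (r_best == best$score && is.null(best$trace)) best$trace <- r_trace
  }
  sites <- best$sites
  used <- which(!is.na(sites))
  counts <- matrix(rep(pseudo, each = width), width, 20L)
  for (i in used)
    counts <- counts + .site_counts(codes[[i]], sites[i], width)
  prob <- counts / rowSums(counts)
  colnames(prob) <- AA_ALPHABET
  motif <- .motif_model("discovered", prob, background)
  names(sites) <- set$ids
  structure(list(motif = motif, consensus = consensus(motif),
                 positions = sites, score = best$score,
                 score_trace = best$trace),
            class = "DiscoveryResult")
}

#' @export
print.DiscoveryResult <- function(x, ...) {
  cat("DiscoveryResult: consensus ", x$consensus, " (score ",
      formatC(x$score, digits = 5, format = "g"), " bits, ",
      sum(!is.na(x$positions)), "/", length(x$positions),
      " sequences aligned)\n", sep = "")
  invisible(x)
}

#' Consensus string of a motif
#'
#' Per-position argmax residue; ties broken alphabetically.
#'
#' @param motif A `MotifModel`.
#' @return Character string of length `motif$length`.
#' @export
consensus <- function(motif) {
  stopifnot(inherits(motif, "MotifModel"))
  paste(AA_ALPHABET[apply(motif$prob, 1L, which.max)], collapse = "")
}

#' Best ungapped identity between two motif/peptide strings
#'
#' Slides the shorter string along the longer at every full-overlap offset
#' and reports the maximal percent identity (matches / length of shorter),
#' the aligned length, and the winning offset (0-based shift of the shorter
#' string along the longer; ties broken by the smallest offset). Symmetric in
#' its arguments.
#'
#' @param a,b Non-empty strings over the amino-acid alphabet.
#' @return List with `identity` (percent), `aligned_length`, `offset`.
#' @examples
#' best_ungapped_identity("RGRG", "RGRG")$identity  # 100
#' @export
best_ungapped_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) <= nchar(b)) { s <- a; l <- b } else { s <- b; l <- a }
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  lc <- strsplit(l, "", fixed = TRUE)[[1]]
  ns <- length(sc); nl <- length(lc)
  best_m <- -1L; best_off <- 0L
  for (off in 0:(nl - ns)) {
    m <- sum(sc == lc[(off + 1L):(off + ns)])
    if (m > best_m) { best_m <- m; best_off <- off }
  }
  list(identity = 100 * best_m / ns, aligned_length = ns, offset = best_off)
}

#' Fixed-width overlay of motif occurrences
#'
#' Renders each protein's best occurrence (scan hit with minimal p-value, or
#' the sampled discovery site) as a fixed-width row; proteins without an
#' occurrence, and ambiguity-code positions, are shown as dots.
#'
#' @param result A `ScanResult` or `DiscoveryResult`.
#' @param set The [protein_set()] the result was computed on.
#' @return Named character vector (one row per protein, names = ids), every
#'   element of the same width as the motif.
#' @export
overlay_occurrences <- function(result, set) {
  stopifnot(inherits(set, "ProteinSet"))
  if (inherits(result, "DiscoveryResult")) {
    width <- result$motif$length
    starts <- result$positions[set$ids]
  } else if (inherits(result, "ScanResult")) {
    per <- result$per_protein
    if (!any(per$n_hits > 0)) stop("scan contains no occurrences")
    width <- nchar(result$hits$matched[1L])
    starts <- vapply(set$ids, function(id) {
      h <- result$hits[result$hits$protein == id, , drop = FALSE]
      if (!nrow(h)) return(NA_integer_)
      h$start[which.min(h$p_value)]
    }, 0L)
  } else stop("result must be a ScanResult or DiscoveryResult")
  rows <- vapply(seq_along(set$ids), function(i) {
    if (is.na(starts[i])) return(strrep(".", width))
    w <- substring(set$sequences[[i]], starts[i], starts[i] + width - 1L)
    gsub(paste0("[", paste(AA_AMBIGUITY, collapse = ""), "]"), ".", w)
  }, "")
  names(rows) <- set$ids
  rows
}
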