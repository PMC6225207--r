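#' Construct a protein set
#'
#' A `ProteinSet` is an ordered collection of named protein sequences over the
#' 20-letter amino-acid alphabet (ambiguity codes X, B, Z, U, O are tolerated
#' but flagged). It is the common input container for composition, enrichment,
#' clustering and motif scanning.
#'
#' @param ids Character vector of unique record identifiers (accession or
#'   gene symbol).
#' @param sequences Character vector of protein sequences, same length as
#'   `ids`. Lowercase input is uppercased.
#' @param name Name of the set (e.g. `"query"`, `"nucleic-acid-binding"`).
#' @param descriptions Optional free-text description per record.
#' @param binding_class Optional per-record label, one of `"dna"`, `"rna"`,
#'   `"both"`, `"unknown"`.
#' @return An object of class `ProteinSet`: a list with elements `name`,
#'   `ids`, `sequences` (named by id), `descriptions`, `binding_class`.
#' @export
protein_set <- function(ids, sequences, name = "set", descriptions = NULL,
                        binding_class = NULL) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("`ids` and `sequences` must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(sequences) && any(!nzchar(sequences)))
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "))
  .check_alphabet(ids, sequences)
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  if (is.null(binding_class)) binding_class <- rep("unknown", length(ids))
  if (length(ids)) {
    binding_class <- match.arg(binding_class,
                               c("dna", "rna", "both", "unknown"),
                               several.ok = TRUE)
    binding_class <- rep_len(binding_class, length(ids))
  } else binding_class <- character()
  names(sequences) <- ids
  structure(list(name = name, ids = ids, sequences = sequences,
                 descriptions = descriptions, binding_class = binding_class),
            class = "ProteinSet")
}

.check_alphabet <- function(ids, sequences) {
  allowed <- c(AA_ALPHABET, AA_AMBIGUITY)
  for (i in seq_along(sequences)) {
    chars <- unique(strsplit(sequences[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop("record '", ids[[i]], "' contains invalid character(s): ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.ProteinSet <- function(x, ...) {
  cat("ProteinSet '", x$name, "': ", length(x$ids), " proteins, ",
      "length range [", if (length(x$ids)) min(nchar(x$sequences)) else 0,
      ", ", if (length(x$ids)) max(nchar(x$sequences)) else 0, "]\n",
      sep = "")
  invisible(x)
}

#' @export
length.ProteinSet <- function(x) length(x$ids)

#' Subset a protein set by index or id
#'
#' @param x A `ProteinSet`.
#' @param i Integer, logical or character (id) index.
#' @param ... Unused.
#' @return A `ProteinSet` with the selected records, order preserved.
#' @export
`[.ProteinSet` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  protein_set(x$ids[i], x$sequences[i], name = x$name,
              descriptions = x$descriptions[i],
              binding_class = x$binding_class[i])
}

#' Read a protein FASTA file into a ProteinSet
#'
#' The id of each record is the header token before the first whitespace.
#' UniProt-style `sp|ACC|NAME` / `tr|ACC|NAME` ids are additionally split so
#' the accession and mnemonic are available as attributes. Sequences are
#' uppercased; parsing is independent of body line-wrapping. Characters
#' outside the canonical alphabet plus ambiguity codes raise an error naming
#' the record and the offending character.
#'
#' @param path Path to a FASTA file.
#' @param name Set name; defaults to the file name without extension.
#' @param binding_class_file Optional path to a two-column TSV (id,
#'   binding_class) attaching dna/rna/both labels.
#' @return A [protein_set()]. Records whose header follows the UniProt
#'   convention carry `accession` and `mnemonic` columns in the
#'   `attr(, "uniprot")` data frame.
#' @export
read_fasta <- function(path, name = NULL,
                       binding_class_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_set(character(), character(), name = name))
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- toupper(as.character(aa))
  set <- protein_set(ids, seqs, name = name, descriptions = desc)

  up <- regmatches(ids, regexec("^(?:sp|tr)\\|([^|]+)\\|(\\S+)$", ids))
  has_up <- lengths(up) == 3L
  if (any(has_up)) {
    attr(set, "uniprot") <- data.frame(
      id = ids[has_up],
      accession = vapply(up[has_up], `[`, "", 2L),
      mnemonic = vapply(up[has_up], `[`, "", 3L),
      stringsAsFactors = FALSE)
  }
  if (!is.null(binding_class_file)) {
    bc <- utils::read.delim(binding_class_file, header = TRUE,
                            stringsAsFactors = FALSE)
    m <- match(set$ids, bc[[1L]])
    set$binding_class[!is.na(m)] <- bc[[2L]][m[!is.na(m)]]
  }
  set
}

#' Write a ProteinSet to FASTA
#'
#' Round-trip guarantee: `read_fasta(write_fasta(s, f))` reproduces ids and
#' sequences exactly.
#'
#' @param set A non-empty `ProteinSet`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path, width = 60L) {
  stopifnot(inherits(set, "ProteinSet"))
  if (length(set$ids) == 0L) stop("refusing to write an empty ProteinSet")
  aa <- Biostrings::AAStringSet(set$sequences)
  names(aa) <- ifelse(nzchar(set$descriptions),
                      paste(set$ids, set$descriptions), set$ids)
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}
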