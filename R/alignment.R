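# Species-labeled sequence containers and FASTA I/O.
#
# Header convention: ">seqID|species|group" with species and group optional.
# The species label is the unit of truth for the intra/interspecific
# partition, so it must come in with the sequences, not be bolted on later.

#' IUPAC nucleotide alphabet accepted by the package
#'
#' The four pure bases, the eleven ambiguity codes, `N` and the gap
#' character `-`. Residues outside this set are rejected in strict mode and
#' replaced by `N` in lenient mode.
#'
#' @format Character vector of length 16.
#' @export
IUPAC_ALPHABET <- c("A", "C", "G", "T",
                    "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N", "-")

PURE_BASES <- c("A", "C", "G", "T")

.as_char_rows <- function(seqs) {
  # accept a named character vector of strings or a character matrix
  if (is.matrix(seqs)) {
    storage.mode(seqs) <- "character"
    return(seqs)
  }
  if (!is.character(seqs))
    stop("'seqs' must be a character vector or matrix", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
         "); an alignment requires equal-length rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  mat
}

#' Construct a species-labeled alignment
#'
#' The central container of the package: an equal-length block of
#' nucleotide (or amino-acid) rows, each carrying a sequence id, a species
#' label (possibly empty, for unidentified query clones) and an optional
#' higher-taxon group label used by the contamination screen.
#'
#' @param seqs Named character vector of equal-length sequence strings, or a
#'   character matrix with one row per sequence (rownames = ids).
#' @param species Character vector of species labels, recycled if length 1.
#'   Defaults to empty labels.
#' @param group Optional character vector of group labels (e.g.
#'   `"Platyhelminthes"`).
#' @param lenient If `TRUE`, residues outside [IUPAC_ALPHABET] are replaced
#'   by `N` with a message; if `FALSE` (default) they are an error.
#' @param alphabet `"dna"` (default; validated against [IUPAC_ALPHABET]) or
#'   `"aa"` (any letter plus `-`, `X`, `*`; used for the amino-acid
#'   consensus utility).
#' @return Object of class `labeled_alignment`: a list with `seq` (character
#'   matrix, uppercased) and `meta` (data frame with `seq_id`, `species`,
#'   `group`).
#' @export
labeled_alignment <- function(seqs, species = NULL, group = NULL,
                              lenient = FALSE, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  mat <- .as_char_rows(seqs)
  n <- nrow(mat)
  if (n < 2L)
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  ids <- rownames(mat)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (is.null(species)) species <- rep("", n)
  if (length(species) == 1L) species <- rep(species, n)
  if (is.null(group)) group <- rep("", n)
  if (length(group) == 1L) group <- rep(group, n)
  stopifnot(length(species) == n, length(group) == n)

  mat[] <- toupper(mat)
  if (alphabet == "dna") {
    bad <- !(mat %in% IUPAC_ALPHABET)
    if (any(bad)) {
      if (lenient) {
        message("replaced ", sum(bad), " non-IUPAC residue(s) with N")
        mat[bad] <- "N"
      } else {
        stop("non-IUPAC residue(s) found (e.g. '",
             mat[which(bad)[1L]], "'); use lenient = TRUE to mask them",
             call. = FALSE)
      }
    }
  }

  structure(list(
    seq = mat,
    meta = data.frame(seq_id = ids, species = as.character(species),
                      group = as.character(group), stringsAsFactors = FALSE)
  ), class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  nsp <- length(unique(x$meta$species[nzchar(x$meta$species)]))
  cat("labeled_alignment: ", nrow(x$seq), " sequences x ", ncol(x$seq),
      " columns, ", nsp, " labeled species\n", sep = "")
  invisible(x)
}

#' Number of sequences and alignment length
#' @param aln A `labeled_alignment`.
#' @return Integer.
#' @export
n_sequences <- function(aln) nrow(aln$seq)

#' @rdname n_sequences
#' @export
alignment_length <- function(aln) ncol(aln$seq)

#' Species labels as a named vector (id -> species)
#' @param aln A `labeled_alignment`.
#' @return Named character vector.
#' @export
species_labels <- function(aln) {
  stats::setNames(aln$meta$species, aln$meta$seq_id)
}

#' Group labels as a named vector (id -> group)
#' @param aln A `labeled_alignment`.
#' @return Named character vector.
#' @export
group_labels <- function(aln) {
  stats::setNames(aln$meta$group, aln$meta$seq_id)
}

.parse_header <- function(h) {
  fields <- strsplit(h, "|", fixed = TRUE)[[1L]]
  if (length(fields) < 1L || length(fields) > 3L || !nzchar(fields[1L]))
    stop("unparseable FASTA header: '>", h,
         "' (expected 'seqID|species|group', species/group optional)",
         call. = FALSE)
  length(fields) <- 3L
  fields[is.na(fields)] <- ""
  fields
}

#' Read a species-labeled FASTA file
#'
#' Headers follow the pipe convention `>seqID|species|group`; species and
#' group may be omitted (a bare `>seqID` yields an empty species label,
#' usable only as a query in the contamination screen). Labels may instead
#' be supplied through a TSV sidecar with columns `seq_id`, `species`,
#' `group`, which overrides header-derived labels.
#'
#' @param path FASTA file.
#' @param aligned If `TRUE` (default) all records must have equal length and
#'   a [labeled_alignment] is returned; unequal lengths are an error. If
#'   `FALSE`, unequal-length input is returned as a `labeled_seqs` list
#'   (fields `seqs`, `meta`).
#' @param lenient Passed to [labeled_alignment]; also tolerated for
#'   unaligned panels.
#' @param labels Optional path to a TSV sidecar or a data frame with columns
#'   `seq_id`, `species` and optionally `group`.
#' @return A `labeled_alignment`, or a `labeled_seqs` list when
#'   `aligned = FALSE` and lengths differ.
#' @export
read_labeled_fasta <- function(path, aligned = TRUE, lenient = FALSE,
                               labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, seqonly = FALSE),
    error = function(e) stop("empty or unreadable FASTA file: ", path,
                             call. = FALSE))
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- vapply(recs, function(r) attr(r, "name"), character(1L))
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1L], character(1L)))
  parsed <- t(vapply(headers, .parse_header, character(3L)))
  ids <- parsed[, 1L]
  species <- parsed[, 2L]
  group <- parsed[, 3L]
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!is.null(labels)) {
    tab <- if (is.character(labels))
      utils::read.delim(labels, stringsAsFactors = FALSE) else as.data.frame(labels)
    if (!all(c("seq_id", "species") %in% names(tab)))
      stop("label sidecar needs columns seq_id and species", call. = FALSE)
    idx <- match(ids, tab$seq_id)
    hit <- !is.na(idx)
    species[hit] <- tab$species[idx[hit]]
    if ("group" %in% names(tab)) group[hit] <- tab$group[idx[hit]]
  }
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) {
    return(labeled_alignment(seqs, species = species, group = group,
                             lenient = lenient))
  }
  if (aligned)
    stop("records in ", path, " have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "),
         ") but an alignment was requested", call. = FALSE)
  structure(list(
    seqs = seqs,
    meta = data.frame(seq_id = ids, species = species, group = group,
                      stringsAsFactors = FALSE)
  ), class = "labeled_seqs")
}

#' Write a labeled alignment (or sequence panel) to FASTA
#'
#' Inverse of [read_labeled_fasta]: headers are rebuilt from the metadata
#' with the pipe convention, trailing empty fields dropped, so that a
#' write/read round trip reproduces ids, labels and residues exactly.
#'
#' @param x A `labeled_alignment` or `labeled_seqs` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labeled_fasta <- function(x, path) {
  seqs <- if (inherits(x, "labeled_alignment"))
    apply(x$seq, 1L, paste, collapse = "") else x$seqs
  meta <- x$meta
  headers <- ifelse(nzchar(meta$group),
                    paste(meta$seq_id, meta$species, meta$group, sep = "|"),
                    ifelse(nzchar(meta$species),
                           paste(meta$seq_id, meta$species, sep = "|"),
                           meta$seq_id))
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", headers)
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

#' Per-column quality report for an alignment
#'
#' Report-only diagnostics: per-column gap fraction, ambiguity fraction
#' (non-gap residues outside `A/C/G/T`), and a flag for uninformative
#' all-gap columns.
#'
#' @param aln A `labeled_alignment`.
#' @return Data frame with columns `position`, `gap_fraction`,
#'   `ambiguity_fraction`, `all_gap`; the number of all-gap columns is in
#'   attribute `n_all_gap`.
#' @export
validate_alignment <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  mat <- aln$seq
  n <- nrow(mat)
  gap <- colSums(mat == "-") / n
  ambig <- colSums(matrix(!(mat %in% c(PURE_BASES, "-")), nrow(mat))) / n
  rep <- data.frame(position = seq_len(ncol(mat)),
                    gap_fraction = gap,
                    ambiguity_fraction = ambig,
                    all_gap = gap == 1)
  attr(rep, "n_all_gap") <- sum(rep$all_gap)
  rep
}

#' Majority-rule consensus mask
#'
#' A column receives a consensus symbol iff the modal symbol's frequency is
#' strictly greater than `threshold`; ties at the mode yield no consensus.
#' By default gaps are excluded from both the numerator and the denominator,
#' so the fraction is "share of non-gap residues agreeing"; set
#' `ignore_gaps = FALSE` to count gaps as ordinary symbols. Works for
#' nucleotide and amino-acid alignments alike.
#'
#' @param aln A `labeled_alignment`.
#' @param threshold Fraction in `[0, 1)`; default 0.5 (strict majority).
#' @param ignore_gaps Exclude `-` from the consensus denominator (default).
#' @return Data frame (class `consensus_mask`) with `position`, `consensus`
#'   (`NA` where no symbol clears the threshold, including all-gap columns)
#'   and `fraction` (the modal fraction, `NA` for all-gap columns).
#' @export
majority_consensus <- function(aln, threshold = 0.5, ignore_gaps = TRUE) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop("'threshold' must be a single number in [0, 1)", call. = FALSE)
  mat <- aln$seq
  res <- apply(mat, 2L, function(col) {
    if (ignore_gaps) col <- col[col != "-"]
    if (length(col) == 0L) return(c(NA_character_, NA_character_))
    tab <- table(col)
    top <- max(tab)
    frac <- top / length(col)
    modal <- names(tab)[tab == top]
    sym <- if (length(modal) == 1L && frac > threshold) modal else NA_character_
    c(sym, format(frac, digits = 15L))
  })
  out <- data.frame(position = seq_len(ncol(mat)),
                    consensus = res[1L, ],
                    fraction = as.numeric(res[2L, ]),
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_mask", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Subset an alignment by sequence id
#' @param aln A `labeled_alignment`.
#' @param ids Ids to keep, in the given order.
#' @return A `labeled_alignment`.
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(inherits(aln, "labeled_alignment"))
  missing <- setdiff(ids, aln$meta$seq_id)
  if (length(missing))
    stop("id(s) not in alignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(ids, aln$meta$seq_id)
  structure(list(seq = aln$seq[idx, , drop = FALSE],
                 meta = aln$meta[idx, , drop = FALSE]),
            class = "labeled_alignment")
}

#' Combine two alignments of equal length
#' @param a,b `labeled_alignment` objects with the same number of columns.
#' @return A `labeled_alignment`.
#' @export
bind_alignments <- function(a, b) {
  stopifnot(inherits(a, "labeled_alignment"), inherits(b, "labeled_alignment"))
  if (ncol(a$seq) != ncol(b$seq))
    stop("alignments differ in length", call. = FALSE)
  labeled_alignment(rbind(a$seq, b$seq),
                    species = c(a$meta$species, b$meta$species),
                    group = c(a$meta$group, b$meta$group))
}
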