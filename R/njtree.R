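# Neighbour-joining tree construction and Newick export.
#
# The tree machinery delegates to ape (the field-standard implementation of
# Saitou & Nei's agglomeration); this module enforces the contracts the
# rest of the package relies on: a complete matrix in, non-negative branch
# lengths out, and Newick labels quoted when they contain reserved
# characters.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ (iteratively joining the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, branch lengths by
#' the split formula). Negative estimated branch lengths are clamped to 0;
#' the total clamped deficit is recorded in attribute `clamped_deficit` and
#' messaged. Matrices with undefined entries are refused: exclude saturated
#' pairs upstream.
#'
#' @param m Complete symmetric distance matrix with dimnames, `n >= 3`.
#' @return An unrooted `phylo` object (see \pkg{ape}).
#' @export
neighbor_joining <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop("'m' must be a square numeric matrix", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 sequences for NJ", call. = FALSE)
  if (is.null(rownames(m))) stop("'m' must have ids as dimnames", call. = FALSE)
  if (anyNA(m))
    stop("distance matrix has undefined entries; exclude saturated or ",
         "zero-overlap pairs before tree construction", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("'m' must be symmetric", call. = FALSE)
  phy <- ape::nj(m)
  neg <- phy$edge.length < 0
  deficit <- 0
  if (any(neg)) {
    deficit <- -sum(phy$edge.length[neg])
    phy$edge.length[neg] <- 0
    message("clamped ", sum(neg), " negative branch length(s); total deficit ",
            format(deficit, digits = 4))
  }
  attr(phy, "clamped_deficit") <- deficit
  phy
}

.needs_quoting <- function(lab) grepl("[][ \t,():;'\"]", lab)

.quote_label <- function(lab) {
  # Newick quoting: wrap in single quotes, double any internal quote
  paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
}

#' Serialize a tree as a Newick string
#'
#' Branch lengths are retained; an unrooted tree is written with its
#' customary trifurcating root. Labels containing Newick-reserved
#' characters (whitespace, commas, parentheses, colons, semicolons,
#' brackets, quotes) are single-quoted per the Newick convention — which
#' `ape::write.tree` alone would instead mangle to underscores.
#'
#' @param phy A `phylo` object.
#' @param path Optional file; when given the string is also written there.
#' @return Newick string (length-1 character).
#' @export
to_newick <- function(phy, path = NULL) {
  stopifnot(inherits(phy, "phylo"))
  labs <- phy$tip.label
  tmp <- phy
  token <- sprintf("zZq%dqZz", seq_along(labs))
  tmp$tip.label <- token
  s <- ape::write.tree(tmp)
  for (i in seq_along(labs)) {
    out_lab <- if (.needs_quoting(labs[i])) .quote_label(labs[i]) else labs[i]
    s <- gsub(token[i], out_lab, s, fixed = TRUE)
  }
  if (!is.null(path)) writeLines(s, path)
  s
}

#' Parse a Newick string or file
#' @param text Newick string, or `NULL` when `path` is given.
#' @param path Optional file to read from.
#' @return A `phylo` object.
#' @export
from_newick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}
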