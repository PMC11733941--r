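# The DMDGP vertex order for a Pro/Gly-free backbone: residue 1 contributes
# (N, HA, C, CA); every later residue contributes (H, N, CA, HA, C), and each
# intermediary residue repeats its CA immediately after the C so that the
# peptide-plane distances keep the order discretizable. Vertices from
# position 4 onward use exactly the three immediately preceding positions as
# reference atoms.

ATOM_KINDS <- c("N", "CA", "C", "H", "HA")

#' Build the backbone DMDGP vertex order
#'
#' Constructs the vertex order for an `n_residues`-residue proline- and
#' glycine-free backbone over the atoms N, CA, C, H, HA. The order has length
#' `6 * n_residues - 3`: residue 1 contributes (N, HA, C, CA) at positions
#' 1--4, each residue `i >= 2` contributes (H, N, CA, HA, C), and each
#' intermediary residue (`2 <= i <= n - 1`) additionally repeats its CA right
#' after its C. Every vertex at position `t >= 4` has reference positions
#' `(t - 1, t - 2, t - 3)`.
#'
#' @param n_residues Number of residues (at least 2).
#' @return An object of class `bb_order`: a data frame with columns
#'   `position`, `kind`, `residue`, `is_repeat`, `ref1`, `ref2`, `ref3`
#'   (references are `NA` for positions 1--3) and attribute `n_residues`.
#' @examples
#' ord <- build_order(3)
#' ord[ord$position %in% c(2, 10, 11), ]
#' @export
build_order <- function(n_residues) {
  if (!is.numeric(n_residues) || length(n_residues) != 1L ||
      n_residues != round(n_residues) || n_residues < 2)
    stop("invalid-argument: 'n_residues' must be an integer >= 2")
  n <- as.integer(n_residues)
  kind <- c("N", "HA", "C", "CA")
  residue <- rep(1L, 4L)
  is_rep <- rep(FALSE, 4L)
  for (i in 2:n) {
    block_kind <- c("H", "N", "CA", "HA", "C")
    block_rep <- rep(FALSE, 5L)
    if (i < n) { # intermediary residue: repeat CA after C
      block_kind <- c(block_kind, "CA")
      block_rep <- c(block_rep, TRUE)
    }
    kind <- c(kind, block_kind)
    residue <- c(residue, rep(i, length(block_kind)))
    is_rep <- c(is_rep, block_rep)
  }
  np <- length(kind)
  stopifnot(np == 6L * n - 3L)
  out <- data.frame(
    position = seq_len(np),
    kind = kind,
    residue = residue,
    is_repeat = is_rep,
    ref1 = c(NA_integer_, NA_integer_, NA_integer_, seq_len(np - 3L) + 2L),
    ref2 = c(NA_integer_, NA_integer_, NA_integer_, seq_len(np - 3L) + 1L),
    ref3 = c(NA_integer_, NA_integer_, NA_integer_, seq_len(np - 3L)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_residues") <- n
  class(out) <- c("bb_order", "data.frame")
  out
}

#' @export
print.bb_order <- function(x, ...) {
  cat("Backbone DMDGP order:", attr(x, "n_residues"), "residues,",
      nrow(x), "vertices (", sum(x$is_repeat), "repeated CA )\n")
  print.data.frame(utils::head(as.data.frame(x), 12L), row.names = FALSE)
  if (nrow(x) > 12L) cat("... (", nrow(x) - 12L, " more vertices)\n", sep = "")
  invisible(x)
}

# position of a (kind, residue) pair; first occurrence unless repeat = TRUE
order_position <- function(order, kind, residue, repeat_occurrence = FALSE) {
  hit <- which(order$kind == kind & order$residue == residue &
                 order$is_repeat == repeat_occurrence)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Classify a pruning edge by its endpoint atoms and span
#'
#' Edge-type label of the segment from position `i` to `j` in the order:
#' `"KINDi-L-KINDj"` where `L = j - i + 1` is the number of order vertices the
#' segment spans. For example the edge joining the alpha-hydrogen at position
#' 2 to the amide hydrogen at position 11 of a 3-residue order is `"HA-10-H"`.
#'
#' @param order A [build_order()] object.
#' @param i,j Endpoint positions, `1 <= i < j <= nrow(order)`.
#' @return A character scalar label.
#' @export
classify_edge <- function(order, i, j) {
  if (!(is.numeric(i) && is.numeric(j) && i >= 1 && j <= nrow(order) && i < j))
    stop("invalid-argument: need 1 <= i < j <= ", nrow(order))
  paste0(order$kind[i], "-", j - i + 1L, "-", order$kind[j])
}

#' Relevant bit positions of a pruning edge
#'
#' For a pruning edge `(i, j)` only the orientation bits at positions
#' `i + 3, ..., j` can change the distance between vertices `i` and `j`;
#' these are the edge's relevant positions (there are `j - i - 2` of them).
#'
#' @param i,j Endpoint positions with `j >= i + 3`.
#' @return Integer vector `(i + 3):j`.
#' @export
relevant_positions <- function(i, j) {
  if (!(is.numeric(i) && is.numeric(j) && j >= i + 3))
    stop("invalid-argument: a pruning edge needs j >= i + 3 (no searchable bits)")
  as.integer(seq.int(i + 3L, j))
}

#' Export a backbone order as TSV
#'
#' Writes one line per vertex: position, atom kind, residue index, repeat
#' flag and the three reference positions.
#'
#' @param order A [build_order()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_order_tsv <- function(order, path) {
  utils::write.table(as.data.frame(order), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
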