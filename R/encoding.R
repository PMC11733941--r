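# Binary representation of backbone conformations. Each vertex from
# position 4 onward gets an orientation bit relative to the plane of its
# three immediate predecessors; the first three bits are 0 by convention,
# repeated vertices carry a fixed 0, and the whole string is normalized so
# that bit 4 is 0 (the two mirror solutions through the plane of the first
# three atoms are identified). Dropping the four fixed leading bits gives
# the reduced representation.

new_bits <- function(bits, offset = 1L, free = NULL, repeated = NULL) {
  bits <- as.integer(bits)
  n <- length(bits)
  if (is.null(free)) free <- rep(TRUE, n)
  if (is.null(repeated)) repeated <- rep(FALSE, n)
  stopifnot(all(bits %in% c(0L, 1L)), length(free) == n, length(repeated) == n)
  structure(list(bits = bits, offset = as.integer(offset), free = free,
                 repeated = repeated), class = "dmdgp_bits")
}

#' @export
print.dmdgp_bits <- function(x, ...) {
  cat("Bit string (offset ", x$offset, "): ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.dmdgp_bits <- function(x, ...) paste(x$bits, collapse = "")

#' @export
length.dmdgp_bits <- function(x) length(x$bits)

#' Encode a conformation as a global bit string
#'
#' Bits 1--3 are 0; every later vertex records the orientation of its point
#' relative to the plane of its three immediate predecessors. Repeated
#' vertices and on-plane (degenerate) vertices record a fixed 0 and are
#' flagged as non-free. By default the result is normalized (bit 4 equal 0,
#' see [normalize_bits()]), which identifies a conformation with its mirror
#' image through the plane of the first three atoms; pass
#' `normalize = FALSE` for the raw geometric bits, for which
#' `decode(encode(conf))` reproduces any canonical-frame conformation.
#'
#' @param conf A `dmdgp_conformation`.
#' @param tol On-plane tolerance (Angstrom^3) for the orientation bit; use
#'   around `1e-3` for experimental coordinates.
#' @param normalize Apply [normalize_bits()] to the result (default).
#' @return A `dmdgp_bits` object with offset 1.
#' @export
encode <- function(conf, tol = 1e-7, normalize = TRUE) {
  X <- conf$coords
  order <- conf$order
  np <- nrow(order)
  bits <- integer(np)
  free <- rep(FALSE, np)
  repeated <- order$is_repeat
  for (t in 4:np) {
    if (repeated[t]) next
    ref <- X[c(t - 1L, t - 2L, t - 3L), , drop = FALSE]
    .check_ref(ref)
    v <- .signed_volume(ref, X[t, ])
    if (abs(v) > tol) {
      bits[t] <- if (v > 0) 1L else 0L
      free[t] <- TRUE
    } # on-plane: fixed 0
  }
  out <- new_bits(bits, 1L, free, repeated)
  if (normalize) normalize_bits(out) else out
}

#' Normalize a global bit string
#'
#' If bit 4 is 1, flips every free bit from position 4 onward (repeated and
#' degenerate positions keep their fixed value); this identifies each
#' solution with its mirror image through the plane of the first three
#' atoms. Idempotent; the output has bit 4 equal 0.
#'
#' @param b A global `dmdgp_bits` (offset 1).
#' @return A normalized `dmdgp_bits`.
#' @export
normalize_bits <- function(b) {
  stopifnot(inherits(b, "dmdgp_bits"))
  if (b$offset != 1L) stop("invalid-argument: normalization needs a global string")
  if (b$bits[4L] == 1L) {
    sel <- seq_along(b$bits) >= 4L & b$free & !b$repeated
    b$bits[sel] <- 1L - b$bits[sel]
  }
  b
}

#' Reduce a normalized global bit string
#'
#' Drops the four fixed leading bits; the offset of the result is 5.
#'
#' @param b A normalized global `dmdgp_bits`.
#' @return A `dmdgp_bits` with offset 5.
#' @export
reduce_bits <- function(b) {
  stopifnot(inherits(b, "dmdgp_bits"))
  if (b$offset != 1L || b$bits[4L] != 0L)
    stop("contract error: reduce_bits needs a normalized global string")
  keep <- -(1:4)
  new_bits(b$bits[keep], 5L, b$free[keep], b$repeated[keep])
}

#' Decode a bit string into a conformation
#'
#' Places the first three vertices canonically, copies repeated vertices
#' from their first occurrence and realizes every other vertex by
#' trilateration from its three predecessors, choosing between two
#' intersection points by the stored bit; degenerate positions take the
#' single point regardless of the stored bit.
#'
#' @param b A global `dmdgp_bits` (offset 1) whose length matches the order.
#' @param instance A `dmdgp_instance` satisfying H1-H2.
#' @param tol_disc Trilateration degeneracy tolerance (Angstrom).
#' @return A `dmdgp_conformation` in the canonical frame.
#' @export
decode <- function(b, instance, tol_disc = 1e-4) {
  stopifnot(inherits(b, "dmdgp_bits"))
  np <- nrow(instance$order)
  if (b$offset != 1L || length(b$bits) != np)
    stop("invalid-argument: need a global bit string of length ", np)
  ctx <- .instance_ctx(instance, tol_disc)
  X <- .realize_bits(ctx, b$bits)
  new_conformation(instance$order, X)
}

#' Relevant-bit restriction of a global string to a pruning edge
#'
#' @param b A global `dmdgp_bits` (offset 1).
#' @param i,j Edge endpoints with `j >= i + 3`.
#' @return A `dmdgp_bits` over positions `i + 3, ..., j`, offset `i + 3`.
#' @export
edge_sequence <- function(b, i, j) {
  stopifnot(inherits(b, "dmdgp_bits"))
  if (b$offset != 1L) stop("invalid-argument: need a global string")
  pos <- relevant_positions(i, j)
  new_bits(b$bits[pos], pos[1L], b$free[pos], b$repeated[pos])
}

#' Invert an edge sequence (complete flip)
#'
#' Flips every free bit of the sequence; repeated-vertex and degenerate
#' positions keep their fixed value. An involution. By the mirror symmetry
#' of the discretizable order, the flip of a feasible edge sequence is the
#' only other feasible sequence for that edge.
#'
#' @param seq_bits A `dmdgp_bits` (edge restriction).
#' @return The flipped `dmdgp_bits`.
#' @export
flip_bits <- function(seq_bits) {
  stopifnot(inherits(seq_bits, "dmdgp_bits"))
  sel <- seq_bits$free & !seq_bits$repeated
  seq_bits$bits[sel] <- 1L - seq_bits$bits[sel]
  seq_bits
}

#' Write / read a bit string as ASCII text
#'
#' A `#` header line carries the length and offset; the second line holds
#' the 0/1 characters. Free/repeat flags are not serialized; they can be
#' reconstructed from an instance via [position_info()] if `instance` is
#' supplied to the reader.
#'
#' @param b A `dmdgp_bits`.
#' @param path File path.
#' @param instance Optional `dmdgp_instance` used to restore position flags.
#' @return `path` (writer) or a `dmdgp_bits` (reader).
#' @export
write_bits <- function(b, path) {
  writeLines(c(sprintf("#length=%d offset=%d", length(b$bits), b$offset),
               as.character(b)), path)
  invisible(path)
}

#' @rdname write_bits
#' @export
read_bits <- function(path, instance = NULL) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1L], regexec("#length=(\\d+) offset=(\\d+)", lines[1L]))[[1L]]
  if (length(hdr) != 3L) stop("parse error: malformed bit-string header")
  bits <- as.integer(strsplit(lines[2L], "")[[1L]])
  if (length(bits) != as.integer(hdr[2L]))
    stop("parse error: bit count disagrees with header")
  offset <- as.integer(hdr[3L])
  free <- NULL; repeated <- NULL
  if (!is.null(instance)) {
    pt <- position_info(instance)
    pos <- seq.int(offset, length.out = length(bits))
    free <- pt[pos] == "free"
    repeated <- pt[pos] == "repeat"
  }
  new_bits(bits, offset, free, repeated)
}
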