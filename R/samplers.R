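# Bit samplers drive the branch choices of the synthetic generator. A
# sampler is a function of the order position that returns 0 or 1; it is
# consulted only at free positions (two sphere-intersection points), in
# increasing position order. Repeated and degenerate (forced) positions
# consume no random bits.

#' Fair-coin bit sampler
#'
#' Each free position independently receives 0 or 1 with probability 1/2
#' from the current RNG stream.
#'
#' @return A sampler function for [sample_conformation()].
#' @export
bit_sampler_fair <- function() {
  function(position) sample(c(0L, 1L), 1L)
}

#' Fixed-bit sampler
#'
#' Returns predetermined bits: `bits` may be a full vector indexed by order
#' position (entries at non-free positions are ignored) or a named vector
#' keyed by position. Unspecified free positions get `default`.
#'
#' @param bits Integer vector of 0/1 (positional or named by order position).
#' @param default Bit used for free positions not covered by `bits`.
#' @return A sampler function for [sample_conformation()].
#' @export
bit_sampler_fixed <- function(bits, default = 0L) {
  if (is.null(names(bits))) {
    function(position) {
      if (position <= length(bits) && !is.na(bits[position]))
        as.integer(bits[position]) else as.integer(default)
    }
  } else {
    function(position) {
      key <- as.character(position)
      if (key %in% names(bits)) as.integer(bits[[key]]) else as.integer(default)
    }
  }
}

#' Planted sequence-law sampler for one edge type
#'
#' Plants a known distribution over relevant-bit sequences of the pruning
#' edges of one edge-type family, so that frequency-recovery experiments
#' have a ground truth. When generation reaches the first position of a
#' window of `type_label` (windows computed from `order` and the family
#' definition in [pruning_policy_edges()]), a whole sequence is drawn from
#' `(sequences, probs)` and its bits are replayed for the free positions of
#' that window; free positions outside any window fall back to a fair coin.
#'
#' Overlapping windows replay whichever window opened first; planting is
#' exact when the windows of the chosen family are disjoint or share only
#' already-consistent bits.
#'
#' @param order A [build_order()] object.
#' @param type_label Edge-type label, e.g. `"HA-10-H"`.
#' @param sequences Character vector of 0/1 strings, one per window length.
#' @param probs Probabilities, same length as `sequences` (normalized
#'   internally).
#' @return A sampler function for [sample_conformation()]; the attribute
#'   `"law"` records the planted distribution.
#' @export
bit_sampler_seq_law <- function(order, type_label, sequences, probs) {
  stopifnot(length(sequences) == length(probs), all(probs >= 0), sum(probs) > 0)
  probs <- probs / sum(probs)
  wins <- pruning_policy_edges(order, type_label)
  if (nrow(wins) == 0L) stop("invalid-argument: no edges of type ", type_label)
  wlen <- wins$j[1L] - wins$i[1L] - 2L
  if (any(nchar(sequences) != wlen))
    stop("invalid-argument: sequences must have the window length ", wlen)
  starts <- wins$i + 3L
  pending <- new.env(parent = emptyenv())
  f <- function(position) {
    key <- as.character(position)
    if (!is.null(pending[[key]])) {
      b <- pending[[key]]
      rm(list = key, envir = pending)
      return(b)
    }
    w <- which(starts == position)
    if (length(w) == 1L) {
      s <- sample(seq_along(sequences), 1L, prob = probs)
      bits <- as.integer(strsplit(sequences[s], "")[[1L]])
      pos <- seq.int(wins$i[w] + 3L, wins$j[w])
      for (k in seq_along(pos)[-1L]) pending[[as.character(pos[k])]] <- bits[k]
      return(bits[1L])
    }
    sample(c(0L, 1L), 1L)
  }
  attr(f, "law") <- list(type = type_label, sequences = sequences, probs = probs)
  f
}
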