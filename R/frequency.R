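# Frequency tables for the frequency-based search: per edge-type ranked
# lists of relevant-bit sequences with counts and probabilities, trained
# from solved segments, plus the accumulated-probability curves and the
# sequence-space accounting.

#' Split items into training and test sets
#'
#' Deterministic seeded shuffle; the training set takes
#' `ceiling(ratio * N)` items, the test set the remainder. The two parts
#' are disjoint and exhaust the input.
#'
#' @param x A list or vector of items.
#' @param ratio Training fraction in (0, 1); 0.8 gives the usual 80/20 split.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(x, ratio = 0.8, seed = 1L) {
  n <- length(x)
  if (n == 0L) stop("invalid-argument: empty input")
  if (!(ratio > 0 && ratio < 1)) stop("invalid-argument: ratio must be in (0,1)")
  set.seed(seed)
  perm <- sample.int(n)
  ntr <- ceiling(ratio * n)
  list(train = x[perm[seq_len(ntr)]],
       test = x[perm[setdiff(seq_len(n), seq_len(ntr))]])
}

#' Train a frequency table from solved instances
#'
#' For every pruning edge of every solution the relevant-bit sequence is
#' extracted and tallied under the edge-type label. Within a type the
#' sequences are ranked by descending count, ties broken lexicographically
#' (0 before 1); probabilities are counts over the type total.
#'
#' @param bits_list List of global `dmdgp_bits` (e.g. solver or encoder
#'   output).
#' @param edges_list List (parallel to `bits_list`) of pruning-edge lists as
#'   returned by [pruning_edges()].
#' @param meta Optional named list of metadata (training size, seed, ...)
#'   stored on the table.
#' @return A `dmdgp_freq` object: data frame `table` with columns
#'   `edge_type`, `sequence`, `count`, `probability`, `rank`, plus `meta`.
#' @export
build_freq_table <- function(bits_list, edges_list, meta = list()) {
  stopifnot(length(bits_list) == length(edges_list))
  types <- character(0)
  seqs <- character(0)
  for (k in seq_along(bits_list)) {
    b <- bits_list[[k]]
    for (e in edges_list[[k]]) {
      types <- c(types, e$type)
      seqs <- c(seqs, as.character(edge_sequence(b, e$i, e$j)))
    }
  }
  if (length(types)) {
    lens <- tapply(nchar(seqs), types, function(v) length(unique(v)))
    if (any(lens != 1L))
      stop("data error: inconsistent sequence lengths within an edge type")
  }
  tab <- if (length(types) == 0L) {
    data.frame(edge_type = character(), sequence = character(),
               count = integer(), probability = numeric(), rank = integer(),
               stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(count = seq_along(seqs)),
                            by = list(edge_type = types, sequence = seqs),
                            FUN = length)
    parts <- lapply(split(agg, agg$edge_type), function(g) {
      g <- g[order(-g$count, g$sequence), , drop = FALSE]
      g$probability <- g$count / sum(g$count)
      g$rank <- seq_len(nrow(g))
      g
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  meta$n_solutions <- length(bits_list)
  structure(list(table = tab, meta = meta), class = "dmdgp_freq")
}

#' @export
print.dmdgp_freq <- function(x, ...) {
  cat("Frequency table:", length(unique(x$table$edge_type)), "edge types,",
      nrow(x$table), "distinct sequences (trained on",
      x$meta$n_solutions, "solutions)\n")
  for (ty in unique(x$table$edge_type)) {
    g <- x$table[x$table$edge_type == ty, ]
    cat(sprintf("  %-10s k=%d, top: %s (p=%.3f)\n", ty, nrow(g),
                g$sequence[1L], g$probability[1L]))
  }
  invisible(x)
}

# ranked candidate sequences of one type (character vector, possibly empty)
freq_sequences <- function(table, type_label) {
  stopifnot(inherits(table, "dmdgp_freq"))
  g <- table$table[table$table$edge_type == type_label, , drop = FALSE]
  g$sequence[order(g$rank)]
}

#' Sequence-space size of an edge type
#'
#' Number of mathematically possible distinct relevant-bit sequences for an
#' edge type with relevant length `L` (the middle number of the label minus
#' 3). The default accounting counts one bit per independent-edge sequence
#' as non-free -- the exhaustive search emits one representative of each
#' flip pair, pinning its first free bit -- giving `2^(L-1)`; `raw = TRUE`
#' returns the unaccounted `2^L`.
#'
#' @param type_label Label such as `"HA-10-H"`.
#' @param raw If `TRUE`, return `2^L` instead of `2^(L-1)`.
#' @return Integer count.
#' @export
kmax <- function(type_label, raw = FALSE) {
  parts <- strsplit(type_label, "-", fixed = TRUE)[[1L]]
  span <- suppressWarnings(as.integer(parts[2L]))
  if (length(parts) != 3L || is.na(span))
    stop("invalid-argument: malformed edge-type label ", type_label)
  L <- span - 3L
  if (L < 1L) stop("invalid-argument: edge type ", type_label, " has no relevant bits")
  as.integer(2^(if (raw) L else L - 1L))
}

#' Accumulated-probability curve of an edge type
#'
#' Maps the k-th ranked sequence to the normalized index `k / K` (K the
#' number of distinct sequences of the type) and accumulates the ranked
#' probabilities; a peaked distribution majorizes the uniform diagonal.
#'
#' @param table A `dmdgp_freq`.
#' @param type_label Edge-type label present in the table.
#' @return Data frame with columns `index` in (0, 1] and `cumulative`.
#' @export
accumulated_curve <- function(table, type_label) {
  g <- table$table[table$table$edge_type == type_label, , drop = FALSE]
  if (nrow(g) == 0L) stop("lookup error: no sequences of type ", type_label)
  g <- g[order(g$rank), ]
  data.frame(index = seq_len(nrow(g)) / nrow(g),
             cumulative = cumsum(g$probability))
}

#' Plot accumulated-probability curves
#'
#' One curve per edge type against the normalized rank index, with the
#' uniform-distribution diagonal dashed.
#'
#' @param x A `dmdgp_freq`.
#' @param types Edge types to draw (default all in the table).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dmdgp_freq <- function(x, types = unique(x$table$edge_type), ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "normalized sequence index",
                 ylab = "accumulated probability", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  for (k in seq_along(types)) {
    cv <- accumulated_curve(x, types[k])
    graphics::lines(c(0, cv$index), c(0, cv$cumulative), type = "s", col = k)
  }
  graphics::legend("bottomright", legend = types, col = seq_along(types),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Write / read a frequency table as CSV
#'
#' Columns: `edge_type`, `sequence`, `count`, `probability`, `rank`.
#' Sequences are quoted to protect leading zeros.
#'
#' @param table A `dmdgp_freq`.
#' @param path File path.
#' @return `path` (writer) or a `dmdgp_freq` (reader).
#' @export
write_freq_csv <- function(table, path) {
  utils::write.csv(table$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_freq_csv
#' @export
read_freq_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(edge_type = "character",
                                             sequence = "character"))
  structure(list(table = df, meta = list(n_solutions = NA_integer_)),
            class = "dmdgp_freq")
}

#' Export accumulated curves as CSV
#'
#' Columns: `edge_type`, `index`, `cumulative_probability`.
#'
#' @param table A `dmdgp_freq`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(table, path) {
  types <- unique(table$table$edge_type)
  rows <- do.call(rbind, lapply(types, function(ty) {
    cv <- accumulated_curve(table, ty)
    data.frame(edge_type = ty, index = cv$index,
               cumulative_probability = cv$cumulative)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
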