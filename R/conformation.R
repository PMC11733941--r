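# Synthetic backbone conformations. A conformation couples a backbone order
# with one 3-D coordinate per order position; repeated vertices carry the
# coordinates of their first occurrence.

new_conformation <- function(order, coords, params = NULL, seed = NULL) {
  stopifnot(nrow(coords) == nrow(order), ncol(coords) == 3L)
  structure(list(order = order, coords = coords, params = params, seed = seed),
            class = "dmdgp_conformation")
}

#' @export
print.dmdgp_conformation <- function(x, ...) {
  cat("Backbone conformation:", attr(x$order, "n_residues"), "residues,",
      nrow(x$coords), "order vertices\n")
  invisible(x)
}

#' Sample an idealized backbone conformation
#'
#' Builds the DMDGP order for `n_residues`, derives a mutually consistent
#' discretization-distance set from the rigid-geometry parameters, places
#' the first three vertices in the canonical frame and realizes every later
#' vertex by three-sphere trilateration from its three immediate
#' predecessors. Where the intersection has two points the choice is made by
#' `bit_sampler`; degenerate positions (single intersection, e.g. atoms
#' forced into an exactly planar peptide unit) and repeated vertices consume
#' no random bits. Identical seeds give identical conformations.
#'
#' @param n_residues Number of residues (>= 2).
#' @param params A [geometry_params()] object.
#' @param bit_sampler A sampler function (see [bit_sampler_fair()]); default
#'   fair coin per free position.
#' @param seed Optional integer seed applied before jitter and bit draws.
#' @param tol_disc Trilateration tolerance (Angstrom) deciding degeneracy.
#' @return A `dmdgp_conformation`.
#' @examples
#' conf <- sample_conformation(3, seed = 1)
#' @export
sample_conformation <- function(n_residues, params = geometry_params(),
                                bit_sampler = NULL, seed = NULL,
                                tol_disc = 1e-4) {
  order <- build_order(n_residues)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bit_sampler)) bit_sampler <- bit_sampler_fair()
  chain <- build_reference_chain(n_residues, params)
  dd <- reference_distances(order, chain)
  dget <- .dist_lookup(dd, nrow(order))
  np <- nrow(order)
  X <- matrix(NA_real_, np, 3L)
  X[1:3, ] <- place_first_three(dget(1L, 2L), dget(1L, 3L), dget(2L, 3L))
  first_occ <- .first_occurrence(order)
  for (t in 4:np) {
    if (order$is_repeat[t]) {
      X[t, ] <- X[first_occ[t], ]
      next
    }
    pts <- trilaterate(X[t - 1L, ], X[t - 2L, ], X[t - 3L, ],
                       dget(t - 1L, t), dget(t - 2L, t), dget(t - 3L, t),
                       tol = tol_disc)
    if (length(pts) == 0L)
      stop("infeasible-geometry: no sphere intersection at position ", t)
    if (length(pts) == 1L) {
      X[t, ] <- pts[[1L]]
    } else {
      b <- as.integer(bit_sampler(t))
      X[t, ] <- if (b == 1L) pts[[1L]] else pts[[2L]]
    }
  }
  new_conformation(order, X, params = params, seed = seed)
}

# position of the first occurrence backing each repeated vertex
.first_occurrence <- function(order) {
  out <- rep(NA_integer_, nrow(order))
  for (t in which(order$is_repeat))
    out[t] <- order_position(order, order$kind[t], order$residue[t], FALSE)
  out
}

# closure over a sparse symmetric distance table
.dist_lookup <- function(dd, np) {
  key <- dd$i + np * dd$j
  val <- dd$value
  names(val) <- as.character(key)
  function(i, j) {
    if (i > j) { k <- i; i <- j; j <- k }
    v <- val[[as.character(i + np * j)]]
    if (is.null(v)) NA_real_ else v
  }
}

#' Write / read conformation coordinates as TSV
#'
#' Columns: position, kind, residue, x, y, z (Angstrom, 6 decimals).
#'
#' @param conf A `dmdgp_conformation`.
#' @param path File path.
#' @return `path` (writer) or a `dmdgp_conformation` (reader).
#' @export
write_coords_tsv <- function(conf, path) {
  df <- data.frame(position = conf$order$position,
                   kind = conf$order$kind,
                   residue = conf$order$residue,
                   x = sprintf("%.6f", conf$coords[, 1L]),
                   y = sprintf("%.6f", conf$coords[, 2L]),
                   z = sprintf("%.6f", conf$coords[, 3L]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coords_tsv
#' @export
read_coords_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  n <- (nrow(df) + 3L) / 6L
  order <- build_order(n)
  if (!identical(order$kind, df$kind) || !identical(order$residue, as.integer(df$residue)))
    stop("parse error: coordinates do not follow the backbone order")
  new_conformation(order, cbind(df$x, df$y, df$z))
}
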