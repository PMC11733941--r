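# DMDGP instances: a backbone order plus exact distance restraints. Every
# vertex from position 4 onward carries its three discretization restraints
# (hypothesis H2) and the first three vertices form a clique (H1); pruning
# restraints come from the configurable edge-family policy.

#' Default pruning-edge policy
#'
#' The three edge families whose distances are available on an idealized
#' backbone: consecutive alpha-hydrogens (`HA-7-HA`), alpha-hydrogen to the
#' amide hydrogen two residues on (`HA-10-H`), both NMR-detectable, and
#' carboxyl carbon to the next first-occurrence alpha-carbon (`C-5-CA`),
#' fixed by peptide-plane geometry.
#'
#' @return Character vector of edge-type labels.
#' @export
default_policy <- function() c("HA-7-HA", "HA-10-H", "C-5-CA")

#' Enumerate the pruning edges of one family
#'
#' @param order A [build_order()] object.
#' @param type_label One of the labels in [default_policy()].
#' @return Data frame with columns `i`, `j` (order positions), one row per
#'   residue index where both endpoints exist.
#' @export
pruning_policy_edges <- function(order, type_label) {
  n <- attr(order, "n_residues")
  ij <- switch(type_label,
    "HA-7-HA" = lapply(seq_len(n - 1L), function(r)
      c(order_position(order, "HA", r), order_position(order, "HA", r + 1L))),
    "HA-10-H" = if (n >= 3L) lapply(seq_len(n - 2L), function(r)
      c(order_position(order, "HA", r), order_position(order, "H", r + 2L)))
      else list(),
    "C-5-CA" = lapply(seq_len(n - 1L), function(r)
      c(order_position(order, "C", r), order_position(order, "CA", r + 1L))),
    stop("invalid-argument: unknown edge family ", type_label)
  )
  if (length(ij) == 0L) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, ij)
  data.frame(i = m[, 1L], j = m[, 2L])
}

#' Build a DMDGP instance from a conformation
#'
#' Emits the three discretization restraints of every vertex `t >= 4` plus
#' the pairwise distances of the first three vertices, all measured from the
#' conformation's coordinates, and a pruning restraint for every edge of the
#' requested families. The generating conformation satisfies every restraint
#' by construction (planted solution).
#'
#' @param conf A `dmdgp_conformation`.
#' @param policy Character vector of edge-family labels (see
#'   [default_policy()]); `character(0)` emits no pruning restraints.
#' @return A `dmdgp_instance`.
#' @export
build_instance <- function(conf, policy = default_policy()) {
  order <- conf$order
  X <- conf$coords
  np <- nrow(order)
  ii <- c(1L, 1L, 2L); jj <- c(2L, 3L, 3L)
  for (t in 4:np) { ii <- c(ii, t - 1L, t - 2L, t - 3L); jj <- c(jj, t, t, t) }
  role <- rep("discretization", length(ii))
  for (fam in policy) {
    pe <- pruning_policy_edges(order, fam)
    if (nrow(pe)) {
      ii <- c(ii, pe$i); jj <- c(jj, pe$j)
      role <- c(role, rep("pruning", nrow(pe)))
    }
  }
  val <- sqrt(rowSums((X[ii, , drop = FALSE] - X[jj, , drop = FALSE])^2))
  restraints <- data.frame(
    i = ii, j = jj, value = val, role = role,
    kind_i = order$kind[ii], kind_j = order$kind[jj],
    res_i = order$residue[ii], res_j = order$residue[jj],
    stringsAsFactors = FALSE)
  new_instance(order, restraints)
}

new_instance <- function(order, restraints) {
  inst <- structure(list(order = order, restraints = restraints),
                    class = "dmdgp_instance")
  validate_instance(inst)
  inst
}

#' Validate the structural hypotheses of an instance
#'
#' Checks that the first three vertices form a distance clique (H1), that
#' every vertex from position 4 onward has its three discretization
#' restraints (H2), that discretization restraints span at most three
#' positions, and that values are non-negative (zero only between a repeated
#' vertex and its first occurrence). The first violating vertex is named.
#'
#' @param instance A `dmdgp_instance`.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_instance <- function(instance) {
  r <- instance$restraints
  order <- instance$order
  np <- nrow(order)
  if (any(r$i >= r$j)) stop("model error: restraints must have i < j")
  if (any(!is.finite(r$value)) || any(r$value < 0))
    stop("model error: restraint values must be finite and non-negative")
  d <- r[r$role == "discretization", ]
  if (any(d$j - d$i > 3L))
    stop("model error: discretization restraint spanning more than 3 positions")
  key <- paste(r$i, r$j)
  for (pr in list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
    if (!(paste(pr[1L], pr[2L]) %in% key))
      stop("model error: H1 violated, missing distance (", pr[1L], ",", pr[2L], ")")
  for (t in 4:np)
    for (k in 1:3)
      if (!(paste(t - k, t) %in% key))
        stop("model error: H2 violated at vertex ", t,
             " (missing distance to predecessor ", t - k, ")")
  z <- r[r$value == 0, ]
  if (nrow(z)) {
    fo <- .first_occurrence(order)
    ok <- order$is_repeat[z$j] & fo[z$j] == z$i
    if (!all(ok))
      stop("model error: zero distance outside a repeated-vertex pair at vertex ",
           z$j[!ok][1L])
  }
  invisible(TRUE)
}

#' @export
print.dmdgp_instance <- function(x, ...) {
  r <- x$restraints
  cat("DMDGP instance:", attr(x$order, "n_residues"), "residues,",
      nrow(x$order), "vertices;", sum(r$role == "discretization"),
      "discretization and", sum(r$role == "pruning"), "pruning restraints\n")
  invisible(x)
}

#' @export
summary.dmdgp_instance <- function(object, ...) {
  pe <- pruning_edges(object)
  types <- vapply(pe, function(e) e$type, character(1L))
  pi <- position_info(object)
  out <- list(n_residues = attr(object$order, "n_residues"),
              n_vertices = nrow(object$order),
              pruning_types = table(types),
              free_bits = sum(pi == "free"))
  cat("DMDGP instance summary\n")
  cat("  residues:", out$n_residues, " vertices:", out$n_vertices,
      " free bits:", out$free_bits, "\n")
  if (length(types)) { cat("  pruning edges by type:\n"); print(out$pruning_types) }
  invisible(out)
}

# --- restraint TSV dialect -------------------------------------------------

#' Write / read a DMDGP instance in the restraint TSV dialect
#'
#' One restraint per line: `i <tab> j <tab> value <tab> role <tab> kind_i
#' <tab> kind_j <tab> res_i <tab> res_j`, preceded by a `#` header line.
#' The reader validates hypotheses H1/H2 and reports the first violating
#' vertex; malformed lines raise a parse error with their line number.
#'
#' @param instance A `dmdgp_instance`.
#' @param path File path.
#' @return `path` (writer) or a `dmdgp_instance` (reader).
#' @export
write_restraints <- function(instance, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#i\tj\tvalue\trole\tkind_i\tkind_j\tres_i\tres_j", con)
  r <- instance$restraints
  writeLines(sprintf("%d\t%d\t%.9f\t%s\t%s\t%s\t%d\t%d",
                     r$i, r$j, r$value, r$role, r$kind_i, r$kind_j,
                     r$res_i, r$res_j), con)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- vector("list", sum(keep))
  ln <- which(keep)
  for (k in seq_along(ln)) {
    f <- strsplit(lines[ln[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 8L)
      stop("parse error at line ", ln[k], ": expected 8 tab-separated fields")
    num <- suppressWarnings(as.numeric(f[c(1L, 2L, 3L, 7L, 8L)]))
    if (any(is.na(num)))
      stop("parse error at line ", ln[k], ": non-numeric field")
    rows[[k]] <- data.frame(i = as.integer(num[1L]), j = as.integer(num[2L]),
                            value = num[3L], role = f[4L], kind_i = f[5L],
                            kind_j = f[6L], res_i = as.integer(num[4L]),
                            res_j = as.integer(num[5L]),
                            stringsAsFactors = FALSE)
  }
  r <- do.call(rbind, rows)
  if (is.null(r) || nrow(r) == 0L) stop("parse error: no restraints in ", path)
  np <- max(r$j)
  if ((np + 3L) %% 6L != 0L)
    stop("model error: ", np, " positions do not fit a backbone order")
  order <- build_order((np + 3L) / 6L)
  bad <- which(order$kind[r$i] != r$kind_i | order$kind[r$j] != r$kind_j)
  if (length(bad))
    stop("parse error at line ", ln[bad[1L]], ": atom kind disagrees with the order")
  new_instance(order, r)
}

# --- realization engine ----------------------------------------------------

# Precomputed context shared by decode/solver: distance lookup, repeat
# backing positions and the intrinsic per-position classification.
.instance_ctx <- function(instance, tol_disc = 1e-4) {
  order <- instance$order
  np <- nrow(order)
  r <- instance$restraints
  d <- r[r$role == "discretization", ]
  dget <- .dist_lookup(d, np)
  first_occ <- .first_occurrence(order)
  ctx <- list(order = order, np = np, dget = dget, first_occ = first_occ,
              tol_disc = tol_disc)
  ctx$ptype <- .classify_positions(ctx)
  pr <- r[r$role == "pruning", ]
  ctx$pruning <- pr
  ctx
}

# candidate points for vertex t given coordinates of its predecessors
.candidates <- function(ctx, X, t, tol_disc = ctx$tol_disc) {
  if (ctx$order$is_repeat[t])
    return(list(kind = "repeat", points = list(X[ctx$first_occ[t], ])))
  pts <- trilaterate(X[t - 1L, ], X[t - 2L, ], X[t - 3L, ],
                     ctx$dget(t - 1L, t), ctx$dget(t - 2L, t), ctx$dget(t - 3L, t),
                     tol = tol_disc)
  if (length(pts) == 0L)
    stop("infeasible-instance: no sphere intersection at position ", t)
  list(kind = if (length(pts) == 1L) "forced" else "free", points = pts)
}

# intrinsic classification: the discriminant at t depends only on the
# discretization distances, so forcedness is a property of the instance
.classify_positions <- function(ctx) {
  np <- ctx$np
  ptype <- c("fixed", "fixed", "fixed", rep(NA_character_, np - 3L))
  X <- matrix(NA_real_, np, 3L)
  X[1:3, ] <- place_first_three(ctx$dget(1L, 2L), ctx$dget(1L, 3L), ctx$dget(2L, 3L))
  for (t in 4:np) {
    cand <- .candidates(ctx, X, t)
    ptype[t] <- cand$kind
    X[t, ] <- cand$points[[length(cand$points)]]
  }
  ptype
}

# realize coordinates for positions 1..upto under a full bit vector
.realize_bits <- function(ctx, bits, upto = ctx$np) {
  X <- matrix(NA_real_, ctx$np, 3L)
  X[1:3, ] <- place_first_three(ctx$dget(1L, 2L), ctx$dget(1L, 3L), ctx$dget(2L, 3L))
  if (upto < 4L) return(X)
  for (t in 4:upto) {
    cand <- .candidates(ctx, X, t)
    X[t, ] <- if (cand$kind == "free" && bits[t] == 0L)
      cand$points[[2L]] else cand$points[[1L]]
  }
  X
}

#' Classify order positions of an instance
#'
#' Position classes: `fixed` (the pinned first three vertices), `repeat`
#' (coordinates copied from the first occurrence), `forced` (single sphere
#' intersection, e.g. planar peptide geometry) and `free` (two intersection
#' points, a genuine orientation bit). Forcedness depends only on the
#' discretization distances, so the classification is intrinsic to the
#' instance.
#'
#' @param instance A `dmdgp_instance`.
#' @param tol_disc Trilateration degeneracy tolerance (Angstrom).
#' @return Character vector, one class per order position.
#' @export
position_info <- function(instance, tol_disc = 1e-4) {
  .instance_ctx(instance, tol_disc)$ptype
}

#' Maximum restraint violation of a conformation
#'
#' @param instance A `dmdgp_instance`.
#' @param conf A `dmdgp_conformation` over the same order.
#' @return Largest absolute difference (Angstrom) between a restraint value
#'   and the corresponding realized distance.
#' @export
max_violation <- function(instance, conf) {
  r <- instance$restraints
  X <- conf$coords
  d <- sqrt(rowSums((X[r$i, , drop = FALSE] - X[r$j, , drop = FALSE])^2))
  max(abs(d - r$value))
}
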