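# Symmetry-based build-up solver. Pruning edges are ordered (ascending by
# j, then i) and grouped into components that share relevant bits. The
# first edge of each component is searched exhaustively over its free
# relevant bits -- left-first DFS or frequency-guided best-first (FBS) --
# with the first free bit pinned to 0 (flip canonicalization: each feasible
# sequence and its complete flip are the only two solutions of an
# independent edge, so one representative suffices). Later edges of a
# component first try the accumulated partial assignment and its complete
# flip before searching their remaining free bits.
#
# Node accounting follows the two schemes of the search-cost analysis: DFS
# counts unique expanded tree nodes (shared prefixes once); FBS charges
# every tested root-leaf path its full length, rank_accepted * window_length.

#' Extract the pruning edges of an instance
#'
#' @param instance A `dmdgp_instance`.
#' @return List of pruning edges ordered ascending by `j` then `i`; each is
#'   a list with `i`, `j`, `value`, `type` (edge-type label) and `relevant`
#'   (the positions `i + 3, ..., j`).
#' @export
pruning_edges <- function(instance) {
  pr <- instance$restraints[instance$restraints$role == "pruning", , drop = FALSE]
  if (nrow(pr) == 0L) return(list())
  pr <- pr[order(pr$j, pr$i), , drop = FALSE]
  lapply(seq_len(nrow(pr)), function(k) {
    e <- pr[k, ]
    list(i = e$i, j = e$j, value = e$value,
         type = classify_edge(instance$order, e$i, e$j),
         relevant = relevant_positions(e$i, e$j))
  })
}

#' Decompose pruning edges into independent and coupled components
#'
#' Connected components of the share-a-relevant-bit graph: two edges are
#' coupled when their relevant position sets intersect. Singleton components
#' are independent constraints (exhaustive search); within a component the
#' edges keep the global processing order.
#'
#' @param edges A list of pruning edges from [pruning_edges()].
#' @return List of components; each has `edges` (ordered list) and
#'   `bit_support` (sorted union of relevant positions).
#' @export
decompose <- function(edges) {
  m <- length(edges)
  if (m == 0L) return(list())
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      if (comp[a] != comp[b] &&
          length(intersect(edges[[a]]$relevant, edges[[b]]$relevant))) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    list(edges = edges[idx],
         bit_support = sort(unique(unlist(lapply(edges[idx], `[[`, "relevant")))))
  })
}

# --- per-edge searches -----------------------------------------------------

# Left-first DFS over the free relevant bits of one edge. bits/assigned are
# full-length vectors; assigned positions keep their bit. canonical = TRUE
# pins the first unassigned free bit of the window to 0. Counts every
# realized tree node once (unique expanded nodes).
.search_edge_dfs <- function(ctx, edge, bits, assigned, tol, canonical) {
  win <- edge$relevant
  L <- length(win)
  Xpre <- .realize_bits(ctx, bits, win[1L] - 1L)
  counter <- new.env(parent = emptyenv())
  counter$nodes <- 0L
  counter$canon_pending <- canonical
  rec <- function(X, idx) {
    t <- win[idx]
    cand <- .candidates(ctx, X, t)
    choices <- if (cand$kind != "free") {
      0L
    } else if (assigned[t]) {
      bits[t]
    } else if (counter$canon_pending) {
      counter$canon_pending <- FALSE
      0L
    } else c(0L, 1L)
    for (b in choices) {
      counter$nodes <- counter$nodes + 1L
      Xb <- X
      Xb[t, ] <- if (cand$kind == "free" && b == 0L)
        cand$points[[2L]] else cand$points[[1L]]
      if (idx == L) {
        if (abs(.norm3(Xb[edge$j, ] - Xb[edge$i, ]) - edge$value) <= tol)
          return(.window_bits(ctx, win, {bb <- bits; bb[t] <- b; bb}, Xb))
      } else {
        bits[t] <<- b # record chain for deeper window bits
        res <- rec(Xb, idx + 1L)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  seq_bits <- rec(Xpre, 1L)
  list(seq = seq_bits, nodes = counter$nodes)
}

# window bits of a realized window: free positions from the working bit
# vector, forced/repeat positions recorded 0
.window_bits <- function(ctx, win, bits, X) {
  out <- integer(length(win))
  free <- ctx$ptype[win] == "free"
  out[free] <- bits[win[free]]
  out
}

# FBS: candidate sequences in descending training frequency (then appended
# left-first canonical patterns), each tested as one full path of length
# |window|; accepted at rank k costs k * |window| nodes.
.search_edge_fbs <- function(ctx, edge, table, bits, assigned, tol) {
  win <- edge$relevant
  L <- length(win)
  free_unassigned <- win[ctx$ptype[win] == "free" & !assigned[win]]
  fixed_free <- win[ctx$ptype[win] == "free" & assigned[win]]
  cand_strings <- character(0)
  if (!is.null(table)) cand_strings <- freq_sequences(table, edge$type)
  # candidate -> assignment over the window's unassigned free bits
  proj <- function(s) {
    bv <- as.integer(strsplit(s, "")[[1L]])
    if (length(bv) != L) return(NULL)
    names(bv) <- as.character(win)
    if (length(fixed_free) &&
        any(bv[as.character(fixed_free)] != bits[fixed_free])) return(NULL)
    bv[as.character(free_unassigned)]
  }
  cands <- list()
  seen <- character(0)
  for (s in cand_strings) {
    p <- proj(s)
    if (is.null(p)) next
    key <- paste(p, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    cands[[length(cands) + 1L]] <- p
  }
  # completeness fallback: left-first canonical patterns over the free bits
  # (first free bit 0; remaining bits in ascending binary order, leftmost
  # most significant, matching the DFS leaf order)
  nf <- length(free_unassigned)
  if (nf > 0L) {
    for (code in 0:(2^(nf - 1L) - 1L)) {
      rest <- rev(as.integer(intToBits(code))[seq_len(nf - 1L)])
      p <- c(0L, rest)
      names(p) <- as.character(free_unassigned)
      key <- paste(p, collapse = "")
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- p
    }
  } else if (length(cands) == 0L) {
    cands[[1L]] <- integer(0)
  }
  Xpre <- .realize_bits(ctx, bits, win[1L] - 1L)
  k <- 0L
  for (p in cands) {
    k <- k + 1L
    bb <- bits
    if (length(p)) bb[as.integer(names(p))] <- p
    X <- Xpre
    for (t in win) {
      cand <- .candidates(ctx, X, t)
      X[t, ] <- if (cand$kind == "free" && bb[t] == 0L)
        cand$points[[2L]] else cand$points[[1L]]
    }
    if (abs(.norm3(X[edge$j, ] - X[edge$i, ]) - edge$value) <= tol)
      return(list(seq = .window_bits(ctx, win, bb, X), nodes = k * L))
  }
  list(seq = NULL, nodes = k * L)
}

#' Search one pruning edge by left-first depth-first search
#'
#' Explores the binary tree over the edge's free relevant bits, 0 before 1,
#' with the first free bit pinned to 0 (flip canonicalization); feasibility
#' is tested at depth `j` by comparing the realized distance with the
#' restraint value. Returns the first feasible sequence and the number of
#' unique tree nodes expanded.
#'
#' @param instance A `dmdgp_instance`.
#' @param edge One element of [pruning_edges()].
#' @param fixed_bits Optional full-length integer vector with `NA` at
#'   unassigned positions; non-`NA` free bits are held fixed (and disable
#'   canonicalization).
#' @param tol Feasibility tolerance (Angstrom).
#' @param tol_disc Trilateration degeneracy tolerance (Angstrom).
#' @return List with `seq` (a `dmdgp_bits` over the relevant window) and
#'   `nodes` (count of visited nodes).
#' @export
solve_edge_dfs <- function(instance, edge, fixed_bits = NULL, tol = 1e-6,
                           tol_disc = 1e-4) {
  ctx <- .instance_ctx(instance, tol_disc)
  st <- .fixed_state(ctx, fixed_bits)
  res <- .search_edge_dfs(ctx, edge, st$bits, st$assigned, tol,
                          canonical = !any(st$assigned[edge$relevant]))
  if (is.null(res$seq))
    stop("infeasible-edge: no feasible sequence for edge (", edge$i, ",", edge$j, ")")
  list(seq = .edge_bits(ctx, edge, res$seq), nodes = res$nodes)
}

#' Search one pruning edge by frequency-based search
#'
#' Tests candidate relevant-bit sequences in descending training-frequency
#' order (ties lexicographic; unseen sequences appended in left-first
#' order), each candidate as one full root-leaf path. The node count is
#' exactly `rank * length(window)` for the accepted candidate.
#'
#' @inheritParams solve_edge_dfs
#' @param table A `dmdgp_freq` frequency table (or `NULL` for pure fallback
#'   ordering).
#' @return List with `seq` (a `dmdgp_bits`) and `nodes`.
#' @export
solve_edge_fbs <- function(instance, edge, table = NULL, fixed_bits = NULL,
                           tol = 1e-6, tol_disc = 1e-4) {
  ctx <- .instance_ctx(instance, tol_disc)
  st <- .fixed_state(ctx, fixed_bits)
  res <- .search_edge_fbs(ctx, edge, table, st$bits, st$assigned, tol)
  if (is.null(res$seq))
    stop("infeasible-edge: no feasible sequence for edge (", edge$i, ",", edge$j, ")")
  list(seq = .edge_bits(ctx, edge, res$seq), nodes = res$nodes)
}

.fixed_state <- function(ctx, fixed_bits) {
  bits <- rep(0L, ctx$np)
  assigned <- rep(FALSE, ctx$np)
  if (!is.null(fixed_bits)) {
    stopifnot(length(fixed_bits) == ctx$np)
    sel <- !is.na(fixed_bits)
    bits[sel] <- as.integer(fixed_bits[sel])
    assigned <- sel
  }
  list(bits = bits, assigned = assigned)
}

.edge_bits <- function(ctx, edge, seq_int) {
  win <- edge$relevant
  new_bits(seq_int, win[1L], ctx$ptype[win] == "free",
           ctx$order$is_repeat[win])
}

# --- full solve ------------------------------------------------------------

#' Solve a DMDGP instance by symmetry-based build-up
#'
#' Components of coupled pruning edges are processed in edge order. The
#' first edge of each component is searched exhaustively with the chosen
#' strategy; each later edge first tries extending the component's partial
#' assignment and its complete flip before searching its remaining free
#' bits. Bits constrained by no pruning edge default to 0.
#'
#' @param instance A `dmdgp_instance` satisfying H1-H2.
#' @param strategy `"dfs"` (left-first depth-first) or `"fbs"`
#'   (frequency-based; requires `table`).
#' @param table A `dmdgp_freq` table for `strategy = "fbs"`.
#' @param tol Feasibility tolerance (Angstrom).
#' @param tol_disc Trilateration degeneracy tolerance (Angstrom).
#' @return A `dmdgp_solution`: list with `conformation`, `bits` (normalized
#'   global `dmdgp_bits`), and `stats` (per-edge node counts, per-type and
#'   total aggregates, strategy name).
#' @export
solve_dmdgp <- function(instance, strategy = c("dfs", "fbs"), table = NULL,
                        tol = 1e-6, tol_disc = 1e-4) {
  strategy <- match.arg(strategy)
  if (strategy == "fbs" && is.null(table))
    stop("invalid-argument: strategy 'fbs' requires a frequency table")
  ctx <- .instance_ctx(instance, tol_disc)
  edges <- pruning_edges(instance)
  comps <- decompose(edges)
  bits <- rep(0L, ctx$np)
  assigned <- rep(FALSE, ctx$np)
  rows <- list()
  for (comp in comps) {
    comp_free <- integer(0)
    for (k in seq_along(comp$edges)) {
      e <- comp$edges[[k]]
      win <- e$relevant
      if (k == 1L) {
        res <- if (strategy == "dfs")
          .search_edge_dfs(ctx, e, bits, assigned, tol, canonical = TRUE)
        else .search_edge_fbs(ctx, e, table, bits, assigned, tol)
        nodes <- res$nodes
        mode <- "search"
      } else {
        nodes <- 0L
        res <- NULL
        for (variant in 1:2) {
          if (variant == 2L) bits[comp_free] <- 1L - bits[comp_free]
          r <- .search_edge_dfs(ctx, e, bits, assigned, tol, canonical = FALSE)
          nodes <- nodes + r$nodes
          if (!is.null(r$seq)) { res <- r; break }
          if (variant == 2L) bits[comp_free] <- 1L - bits[comp_free] # restore
        }
        mode <- "extend"
      }
      if (is.null(res$seq))
        stop("infeasible-instance: edge (", e$i, ",", e$j, ") has no feasible sequence")
      newly <- win[ctx$ptype[win] == "free" & !assigned[win]]
      bits[win] <- ifelse(ctx$ptype[win] == "free" & assigned[win],
                          bits[win], res$seq)
      assigned[win] <- TRUE
      comp_free <- c(comp_free, newly)
      rows[[length(rows) + 1L]] <- data.frame(
        i = e$i, j = e$j, type = e$type, nodes = nodes, mode = mode,
        stringsAsFactors = FALSE)
    }
  }
  X <- .realize_bits(ctx, bits)
  conf <- new_conformation(instance$order, X)
  viol <- if (nrow(instance$restraints)) max_violation(instance, conf) else 0
  if (viol > tol)
    stop("infeasible-instance: residual violation ", signif(viol, 3), " A")
  per_edge <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), type = character(),
               nodes = integer(), mode = character())
  by_type <- if (nrow(per_edge))
    tapply(per_edge$nodes, per_edge$type, sum) else integer(0)
  stats <- list(strategy = strategy, per_edge = per_edge,
                by_type = by_type, total_nodes = sum(per_edge$nodes))
  structure(list(conformation = conf,
                 bits = normalize_bits(new_bits(bits, 1L,
                                                ctx$ptype == "free",
                                                instance$order$is_repeat)),
                 stats = stats, max_violation = viol),
            class = "dmdgp_solution")
}

#' @export
print.dmdgp_solution <- function(x, ...) {
  cat("DMDGP solution (", x$stats$strategy, "): ",
      nrow(x$conformation$coords), " vertices, ",
      x$stats$total_nodes, " nodes visited, max violation ",
      format(x$max_violation, digits = 3), " A\n", sep = "")
  cat("  bits: ", as.character(x$bits), "\n", sep = "")
  invisible(x)
}

#' Write a solution's coordinate, bit-string and stats files
#'
#' @param solution A `dmdgp_solution`.
#' @param prefix Output path prefix; writes `<prefix>_coords.tsv`,
#'   `<prefix>_bits.txt` and `<prefix>_stats.json`.
#' @return The three paths, invisibly.
#' @export
write_solution <- function(solution, prefix) {
  p1 <- paste0(prefix, "_coords.tsv")
  p2 <- paste0(prefix, "_bits.txt")
  p3 <- paste0(prefix, "_stats.json")
  write_coords_tsv(solution$conformation, p1)
  write_bits(solution$bits, p2)
  st <- solution$stats
  jsonlite::write_json(list(strategy = st$strategy,
                            total_nodes = st$total_nodes,
                            by_type = as.list(st$by_type),
                            per_edge = st$per_edge),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' Exhaustive branch-and-prune reference solver
#'
#' Enumerates every feasible normalized bit string of an instance by
#' depth-first traversal of the full discretization tree, pruning a branch
#' as soon as a pruning restraint ending at the current position is
#' violated. Used as the brute-force oracle for the build-up solver.
#'
#' @param instance A `dmdgp_instance`.
#' @param tol Feasibility tolerance (Angstrom).
#' @param tol_disc Trilateration degeneracy tolerance (Angstrom).
#' @param max_free_bits Refuse instances with more free bits than this.
#' @param normalized If `TRUE` (default) fix bit 4 to 0 and return
#'   normalized strings; if `FALSE` enumerate both mirror families.
#' @return Sorted character vector of feasible global bit strings.
#' @export
bp_reference <- function(instance, tol = 1e-6, tol_disc = 1e-4,
                         max_free_bits = 22L, normalized = TRUE) {
  ctx <- .instance_ctx(instance, tol_disc)
  nfree <- sum(ctx$ptype == "free") - if (normalized) 1L else 0L
  if (nfree > max_free_bits)
    stop("refused: ", nfree, " free bits exceed the cap of ", max_free_bits)
  pr <- ctx$pruning
  prune_at <- split(seq_len(nrow(pr)), pr$j)
  np <- ctx$np
  sols <- character(0)
  rec <- function(X, bits, t) {
    if (t > np) {
      sols[[length(sols) + 1L]] <<- paste(bits, collapse = "")
      return(invisible(NULL))
    }
    cand <- .candidates(ctx, X, t)
    choices <- if (cand$kind != "free") 0L
      else if (t == 4L && normalized) 0L
      else c(0L, 1L)
    for (b in choices) {
      Xb <- X
      Xb[t, ] <- if (cand$kind == "free" && b == 0L)
        cand$points[[2L]] else cand$points[[1L]]
      ok <- TRUE
      hits <- prune_at[[as.character(t)]]
      for (h in hits) {
        if (abs(.norm3(Xb[pr$j[h], ] - Xb[pr$i[h], ]) - pr$value[h]) > tol) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        bits[t] <- if (cand$kind == "free") b else 0L
        rec(Xb, bits, t + 1L)
      }
    }
    invisible(NULL)
  }
  X <- matrix(NA_real_, np, 3L)
  X[1:3, ] <- place_first_three(ctx$dget(1L, 2L), ctx$dget(1L, 3L), ctx$dget(2L, 3L))
  rec(X, integer(np), 4L)
  sort(unique(sols))
}
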