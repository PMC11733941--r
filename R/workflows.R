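# End-to-end workflows behind the command-line entry point: simulate a
# batch of synthetic instances, train a frequency table on an 80/20 split,
# and benchmark DFS against FBS on held-out instances. All workflows are
# deterministic given (config, seed), wall-clock fields excepted.

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: expected a list or a YAML file path")
  config
}

.cfg <- function(config, name, default = NULL) {
  if (!is.null(config[[name]])) config[[name]] else default
}

.make_sampler <- function(config, order) {
  sm <- .cfg(config, "sampler")
  if (is.null(sm) || identical(sm$type, "fair") || identical(sm, "fair"))
    return(bit_sampler_fair())
  if (identical(sm$type, "seq_law"))
    return(bit_sampler_seq_law(order, sm$edge_type, sm$sequences, sm$probs))
  stop("config error: unknown sampler type")
}

.geometry_from <- function(config) {
  g <- .cfg(config, "geometry", list())
  do.call(geometry_params, g)
}

#' Simulate a batch of synthetic instances
#'
#' Samples `count` conformations of `n_residues` residues and writes, per
#' instance `k`: `conf_k.tsv` (coordinates), `inst_k.tsv` (restraints) and
#' `fixture_k.pdb` (poly-alanine PDB). Deterministic given the seed.
#'
#' @param config Named list or YAML path with fields `out_dir`,
#'   `n_residues`, `count`, `seed`, optional `geometry` (arguments to
#'   [geometry_params()]), `sampler` (`fair`, or
#'   `list(type = "seq_law", edge_type=, sequences=, probs=)`) and `policy`
#'   (edge-family labels, default [default_policy()]).
#' @return Invisibly, a data frame manifest of written files.
#' @export
run_simulate <- function(config) {
  config <- .load_config(config)
  n <- .cfg(config, "n_residues")
  count <- .cfg(config, "count", 1L)
  seed <- .cfg(config, "seed", 1L)
  out <- .cfg(config, "out_dir")
  if (is.null(n) || is.null(out))
    stop("config error: 'n_residues' and 'out_dir' are required")
  if (!is.numeric(n) || n < 2) stop("config error: n_residues must be >= 2")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- .geometry_from(config)
  policy <- .cfg(config, "policy", default_policy())
  order <- build_order(n)
  rows <- list()
  for (k in seq_len(count)) {
    conf <- sample_conformation(n, params, .make_sampler(config, order),
                                seed = seed + k - 1L)
    inst <- build_instance(conf, policy)
    pc <- file.path(out, sprintf("conf_%03d.tsv", k))
    pi <- file.path(out, sprintf("inst_%03d.tsv", k))
    pp <- file.path(out, sprintf("fixture_%03d.pdb", k))
    write_coords_tsv(conf, pc)
    write_restraints(inst, pi)
    write_fixture_pdb(conf, pp)
    rows[[k]] <- data.frame(k = k, conf = pc, instance = pi, pdb = pp,
                            seed = seed + k - 1L, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Train a frequency table from simulated or ingested instances
#'
#' Reads every `inst_*.tsv` under `in_dir`, applies the seeded
#' training/test split (default 80/20), solves the training instances with
#' the depth-first strategy and tallies the per-edge sequences of the first
#' solutions into a frequency table written as CSV (plus a JSON metadata
#' sidecar).
#'
#' @param config Named list or YAML path with `in_dir`, `table_out`,
#'   optional `ratio` (default 0.8), `seed`, `tol`.
#' @return Invisibly, a list with the `dmdgp_freq` table and the split.
#' @export
run_train <- function(config) {
  config <- .load_config(config)
  in_dir <- .cfg(config, "in_dir")
  table_out <- .cfg(config, "table_out")
  if (is.null(in_dir) || is.null(table_out))
    stop("config error: 'in_dir' and 'table_out' are required")
  files <- sort(list.files(in_dir, pattern = "^inst_.*\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("config error: no instance files in ", in_dir)
  ratio <- .cfg(config, "ratio", 0.8)
  seed <- .cfg(config, "seed", 1L)
  tol <- .cfg(config, "tol", 1e-6)
  sp <- split_train_test(files, ratio, seed)
  bits_list <- list()
  edges_list <- list()
  for (f in sp$train) {
    inst <- read_restraints(f)
    sol <- solve_dmdgp(inst, "dfs", tol = tol)
    bits_list[[length(bits_list) + 1L]] <- sol$bits
    edges_list[[length(edges_list) + 1L]] <- pruning_edges(inst)
  }
  ft <- build_freq_table(bits_list, edges_list,
                         meta = list(seed = seed, ratio = ratio,
                                     n_train = length(sp$train),
                                     n_test = length(sp$test)))
  write_freq_csv(ft, table_out)
  jsonlite::write_json(ft$meta, paste0(table_out, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = ft, split = sp))
}

#' Benchmark DFS against FBS on test instances
#'
#' Solves every instance under `in_dir` (or the held-out test files of a
#' split) with both strategies at the same tolerance and records visited
#' nodes (the hardware-independent primary metric) and wall times
#' (secondary). Reports the fraction of instances where FBS visits strictly
#' fewer nodes than DFS and per-edge-type node aggregates; infeasible
#' instances are recorded, excluded and warned about.
#'
#' @param config Named list or YAML path with `in_dir` (or `files`),
#'   `table` (frequency CSV path or `dmdgp_freq`), optional `out_dir`,
#'   `tol`.
#' @return A `dmdgp_benchmark` list: `per_instance` data frame, `by_type`
#'   aggregates, `fbs_win_fraction`, `n`.
#' @export
run_benchmark <- function(config) {
  config <- .load_config(config)
  files <- .cfg(config, "files")
  if (is.null(files)) {
    in_dir <- .cfg(config, "in_dir")
    if (is.null(in_dir)) stop("config error: need 'files' or 'in_dir'")
    files <- sort(list.files(in_dir, pattern = "^inst_.*\\.tsv$", full.names = TRUE))
  }
  if (length(files) == 0L) stop("config error: no test instances")
  table <- .cfg(config, "table")
  if (is.character(table)) table <- read_freq_csv(table)
  if (!inherits(table, "dmdgp_freq")) stop("config error: 'table' is required")
  tol <- .cfg(config, "tol", 1e-6)
  rows <- list()
  type_nodes <- list(dfs = list(), fbs = list())
  for (f in files) {
    inst <- read_restraints(f)
    res <- lapply(c(dfs = "dfs", fbs = "fbs"), function(strat) {
      t0 <- proc.time()[["elapsed"]]
      sol <- tryCatch(solve_dmdgp(inst, strat, table = table, tol = tol),
                      error = function(e) e)
      list(sol = sol, time = proc.time()[["elapsed"]] - t0)
    })
    if (inherits(res$dfs$sol, "error") || inherits(res$fbs$sol, "error")) {
      warning("infeasible instance excluded: ", f)
      next
    }
    for (strat in c("dfs", "fbs")) {
      pe <- res[[strat]]$sol$stats$per_edge
      type_nodes[[strat]][[length(type_nodes[[strat]]) + 1L]] <- pe
    }
    rows[[length(rows) + 1L]] <- data.frame(
      file = f,
      dfs_nodes = res$dfs$sol$stats$total_nodes,
      fbs_nodes = res$fbs$sol$stats$total_nodes,
      dfs_time = res$dfs$time, fbs_time = res$fbs$time,
      stringsAsFactors = FALSE)
  }
  per_instance <- do.call(rbind, rows)
  if (is.null(per_instance) || nrow(per_instance) == 0L)
    stop("no feasible instances to benchmark")
  by_type <- lapply(type_nodes, function(lst) {
    pe <- do.call(rbind, lst)
    tapply(pe$nodes, pe$type, sum)
  })
  report <- structure(list(
    per_instance = per_instance,
    by_type = by_type,
    fbs_win_fraction = mean(per_instance$fbs_nodes < per_instance$dfs_nodes),
    n = nrow(per_instance)), class = "dmdgp_benchmark")
  out_dir <- .cfg(config, "out_dir")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_instance, file.path(out_dir, "benchmark.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(n = report$n,
                              fbs_win_fraction = report$fbs_win_fraction,
                              total_dfs_nodes = sum(per_instance$dfs_nodes),
                              total_fbs_nodes = sum(per_instance$fbs_nodes),
                              by_type = lapply(by_type, as.list)),
                         file.path(out_dir, "benchmark.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.dmdgp_benchmark <- function(x, ...) {
  cat("DFS vs FBS benchmark on", x$n, "instances\n")
  cat(sprintf("  FBS wins (fewer nodes): %.1f%%\n", 100 * x$fbs_win_fraction))
  cat(sprintf("  total nodes: DFS %d, FBS %d\n",
              sum(x$per_instance$dfs_nodes), sum(x$per_instance$fbs_nodes)))
  invisible(x)
}

#' Ingest a PDB file into backbone segments
#'
#' Parses the first model, extracts proline/glycine-free complete segments
#' and writes, per segment, the coordinates TSV of its DMDGP-order
#' conformation plus a manifest CSV.
#'
#' @param config Named list or YAML path with `pdb` (input path), `out_dir`
#'   and optional `source_id`.
#' @return Invisibly, the manifest data frame (zero rows if no segments).
#' @export
run_ingest <- function(config) {
  config <- .load_config(config)
  pdb <- .cfg(config, "pdb")
  out <- .cfg(config, "out_dir")
  if (is.null(pdb) || is.null(out)) stop("config error: need 'pdb' and 'out_dir'")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  segs <- segmentize(parse_first_model(pdb),
                     .cfg(config, "source_id", basename(pdb)))
  rows <- lapply(seq_along(segs), function(k) {
    s <- segs[[k]]
    pc <- file.path(out, sprintf("segment_%03d.tsv", k))
    write_coords_tsv(segment_conformation(s), pc)
    data.frame(source = s$source, chain = s$chain, start = s$start,
               end = s$end, length = s$n_residues, coords = pc,
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), chain = character(), start = integer(),
               end = integer(), length = integer(), coords = character())
  utils::write.csv(manifest, file.path(out, "segments.csv"), row.names = FALSE)
  invisible(manifest)
}
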