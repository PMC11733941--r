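test_that("simulate writes a deterministic batch that re-validates", {
  out1 <- file.path(tempdir(), "sim1")
  out2 <- file.path(tempdir(), "sim2")
  cfg <- list(out_dir = out1, n_residues = 3, count = 3, seed = 5)
  run_simulate(cfg)
  run_simulate(modifyList(cfg, list(out_dir = out2)))
  for (f in c("inst_001.tsv", "inst_002.tsv", "conf_003.tsv", "fixture_001.pdb")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  inst <- read_restraints(file.path(out1, "inst_002.tsv"))
  expect_true(validate_instance(inst))
  expect_error(run_simulate(list(out_dir = tempdir(), n_residues = 1)),
               "config error")
  expect_error(run_simulate(list(n_residues = 3)), "config error")
})

test_that("training applies the 80/20 split and is reproducible", {
  out <- file.path(tempdir(), "train_in")
  run_simulate(list(out_dir = out, n_residues = 3, count = 10, seed = 2))
  t1 <- file.path(tempdir(), "table1.csv")
  t2 <- file.path(tempdir(), "table2.csv")
  cfg <- list(in_dir = out, table_out = t1, seed = 7)
  res <- run_train(cfg)
  expect_length(res$split$train, 8L)
  expect_length(res$split$test, 2L)
  tab <- res$table$table
  for (ty in unique(tab$edge_type))
    expect_equal(sum(tab$probability[tab$edge_type == ty]), 1)
  run_train(modifyList(cfg, list(table_out = t2)))
  expect_identical(readLines(t1), readLines(t2))
  meta <- jsonlite::read_json(paste0(t1, ".meta.json"))
  expect_equal(meta$n_train, 8L)
})

test_that("yaml configs drive the workflows", {
  out <- file.path(tempdir(), "sim_yaml")
  cfgfile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(out_dir = out, n_residues = 3, count = 2, seed = 1),
                   cfgfile)
  m <- run_simulate(cfgfile)
  expect_equal(nrow(m), 2L)
})

test_that("the benchmark reports consistent aggregates and wins with a peaked law", {
  law <- ha10_law()
  sim_dir <- file.path(tempdir(), "bench_train")
  test_dir <- file.path(tempdir(), "bench_test")
  base <- list(n_residues = 3, geometry = list(omega_jitter = 5),
               policy = "HA-10-H",
               sampler = list(type = "seq_law", edge_type = "HA-10-H",
                              sequences = law$sequences, probs = law$probs))
  run_simulate(modifyList(base, list(out_dir = sim_dir, count = 40, seed = 100)))
  run_simulate(modifyList(base, list(out_dir = test_dir, count = 30, seed = 900)))
  tpath <- file.path(tempdir(), "bench_table.csv")
  run_train(list(in_dir = sim_dir, table_out = tpath, seed = 1, ratio = 0.8))
  rep_dir <- file.path(tempdir(), "bench_out")
  rep <- run_benchmark(list(in_dir = test_dir, table = tpath,
                            out_dir = rep_dir))
  expect_equal(rep$n, 30L)
  expect_gte(rep$fbs_win_fraction, 0.5)
  js <- jsonlite::read_json(file.path(rep_dir, "benchmark.json"))
  expect_equal(js$total_dfs_nodes, sum(rep$per_instance$dfs_nodes))
  expect_equal(js$total_fbs_nodes, sum(rep$per_instance$fbs_nodes))
  expect_equal(js$fbs_win_fraction,
               mean(rep$per_instance$fbs_nodes < rep$per_instance$dfs_nodes))
})

test_that("under a uniform table the full-path accounting never beats DFS", {
  # with tied counts the frequency order falls back to the left-first leaf
  # order, and charging every tested path in full can only match DFS at
  # rank 1 and lose beyond it
  test_dir <- file.path(tempdir(), "unif_test")
  run_simulate(list(out_dir = test_dir, n_residues = 3, count = 20, seed = 50,
                    geometry = list(omega_jitter = 5), policy = "HA-10-H"))
  e <- list(i = 2L, j = 11L, value = 1, type = "HA-10-H",
            relevant = relevant_positions(2, 11))
  seqs <- vapply(0:63, function(code) paste(
    c(0L, rev(as.integer(intToBits(code))[1:6])), collapse = ""), character(1))
  ft <- build_freq_table(lapply(seqs, global_with_window),
                         rep(list(list(e)), length(seqs)))
  rep <- run_benchmark(list(in_dir = test_dir, table = ft))
  expect_equal(mean(rep$per_instance$fbs_nodes < rep$per_instance$dfs_nodes), 0)
  expect_true(all(rep$per_instance$fbs_nodes >= rep$per_instance$dfs_nodes))
})

test_that("PDB ingestion writes a segment manifest and coordinates", {
  conf <- sample_conformation(4, geometry_params(omega_jitter = 5), seed = 31)
  pdb <- tempfile(fileext = ".pdb")
  write_fixture_pdb(conf, pdb)
  out <- file.path(tempdir(), "ingest_out")
  m <- run_ingest(list(pdb = pdb, out_dir = out, source_id = "fixture"))
  # residue 1 lacks the amide H the order does not model: segment spans 2..4
  expect_equal(nrow(m), 1L)
  expect_equal(m$length, 3L)
  expect_true(file.exists(m$coords))
  back <- read_coords_tsv(m$coords)
  expect_equal(nrow(back$coords), 6L * 3L - 3L)
})
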