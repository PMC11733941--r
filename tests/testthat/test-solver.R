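test_that("constraint decomposition follows shared relevant bits", {
  pl <- planted_instance(3, 1)
  comps <- decompose(pruning_edges(pl$instance))
  # windows {5-8},{5-11},{6-7},{11-14},{12-13} chain into one component
  expect_length(comps, 1L)
  expect_length(comps[[1]]$edges, 5L)
  expect_equal(comps[[1]]$bit_support, 5:14)

  # single-family HA-7-HA windows are disjoint: all singletons
  pl2 <- planted_instance(4, 2, policy = "HA-7-HA")
  comps2 <- decompose(pruning_edges(pl2$instance))
  expect_length(comps2, 3L)
  expect_true(all(vapply(comps2, function(cm) length(cm$edges), 1L) == 1L))
  expect_length(decompose(list()), 0L)
})

test_that("the height-4 tree worked example gives 14 DFS and 12 FBS nodes", {
  params <- geometry_params(omega_jitter = 8)
  sampler <- bit_sampler_fixed(c(NA, NA, NA, 0L, 0L, 1L, 1L, 0L, 0L))
  conf <- sample_conformation(2, params, sampler, seed = 11)
  inst <- build_instance(conf, policy = "HA-7-HA")
  e <- pruning_edges(inst)[[1]]
  expect_length(e$relevant, 4L)

  # solution path is the 7th of 8 left-to-right leaves: DFS expands all
  # tree nodes but the rightmost leaf, 14 of 15
  r <- solve_edge_dfs(inst, e)
  expect_equal(r$nodes, 14L)
  expect_equal(as.character(r$seq), "0110")

  # solution ranked 3rd in the frequency order: 3 paths of length 4
  mk <- function(s, count) {
    b <- dmdgp:::new_bits(c(0L, 0L, 0L, 0L,
                            as.integer(strsplit(s, "")[[1]]), 0L), 1L)
    rep(list(b), count)
  }
  bits_list <- c(mk("0001", 3), mk("0010", 2), mk("0110", 1))
  ft <- build_freq_table(bits_list, rep(list(list(e)), 6))
  rf <- solve_edge_fbs(inst, e, table = ft)
  expect_equal(rf$nodes, 12L)
  expect_equal(as.character(rf$seq), "0110")
})

test_that("a solution at the all-zero leaf costs one straight left spine", {
  params <- geometry_params(omega_jitter = 8)
  conf <- sample_conformation(2, params, bit_sampler_fixed(rep(0L, 9)), seed = 4)
  inst <- build_instance(conf, policy = "HA-7-HA")
  e <- pruning_edges(inst)[[1]]
  r <- solve_edge_dfs(inst, e)
  expect_equal(r$nodes, length(e$relevant))
  expect_equal(as.character(r$seq), "0000")
})

test_that("flip is an involution mapping feasible edge sequences to feasible ones", {
  s <- dmdgp:::new_bits(0L, 5L)
  expect_equal(flip_bits(s)$bits, 1L)
  pl <- planted_instance(3, 21, jitter = 5, policy = "HA-10-H")
  e <- pruning_edges(pl$instance)[[1]]
  r <- solve_edge_dfs(pl$instance, e)
  fl <- flip_bits(r$seq)
  expect_identical(flip_bits(fl)$bits, r$seq$bits)
  # decode with the flipped window: the edge distance is still met
  bits <- rep(0L, 15)
  bits[e$relevant] <- fl$bits
  X <- decode(dmdgp:::new_bits(bits, 1L), pl$instance)$coords
  expect_lt(abs(sqrt(sum((X[e$j, ] - X[e$i, ])^2)) - e$value), 1e-6)
})

test_that("both strategies solve planted instances to tolerance", {
  ft0 <- build_freq_table(list(), list())
  for (seed in 1:5) {
    pl <- planted_instance(sample(3:4, 1), 40 + seed)
    for (strat in c("dfs", "fbs")) {
      sol <- solve_dmdgp(pl$instance, strat, table = ft0)
      expect_lt(sol$max_violation, 1e-6)
      expect_true(all(sol$stats$per_edge$nodes > 0))
      expect_equal(sol$stats$total_nodes, sum(sol$stats$per_edge$nodes))
    }
  }
})

test_that("an instance without pruning edges is solved with zero search", {
  pl <- planted_instance(3, 2, policy = character(0))
  sol <- solve_dmdgp(pl$instance, "dfs")
  expect_equal(sol$stats$total_nodes, 0L)
  expect_equal(as.character(sol$bits), paste(rep(0, 15), collapse = ""))
  expect_lt(sol$max_violation, 1e-6)
})

test_that("the exhaustive reference counts unconstrained trees exactly", {
  pl <- planted_instance(3, 13, policy = character(0))
  f <- sum(position_info(pl$instance) == "free")
  sols <- bp_reference(pl$instance)
  expect_length(sols, 2^(f - 1))
  # before normalization solutions come in complete-flip pairs
  raw <- bp_reference(pl$instance, normalized = FALSE)
  expect_length(raw, 2^f)
  free <- position_info(pl$instance) == "free"
  partner <- vapply(raw, function(s) {
    b <- as.integer(strsplit(s, "")[[1]])
    b[free] <- 1L - b[free]
    paste(b, collapse = "")
  }, character(1))
  expect_true(all(partner %in% raw))
  expect_error(bp_reference(pl$instance, max_free_bits = 3), "refused")
})

test_that("build-up solutions always belong to the exhaustive solution set", {
  ft0 <- build_freq_table(list(), list())
  for (seed in 1:10) {
    pl <- planted_instance(sample(3:5, 1), 700 + seed)
    sols <- bp_reference(pl$instance)
    expect_true(as.character(solve_dmdgp(pl$instance, "dfs")$bits) %in% sols)
    expect_true(as.character(solve_dmdgp(pl$instance, "fbs", table = ft0)$bits) %in% sols)
    expect_true(as.character(encode(pl$conf)) %in% sols)
  }
})

test_that("solution files are written in the three declared formats", {
  pl <- planted_instance(3, 3)
  sol <- solve_dmdgp(pl$instance, "dfs")
  prefix <- tempfile()
  paths <- write_solution(sol, prefix)
  expect_true(all(file.exists(paths)))
  st <- jsonlite::read_json(paths[3])
  expect_equal(st$total_nodes, sol$stats$total_nodes)
  expect_equal(st$strategy, "dfs")
})
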