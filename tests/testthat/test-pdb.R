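# helper: append a synthetic amide H for residue 1 (the DMDGP order does not
# model it) so every residue passes the five-atom completeness rule
complete_fixture <- function(conf, path) {
  write_fixture_pdb(conf, path)
  lines <- readLines(path)
  n1 <- conf$coords[1, ]
  h <- sprintf(
    "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
    9999, "H", " ", "ALA", "A", 1, " ",
    n1[1] - 1.0, n1[2], n1[3], 1.0, 0.0, "H")
  writeLines(append(lines, h, after = 1L), path)
  path
}

test_that("fixture PDBs round-trip through the parser at PDB precision", {
  conf <- sample_conformation(3, geometry_params(omega_jitter = 5), seed = 9)
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(conf, path)
  # 15 order vertices map to 14 distinct atoms (one repeated CA)
  expect_equal(sum(startsWith(readLines(path), "ATOM")), 14L)
  res <- parse_first_model(path)
  expect_equal(nrow(res), 14L)
  for (t in seq_len(nrow(conf$order))) {
    k <- conf$order$kind[t]
    r <- conf$order$residue[t]
    a <- res[res$elety == k & res$resno == r, ]
    expect_equal(nrow(a), 1L)
    expect_point_equal(unlist(a[, c("x", "y", "z")], use.names = FALSE),
                       conf$coords[t, ], 1e-3 + 1e-9)
  }
})

test_that("fixture ATOM records obey the fixed-width layout", {
  conf <- sample_conformation(2, seed = 1)
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(conf, path)
  atoms <- grep("^ATOM", readLines(path), value = TRUE)
  expect_true(all(nchar(atoms) == 80L))
  expect_true(all(substr(atoms, 18, 20) == "ALA"))
  expect_true(all(substr(atoms, 22, 22) == "A"))
  # coordinate columns parse back as numbers
  expect_false(any(is.na(as.numeric(substr(atoms, 31, 38)))))
})

test_that("only the first model is parsed and non-backbone atoms are dropped", {
  c1 <- sample_conformation(2, seed = 2)
  c2 <- sample_conformation(2, seed = 3)
  p1 <- tempfile(); p2 <- tempfile(); both <- tempfile(fileext = ".pdb")
  write_fixture_pdb(c1, p1)
  write_fixture_pdb(c2, p2)
  l1 <- readLines(p1)
  l2 <- sub("MODEL     1", "MODEL     2", readLines(p2), fixed = TRUE)
  cb <- sprintf(
    "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
    9000, "CB", " ", "ALA", "A", 1, " ", 1.0, 2.0, 3.0, 1.0, 0.0, "C")
  writeLines(c(l1[-length(l1)], l2[-1], cb, "END"), both)
  res <- parse_first_model(both)
  expect_false("CB" %in% res$elety)
  a <- res[res$elety == "N" & res$resno == 1, ]
  expect_point_equal(unlist(a[, c("x", "y", "z")], use.names = FALSE),
                     c1$coords[1, ], 1e-3 + 1e-9)
  expect_equal(nrow(res), 9L) # first model only
})

test_that("segmentation splits at Pro/Gly, gaps and incomplete residues", {
  conf <- sample_conformation(5, seed = 4)
  path <- complete_fixture(conf, tempfile(fileext = ".pdb"))
  segs <- segmentize(parse_first_model(path), "fix")
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$n_residues, 5L)

  # renaming residue 3 to GLY splits into two 2-residue segments
  lines <- readLines(path)
  sel <- grepl("^ATOM", lines) & substr(lines, 23, 26) == "   3"
  lines[sel] <- sub("ALA", "GLY", lines[sel])
  p2 <- tempfile(fileext = ".pdb")
  writeLines(lines, p2)
  segs2 <- segmentize(parse_first_model(p2), "fix")
  expect_length(segs2, 2L)
  expect_equal(vapply(segs2, function(s) s$n_residues, 1L), c(2L, 2L))

  # a residue missing its amide H acts as a break point
  lines <- readLines(path)
  drop <- which(grepl("^ATOM", lines) & substr(lines, 23, 26) == "   3" &
                  trimws(substr(lines, 13, 16)) == "H")
  p3 <- tempfile(fileext = ".pdb")
  writeLines(lines[-drop], p3)
  segs3 <- segmentize(parse_first_model(p3), "fix")
  expect_length(segs3, 2L)

  # a numbering gap too
  lines <- readLines(path)
  keep <- !(grepl("^ATOM", lines) & substr(lines, 23, 26) == "   3")
  p4 <- tempfile(fileext = ".pdb")
  writeLines(lines[keep], p4)
  expect_length(segmentize(parse_first_model(p4), "fix"), 2L)
})

test_that("segment conformations encode like the original coordinates", {
  conf <- sample_conformation(4, geometry_params(omega_jitter = 5), seed = 15)
  path <- complete_fixture(conf, tempfile(fileext = ".pdb"))
  segs <- segmentize(parse_first_model(path), "fix")
  expect_length(segs, 1L)
  sc <- segment_conformation(segs[[1]])
  expect_equal(nrow(sc$coords), nrow(conf$coords))
  # orientation bits survive the 1e-3 A coordinate rounding
  expect_identical(as.character(encode(sc, tol = 1e-4)),
                   as.character(encode(conf)))
})
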