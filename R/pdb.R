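# PDB ingestion: first-model backbone extraction, segmentation into
# proline/glycine-free stretches with complete (N, CA, C, H, HA) residues,
# and a fixed-width fixture writer so tests and examples need no download.

#' Parse the first model of a PDB file
#'
#' Keeps only the ATOM records of MODEL 1 (or of the sole model), restricted
#' to the backbone atoms N, CA, C, H, HA with blank or `A` alternate
#' location. Hydrogen naming variants such as `H1`, `HA2`, `HA3` are treated
#' as missing. Parsing is delegated to [bio3d::read.pdb()] after trimming
#' the text to the first model.
#'
#' @param path Path to a PDB-format file.
#' @return Data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`; zero rows (with a warning) when the file has no
#'   ATOM records.
#' @export
parse_first_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) lines <- lines[seq_len(endm[1L])]
  if (!any(startsWith(lines, "ATOM"))) {
    warning("no ATOM records in ", path)
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      elety = character(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" &
             at$elety %in% c("N", "CA", "C", "H", "HA") &
             (is.na(at$alt) | at$alt %in% c("", "A")), , drop = FALSE]
  data.frame(chain = at$chain, resno = at$resno,
             insert = ifelse(is.na(at$insert), "", at$insert),
             resid = at$resid, elety = at$elety,
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}

#' Split parsed residues into backbone segments
#'
#' A segment is a maximal stretch of residues that is contiguous in author
#' numbering within one chain, contains no proline or glycine, has no
#' insertion codes, and has all five backbone atoms (N, CA, C, H, HA) in
#' every residue. Proline/glycine residues, numbering gaps, chain changes
#' and incomplete residues act as break points; segments shorter than 2
#' residues are dropped.
#'
#' @param residues Output of [parse_first_model()].
#' @param source_id Identifier recorded on each segment.
#' @return List of `dmdgp_segment` objects: `source`, `chain`, `start`,
#'   `end`, `n_residues` and `residues` (a per-residue data frame with one
#'   coordinate triple per atom kind).
#' @export
segmentize <- function(residues, source_id = "unknown") {
  segs <- list()
  if (nrow(residues) == 0L) return(segs)
  need <- c("N", "CA", "C", "H", "HA")
  for (ch in unique(residues$chain)) {
    rch <- residues[residues$chain == ch, , drop = FALSE]
    nums <- sort(unique(rch$resno))
    run <- list()
    flush <- function() {
      if (length(run) >= 2L) {
        df <- do.call(rbind, run)
        segs[[length(segs) + 1L]] <<- structure(
          list(source = source_id, chain = ch, start = df$resno[1L],
               end = df$resno[nrow(df)], n_residues = nrow(df), residues = df),
          class = "dmdgp_segment")
      }
      run <<- list()
    }
    prev <- NULL
    for (rn in nums) {
      rr <- rch[rch$resno == rn, , drop = FALSE]
      ok <- all(need %in% rr$elety) && all(rr$insert == "") &&
        !(rr$resid[1L] %in% c("PRO", "GLY")) &&
        !any(duplicated(rr$elety))
      contiguous <- !is.null(prev) && rn == prev + 1L
      if (!ok || (!contiguous && length(run) > 0L)) {
        flush()
        prev <- NULL
        if (!ok) next
      }
      row <- data.frame(resno = rn, resid = rr$resid[1L], stringsAsFactors = FALSE)
      for (k in need) {
        a <- rr[rr$elety == k, ]
        row[[paste0(tolower(k), "_x")]] <- a$x
        row[[paste0(tolower(k), "_y")]] <- a$y
        row[[paste0(tolower(k), "_z")]] <- a$z
      }
      run[[length(run) + 1L]] <- row
      prev <- rn
    }
    flush()
  }
  segs
}

#' @export
print.dmdgp_segment <- function(x, ...) {
  cat("Backbone segment ", x$source, " chain ", x$chain, ": residues ",
      x$start, "-", x$end, " (", x$n_residues, ")\n", sep = "")
  invisible(x)
}

#' Conformation of a backbone segment in the DMDGP order
#'
#' Maps a segment's atom coordinates onto [build_order()] positions
#' (repeated alpha-carbons reuse the first-occurrence coordinates).
#'
#' @param segment A `dmdgp_segment`.
#' @return A `dmdgp_conformation`.
#' @export
segment_conformation <- function(segment) {
  order <- build_order(segment$n_residues)
  df <- segment$residues
  coords <- t(vapply(seq_len(nrow(order)), function(t) {
    k <- tolower(order$kind[t])
    r <- order$residue[t]
    c(df[[paste0(k, "_x")]][r], df[[paste0(k, "_y")]][r], df[[paste0(k, "_z")]][r])
  }, numeric(3L)))
  new_conformation(order, coords)
}

#' Write a conformation as a poly-alanine PDB fixture
#'
#' Emits standard fixed-width ATOM records (first model, occupancy 1.00,
#' B-factor 0.00, element column set) for the distinct atoms of a sampled
#' conformation; repeated order vertices share their atom and are written
#' once. Residues are named ALA so the file survives the proline/glycine
#' filter on re-ingestion.
#'
#' @param conf A `dmdgp_conformation`.
#' @param path Output path.
#' @param chain Chain identifier (single character).
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(conf, path, chain = "A") {
  order <- conf$order
  X <- conf$coords
  elem <- c(N = "N", CA = "C", C = "C", H = "H", HA = "H")
  lines <- c("MODEL     1")
  serial <- 0L
  for (r in seq_len(attr(order, "n_residues"))) {
    for (k in c("N", "CA", "C", "H", "HA")) {
      t <- order_position(order, k, r)
      if (is.na(t)) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
        serial, k, " ", "ALA", chain, r, " ",
        X[t, 1L], X[t, 2L], X[t, 3L], 1.0, 0.0, elem[[k]]))
    }
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                            serial + 1L, "ALA", chain,
                            attr(order, "n_residues")),
             "ENDMDL", "END")
  writeLines(lines, path)
  invisible(path)
}
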