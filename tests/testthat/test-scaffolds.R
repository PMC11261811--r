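test_that("Class-1 scaffold realizes the requested orientation pattern", {
  sc <- build_cross_beta_scaffold(1, 4, 7, 5.5, 12.0)
  expect_equal(nrow(sc$chains), 8)
  dirs <- as.matrix(sc$chains[, c("dx", "dy", "dz")])
  for (s in 1:2) {
    idx <- which(sc$chains$sheet_id == s)
    dots <- tcrossprod(dirs[idx, ])
    expect_true(all(dots[upper.tri(dots)] > 0))
  }
  cross <- tcrossprod(dirs[sc$chains$sheet_id == 1, ],
                      dirs[sc$chains$sheet_id == 2, ])
  expect_true(all(cross < 0))
})

test_that("degenerate single-strand sheets give two antiparallel chains", {
  sc <- build_cross_beta_scaffold(1, 1, 7)
  expect_equal(nrow(sc$chains), 2)
  d <- as.matrix(sc$chains[, c("dx", "dy", "dz")])
  expect_lt(sum(d[1, ] * d[2, ]), 0)
})

test_that("in-sheet CA spacing matches the request (independent geometry)", {
  sc <- build_cross_beta_scaffold(1, 4, 7, 5.5, 12.0)
  at <- scaffold_atoms(sc)
  # independent check: per sheet, order strands by mean y, mean nearest
  # CA-CA distance between adjacent strands
  vals <- c()
  for (s in 1:2) {
    ids <- sc$chains$chain[sc$chains$sheet_id == s]
    cas <- lapply(ids, function(id) {
      as.matrix(at[at$chain == id & at$atom == "CA", c("x", "y", "z")])
    })
    ord <- order(vapply(cas, function(m) mean(m[, 2]), numeric(1)))
    for (j in seq_len(length(ids) - 1)) {
      a <- cas[[ord[j]]]; b <- cas[[ord[j + 1]]]
      dmat <- as.matrix(dist(rbind(a, b)))[seq_len(nrow(a)),
                                           nrow(a) + seq_len(nrow(b))]
      vals <- c(vals, mean(apply(dmat, 1, min)))
    }
  }
  expect_lt(abs(mean(vals) - 5.5), 0.1)
  expect_lt(abs(measure_d_sheet(sc) - 12.0), 0.5)
})

test_that("Class-8 sheets are antiparallel within each sheet", {
  sc <- build_cross_beta_scaffold(8, 4, 7)
  dirs <- as.matrix(sc$chains[, c("dx", "dy", "dz")])
  for (s in 1:2) {
    idx <- which(sc$chains$sheet_id == s)
    for (j in seq_len(length(idx) - 1)) {
      expect_lt(sum(dirs[idx[j], ] * dirs[idx[j + 1], ]), 0)
    }
  }
})

test_that("unsupported symmetry classes are rejected", {
  expect_error(build_cross_beta_scaffold(3, 4, 7), "unsupported")
})

test_that("replicate_unit with identity transform and one copy is identity", {
  sc <- build_cross_beta_scaffold(1, 2, 7)
  out <- replicate_unit(sc, diag(3), c(0, 0, 0), 1)
  expect_equal(out$atoms, sc$atoms)
  expect_equal(out$chains, sc$chains)
})

test_that("translational replication extends the sheets without clashes", {
  sc <- build_cross_beta_scaffold(1, 2, 7)
  out <- replicate_unit(sc, diag(3), c(0, 2 * sc$d_strand, 0), 4)
  expect_equal(nrow(out$chains), 16)
  expect_lt(abs(measure_d_strand(out) - sc$d_strand), 0.1)
})

test_that("overlapping copies raise a clash error naming the copies", {
  sc <- build_cross_beta_scaffold(1, 2, 7)
  expect_error(replicate_unit(sc, diag(3), c(0, 0, 0), 2),
               "clash between copies 1 and 2")
  expect_error(replicate_unit(sc, diag(3), c(0.4, 0, 0), 2), "clash")
})

test_that("capping flags termini and is idempotent", {
  sc <- build_cross_beta_scaffold(1, 2, 7)
  expect_false(any(sc$chains$capped_n))
  capped <- cap_termini(sc, TRUE, TRUE)
  expect_true(all(capped$chains$capped_n))
  expect_true(all(capped$chains$capped_c))
  expect_identical(cap_termini(capped, TRUE, TRUE), capped)
  expect_identical(cap_termini(sc, FALSE, FALSE)$chains, sc$chains)
})

test_that("PDB round trip preserves coordinates, order and counts", {
  sc <- build_cross_beta_scaffold(1, 4, 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sc, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(sc$atoms))
  expect_equal(back$n_residues, 7)
  expect_equal(unique(back$atoms$chain), unique(sc$atoms$chain))
  ord0 <- order(sc$atoms$chain, sc$atoms$resno,
                match(sc$atoms$atom, c("N", "CA", "C", "O")))
  ord1 <- order(back$atoms$chain, back$atoms$resno,
                match(back$atoms$atom, c("N", "CA", "C", "O")))
  expect_lt(max(abs(as.matrix(sc$atoms[ord0, c("x", "y", "z")]) -
                      as.matrix(back$atoms[ord1, c("x", "y", "z")]))), 1e-3)
  # chain count by independent text scan of the file
  lines <- readLines(f)
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  expect_equal(length(unique(substr(atom_lines, 22, 22))), 8)
})

test_that("malformed or incomplete PDB input gives informative errors", {
  sc <- build_cross_beta_scaffold(1, 1, 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sc, f)
  lines <- readLines(f)
  bad <- lines
  i <- grep("^ATOM", bad)[2]
  substr(bad[i], 31, 38) <- "   xx.xx"
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(read_pdb(f2), paste0("line ", i))

  # drop every CA of residue 2
  noCA <- lines[!(grepl("^ATOM", lines) & grepl(" CA ", lines) &
                    substr(lines, 23, 26) == "   2")]
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(noCA, f3)
  expect_error(read_pdb(f3), "missing its CA")
  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "no such file")
})
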