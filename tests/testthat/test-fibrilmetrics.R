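test_that("H-bond detection matches a distance-matrix oracle on the scaffold", {
  sc <- build_cross_beta_scaffold(1, 4, 7)
  at <- scaffold_atoms(sc)
  crit <- hbond_criterion()
  hb <- backbone_hbonds(at, crit)
  # independent oracle: all N-O pairs within the cutoff, excluding close
  # intra-chain neighbours
  don <- at[at$atom == "N", ]
  acc <- at[at$atom == "O", ]
  d <- as.matrix(dist(rbind(as.matrix(don[, c("x", "y", "z")]),
                            as.matrix(acc[, c("x", "y", "z")]))))
  d <- d[seq_len(nrow(don)), nrow(don) + seq_len(nrow(acc))]
  cnt <- 0
  for (i in seq_len(nrow(don))) {
    for (j in seq_len(nrow(acc))) {
      if (d[i, j] <= crit$distance &&
          (don$chain[i] != acc$chain[j] ||
             abs(don$resno[i] - acc$resno[j]) >= 3)) cnt <- cnt + 1
    }
  }
  expect_equal(nrow(hb), cnt)
  expect_gt(nrow(hb), 0)
})

test_that("distant chains and a zero threshold give no H-bonds", {
  sc <- build_cross_beta_scaffold(1, 1, 7)  # two sheets 12 A apart
  far <- scaffold_atoms(sc)
  far$y[far$chain == "B"] <- far$y[far$chain == "B"] + 50
  expect_equal(nrow(backbone_hbonds(far)), 0)
  at <- scaffold_atoms(build_cross_beta_scaffold(1, 4, 7))
  expect_equal(nrow(backbone_hbonds(at, hbond_criterion(distance = 1e-12))), 0)
})

test_that("beta content is high for fibrils, zero for coils, half for mixtures", {
  fib <- scaffold_atoms(build_cross_beta_scaffold(1, 4, 7))
  expect_gte(beta_content(fib), 90)
  coil <- coil_frame(8, 7, seed = 5)
  expect_equal(beta_content(coil), 0)
  # half the chains in a sheet, half dispersed far away
  sheet <- mixed_sheet_frame(4, 0)
  disp <- coil_frame(4, 7, seed = 6)
  disp$chain <- chartr("ABCD", "EFGH", disp$chain)
  disp$x <- disp$x + 200
  half <- dplyr::bind_rows(sheet, disp)
  quantum <- 100 / (8 * 7)
  expect_lt(abs(beta_content(half) - 50), 4 * quantum + 1e-9)
})

test_that("parallel fraction is exact on ideal Class-1/Class-8 fixtures", {
  for (n in 2:4) {
    c1 <- scaffold_atoms(build_cross_beta_scaffold(1, n, 7))
    c8 <- scaffold_atoms(build_cross_beta_scaffold(8, n, 7))
    expect_equal(parallel_fraction(c1), 100)
    expect_equal(parallel_fraction(c8), 0)
  }
})

test_that("no-sheet frames report the NA sentinel, not zero", {
  coil <- coil_frame(4, 7, seed = 8)
  expect_true(is.na(parallel_fraction(coil)))
})

test_that("a constructed 3:1 mixed sheet gives 75% parallel", {
  fr <- mixed_sheet_frame(4, 1)
  sp <- crossbeta:::.strand_pairs(fr, hbond_criterion())
  expect_equal(nrow(sp$pairs), 4)  # adjacency ladder of 5 strands
  expect_equal(parallel_fraction(fr), 75)
})

test_that("layer counting finds the sheets of the largest aggregate", {
  c1 <- scaffold_atoms(build_cross_beta_scaffold(1, 4, 7))
  expect_equal(count_layers(c1), 2L)
  single <- mixed_sheet_frame(4, 0)
  expect_equal(count_layers(single), 1L)
  # a second assembly 100 A away is a different aggregate
  far <- c1
  far$chain <- chartr("ABCDEFGH", "IJKLMNOP", far$chain)
  far$x <- far$x + 100
  both <- dplyr::bind_rows(c1, far)
  expect_equal(count_layers(both), 2L)
  expect_equal(largest_aggregate(both), 8L)
})

test_that("graph layer counting agrees with a union-find oracle", {
  frames <- list(scaffold_atoms(build_cross_beta_scaffold(1, 4, 7)),
                 scaffold_atoms(build_cross_beta_scaffold(8, 3, 7)),
                 mixed_sheet_frame(3, 2))
  for (fr in frames) {
    sp <- crossbeta:::.strand_pairs(fr, hbond_criterion())
    # union-find over the strand-pair graph
    ids <- unique(fr$chain)
    parent <- stats::setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    if (nrow(sp$pairs) > 0) {
      for (r in seq_len(nrow(sp$pairs))) {
        ra <- find(sp$pairs$chain_a[r]); rb <- find(sp$pairs$chain_b[r])
        if (ra != rb) parent[[ra]] <- rb
      }
    }
    roots <- vapply(ids, find, character(1))
    sizes <- table(roots)
    oracle_layers <- sum(sizes >= 2)
    expect_equal(count_layers(fr), oracle_layers)
  }
})

test_that("metrics are invariant under rigid motion and periodic rewrap", {
  fr <- scaffold_atoms(build_cross_beta_scaffold(1, 2, 7))
  crit <- hbond_criterion()
  b0 <- beta_content(fr, crit); p0 <- parallel_fraction(fr, crit)
  # rigid motion
  rot <- rotation_about_z(1.1)
  moved <- fr
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% t(rot)
  moved[, c("x", "y", "z")] <- as.data.frame(sweep(xyz, 2, c(5, -3, 8), "+"))
  expect_equal(beta_content(moved, crit), b0)
  expect_equal(parallel_fraction(moved, crit), p0)
  # periodic rewrap: push the frame across a box boundary and wrap
  box <- 60
  wrapped <- fr
  wrapped$x <- (wrapped$x + 55) %% box
  wrapped$y <- (wrapped$y + 58) %% box
  attr(wrapped, "box") <- box
  expect_equal(beta_content(wrapped, crit), b0)
  expect_equal(parallel_fraction(wrapped, crit), p0)
  expect_equal(count_layers(wrapped, crit), count_layers(fr, crit))
})

test_that("trajectory metrics are per-frame, time-ordered, and error on empty", {
  sc <- scaffold_atoms(build_cross_beta_scaffold(1, 4, 7))
  traj <- list(sc, sc, sc)
  attr(traj, "times") <- c(0, 1, 2)
  m <- traj_metrics(traj)
  expect_equal(nrow(m), 3)
  expect_equal(length(unique(m$beta_content)), 1)
  expect_equal(length(unique(m$n_layers)), 1)
  expect_error(traj_metrics(list()), "empty")
})

test_that("beta content rises along a coil-to-fibril interpolation", {
  fib <- scaffold_atoms(build_cross_beta_scaffold(1, 4, 7))
  coil <- coil_frame(8, 7, spacing = 40, seed = 10)
  # align tables and interpolate coordinates
  key <- function(d) paste(d$chain, d$resno, d$atom)
  coil <- coil[match(key(fib), key(coil)), ]
  frames <- lapply(seq(0, 1, length.out = 6), function(a) {
    f <- fib
    f$x <- (1 - a) * coil$x + a * fib$x
    f$y <- (1 - a) * coil$y + a * fib$y
    f$z <- (1 - a) * coil$z + a * fib$z
    f
  })
  attr(frames, "times") <- seq_along(frames)
  m <- traj_metrics(frames)
  sm <- stats::filter(m$beta_content, rep(1 / 2, 2), sides = 1)
  expect_true(all(diff(sm[-1]) >= -1e-9))
  expect_equal(m$beta_content[1], 0)
  expect_gte(m$beta_content[6], 90)
})
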