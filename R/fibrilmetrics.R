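#' Hydrogen-bond criterion for beta-ladder detection
#'
#' A backbone H-bond is called when a donor amide bead/atom (`N`/`NH`) and
#' an acceptor carbonyl (`O` if present, else the `CO`/`C` bead) lie
#' within `distance`. A strand pair is called when the H-bonded residues
#' on either chain form a consecutive run of at least `min_run`.
#'
#' @param distance Donor-acceptor cutoff, Angstrom.
#' @param min_run Minimum consecutive H-bonded residue run (>= 2).
#' @param aggregate_cut Chain-chain CA contact distance defining membership
#'   in one aggregate, Angstrom (spans the inter-sheet stacking distance).
#' @return An `hbond_criterion` list.
#' @export
hbond_criterion <- function(distance = 4.5, min_run = 3, aggregate_cut = 13) {
  stopifnot(distance >= 0, min_run >= 2, aggregate_cut > 0)
  structure(list(distance = distance, min_run = min_run,
                 aggregate_cut = aggregate_cut),
            class = "hbond_criterion")
}

# A "frame" is a tibble with columns chain, resno, atom, x, y, z.
# Scaffold atom tables and CG trajectory frames share this layout; CG
# frames carry the periodic box edge in attr(frame, "box").
.check_frame <- function(frame) {
  need <- c("chain", "resno", "atom", "x", "y", "z")
  if (!all(need %in% names(frame))) {
    abort(paste0("frame must have columns: ", paste(need, collapse = ", ")))
  }
  invisible(TRUE)
}

# squared distance matrix, minimum-image when a box is given
.pd2 <- function(a, b, box = NULL) {
  if (is.null(box)) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    return(d2)
  }
  d2 <- 0
  for (k in 1:3) {
    dk <- abs(outer(a[, k], b[, k], "-"))
    dk <- pmin(dk, box - dk)
    d2 <- d2 + dk^2
  }
  d2
}

# make each chain whole across the periodic boundary (walk beads in file
# order, shifting each by the minimum image of its step)
.unwrap_frame <- function(frame) {
  box <- attr(frame, "box")
  if (is.null(box)) return(frame)
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  for (id in unique(frame$chain)) {
    idx <- which(frame$chain == id)
    for (j in seq_along(idx)[-1]) {
      k <- idx[j]; prev <- idx[j - 1]
      step <- xyz[k, ] - xyz[prev, ]
      step <- step - box * round(step / box)
      xyz[k, ] <- xyz[prev, ] + step
    }
  }
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

#' Backbone hydrogen bonds in a frame
#'
#' @param frame Frame tibble (chain, resno, atom, x, y, z); atomistic
#'   frames use atoms N/CA/C/O, coarse-grained frames NH/CA/CO/R.
#' @param criterion An [hbond_criterion()].
#' @return Tibble: donor_chain, donor_resno, acceptor_chain,
#'   acceptor_resno, distance.
#' @export
backbone_hbonds <- function(frame, criterion = hbond_criterion()) {
  .check_frame(frame)
  box <- attr(frame, "box")
  frame <- .unwrap_frame(frame)
  don <- frame[frame$atom %in% c("N", "NH"), ]
  acc_name <- if (any(frame$atom == "O")) "O" else if (any(frame$atom == "CO")) "CO" else "C"
  acc <- frame[frame$atom == acc_name, ]
  if (nrow(don) == 0 || nrow(acc) == 0) {
    abort("frame lacks donor (N/NH) or acceptor (O/CO) sites")
  }
  empty <- tibble(donor_chain = character(), donor_resno = integer(),
                  acceptor_chain = character(), acceptor_resno = integer(),
                  distance = numeric())
  if (criterion$distance <= 0) return(empty)
  dm <- as.matrix(don[, c("x", "y", "z")])
  am <- as.matrix(acc[, c("x", "y", "z")])
  d2 <- .pd2(dm, am, box)
  hit <- which(d2 <= criterion$distance^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- tibble(
    donor_chain = don$chain[hit[, 1]],
    donor_resno = as.integer(don$resno[hit[, 1]]),
    acceptor_chain = acc$chain[hit[, 2]],
    acceptor_resno = as.integer(acc$resno[hit[, 2]]),
    distance = sqrt(d2[hit])
  )
  # drop intra-chain sequence neighbors (|i - j| < 3)
  keep <- out$donor_chain != out$acceptor_chain |
    abs(out$donor_resno - out$acceptor_resno) >= 3
  out[keep, ]
}

# longest run of consecutive integers in a sorted unique vector
.longest_run <- function(r) {
  if (length(r) == 0) return(0L)
  r <- sort(unique(r))
  best <- 1L
  len <- 1L
  for (i in seq_along(r)[-1]) {
    len <- if (r[i] - r[i - 1] == 1) len + 1L else 1L
    best <- max(best, len)
  }
  best
}

# residues within runs >= min_run
.run_members <- function(r, min_run) {
  r <- sort(unique(r))
  if (length(r) == 0) return(integer())
  grp <- cumsum(c(1L, diff(r) != 1))
  keep <- as.integer(names(table(grp)[table(grp) >= min_run]))
  r[grp %in% keep]
}

# H-bonded strand pairs with orientation and ladder membership
.strand_pairs <- function(frame, criterion) {
  frame <- .unwrap_frame(frame)
  hb <- backbone_hbonds(frame, criterion)
  if (nrow(hb) == 0) {
    return(list(pairs = tibble(chain_a = character(), chain_b = character(),
                               n_bonds = integer(), parallel = logical()),
                members = list()))
  }
  a <- pmin(hb$donor_chain, hb$acceptor_chain)
  b <- pmax(hb$donor_chain, hb$acceptor_chain)
  inter <- a != b
  hb <- hb[inter, ]; a <- a[inter]; b <- b[inter]
  key <- paste(a, b, sep = "|")
  dirs <- .chain_dirs(frame)
  pairs <- list(); members <- list()
  for (k in unique(key)) {
    sub <- hb[key == k, ]
    ca <- sub("\\|.*", "", k); cb <- sub(".*\\|", "", k)
    res_a <- c(sub$donor_resno[sub$donor_chain == ca],
               sub$acceptor_resno[sub$acceptor_chain == ca])
    res_b <- c(sub$donor_resno[sub$donor_chain == cb],
               sub$acceptor_resno[sub$acceptor_chain == cb])
    if (max(.longest_run(res_a), .longest_run(res_b)) < criterion$min_run) next
    par <- sum(dirs[[ca]] * dirs[[cb]]) > 0
    pairs[[k]] <- tibble(chain_a = ca, chain_b = cb,
                         n_bonds = nrow(sub), parallel = par)
    members[[k]] <- list(
      chain = c(rep(ca, length(.run_members(res_a, criterion$min_run))),
                rep(cb, length(.run_members(res_b, criterion$min_run)))),
      resno = c(.run_members(res_a, criterion$min_run),
                .run_members(res_b, criterion$min_run)))
  }
  list(pairs = if (length(pairs)) bind_rows(pairs) else
         tibble(chain_a = character(), chain_b = character(),
                n_bonds = integer(), parallel = logical()),
       members = members)
}

# N-to-C end-to-end unit vector per chain, from CA positions
.chain_dirs <- function(frame) {
  out <- list()
  for (id in unique(frame$chain)) {
    m <- frame[frame$chain == id & frame$atom == "CA", ]
    m <- m[order(m$resno), c("x", "y", "z")]
    v <- as.numeric(m[nrow(m), ] - m[1, ])
    out[[id]] <- if (sum(v^2) == 0) c(0, 0, 0) else v / sqrt(sum(v^2))
  }
  out
}

#' Percent of residues in beta-sheet ladders
#'
#' @inheritParams backbone_hbonds
#' @return Percentage (0-100).
#' @export
beta_content <- function(frame, criterion = hbond_criterion()) {
  .check_frame(frame)
  sp <- .strand_pairs(frame, criterion)
  total <- nrow(unique(frame[, c("chain", "resno")]))
  if (length(sp$members) == 0) return(0)
  marked <- unique(bind_rows(lapply(sp$members, as_tibble)))
  100 * nrow(marked) / total
}

#' Percent of H-bonded strand pairs with parallel orientation
#'
#' Orientation of a pair is the sign of the dot product of the two
#' strands' N-to-C end-to-end vectors. Returns `NA` ("no sheets") when no
#' H-bonded strand pair exists, rather than 0, so that coil frames do not
#' masquerade as antiparallel.
#'
#' @inheritParams backbone_hbonds
#' @return Percentage (0-100) or `NA_real_` when no pairs exist.
#' @export
parallel_fraction <- function(frame, criterion = hbond_criterion()) {
  sp <- .strand_pairs(frame, criterion)
  if (nrow(sp$pairs) == 0) return(NA_real_)
  100 * mean(sp$pairs$parallel)
}

# chain-level aggregate graph (CA-CA contact within aggregate_cut)
.aggregate_components <- function(frame, criterion) {
  ids <- unique(frame$chain)
  if (length(ids) == 1) return(list(ids))
  box <- attr(frame, "box")
  frame <- .unwrap_frame(frame)
  cas <- lapply(ids, function(id) {
    as.matrix(frame[frame$chain == id & frame$atom == "CA",
                    c("x", "y", "z")])
  })
  edges <- NULL
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      d2 <- .pd2(cas[[i]], cas[[j]], box)
      if (min(d2) <= criterion$aggregate_cut^2) {
        edges <- rbind(edges, c(ids[i], ids[j]))
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(), to = character())
        else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  split(ids, comp$membership[ids])
}

#' Number of beta-sheet layers in the largest aggregate
#'
#' Sheets are connected components of the H-bonded strand-pair graph; the
#' count is taken over the chains of the largest aggregate (chains within
#' CA-contact distance of each other).
#'
#' @inheritParams backbone_hbonds
#' @return Integer layer count (0 if the largest aggregate has no sheets).
#' @export
count_layers <- function(frame, criterion = hbond_criterion()) {
  .check_frame(frame)
  comps <- .aggregate_components(frame, criterion)
  big <- comps[[which.max(vapply(comps, length, integer(1)))]]
  sp <- .strand_pairs(frame, criterion)
  pr <- sp$pairs
  pr <- pr[pr$chain_a %in% big & pr$chain_b %in% big, ]
  if (nrow(pr) == 0) return(0L)
  g <- igraph::graph_from_data_frame(pr[, c("chain_a", "chain_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  sum(comp$csize >= 2)
}

#' Size of the largest aggregate (chains)
#'
#' @inheritParams backbone_hbonds
#' @return Integer chain count.
#' @export
largest_aggregate <- function(frame, criterion = hbond_criterion()) {
  .check_frame(frame)
  comps <- .aggregate_components(frame, criterion)
  max(vapply(comps, length, integer(1)))
}

#' All fibril metrics for one frame
#'
#' @inheritParams backbone_hbonds
#' @param time Time stamp carried into the output.
#' @return One-row tibble: time, beta_content, parallel_fraction,
#'   n_layers, largest_aggregate.
#' @export
frame_metrics <- function(frame, criterion = hbond_criterion(), time = NA_real_) {
  tibble(
    time = time,
    beta_content = beta_content(frame, criterion),
    parallel_fraction = parallel_fraction(frame, criterion),
    n_layers = count_layers(frame, criterion),
    largest_aggregate = largest_aggregate(frame, criterion)
  )
}

#' Fibril metrics along a trajectory
#'
#' @param traj A `cg_trajectory` (from [run_dmd()]) or a list of frame
#'   tibbles with a `times` attribute.
#' @param criterion An [hbond_criterion()].
#' @return Tibble of per-frame metrics, one row per frame in time order.
#' @export
traj_metrics <- function(traj, criterion = hbond_criterion()) {
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  times <- if (inherits(traj, "cg_trajectory")) traj$times
           else attr(traj, "times") %||% seq_along(frames)
  if (length(frames) == 0) abort("empty trajectory")
  out <- purrr::map2(frames, times, function(f, t) {
    frame_metrics(.as_frame_tibble(f), criterion, time = t)
  })
  out <- bind_rows(out)
  class(out) <- c("cg_metrics", class(out))
  out
}

.as_frame_tibble <- function(f) {
  if (inherits(f, "scaffold")) return(scaffold_atoms(f))
  as_tibble(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
autoplot.cg_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("beta_content", "parallel_fraction"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$time, y = .data$value, colour = .data$metric)) +
    geom_line() +
    labs(x = "time (reduced units)", y = "percent", colour = NULL) +
    theme_minimal()
}
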