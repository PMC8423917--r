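#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity for weighted undirected graphs:
#' \deqn{Q = \frac{1}{2m}\sum_{u,v}\left[W_{uv} -
#'   \frac{s_u s_v}{2m}\right]\delta(c_u, c_v)}
#' with \eqn{s_u} the weighted strength of node u and 2m the total edge
#' weight doubled. Q measures the excess of within-community edge weight
#' over a strength-matched random expectation; it is 0 for the all-in-one
#' partition and at most 1.
#'
#' @param net an `igraph` weighted undirected network.
#' @param membership integer vector of community ids, named by node or
#'   aligned with the vertex order; must cover every node.
#' @param resolution resolution parameter (1 = plain modularity).
#' @return The modularity Q.
#' @export
modularity_q <- function(net, membership, resolution = 1) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  vnames <- igraph::V(net)$name
  if (!is.null(names(membership))) {
    if (!all(vnames %in% names(membership))) {
      stop("membership does not cover all nodes")
    }
    membership <- membership[vnames]
  }
  if (length(membership) != n || anyNA(membership)) {
    stop("membership does not cover all nodes")
  }
  A <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = TRUE)
  .modularity_matrix(A, as.integer(factor(membership)), resolution)
}

# Q from a (symmetric, zero-diagonal or 2x-loop-diagonal) adjacency matrix
.modularity_matrix <- function(A, memb, resolution = 1) {
  s <- Matrix::rowSums(A)
  m2 <- sum(s)
  if (m2 == 0) stop("network has no edges")
  comms <- sort(unique(memb))
  e_in <- vapply(comms, function(c) {
    idx <- which(memb == c)
    sum(A[idx, idx, drop = FALSE])
  }, 0)
  a <- vapply(comms, function(c) sum(s[memb == c]), 0)
  sum(e_in) / m2 - resolution * sum((a / m2)^2)
}

#' Louvain community detection
#'
#' Greedy modularity optimisation in two repeated phases: local moves (each
#' node is moved to the neighbouring community giving the largest modularity
#' increase, sweeping in a seeded random order until no move helps) and
#' aggregation (communities collapse to single nodes and the procedure
#' repeats on the reduced graph). Iteration stops when a full phase improves
#' Q by less than `tol`. Ties in the gain keep the node in its current
#' community, so runs are deterministic given the seed.
#'
#' @param net an `igraph` weighted undirected network with at least one edge.
#' @param seed integer seed for the node visit order.
#' @param resolution resolution parameter (1 = plain modularity, the
#'   default; exposed for exploration).
#' @param tol minimum per-phase modularity gain to continue.
#' @return An object of class `community_partition`: a list with
#'   `membership` (named integer vector, community ids contiguous from 1 and
#'   relabelled by community size, largest first), `Q` (the modularity of
#'   the assignment, identical to [modularity_q()] recomputed from scratch),
#'   `phase_q` (Q after each phase; non-decreasing), and `n_communities`.
#' @export
louvain <- function(net, seed = 1L, resolution = 1, tol = 1e-7) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0) stop("network has no edges")
  vnames <- igraph::V(net)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(net)))
  A0 <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = TRUE)
  A0 <- methods::as(A0, "generalMatrix")
  n0 <- nrow(A0)
  node2comm <- seq_len(n0)  # original node -> current community
  A <- A0
  phase_q <- numeric()
  q_prev <- -Inf
  rng_state <- .seed_stream(seed)
  repeat {
    order <- .local_shuffle(nrow(A), rng_state)
    rng_state <- rng_state + 1L
    memb <- .louvain_local_moves(A, order, resolution)
    node2comm <- memb[node2comm]
    q <- .modularity_matrix(A0, as.integer(factor(node2comm)), resolution)
    phase_q <- c(phase_q, q)
    if (q - q_prev < tol) break
    q_prev <- q
    # aggregate: communities become nodes; diagonal holds 2x internal weight
    f <- as.integer(factor(memb))
    B <- Matrix::sparseMatrix(i = seq_along(f), j = f, x = 1,
                              dims = c(length(f), max(f)))
    A <- Matrix::t(B) %*% A %*% B
    node2comm <- as.integer(factor(node2comm))
    if (nrow(A) == 1) break
  }
  final <- as.integer(factor(node2comm))
  # relabel by community size, largest first (ties keep first-seen order)
  sizes <- tabulate(final)
  relabel <- match(seq_along(sizes), order(-sizes, seq_along(sizes)))
  final <- relabel[final]
  q_final <- .modularity_matrix(A0, final, resolution)
  structure(
    list(membership = stats::setNames(final, vnames),
         Q = q_final, phase_q = phase_q,
         n_communities = max(final)),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  print(sort(table(x$membership), decreasing = TRUE))
  invisible(x)
}

# deterministic shuffle independent of the caller's RNG state
.seed_stream <- function(seed) as.integer(seed %% .Machine$integer.max)

.local_shuffle <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(n)
}

# one phase of local moves on adjacency matrix A (dgCMatrix);
# diagonal entries (2x self-loop weight from aggregation) stay internal to
# whatever community the node is in, so they drop out of the gains.
.louvain_local_moves <- function(A, order, resolution) {
  n <- nrow(A)
  s <- Matrix::rowSums(A)
  m2 <- sum(s)
  memb <- seq_len(n)
  sigma <- s  # total strength per community
  Ap <- A@p
  Ai <- A@i
  Ax <- A@x
  repeat {
    moved <- 0L
    for (i in order) {
      lo <- Ap[i] + 1L
      hi <- Ap[i + 1L]
      if (hi < lo) next
      nb <- Ai[lo:hi] + 1L
      w <- Ax[lo:hi]
      keep <- nb != i
      nb <- nb[keep]
      w <- w[keep]
      if (length(nb) == 0) next
      ci <- memb[i]
      sigma[ci] <- sigma[ci] - s[i]
      kin <- rowsum(w, memb[nb])
      cand <- as.integer(rownames(kin))
      gain <- kin[, 1] - resolution * s[i] * sigma[cand] / m2
      g_stay <- if (ci %in% cand) gain[match(ci, cand)] else 0
      best_idx <- which.max(gain)
      if (gain[best_idx] > g_stay + 1e-12) {
        ci_new <- cand[best_idx]
        memb[i] <- ci_new
        sigma[ci_new] <- sigma[ci_new] + s[i]
        moved <- moved + 1L
      } else {
        sigma[ci] <- sigma[ci] + s[i]
      }
    }
    if (moved == 0L) break
  }
  memb
}

#' Language composition of communities
#'
#' For each community, the number of member nodes and the percentage of each
#' language tag among them, mirroring the community-detection summary tables
#' of corpus studies (N, L1%, L2%, other%). Rows are ordered by community
#' size, largest first.
#'
#' @param partition a [louvain()] result (or any list with a named
#'   `membership` vector).
#' @param tags named character vector mapping every node to a tag (e.g. the
#'   language names, with `"other"` for ambiguous words).
#' @return Data frame with columns `community`, `n`, and one `pct_<tag>`
#'   column per distinct tag; percentages in each row sum to 100.
#' @export
community_composition <- function(partition, tags) {
  memb <- partition$membership
  if (!all(names(memb) %in% names(tags))) {
    stop("tags do not cover all nodes")
  }
  tags <- tags[names(memb)]
  lv <- unique(tags)
  comms <- sort(unique(memb))
  rows <- lapply(comms, function(c) {
    sub <- tags[memb == c]
    pcts <- vapply(lv, function(t) 100 * sum(sub == t) / length(sub), 0)
    cbind(data.frame(community = c, n = length(sub)),
          as.data.frame(as.list(stats::setNames(pcts, paste0("pct_", lv)))))
  })
  out <- do.call(rbind, rows)
  out[order(-out$n, out$community), , drop = FALSE]
}

#' Export a partition as TSV
#'
#' Columns: word, lang (if available from `tags`), community.
#'
#' @param partition a [louvain()] result.
#' @param path file path.
#' @param tags optional named character vector of node tags.
#' @export
write_partition <- function(partition, path, tags = NULL) {
  memb <- partition$membership
  df <- data.frame(word = names(memb),
                   lang = if (is.null(tags)) NA_character_ else tags[names(memb)],
                   community = as.integer(memb), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
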