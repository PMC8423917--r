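# Independent oracles and fixture builders used across the suite.

# build a cs_corpus from tagged-dialect lines without touching disk
corpus_from_lines <- function(lines, lang_a = "L1", lang_b = "L2") {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path, useBytes = FALSE)
  read_corpus(path, format = "tagged", lang_names = c(lang_a, lang_b))
}

# seeded random weighted graph: each pair connected with prob p,
# weights uniform in (lo, hi)
random_weighted_graph <- function(n, p = 0.5, lo = 0.05, hi = 1, seed = 1) {
  set.seed(seed)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- paste0("w", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (any(keep)) {
    g <- igraph::add_edges(g, pairs[, keep, drop = FALSE],
                           weight = stats::runif(sum(keep), lo, hi))
  }
  maxw <- if (igraph::ecount(g) > 0) max(igraph::E(g)$weight) else 0
  igraph::set_graph_attr(g, "maxw", maxw)
}

# brute-force geometric-mean weighted clustering: direct enumeration over
# all neighbour pairs, independent of the package implementation
oracle_clustering <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, attr = "weight",
                                             sparse = FALSE))
  if (max(A) == 0) return(stats::setNames(rep(0, nrow(A)), rownames(A)))
  W <- A / max(A)
  out <- numeric(nrow(A))
  for (u in seq_len(nrow(A))) {
    nb <- which(A[u, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- nb[[i]]
        w <- nb[[j]]
        if (A[v, w] > 0) s <- s + (W[u, v] * W[u, w] * W[v, w])^(1 / 3)
      }
    }
    out[[u]] <- 2 * s / (k * (k - 1))
  }
  stats::setNames(out, rownames(A))
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (k in seq_len(maxid + 1)) rec(c(prefix, k), max(maxid, k))
  }
  rec(integer(), 0L)
  out
}

# fast modularity for exhaustive search on tiny graphs
q_quick <- function(A, s, m2, memb) {
  same <- outer(memb, memb, "==")
  sum(A[same]) / m2 - sum(tapply(s, memb, sum)^2) / m2^2
}

# exhaustive modularity optimum over every partition (tiny graphs only)
oracle_best_modularity <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, attr = "weight",
                                             sparse = FALSE))
  s <- rowSums(A)
  m2 <- sum(s)
  best <- -Inf
  for (memb in all_partitions(nrow(A))) {
    q <- q_quick(A, s, m2, memb)
    if (q > best) best <- q
  }
  best
}

# independently coded Newton-Raphson logistic regression
oracle_logistic <- function(y, x, iter = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  H <- NULL
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    H <- t(X) %*% (X * w)
    step <- solve(H, t(X) %*% (y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  list(beta = beta, vcov = solve(H))
}

# Levenshtein distance by dynamic programming (oracle for adist-based code)
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  d <- matrix(0, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a)
  d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (a[[i]] != b[[j]]))
    }
  }
  d[length(a) + 1, length(b) + 1]
}

# graph with two disjoint triangles (unit weights), a standard modularity
# fixture
two_triangles <- function() {
  g <- igraph::make_empty_graph(n = 6, directed = FALSE)
  igraph::V(g)$name <- letters[1:6]
  g <- igraph::add_edges(g, c(1, 2, 2, 3, 1, 3, 4, 5, 5, 6, 4, 6),
                         weight = rep(1, 6))
  igraph::set_graph_attr(g, "maxw", 1)
}

# common Han-script fixtures (UTF-8 literals)
zh <- list(
  gangcai = "刚才",  # "just now"
  wo = "我",             # "I"
  bushi = "不是",
  gen = "跟",
  ni = "你",
  jiang = "讲",
  nage = "那个",     # "that"
  yao = "要",
  huijia = "回家",
  kan = "看",
  ligong = "理工"    # a word whose translation is a multiword phrase
)
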