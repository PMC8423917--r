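#' Build a weighted semantic network from word vectors
#'
#' Nodes are word types; an edge connects two words if and only if the
#' cosine similarity between their vectors is strictly positive, and the
#' edge weight is that cosine. Word pairs with negative cosines represent
#' high dissimilarity and are left unconnected; a cosine of exactly zero
#' carries no similarity signal and is likewise treated as a non-edge.
#' The maximum edge weight of the network is stored as a graph attribute
#' (`maxw`) for the clustering-coefficient normalisation.
#'
#' @param words either a character vector of word forms or a data frame with
#'   columns `form` and `lang`. Forms must be unique. Words absent from the
#'   embedding table are dropped (count recorded in the `n_dropped`
#'   attribute of the result).
#' @param table embedding matrix with rownames (from [train_sgns()] or
#'   [load_vectors()]).
#' @param block block size for the pairwise cosine computation; similarities
#'   are computed blockwise so memory stays proportional to one block of the
#'   similarity matrix rather than its full square.
#' @return An `igraph` undirected graph with vertex attributes `name` and
#'   `lang`, edge attribute `weight`, and graph attribute `maxw`.
#' @export
build_network <- function(words, table, block = 1024L) {
  if (is.data.frame(words)) {
    stopifnot(all(c("form", "lang") %in% names(words)))
    forms <- as.character(words$form)
    langs <- as.character(words$lang)
  } else {
    forms <- as.character(words)
    langs <- rep(NA_character_, length(forms))
  }
  if (anyDuplicated(forms)) stop("word forms must be unique")
  present <- forms %in% rownames(table)
  n_dropped <- sum(!present)
  forms <- forms[present]
  langs <- langs[present]
  if (length(forms) < 2) stop("fewer than 2 usable nodes")
  V <- table[forms, , drop = FALSE]
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0)) stop("zero-norm vector for: ",
                            paste(utils::head(forms[norms == 0]), collapse = ", "))
  Vn <- V / norms
  n <- nrow(Vn)
  edges_from <- list()
  edges_to <- list()
  edges_w <- list()
  bi <- 0L
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    S <- tcrossprod(Vn[start:end, , drop = FALSE], Vn)
    idx <- which(S > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      gi <- idx[, 1] + start - 1L
      gj <- idx[, 2]
      keep <- gi < gj
      if (any(keep)) {
        bi <- bi + 1L
        edges_from[[bi]] <- gi[keep]
        edges_to[[bi]] <- gj[keep]
        edges_w[[bi]] <- pmin(S[idx][keep], 1)
      }
    }
  }
  ef <- unlist(edges_from)
  et <- unlist(edges_to)
  ew <- unlist(edges_w)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- forms
  igraph::V(g)$lang <- langs
  if (length(ef) > 0) {
    g <- igraph::add_edges(g, rbind(ef, et), weight = ew)
  }
  g <- igraph::set_graph_attr(g, "maxw",
                              if (length(ew) > 0) max(ew) else 0)
  attr(g, "n_dropped") <- n_dropped
  g
}

#' Weighted clustering coefficient (geometric-mean form)
#'
#' For a node u with degree deg(u) (the number of retained edges at u), the
#' weighted clustering coefficient is
#' \deqn{C_u = \frac{2}{deg(u)(deg(u)-1)}
#'   \sum_{\{v,w\}} (\hat{W}_{uv}\hat{W}_{uw}\hat{W}_{vw})^{1/3}}
#' where the sum runs over unordered pairs of neighbours of u, edge weights
#' are normalised by the maximum weight in the network
#' (\eqn{\hat{W} = W / \max(w)}), and neighbour pairs without an edge
#' contribute zero. Nodes with degree below 2 have \eqn{C_u = 0}. The value
#' lies in `[0, 1]` and is invariant under uniform rescaling of all edge
#' weights. With all weights equal it reduces to the unweighted local
#' clustering coefficient (fraction of closed neighbour pairs).
#'
#' @param net an `igraph` network from [build_network()] (any weighted
#'   undirected graph works; `maxw` defaults to the maximum edge weight).
#' @param nodes optional vector of node names or indices; default all nodes.
#' @return Named numeric vector of clustering coefficients.
#' @export
clustering_coefficient <- function(net, nodes = NULL) {
  stopifnot(igraph::is_igraph(net))
  vnames <- igraph::V(net)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(net)))
  if (igraph::ecount(net) == 0) {
    out <- stats::setNames(rep(0, igraph::vcount(net)), vnames)
    return(if (is.null(nodes)) out else out[.resolve_nodes(nodes, vnames)])
  }
  maxw <- igraph::graph_attr(net, "maxw")
  if (is.null(maxw)) maxw <- max(igraph::E(net)$weight)
  A <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = TRUE)
  A <- methods::as(A, "generalMatrix")
  M <- A
  M@x <- (M@x / maxw)^(1 / 3)
  P <- M %*% M
  tri <- Matrix::rowSums(P * M)  # = diag(M^3): ordered neighbour pairs
  k <- igraph::degree(net)
  C <- ifelse(k < 2, 0, as.numeric(tri) / (k * (k - 1)))
  out <- stats::setNames(pmin(pmax(C, 0), 1), vnames)
  if (is.null(nodes)) out else out[.resolve_nodes(nodes, vnames)]
}

.resolve_nodes <- function(nodes, vnames) {
  if (is.character(nodes)) {
    missing <- setdiff(nodes, vnames)
    if (length(missing) > 0) {
      stop("node(s) not in network: ", paste(utils::head(missing), collapse = ", "))
    }
    nodes
  } else {
    if (any(nodes < 1 | nodes > length(vnames))) stop("node index out of range")
    vnames[nodes]
  }
}

#' Export / import a network as a weighted edge list
#'
#' Tab-separated `u v weight` rows, UTF-8.
#'
#' @param net an `igraph` network.
#' @param path file path.
#' @return `path` invisibly (write) or an `igraph` graph (read).
#' @export
write_edgelist <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(el[, c("from", "to", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  el <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          col.names = c("from", "to", "weight"),
                          colClasses = c("character", "character", "numeric"),
                          fileEncoding = "UTF-8")
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::set_graph_attr(g, "maxw",
                         if (nrow(el) > 0) max(el$weight) else 0)
}

#' Export a network as GraphML
#'
#' @param net an `igraph` network.
#' @param path file path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
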