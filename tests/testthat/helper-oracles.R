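# Independent brute-force oracles for the topology indicators and the
# two enrichment statistics. Deliberately naive: hand-rolled BFS over an
# adjacency list, exhaustive triangle enumeration, explicit Welch formula
# and explicit hypergeometric tail sums. They never call the package's
# metric code paths.

# adjacency list (named list of character vectors) from an igraph object
adj_list <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character()
  if (nrow(el)) for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

oracle_bfs <- function(adj, s) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist
}

oracle_apl_node <- function(adj, s) {
  d <- oracle_bfs(adj, s)
  reach <- d[is.finite(d)]
  if (length(reach) <= 1) 0 else sum(reach) / length(reach)
}

oracle_cc_node <- function(adj, s) {
  d <- oracle_bfs(adj, s)
  reach <- d[is.finite(d)]
  if (length(reach) <= 1) 0 else (length(reach) - 1) / sum(reach)
}

oracle_apl_net <- function(adj) {
  tot <- 0; cnt <- 0
  for (s in names(adj)) {
    d <- oracle_bfs(adj, s)
    r <- d[is.finite(d) & d > 0]
    tot <- tot + sum(r); cnt <- cnt + length(r)
  }
  if (cnt == 0) NA_real_ else tot / cnt
}

oracle_clustering_node <- function(adj, v) {
  nb <- adj[[v]]
  k <- length(nb)
  if (k < 2) return(0)
  tri <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (nb[j] %in% adj[[nb[i]]]) tri <- tri + 1
  2 * tri / (k * (k - 1))
}

oracle_cc_net <- function(adj) {
  mean(vapply(names(adj), function(v) oracle_clustering_node(adj, v),
              numeric(1)))
}

# Welch two-sample two-sided p from first principles
oracle_welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(t), df)
}

# closed-form Pearson chi-square for a 2x2 table
oracle_chi2_2x2 <- function(m) {
  m <- matrix(as.numeric(m), 2)  # avoid integer overflow in the products
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact upper-tail hypergeometric P(X >= k) by explicit tail sum
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# seeded random test graph with named vertices
random_test_graph <- function(n, seed, p = NULL) {
  withr::with_seed(seed, {
    if (is.null(p)) p <- stats::runif(1, 0.05, 0.5)
    g <- igraph::sample_gnp(n, p)
    igraph::set_vertex_attr(g, "name", value = sprintf("V%02d", seq_len(n)))
  })
}

# small star-shaped interaction table: CENTER linked to n_leaves leaves
star_interactions <- function(n_leaves = 9) {
  interaction_table(rep("HUB0", n_leaves),
                    sprintf("LEAF%02d", seq_len(n_leaves)),
                    rep(0.9, n_leaves))
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
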