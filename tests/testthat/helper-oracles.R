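# Independent oracles used to check the implementation by a second route.

# all simple cycles of a small molecular graph, by exhaustive DFS from every
# start atom (canonicalized to deduplicate rotations/reflections)
enumerate_simple_cycles <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- lapply(graph$adj, function(a) a$nbr)
  found <- list()
  seen <- character(0)
  canon <- function(cyc) {
    k <- length(cyc)
    best <- NULL
    for (v in list(cyc, rev(cyc))) {
      for (s in seq_len(k)) {
        cand <- v[c(s:k, seq_len(s - 1L))[seq_len(k)]]
        key <- paste(cand, collapse = ",")
        if (is.null(best) || key < best) best <- key
      }
    }
    best
  }
  walk <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1L] && length(path) >= 3L) {
        key <- canon(path)
        if (!key %in% seen) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (!w %in% path && w > path[1L]) {
        walk(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  found
}

# cycle-space dimension via an independent component count (igraph)
oracle_circuit_rank <- function(graph) {
  n <- nrow(graph$atoms)
  m <- nrow(graph$bonds)
  g <- igraph::graph_from_edgelist(as.matrix(graph$bonds[, c("a", "b")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  m - n + igraph::components(g)$no
}

# brute-force canonical ring string: generate every rotation x direction and
# pick the smallest under element-string / bond-precedence ordering
oracle_cycle_code <- function(graph, ring) {
  k <- length(ring)
  bond_sym <- c(single = "-", double = "=", triple = "#", aromatic = ":")
  bond_rank <- c(single = 1, double = 2, triple = 3, aromatic = 4)
  get_order <- function(a, b) {
    hit <- graph$bonds$a == min(a, b) & graph$bonds$b == max(a, b)
    graph$bonds$order[hit][1L]
  }
  cands <- list()
  for (v in list(ring, rev(ring))) {
    for (s in seq_len(k)) {
      cyc <- v[c(s:k, seq_len(s - 1L))[seq_len(k)]]
      el <- graph$atoms$element[cyc]
      ords <- vapply(seq_len(k), function(i)
        get_order(cyc[i], cyc[if (i == k) 1L else i + 1L]), "")
      cands[[length(cands) + 1L]] <- list(
        key = paste0(sprintf("%-2s", el), bond_rank[ords], collapse = ""),
        code = paste0(el, bond_sym[ords], collapse = ""))
    }
  }
  keys <- vapply(cands, `[[`, "", "key")
  cands[[order(keys, method = "radix")[1L]]]$code
}

# positional brute-force overlapping substring count
oracle_count_motif <- function(seq, motif) {
  n <- nchar(seq); w <- nchar(motif)
  if (w > n) return(0L)
  sum(vapply(1:(n - w + 1L), function(i)
    substring(seq, i, i + w - 1L) == motif, FALSE))
}

# trapezoidal area under an ROC point set, computed from the curve alone
oracle_trapezoid <- function(points) {
  dx <- diff(points$fpr)
  ybar <- (points$tpr[-1] + points$tpr[-nrow(points)]) / 2
  sum(dx * ybar)
}

# a small separable labeled dataset in binding_dataset form
make_toy_dataset <- function(n = 120L, seed = 42L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- cbind(matrix(rnorm(n * 3L), n), y * 2 + rnorm(n, sd = 0.3))
  colnames(X) <- c("1AAF:A", "2AAF:AA", "4chars:MW", "Hub:C-C-C-C")
  structure(list(pairs = data.frame(receptor_id = paste0("r", seq_len(n)),
                                    ligand_id = paste0("l", seq_len(n)),
                                    label = y),
                 X = X, y = y,
                 column_tags = c("1AAF", "2AAF", "4chars", "Hub")),
            class = "binding_dataset")
}
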