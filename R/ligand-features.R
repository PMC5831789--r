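# Structural ligand features: hub and cycle detection, canonical string
# encodings, the four physicochemical descriptors, and the per-ligand
# count vector.
#
# Canonical ordering used throughout: element symbols compare by plain
# (byte-wise) string order ("Br" < "C" < "Cl" < "N" < "O"); bond symbols by
# the precedence "-" < "=" < "#" < ":". "Clockwise" traversal on a drawing
# has no meaning on a topological graph, so both encodings take the
# lexicographically smallest candidate under this ordering, which in
# particular starts at the alphabetically first element.

# sortable key for one (element) or (bond, element) token; element padded to
# width 2 with a space so "C " < "Cl" byte-wise, bond mapped to its rank digit
element_key <- function(el) sprintf("%-2s", el)
bond_key <- function(order) as.character(BOND_RANK[order])

#' Find hub atoms
#'
#' A hub is an atom bonded to at least `min_satellites` heavy-atom neighbors.
#' Implicit hydrogens never count. The default threshold of 3 reproduces the
#' hub counts of drug-like ligands (an atom with three or more heavy
#' neighbors, i.e. any branching point).
#'
#' @param graph A `molgraph`.
#' @param min_satellites Minimum heavy-atom degree (>= 3).
#' @return Integer vector of hub atom indices, ascending.
#' @export
find_hubs <- function(graph, min_satellites = 3L) {
  if (!is_count(min_satellites) || min_satellites < 3)
    gpcr_stop("min_satellites must be an integer >= 3", "gpcr_config_error")
  which(atom_degrees(graph) >= min_satellites)
}

#' Encode one hub as a canonical string
#'
#' The code is the hub element followed by one (bond symbol, satellite
#' element) pair per neighbor, pairs sorted by satellite element (string
#' order) then bond symbol ("-" < "=" < "#" < ":"). String equality of codes
#' is structural equality of hub neighborhoods, independent of atom input
#' order.
#'
#' @param graph A `molgraph`.
#' @param hub Atom index of the hub.
#' @param min_satellites Threshold the hub must meet (default 3).
#' @return Single string, e.g. `"C-C-C-C-C"` for the neopentane center.
#' @export
encode_hub <- function(graph, hub, min_satellites = 3L) {
  na <- nrow(graph$atoms)
  if (!is_count(hub) || hub < 1 || hub > na)
    gpcr_stop(sprintf("hub index %s out of range", format(hub)), "gpcr_argument_error")
  sat <- graph$adj[[hub]]
  if (nrow(sat) < min_satellites)
    gpcr_stop(sprintf("atom %d has degree %d, below the hub threshold %d",
                      hub, nrow(sat), min_satellites), "gpcr_argument_error")
  el <- graph$atoms$element[sat$nbr]
  ord <- corder(element_key(el), BOND_RANK[sat$order])
  paste0(graph$atoms$element[hub],
         paste0(BOND_SYMBOL[sat$order[ord]], el[ord], collapse = ""))
}

#' Find ring cycles (minimum cycle basis)
#'
#' Returns a cycle basis of the molecular graph with exactly
#' `bonds - atoms + components` cycles (the circuit rank), chosen
#' smallest-first so fused ring systems yield the chemically expected small
#' rings (naphthalene gives two 6-rings, never the 10-atom envelope).
#' Candidate rings are the shortest cycles through each bond (breadth-first
#' search in the graph minus that bond); a greedy pass keeps candidates that
#' are independent over GF(2), and any shortfall is completed with
#' fundamental cycles of a spanning tree. Deterministic for a given graph.
#'
#' @param graph A `molgraph`.
#' @return List of integer vectors, each an ordered atom ring (no repeated
#'   first atom). Empty list for acyclic graphs.
#' @export
find_cycles <- function(graph) {
  rank <- circuit_rank(graph)
  if (rank == 0L) return(list())
  m <- nrow(graph$bonds)
  edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  eids <- edge_id(graph$bonds$a, graph$bonds$b)

  ring_edges <- function(ring) {
    k <- length(ring)
    match(edge_id(ring, ring[c(2:k, 1L)]), eids)
  }
  # canonical key of a ring as an index sequence (min over rotation/direction)
  ring_key <- function(ring) {
    k <- length(ring)
    best <- NULL
    for (seqv in list(ring, rev(ring))) {
      for (s in seq_len(k)) {
        cand <- seqv[c(s:k, seq_len(s - 1L))[seq_len(k)]]
        key <- paste(cand, collapse = ",")
        if (is.null(best) || key < best) best <- key
      }
    }
    best
  }

  # candidate rings: shortest cycle through every bond
  cands <- list()
  seen <- character(0)
  for (k in seq_len(m)) {
    u <- graph$bonds$a[k]; v <- graph$bonds$b[k]
    path <- bfs_path(graph, u, v, skip_edge = k)
    if (is.null(path)) next
    key <- ring_key(path)
    if (key %in% seen) next
    seen <- c(seen, key)
    cands[[length(cands) + 1L]] <- path
  }
  lens <- vapply(cands, length, 0L)
  keys <- vapply(cands, ring_key, "")
  cands <- cands[corder(lens, keys)]

  # greedy GF(2) independence over edge incidence vectors
  basis <- list()
  reduced <- list()   # reduced vectors, each with attr "pivot"
  add_if_independent <- function(ring) {
    vec <- rep(FALSE, m)
    vec[ring_edges(ring)] <- TRUE
    for (r in reduced) {
      p <- attr(r, "pivot")
      if (vec[p]) vec <- xor(vec, r)
    }
    if (!any(vec)) return(FALSE)
    attr(vec, "pivot") <- which(vec)[1L]
    reduced[[length(reduced) + 1L]] <<- vec
    basis[[length(basis) + 1L]] <<- ring
    TRUE
  }
  for (ring in cands) {
    if (length(basis) == rank) break
    add_if_independent(ring)
  }
  if (length(basis) < rank) {
    for (ring in fundamental_cycles(graph)) {
      if (length(basis) == rank) break
      add_if_independent(ring)
    }
  }
  basis
}

# shortest u..v path avoiding bond skip_edge; BFS with smallest-index
# tie-breaking so the result is deterministic. Returns atom sequence u..v
# (a ring when closed by the skipped bond), or NULL if disconnected.
bfs_path <- function(graph, u, v, skip_edge) {
  na <- nrow(graph$atoms)
  sa <- graph$bonds$a[skip_edge]; sb <- graph$bonds$b[skip_edge]
  parent <- integer(na)
  parent[u] <- -1L
  queue <- u
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    if (x == v) break
    nb <- graph$adj[[x]]$nbr
    nb <- nb[!((x == sa & nb == sb) | (x == sb & nb == sa))]
    nb <- sort(nb)
    new <- nb[parent[nb] == 0L & nb != u]
    parent[new] <- x
    queue <- c(queue, new)
  }
  if (parent[v] == 0L) return(NULL)
  path <- v
  while (path[1L] != u) path <- c(parent[path[1L]], path)
  path
}

# fundamental cycles of a DFS spanning forest (fallback basis completion)
fundamental_cycles <- function(graph) {
  na <- nrow(graph$atoms)
  parent <- integer(na)
  depth <- rep(-1L, na)
  tree_edges <- character(0)
  edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  out <- list()
  for (root in seq_len(na)) {
    if (depth[root] >= 0L) next
    depth[root] <- 0L
    stack <- root
    while (length(stack)) {
      x <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (y in sort(graph$adj[[x]]$nbr)) {
        if (depth[y] < 0L) {
          parent[y] <- x
          depth[y] <- depth[x] + 1L
          tree_edges <- c(tree_edges, edge_id(x, y))
          stack <- c(stack, y)
        }
      }
    }
  }
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[k]; b <- graph$bonds$b[k]
    if (edge_id(a, b) %in% tree_edges) next
    # cycle = a .. lca .. b, closed by the non-tree edge (a, b)
    anc_a <- a
    while (depth[anc_a[length(anc_a)]] > 0L)
      anc_a <- c(anc_a, parent[anc_a[length(anc_a)]])
    pb_path <- b
    while (!(pb_path[length(pb_path)] %in% anc_a))
      pb_path <- c(pb_path, parent[pb_path[length(pb_path)]])
    lca <- pb_path[length(pb_path)]
    a_path <- anc_a[seq_len(match(lca, anc_a))]       # a .. lca
    out[[length(out) + 1L]] <- c(a_path, rev(pb_path[-length(pb_path)]))
  }
  out
}

#' Encode one cycle as a canonical string
#'
#' The ring is written as alternating element and bond symbols including the
#' closing bond, e.g. benzene `"C:C:C:C:C:C:"`. Among all rotations and both
#' traversal directions the lexicographically smallest candidate is returned
#' (element symbols by string order, bonds "-" < "=" < "#" < ":"), so the
#' code starts at the alphabetically first element and is invariant to how
#' the ring was supplied.
#'
#' @param graph A `molgraph`.
#' @param cycle Integer vector of atom indices forming a simple cycle
#'   (consecutive atoms bonded, last bonded to first).
#' @return Single string code.
#' @export
encode_cycle <- function(graph, cycle) {
  k <- length(cycle)
  if (k < 3L) gpcr_stop("a cycle needs at least 3 atoms", "gpcr_argument_error")
  if (anyDuplicated(cycle))
    gpcr_stop("cycle atoms must be distinct", "gpcr_argument_error")
  bmap <- bond_lookup(graph)
  orders <- character(k)
  for (i in seq_len(k)) {
    a <- cycle[i]; b <- cycle[if (i == k) 1L else i + 1L]
    o <- bmap[[paste(min(a, b), max(a, b))]]
    if (is.null(o))
      gpcr_stop(sprintf("atoms %d and %d are not bonded: not a cycle", a, b),
                "gpcr_argument_error")
    orders[i] <- o
  }
  el <- graph$atoms$element[cycle]
  best_key <- NULL; best_code <- NULL
  for (dir in 1:2) {
    e <- if (dir == 1L) el else rev(el)
    # reversing atoms maps bond i (between atom i, i+1) to reversed order
    o <- if (dir == 1L) orders else rev(c(orders[k], orders[-k]))
    for (s in seq_len(k)) {
      idx <- c(s:k, seq_len(s - 1L))[seq_len(k)]
      ee <- e[idx]; oo <- o[idx]
      key <- paste0(element_key(ee), bond_key(oo), collapse = "")
      if (is.null(best_key) || key < best_key) {
        best_key <- key
        best_code <- paste0(ee, BOND_SYMBOL[oo], collapse = "")
      }
    }
  }
  best_code
}

bond_lookup <- function(graph) {
  b <- graph$bonds
  out <- list()
  for (k in seq_len(nrow(b)))
    out[[paste(b$a[k], b$b[k])]] <- b$order[k]
  out
}

# all hub / cycle codes of one molecule
hub_codes <- function(graph, min_satellites = 3L) {
  vapply(find_hubs(graph, min_satellites), function(h)
    encode_hub(graph, h, min_satellites), "")
}
cycle_codes <- function(graph) {
  vapply(find_cycles(graph), function(cy) encode_cycle(graph, cy), "")
}

# additive atom-contribution XlogP approximation (clearly approximate; the
# preferred source is a supplied physicochemical table)
XLOGP_CONTRIB <- c(B = 0.18, C = 0.27, N = -0.60, O = -0.45, P = -0.40,
                   S = 0.45, F = 0.15, Cl = 0.65, Br = 0.89, I = 1.12)
XLOGP_AROMATIC_BONUS <- 0.07   # aromatic atoms are slightly more lipophilic
XLOGP_POLAR_H <- -0.35         # per H on N or O

#' Physicochemical descriptors of a ligand
#'
#' Molecular weight (heavy atoms plus implicit/explicit hydrogens at standard
#' atomic weights), hydrogen-bond donors (N or O atoms carrying at least one
#' hydrogen), hydrogen-bond acceptors (all N and O atoms) and XlogP. If a
#' `supplied` vector is given (e.g. from a physicochemical table) it is
#' returned unchanged; otherwise XlogP falls back to a crude additive
#' atom-contribution estimate whose `xlogp_source` attribute is set to
#' `"approximate"`. With `strict = TRUE` the fallback is refused.
#'
#' @param graph A `molgraph`.
#' @param supplied Optional named numeric `c(MW=, XlogP=, HBD=, HBA=)`.
#' @param strict Refuse the approximate XlogP fallback.
#' @return Named numeric vector `MW`, `XlogP`, `HBD`, `HBA` of class
#'   `fourchars`.
#' @export
compute_fourchars <- function(graph, supplied = NULL, strict = FALSE) {
  if (!is.null(supplied)) {
    need <- c("MW", "XlogP", "HBD", "HBA")
    if (!all(need %in% names(supplied)))
      gpcr_stop("supplied descriptors must be named MW, XlogP, HBD, HBA",
                "gpcr_descriptor_error")
    out <- as.numeric(supplied[need])
    names(out) <- need
    return(structure(out, xlogp_source = "supplied", class = "fourchars"))
  }
  if (strict)
    gpcr_stop(paste("strict mode: no supplied descriptors and the internal",
                    "XlogP estimate is approximate"), "gpcr_descriptor_error")
  el <- graph$atoms$element
  if (!all(el %in% names(ATOMIC_MASS)))
    gpcr_stop("unknown element mass", "gpcr_descriptor_error")
  h <- graph$atoms$implicit_h
  mw <- sum(ATOMIC_MASS[el]) + ATOMIC_MASS[["H"]] * sum(h)
  is_no <- el %in% c("N", "O")
  hbd <- sum(is_no & h >= 1L)
  hba <- sum(is_no)
  xlogp <- sum(XLOGP_CONTRIB[el]) +
    XLOGP_AROMATIC_BONUS * sum(graph$atoms$aromatic) +
    XLOGP_POLAR_H * sum(h[is_no])
  structure(c(MW = mw, XlogP = xlogp, HBD = hbd, HBA = hba),
            xlogp_source = "approximate", class = "fourchars")
}

#' Assemble the per-ligand feature vector
#'
#' Counts of each vocabulary hub code and cycle code in the molecule,
#' followed by the four physicochemical descriptors. Codes present in the
#' molecule but absent from the vocabulary are dropped and reported in the
#' `dropped_codes` attribute.
#'
#' @param graph A `molgraph`.
#' @param hub_vocab,cycle_vocab Ordered, duplicate-free code vocabularies.
#' @param fourchars Output of [compute_fourchars()].
#' @param min_satellites Hub threshold, must match the vocabulary's.
#' @return Named numeric vector of length
#'   `length(hub_vocab) + length(cycle_vocab) + 4`, names prefixed with
#'   feature-set tags `Hub:`, `Cycle:`, `4chars:`.
#' @export
ligand_vector <- function(graph, hub_vocab, cycle_vocab, fourchars,
                          min_satellites = 3L) {
  if (anyDuplicated(hub_vocab) || anyDuplicated(cycle_vocab))
    gpcr_stop("vocabularies must be duplicate-free", "gpcr_argument_error")
  hc <- hub_codes(graph, min_satellites)
  cc <- cycle_codes(graph)
  hub_n <- vapply(hub_vocab, function(code) sum(hc == code), 0)
  cyc_n <- vapply(cycle_vocab, function(code) sum(cc == code), 0)
  dropped <- c(setdiff(hc, hub_vocab), setdiff(cc, cycle_vocab))
  prefix <- function(tag, x) if (length(x)) paste0(tag, x) else character(0)
  out <- c(setNames(hub_n, prefix("Hub:", hub_vocab)),
           setNames(cyc_n, prefix("Cycle:", cycle_vocab)),
           setNames(as.numeric(fourchars[c("MW", "XlogP", "HBD", "HBA")]),
                    paste0("4chars:", c("MW", "XlogP", "HBD", "HBA"))))
  attr(out, "dropped_codes") <- dropped
  out
}
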