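# Synthetic desk-scale corpora: valence-legal molecules built from a
# constructive grammar (so their hub and cycle codes are known exactly),
# receptor sequences with planted motifs, and binding tables governed by a
# planted logistic rule over those features.
#
# Ground-truth codes are derived from the generator's own construction
# records with small local canonicalization routines, independent of the
# parsing/featurization path they are used to check.

# ---- construction state -----------------------------------------------------

new_mol_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$element <- character(0)
  env$aromatic <- logical(0)
  env$bond_a <- integer(0); env$bond_b <- integer(0); env$bond_o <- character(0)
  env$rings <- list()      # recorded ring atom index vectors
  env
}

mb_add_atom <- function(mb, element, aromatic = FALSE) {
  mb$element <- c(mb$element, element)
  mb$aromatic <- c(mb$aromatic, aromatic)
  length(mb$element)
}

mb_add_bond <- function(mb, a, b, order = "single") {
  mb$bond_a <- c(mb$bond_a, min(a, b))
  mb$bond_b <- c(mb$bond_b, max(a, b))
  mb$bond_o <- c(mb$bond_o, order)
}

mb_valence_used <- function(mb) {
  used <- numeric(length(mb$element))
  v <- BOND_ORDER_VALUE[mb$bond_o]
  for (k in seq_along(mb$bond_a)) {
    used[mb$bond_a[k]] <- used[mb$bond_a[k]] + v[k]
    used[mb$bond_b[k]] <- used[mb$bond_b[k]] + v[k]
  }
  used
}

# atoms that can accept one more single bond; aromatic N and ring O are full
mb_free_atoms <- function(mb, need = 1) {
  free <- ELEMENT_VALENCE[mb$element] - mb_valence_used(mb)
  which(free >= need)
}

# ---- structural units -------------------------------------------------------

# each returns the indices of its newly added atoms
unit_chain <- function(mb, len) {
  prev <- NA_integer_
  idx <- integer(0)
  for (i in seq_len(len)) {
    el <- sample(c("C", "N", "O"), 1L, prob = c(0.70, 0.15, 0.15))
    # avoid O-O / N-O chain adjacency (peroxide-like) for chemical sanity
    if (!is.na(prev) && mb$element[prev] %in% c("N", "O") && el != "C") el <- "C"
    a <- mb_add_atom(mb, el)
    if (!is.na(prev)) mb_add_bond(mb, prev, a, "single")
    prev <- a
    idx <- c(idx, a)
  }
  idx
}

unit_ring <- function(mb, kind) {
  spec <- switch(kind,
    benzene = list(el = rep("C", 6L), ar = TRUE),
    pyridine = list(el = c("C", "C", "C", "C", "C", "N"), ar = TRUE),
    cyclohexane = list(el = rep("C", 6L), ar = FALSE),
    cyclopentane = list(el = rep("C", 5L), ar = FALSE),
    oxolane = list(el = c("C", "C", "C", "C", "O"), ar = FALSE))
  k <- length(spec$el)
  order <- if (spec$ar) "aromatic" else "single"
  idx <- vapply(spec$el, function(e) mb_add_atom(mb, e, spec$ar), 0L)
  for (i in seq_len(k)) mb_add_bond(mb, idx[i], idx[if (i == k) 1L else i + 1L], order)
  mb$rings[[length(mb$rings) + 1L]] <- idx
  idx
}

# two fused six-rings sharing one bond (naphthalene / decalin skeleton)
unit_fused_pair <- function(mb, aromatic) {
  order <- if (aromatic) "aromatic" else "single"
  idx <- vapply(rep("C", 10L), function(e) mb_add_atom(mb, e, aromatic), 0L)
  ring1 <- idx[1:6]
  ring2 <- c(idx[1L], idx[7:10], idx[6L])   # shares bond idx[1]-idx[6]
  for (r in list(ring1, ring2)) {
    k <- length(r)
    for (i in seq_len(k)) {
      a <- r[i]; b <- r[if (i == k) 1L else i + 1L]
      dup <- any(mb$bond_a == min(a, b) & mb$bond_b == max(a, b))
      if (!dup) mb_add_bond(mb, a, b, order)
    }
    mb$rings[[length(mb$rings) + 1L]] <- r
  }
  idx
}

RING_KINDS <- c("benzene", "pyridine", "cyclohexane", "cyclopentane", "oxolane")
RING_SIZE <- c(6L, 6L, 6L, 5L, 5L)
RING_PROBS <- c(0.20, 0.14, 0.28, 0.28, 0.10)

# ---- molecule generator -----------------------------------------------------

#' Generate one valence-legal molecule with known structural ground truth
#'
#' Molecules are assembled from a template grammar: chain units and ring
#' units (benzene, pyridine, cyclohexane, cyclopentane, oxolane, and
#' occasionally a fused six-six pair) joined by single bonds, then decorated
#' with substituents (methyl, amino, hydroxy, F, Cl, carbonyl). Because the
#' construction is explicit, the exact hub codes and cycle codes the
#' featurizer must recover are recorded alongside the emitted SMILES.
#'
#' @param seed Integer seed.
#' @param size_range Heavy-atom count range, within 3 to 60.
#' @param ring_prob Probability that each structural unit is a ring; 0 gives
#'   an acyclic molecule.
#' @param min_satellites Hub threshold used for the recorded ground truth.
#' @return List: `smiles`, `hubs` (character multiset of hub codes),
#'   `cycles` (character multiset of cycle codes), `n_atoms`, `n_bonds`.
#' @export
generate_molecule <- function(seed, size_range = c(8L, 30L), ring_prob = 0.6,
                              min_satellites = 3L) {
  if (size_range[1] < 3L || size_range[2] > 60L || size_range[1] > size_range[2])
    gpcr_stop("size_range must lie within [3, 60]", "gpcr_argument_error")
  with_seed(seed, {
    target <- sample_range(size_range[1], size_range[2])
    mb <- new_mol_builder()
    repeat {
      remaining <- target - length(mb$element)
      if (remaining <= 0L) break
      is_ring <- runif(1L) < ring_prob && remaining >= 5L
      if (!is_ring && ring_prob >= 1) break   # rings only, nothing fits
      new_idx <- if (is_ring) {
        if (remaining >= 10L && runif(1L) < 0.15)
          unit_fused_pair(mb, aromatic = runif(1L) < 0.6)
        else {
          kinds <- RING_KINDS[RING_SIZE <= remaining]
          # rings-only grammar: fill the remaining budget exactly when possible
          if (ring_prob >= 1 && any(RING_SIZE[match(kinds, RING_KINDS)] == remaining))
            kinds <- kinds[RING_SIZE[match(kinds, RING_KINDS)] == remaining]
          if (length(kinds) == 0L) break
          p <- RING_PROBS[match(kinds, RING_KINDS)]
          unit_ring(mb, sample(kinds, 1L, prob = p))
        }
      } else {
        unit_chain(mb, sample_range(1L, min(4L, remaining)))
      }
      if (length(new_idx) < length(mb$element)) {
        # join the new unit to the existing scaffold with a single bond
        old <- setdiff(mb_free_atoms(mb), new_idx)
        anchor <- intersect(mb_free_atoms(mb), new_idx)
        if (length(old) == 0L || length(anchor) == 0L) break
        mb_add_bond(mb, sample_one(old), sample_one(anchor), "single")
      }
    }
    # substituents (create hubs); stay within the size cap
    cap <- size_range[2]
    for (a in mb_free_atoms(mb)) {
      if (length(mb$element) >= cap) break
      if (runif(1L) >= 0.35) next
      free <- ELEMENT_VALENCE[[mb$element[a]]] - mb_valence_used(mb)[a]
      if (free < 1) next
      choices <- c("C", "N", "O", "F", "Cl")
      probs <- c(0.45, 0.15, 0.15, 0.15, 0.10)
      if (free >= 2 && mb$element[a] == "C" && !mb$aromatic[a]) {
        choices <- c(choices, "=O"); probs <- c(probs, 0.25)
      }
      pick <- sample(choices, 1L, prob = probs)
      if (pick == "=O") {
        s <- mb_add_atom(mb, "O")
        mb_add_bond(mb, a, s, "double")
      } else {
        s <- mb_add_atom(mb, pick)
        mb_add_bond(mb, a, s, "single")
      }
    }
    list(smiles = write_smiles(mb$element, mb$aromatic,
                               data.frame(a = mb$bond_a, b = mb$bond_b,
                                          order = mb$bond_o)),
         hubs = gt_hub_codes(mb, min_satellites),
         cycles = gt_cycle_codes(mb),
         n_atoms = length(mb$element),
         n_bonds = length(mb$bond_a))
  })
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# sample one integer from [lo, hi] (safe when lo == hi)
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

# ---- ground-truth encodings (construction-side canonicalization) ------------

gt_hub_codes <- function(mb, min_satellites) {
  n <- length(mb$element)
  deg <- integer(n)
  for (k in seq_along(mb$bond_a)) {
    deg[mb$bond_a[k]] <- deg[mb$bond_a[k]] + 1L
    deg[mb$bond_b[k]] <- deg[mb$bond_b[k]] + 1L
  }
  out <- character(0)
  for (a in which(deg >= min_satellites)) {
    sel <- mb$bond_a == a | mb$bond_b == a
    nbr <- ifelse(mb$bond_a[sel] == a, mb$bond_b[sel], mb$bond_a[sel])
    el <- mb$element[nbr]
    ord <- mb$bond_o[sel]
    o <- corder(sprintf("%-2s", el), BOND_RANK[ord])
    out <- c(out, paste0(mb$element[a],
                         paste0(BOND_SYMBOL[ord[o]], el[o], collapse = "")))
  }
  out
}

gt_cycle_codes <- function(mb) {
  vapply(mb$rings, function(ring) {
    k <- length(ring)
    el <- mb$element[ring]
    orders <- vapply(seq_len(k), function(i) {
      a <- ring[i]; b <- ring[if (i == k) 1L else i + 1L]
      mb$bond_o[mb$bond_a == min(a, b) & mb$bond_b == max(a, b)][1L]
    }, "")
    best_key <- NULL; best <- NULL
    for (dir in 1:2) {
      e <- if (dir == 1L) el else rev(el)
      o <- if (dir == 1L) orders else rev(c(orders[k], orders[-k]))
      for (s in seq_len(k)) {
        idx <- c(s:k, seq_len(s - 1L))[seq_len(k)]
        key <- paste0(sprintf("%-2s", e[idx]), BOND_RANK[o[idx]], collapse = "")
        if (is.null(best_key) || key < best_key) {
          best_key <- key
          best <- paste0(e[idx], BOND_SYMBOL[o[idx]], collapse = "")
        }
      }
    }
    best
  }, "")
}

# ---- SMILES writer ----------------------------------------------------------

# Serialize an atom/bond table to SMILES (connected graphs). Aromatic atoms
# are written lowercase; a bond symbol is emitted only where the written
# default (aromatic between two aromatic atoms, else single) would be wrong.
write_smiles <- function(element, aromatic, bonds) {
  n <- length(element)
  adj <- rep(list(integer(0)), n)
  bond_order <- list()
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    bond_order[[paste(min(a, b), max(a, b))]] <- bonds$order[k]
  }
  get_order <- function(a, b) bond_order[[paste(min(a, b), max(a, b))]]
  written_default <- function(a, b) {
    if (aromatic[a] && aromatic[b]) "aromatic" else "single"
  }
  bond_prefix <- function(a, b) {
    o <- get_order(a, b)
    if (o == written_default(a, b)) "" else BOND_SYMBOL[[o]]
  }

  # DFS: tree edges and back edges
  visited <- logical(n)
  parent <- integer(n)
  children <- rep(list(integer(0)), n)
  back_at <- rep(list(integer(0)), n)    # back-edge ids opening/closing here
  back_edges <- list()
  dfs <- function(v) {
    visited[v] <<- TRUE
    for (w in sort(adj[[v]])) {
      if (!visited[w]) {
        parent[w] <<- v
        children[[v]] <<- c(children[[v]], w)
        dfs(w)
      } else if (w != parent[v]) {
        key <- paste(min(v, w), max(v, w))
        already <- any(vapply(back_edges, function(e) e$key == key, FALSE))
        if (!already) {
          id <- length(back_edges) + 1L
          back_edges[[id]] <<- list(key = key, a = w, b = v)  # a seen first
          back_at[[w]] <<- c(back_at[[w]], id)
          back_at[[v]] <<- c(back_at[[v]], id)
        }
      }
    }
  }
  dfs(1L)
  if (!all(visited))
    gpcr_stop("write_smiles expects a connected graph", "gpcr_argument_error")

  digit_token <- function(id) if (id <= 9L) as.character(id) else sprintf("%%%02d", id)
  atom_token <- function(v) {
    el <- element[v]
    if (aromatic[v]) tolower(el) else el
  }
  emit <- function(v) {
    s <- atom_token(v)
    for (id in back_at[[v]]) {
      e <- back_edges[[id]]
      other <- if (e$a == v) e$b else e$a
      pre <- if (e$a == v) bond_prefix(e$a, e$b) else ""   # symbol at opening
      s <- paste0(s, pre, digit_token(id))
    }
    kids <- children[[v]]
    if (length(kids)) {
      for (i in seq_along(kids)) {
        sub <- paste0(bond_prefix(v, kids[i]), emit(kids[i]))
        s <- if (i < length(kids)) paste0(s, "(", sub, ")") else paste0(s, sub)
      }
    }
    s
  }
  emit(1L)
}

# ---- receptor generator -----------------------------------------------------

#' Generate a receptor sequence with planted motifs
#'
#' An i.i.d. background of the 20 standard residues with `n_plants`
#' non-overlapping motif insertions (overwriting the background) at recorded
#' positions; each plant draws its motif uniformly from `motif_set`.
#'
#' @param seed Integer seed.
#' @param length_range Sequence length range.
#' @param motif_set Character vector of motifs to plant from.
#' @param n_plants Number of insertions.
#' @return List: `sequence`, `planted` (data.frame `motif`, `start`),
#'   `planted_counts` (named count per motif in `motif_set`).
#' @export
generate_receptor <- function(seed, length_range = c(200L, 400L),
                              motif_set = character(0), n_plants = 0L) {
  with_seed(seed, {
    len <- sample_range(length_range[1], length_range[2])
    maxlen <- if (length(motif_set)) max(nchar(motif_set)) else 0L
    if (n_plants > 0L && (length(motif_set) == 0L || n_plants * maxlen > len))
      gpcr_stop("planted motifs do not fit in the sequence length",
                "gpcr_generation_error")
    chars <- sample(AA_ALPHABET, len, replace = TRUE)
    planted <- data.frame(motif = character(0), start = integer(0))
    occupied <- logical(len)
    tries <- 0L
    while (nrow(planted) < n_plants) {
      tries <- tries + 1L
      if (tries > 200L)
        gpcr_stop("could not place all motif plants without overlap",
                  "gpcr_generation_error")
      m <- sample_one(motif_set)
      w <- nchar(m)
      s <- sample.int(len - w + 1L, 1L)
      if (any(occupied[s:(s + w - 1L)])) next
      chars[s:(s + w - 1L)] <- strsplit(m, "")[[1]]
      occupied[s:(s + w - 1L)] <- TRUE
      planted <- rbind(planted, data.frame(motif = m, start = s))
    }
    seqstr <- paste(chars, collapse = "")
    counts <- vapply(motif_set, function(m) sum(planted$motif == m), 0L)
    list(sequence = seqstr, planted = planted,
         planted_counts = setNames(counts, motif_set))
  })
}

# ---- binding corpus ---------------------------------------------------------

#' Specification for a synthetic binding corpus
#'
#' Bundles the corpus dimensions, the motif set, the planted binding rule
#' and the label-noise level. The rule assigns weights to specific cycle
#' codes, hub codes and motifs; a pair's binding propensity is the logistic
#' of the standardized weighted feature sum (see
#' [generate_binding_corpus()]).
#'
#' @param n_receptors,n_ligands,n_pos Corpus dimensions.
#' @param motif_set Motifs available for planting.
#' @param rule List with named numeric `cycle`, `hub`, `motif` weight
#'   vectors and a `steepness` scalar.
#' @param noise Label-flip probability in `[0, 1]`.
#' @param seed Root seed for the corpus.
#' @param size_range,ring_prob Molecule generator settings.
#' @param length_range,plants_range Receptor generator settings.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_receptors = 40L, n_ligands = 2000L, n_pos = 1000L,
                           motif_set = c("DRYW", "CWTPY", "NPMLY"),
                           rule = default_rule(), noise = 0, seed = 1L,
                           size_range = c(8L, 30L), ring_prob = 0.7,
                           length_range = c(200L, 400L),
                           plants_range = 0:4) {
  if (noise < 0 || noise > 1)
    gpcr_stop("noise must lie in [0, 1]", "gpcr_argument_error")
  structure(list(n_receptors = n_receptors, n_ligands = n_ligands,
                 n_pos = n_pos, motif_set = motif_set, rule = rule,
                 noise = noise, seed = seed, size_range = size_range,
                 ring_prob = ring_prob, length_range = length_range,
                 plants_range = plants_range),
            class = "synthetic_spec")
}

#' Default planted binding rule
#'
#' Loads on ligand ring topology (five-membered carbocycles favored,
#' six-membered carbocycles disfavored, branched sp3 carbon hubs favored)
#' and on the planted receptor motifs, so both sides of the concatenated
#' feature vector carry signal. The ligand signal is deliberately carried by
#' ring size and branching of pure-carbon substructures, which the four
#' physicochemical descriptors are nearly blind to (a CH2 of molecular
#' weight, no change in XlogP class, donors or acceptors) — structural
#' features must dominate the descriptor features, mirroring real ablations.
#'
#' @return Rule list for [synthetic_spec()].
#' @export
default_rule <- function() {
  list(cycle = c("C-C-C-C-C-" = 2.5, "C-C-C-C-C-C-" = -2.5),
       hub = c("C-C-C-C" = 2.0),
       motif = c(DRYW = 1.5, CWTPY = 1.5, NPMLY = 1.5),
       steepness = 10)
}

#' Generate a synthetic binding corpus
#'
#' Generates ligands and receptors, computes every pair's binding propensity
#' as `plogis(steepness * z)` where `z` is the standardized rule score
#' (receptor motif counts and ligand ground-truth code counts, weighted by
#' the rule), samples `n_pos` positive pairs proportional to propensity and
#' `n_pos` negative pairs uniformly from the remainder, then flips each
#' label with probability `noise`. All randomness derives from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; when given, writes `ligands.smi`,
#'   `receptors.fasta`, `bindings.tsv` (pairs labeled positive) and
#'   `truth.json`.
#' @return List of class `synthetic_corpus`: `spec`, `ligands` (data.frame
#'   `ligand_id`, `smiles`), `receptors` (data.frame `receptor_id`,
#'   `sequence`), `pairs` (with `label` after noise and true `propensity`),
#'   `truth` (per-ligand code multisets, per-receptor motif counts).
#' @export
generate_binding_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- spec$seed
  ligs <- lapply(seq_len(spec$n_ligands), function(i)
    generate_molecule(derive_seed(seed, 1000L + i), spec$size_range,
                      spec$ring_prob))
  lids <- sprintf("L%04d", seq_len(spec$n_ligands))
  n_plants <- with_seed(derive_seed(seed, 3000L),
    sample(spec$plants_range, spec$n_receptors, replace = TRUE))
  recs <- lapply(seq_len(spec$n_receptors), function(j)
    generate_receptor(derive_seed(seed, 2000L + j), spec$length_range,
                      spec$motif_set, n_plants[j]))
  rids <- sprintf("R%03d", seq_len(spec$n_receptors))

  # rule scores from construction-side truth (receptor side counts actual
  # occurrences, i.e. plants plus background collisions)
  motif_counts <- t(vapply(recs, function(r)
    vapply(spec$motif_set, function(m) {
      hits <- gregexpr(paste0("(?=", m, ")"), r$sequence, perl = TRUE)[[1]]
      if (hits[1L] == -1L) 0 else length(hits)
    }, 0), numeric(length(spec$motif_set))))
  rownames(motif_counts) <- rids
  r_score <- as.numeric(motif_counts[, names(spec$rule$motif), drop = FALSE] %*%
                          spec$rule$motif)
  l_score <- vapply(ligs, function(lg) {
    sum(vapply(names(spec$rule$cycle), function(code)
          spec$rule$cycle[[code]] * sum(lg$cycles == code), 0)) +
    sum(vapply(names(spec$rule$hub), function(code)
          spec$rule$hub[[code]] * sum(lg$hubs == code), 0))
  }, 0)

  raw <- outer(r_score, l_score, `+`)            # receptors x ligands
  z <- (raw - mean(raw)) / max(stats::sd(raw), 1e-9)
  propensity <- plogis(spec$rule$steepness * z)

  n_cells <- spec$n_receptors * spec$n_ligands
  if (spec$n_pos * 2L > n_cells)
    gpcr_stop(sprintf("n_pos = %d needs %d cells but only %d exist",
                      spec$n_pos, 2L * spec$n_pos, n_cells),
              "gpcr_capacity_error")
  cells <- seq_len(n_cells)                      # column-major over matrix
  pos_cells <- with_seed(derive_seed(seed, 4000L),
    sample(cells, spec$n_pos, prob = as.numeric(propensity)))
  rest <- setdiff(cells, pos_cells)
  # non-binders follow the complement of the rule, as a planted rule implies
  neg_cells <- with_seed(derive_seed(seed, 5000L),
    sample(rest, spec$n_pos, prob = 1 - as.numeric(propensity)[rest]))
  cell_pair <- function(cell, label) {
    r <- (cell - 1L) %% spec$n_receptors + 1L
    l <- (cell - 1L) %/% spec$n_receptors + 1L
    data.frame(receptor_id = rids[r], ligand_id = lids[l], label = label,
               propensity = propensity[cbind(r, l)])
  }
  pairs <- rbind(cell_pair(pos_cells, 1L), cell_pair(neg_cells, 0L))
  if (spec$noise > 0) {
    flip <- with_seed(derive_seed(seed, 6000L),
                      runif(nrow(pairs)) < spec$noise)
    pairs$label <- ifelse(flip, 1L - pairs$label, pairs$label)
  }

  corpus <- structure(list(
    spec = spec,
    ligands = data.frame(ligand_id = lids,
                         smiles = vapply(ligs, `[[`, "", "smiles")),
    receptors = data.frame(receptor_id = rids,
                           sequence = vapply(recs, `[[`, "", "sequence")),
    pairs = pairs,
    truth = list(ligand_codes = setNames(lapply(ligs, function(lg)
                   list(hubs = lg$hubs, cycles = lg$cycles)), lids),
                 motif_counts = motif_counts,
                 planted = setNames(lapply(recs, `[[`, "planted"), rids),
                 r_score = setNames(r_score, rids),
                 l_score = setNames(l_score, lids))
  ), class = "synthetic_corpus")
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("%s\t%s", corpus$ligands$smiles, corpus$ligands$ligand_id),
             file.path(dir, "ligands.smi"))
  writeLines(as.vector(rbind(paste0(">", corpus$receptors$receptor_id),
                             corpus$receptors$sequence)),
             file.path(dir, "receptors.fasta"))
  pos <- corpus$pairs[corpus$pairs$label == 1L, c("receptor_id", "ligand_id")]
  write.table(pos, file.path(dir, "bindings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(corpus$spec)[setdiff(names(corpus$spec), "rule")],
         rule = corpus$spec$rule,
         ligand_codes = corpus$truth$ligand_codes,
         motif_counts = as.data.frame(corpus$truth$motif_counts)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(corpus)
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d receptors x %d ligands, %d pairs (noise %.2f, seed %d)\n",
    nrow(x$receptors), nrow(x$ligands), nrow(x$pairs), x$spec$noise,
    x$spec$seed))
  invisible(x)
}

#' Assemble a labeled dataset from a synthetic corpus
#'
#' Runs the real featurization pipeline (SMILES parsing, hub/cycle
#' vocabularies, receptor composition and motif counting) on the corpus
#' files and pairs them with the corpus labels. The molecular-weight filter
#' is disabled: every generated pair must survive featurization.
#'
#' @param corpus A `synthetic_corpus`.
#' @param min_satellites Hub threshold.
#' @return A `binding_dataset`.
#' @export
corpus_dataset <- function(corpus, min_satellites = 3L) {
  lf <- featurize_ligands(corpus$ligands, weight_filter = FALSE,
                          min_satellites = min_satellites, strict = TRUE)
  seqs <- setNames(corpus$receptors$sequence, corpus$receptors$receptor_id)
  rf <- featurize_receptors(seqs, corpus$spec$motif_set, filter = TRUE)
  assemble(corpus$pairs[c("receptor_id", "ligand_id", "label")],
           rf$features, lf$features)
}
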