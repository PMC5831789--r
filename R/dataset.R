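# Dataset assembly: ligand weight filter, corpus vocabularies, seeded
# negative-pair sampling, and the concatenated receptor||ligand feature
# matrix with feature-set tags.

#' Filter ligands by molecular weight
#'
#' Keeps ligands with molecular weight strictly between 150 and 500 g/mol;
#' ligands at or outside the bounds are excluded (too light are likely ions,
#' too heavy likely peptides).
#'
#' @param ligands data.frame with a numeric `MW` column.
#' @param lower,upper Exclusive bounds (defaults 150 and 500).
#' @return The retained rows of `ligands`.
#' @export
filter_ligands_by_weight <- function(ligands, lower = 150, upper = 500) {
  if (!"MW" %in% names(ligands))
    gpcr_stop("ligands must carry an MW column", "gpcr_argument_error")
  ligands[!is.na(ligands$MW) & ligands$MW > lower & ligands$MW < upper, ,
          drop = FALSE]
}

#' Build hub and cycle vocabularies over a ligand corpus
#'
#' The vocabularies are the sorted unique canonical hub codes and cycle codes
#' observed across all graphs; deterministic for a fixed corpus.
#'
#' @param graphs List of `molgraph` objects.
#' @param min_satellites Hub threshold.
#' @return List with character vectors `hub` and `cycle`.
#' @export
build_vocabularies <- function(graphs, min_satellites = 3L) {
  hub <- unlist(lapply(graphs, hub_codes, min_satellites = min_satellites))
  cyc <- unlist(lapply(graphs, cycle_codes))
  list(hub = csort(unique(c(hub, character(0)))),
       cycle = csort(unique(c(cyc, character(0)))))
}

#' Generate negative (non-binding) pairs
#'
#' Samples `n` distinct receptor-ligand pairs uniformly from the
#' receptor x ligand cross-product, excluding all known positive pairs.
#' Reproducible for a fixed seed. This reconstructs the usual
#' negative-sampling procedure for interaction data; sampled negatives may
#' of course contain unknown true positives (the standard PU-learning
#' caveat) and no correction is applied.
#'
#' @param positives data.frame with columns `receptor_id`, `ligand_id`.
#' @param receptors,ligands Character vectors of candidate IDs.
#' @param n Number of negatives to draw.
#' @param seed Integer seed.
#' @return data.frame `receptor_id`, `ligand_id`, `label` (all 0).
#' @export
generate_negatives <- function(positives, receptors, ligands, n, seed = 1L) {
  if (!is_count(n) || n < 1) gpcr_stop("n must be a positive integer", "gpcr_argument_error")
  if (anyDuplicated(receptors) || anyDuplicated(ligands))
    gpcr_stop("receptor and ligand ID lists must be unique", "gpcr_argument_error")
  nr <- length(receptors); nl <- length(ligands)
  ri <- match(positives$receptor_id, receptors)
  li <- match(positives$ligand_id, ligands)
  if (anyNA(ri) || anyNA(li))
    gpcr_stop("positives reference IDs outside the candidate lists",
              "gpcr_argument_error")
  pos_cells <- unique((ri - 1) * nl + li)
  capacity <- nr * nl - length(pos_cells)
  if (capacity < n)
    gpcr_stop(sprintf(
      "cannot draw %d negatives: only %d non-positive pairs exist", n, capacity),
      "gpcr_capacity_error")
  cells <- setdiff(seq_len(nr * nl), pos_cells)
  take <- with_seed(seed, sample(cells, n))
  data.frame(receptor_id = receptors[(take - 1) %/% nl + 1],
             ligand_id = ligands[(take - 1) %% nl + 1],
             label = 0L)
}

#' Sample positive pairs from a binding table
#'
#' Uniform sampling without replacement of known binding pairs, seeded;
#' used to draw the positive half of a training dataset.
#'
#' @param bindings data.frame `receptor_id`, `ligand_id` of known bindings.
#' @param n Number of positives (defaults to all).
#' @param seed Integer seed.
#' @return data.frame `receptor_id`, `ligand_id`, `label` (all 1).
#' @export
sample_positives <- function(bindings, n = nrow(bindings), seed = 1L) {
  if (n > nrow(bindings))
    gpcr_stop(sprintf("requested %d positives but only %d bindings known",
                      n, nrow(bindings)), "gpcr_capacity_error")
  idx <- with_seed(seed, sample(nrow(bindings), n))
  data.frame(receptor_id = bindings$receptor_id[idx],
             ligand_id = bindings$ligand_id[idx],
             label = 1L)
}

#' Assemble a labeled binding dataset
#'
#' Row i of the feature matrix is the concatenation of the receptor vector
#' and the ligand vector of pair i; column names keep their feature-set tag
#' prefixes (`MF:`, `1AAF:`, `2AAF:`, `4chars:`, `Hub:`, `Cycle:`) so
#' feature-set combinations are pure column selections.
#'
#' @param pairs data.frame `receptor_id`, `ligand_id`, `label` (0/1).
#' @param receptor_vectors Numeric matrix, rows named by receptor ID.
#' @param ligand_vectors Numeric matrix, rows named by ligand ID.
#' @return Object of class `binding_dataset`: list with `pairs`, `X`, `y`,
#'   `column_tags`.
#' @export
assemble <- function(pairs, receptor_vectors, ligand_vectors) {
  need <- c("receptor_id", "ligand_id", "label")
  if (!all(need %in% names(pairs)))
    gpcr_stop("pairs needs receptor_id, ligand_id, label", "gpcr_argument_error")
  key <- paste(pairs$receptor_id, pairs$ligand_id)
  if (anyDuplicated(key))
    gpcr_stop(sprintf("duplicate pair (%s)", key[duplicated(key)][1L]),
              "gpcr_assembly_error")
  ri <- match(pairs$receptor_id, rownames(receptor_vectors))
  li <- match(pairs$ligand_id, rownames(ligand_vectors))
  if (anyNA(ri))
    gpcr_stop(sprintf("pair (%s, %s): receptor has no feature vector",
                      pairs$receptor_id[which(is.na(ri))[1L]],
                      pairs$ligand_id[which(is.na(ri))[1L]]),
              "gpcr_assembly_error")
  if (anyNA(li))
    gpcr_stop(sprintf("pair (%s, %s): ligand has no feature vector",
                      pairs$receptor_id[which(is.na(li))[1L]],
                      pairs$ligand_id[which(is.na(li))[1L]]),
              "gpcr_assembly_error")
  X <- cbind(receptor_vectors[ri, , drop = FALSE],
             ligand_vectors[li, , drop = FALSE])
  rownames(X) <- key
  structure(list(pairs = pairs, X = X, y = as.integer(pairs$label),
                 column_tags = column_tags(colnames(X))),
            class = "binding_dataset")
}

column_tags <- function(cn) {
  vapply(strsplit(cn, ":", fixed = TRUE), `[[`, "", 1L)
}

#' Select feature columns by tag
#'
#' @param dataset A `binding_dataset`.
#' @param tags Character vector of feature-set tags among `MF`, `1AAF`,
#'   `2AAF`, `4chars`, `Hub`, `Cycle`; `NULL` selects everything.
#' @return Column index vector into `dataset$X`.
#' @export
feature_columns <- function(dataset, tags = NULL) {
  if (is.null(tags)) return(seq_len(ncol(dataset$X)))
  known <- c("MF", "1AAF", "2AAF", "4chars", "Hub", "Cycle")
  bad <- setdiff(tags, known)
  if (length(bad))
    gpcr_stop(sprintf("unknown feature tag(s): %s", paste(bad, collapse = ", ")),
              "gpcr_argument_error")
  which(dataset$column_tags %in% tags)
}

#' @export
print.binding_dataset <- function(x, ...) {
  cat(sprintf("<binding_dataset> %d pairs (%d positive), %d features [%s]\n",
              nrow(x$X), sum(x$y), ncol(x$X),
              paste(unique(x$column_tags), collapse = ", ")))
  invisible(x)
}

#' Read a binding table TSV
#'
#' Tab-separated with header columns `receptor_id` and `ligand_id`.
#'
#' @param path Path to the TSV.
#' @return data.frame `receptor_id`, `ligand_id`.
#' @export
read_bindings <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("receptor_id", "ligand_id") %in% names(df)))
    gpcr_stop("binding table needs receptor_id and ligand_id columns",
              "gpcr_io_error")
  df[c("receptor_id", "ligand_id")]
}

#' Read a per-ligand physicochemical table
#'
#' Tab-separated with header `ligand_id`, `MW`, `XlogP`, `HBD`, `HBA`.
#'
#' @param path Path to the TSV.
#' @return data.frame indexed by `ligand_id`.
#' @export
read_physchem <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("ligand_id", "MW", "XlogP", "HBD", "HBA")
  if (!all(need %in% names(df)))
    gpcr_stop("physicochemical table needs ligand_id, MW, XlogP, HBD, HBA",
              "gpcr_io_error")
  df[need]
}

#' Featurize a ligand corpus
#'
#' Parses every SMILES, optionally applies the molecular-weight filter,
#' builds (or reuses) hub/cycle vocabularies, and returns the ligand feature
#' matrix.
#'
#' @param ligands data.frame `ligand_id`, `smiles` (e.g. from [read_smi()]).
#' @param physchem Optional physicochemical table (from [read_physchem()]);
#'   used in preference to computed descriptors.
#' @param vocab Optional precomputed `list(hub=, cycle=)`; built from the
#'   corpus when `NULL`.
#' @param min_satellites Hub threshold.
#' @param weight_filter Apply the 150 < MW < 500 filter.
#' @param strict Strict SMILES parsing.
#' @return List: `features` (matrix, rows = ligand IDs), `vocab`, `graphs`,
#'   `ligands` (retained rows).
#' @export
featurize_ligands <- function(ligands, physchem = NULL, vocab = NULL,
                              min_satellites = 3L, weight_filter = TRUE,
                              strict = FALSE) {
  graphs <- lapply(ligands$smiles, parse_smiles, strict = strict)
  names(graphs) <- ligands$ligand_id
  fcs <- lapply(seq_along(graphs), function(i) {
    sup <- NULL
    if (!is.null(physchem)) {
      row <- physchem[physchem$ligand_id == ligands$ligand_id[i], , drop = FALSE]
      if (nrow(row) == 1L)
        sup <- c(MW = row$MW, XlogP = row$XlogP, HBD = row$HBD, HBA = row$HBA)
    }
    compute_fourchars(graphs[[i]], supplied = sup)
  })
  ligands$MW <- vapply(fcs, `[[`, 0, "MW")
  keep <- if (weight_filter)
    ligands$ligand_id %in% filter_ligands_by_weight(ligands)$ligand_id
  else rep(TRUE, nrow(ligands))
  graphs <- graphs[keep]; fcs <- fcs[keep]; ligands <- ligands[keep, , drop = FALSE]
  if (is.null(vocab)) vocab <- build_vocabularies(graphs, min_satellites)
  feats <- t(vapply(seq_along(graphs), function(i)
    ligand_vector(graphs[[i]], vocab$hub, vocab$cycle, fcs[[i]],
                  min_satellites),
    numeric(length(vocab$hub) + length(vocab$cycle) + 4L)))
  rownames(feats) <- ligands$ligand_id
  list(features = feats, vocab = vocab, graphs = graphs, ligands = ligands)
}

#' Featurize a receptor corpus
#'
#' Counts candidate motifs across all sequences, applies the corpus motif
#' filter (total occurrences >= 2) unless disabled, and returns the receptor
#' feature matrix.
#'
#' @param sequences Named character vector (names = receptor IDs).
#' @param motifs Candidate motif strings.
#' @param filter Apply the corpus-level motif filter.
#' @param strict,normalize Passed to the composition features.
#' @return List: `features` (matrix, rows = receptor IDs), `motifs`
#'   (retained).
#' @export
featurize_receptors <- function(sequences, motifs = character(0),
                                filter = TRUE, strict = TRUE,
                                normalize = FALSE) {
  if (length(motifs) && filter) {
    counts <- vapply(motifs, function(m)
      vapply(sequences, count_motif, 0L, motif = m), integer(length(sequences)))
    counts <- matrix(counts, nrow = length(sequences),
                     dimnames = list(names(sequences), motifs))
    motifs <- filter_motifs(counts)
  }
  feats <- t(vapply(sequences, receptor_vector, motifs = motifs,
                    strict = strict, normalize = normalize,
                    FUN.VALUE = numeric(420L + length(motifs))))
  rownames(feats) <- names(sequences)
  list(features = feats, motifs = motifs)
}
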