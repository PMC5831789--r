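# SMILES subset parser: heavy-atom molecular graphs with typed bonds.
#
# Supported subset: organic-subset atoms (B, C, N, O, P, S, F, Cl, Br, I and
# aromatic b, c, n, o, p, s), bracket atoms with element / charge / explicit H,
# bond symbols - = # :, branches ( ), ring closures 1-9 and %nn, and the "."
# component separator. Stereo markers (/ \ @ @@) and isotopes are discarded
# (an error in strict mode). Hydrogens are never graph nodes.

ELEMENT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")
ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, P = 30.974, S = 32.06, Cl = 35.453,
                 Br = 79.904, I = 126.904)

BOND_SYMBOL <- c(single = "-", double = "=", triple = "#", aromatic = ":")
BOND_ORDER_VALUE <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
BOND_RANK <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

bond_from_symbol <- function(sym) names(BOND_SYMBOL)[match(sym, BOND_SYMBOL)]

#' Implicit hydrogen count under the valence model
#'
#' Number of hydrogens implied on a heavy atom given its element, the sum of
#' the orders of its explicit bonds (aromatic bonds contribute 1.5) and its
#' formal charge: `max(0, floor(default_valence + charge - bond_order_sum))`.
#' The charge term raises the effective valence of cations and lowers that of
#' anions, matching the usual effective valences (ammonium N: 4, alkoxide O: 1).
#' Used for organic-subset atoms; bracket atoms carry their hydrogen count
#' explicitly and bypass this model.
#'
#' @param element Element symbol, e.g. `"C"`, `"Cl"`.
#' @param bond_order_sum Sum of bond orders of the atom's explicit bonds.
#' @param formal_charge Integer formal charge (default 0).
#' @param aromatic_flag Whether the atom is aromatic (informational; the
#'   aromatic contribution is already in `bond_order_sum`).
#' @return Non-negative integer hydrogen count.
#' @examples
#' implicit_hydrogens("O", 1)       # hydroxyl -> 1
#' implicit_hydrogens("N", 3, +1)   # protonated tertiary amine -> 1
#' @export
implicit_hydrogens <- function(element, bond_order_sum, formal_charge = 0L,
                               aromatic_flag = FALSE) {
  if (!element %in% names(ELEMENT_VALENCE))
    gpcr_stop(sprintf("element '%s' not in valence table", element),
              "gpcr_descriptor_error")
  as.integer(max(0, floor(ELEMENT_VALENCE[[element]] + formal_charge - bond_order_sum)))
}

parse_err <- function(pos, msg) {
  gpcr_stop(sprintf("SMILES parse error at position %d: %s", pos, msg),
            "gpcr_parse_error")
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds an explicit heavy-atom graph: atoms in SMILES reading order with
#' element, aromatic flag, formal charge and implicit hydrogen count; bonds
#' typed single/double/triple/aromatic. A bond written without a symbol
#' between two aromatic atoms is typed aromatic, otherwise single. Aromatic
#' rings are kept as aromatic bonds (no kekulization). Disconnected
#' components (`.`) are kept in one graph.
#'
#' @param smiles A single non-empty SMILES string.
#' @param strict If `TRUE`, stereo markers and isotopes raise an
#'   unsupported-feature error instead of being discarded.
#' @return An object of class `molgraph`: list with `atoms` (data.frame:
#'   `element`, `aromatic`, `charge`, `implicit_h`), `bonds` (data.frame:
#'   `a`, `b`, `order`), `adj` (per-atom list of neighbor index / bond order),
#'   and the source `smiles`.
#' @examples
#' g <- parse_smiles("CCO")
#' g$atoms$implicit_h   # 3 2 1
#' @export
parse_smiles <- function(smiles, strict = FALSE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    gpcr_stop("smiles must be a single non-empty string", "gpcr_parse_error")
  ch <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(ch)

  atoms <- list()   # each: list(element, aromatic, charge, explicit_h or NA)
  bonds <- list()   # each: list(a, b, order)
  seen_pairs <- character(0)

  prev <- NA_integer_          # last atom emitted on current chain
  stack <- integer(0)          # branch stack of prev atoms
  pending <- NULL              # explicit bond symbol awaiting next atom
  pending_pos <- NA_integer_
  fresh <- TRUE                # TRUE after start or ".": next atom starts a component
  rings <- list()              # open ring closures: key -> list(atom, order, pos)

  add_atom <- function(element, aromatic, charge = 0L, explicit_h = NA_integer_, pos = NA) {
    if (!element %in% names(ELEMENT_VALENCE))
      parse_err(pos, sprintf("unknown element '%s'", element))
    if (aromatic && !element %in% AROMATIC_OK)
      parse_err(pos, sprintf("element '%s' cannot be aromatic", element))
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = as.integer(charge),
                                         explicit_h = explicit_h)
    length(atoms)
  }
  add_bond <- function(a, b, order, pos) {
    if (a == b) parse_err(pos, "bond endpoints must be distinct")
    key <- paste(min(a, b), max(a, b))
    if (key %in% seen_pairs) parse_err(pos, "duplicate bond between one atom pair")
    seen_pairs <<- c(seen_pairs, key)
    bonds[[length(bonds) + 1L]] <<- list(a = min(a, b), b = max(a, b), order = order)
  }
  default_order <- function(a, b) {
    if (atoms[[a]]$aromatic && atoms[[b]]$aromatic) "aromatic" else "single"
  }
  connect <- function(idx, pos) {
    force(idx)   # add_atom() must run before atoms is read below
    # link new atom idx to prev unless starting a fresh component
    if (!fresh && !is.na(prev)) {
      ord <- if (is.null(pending)) default_order(prev, idx) else pending
      add_bond(prev, idx, ord, pos)
    } else if (!is.null(pending)) {
      parse_err(pending_pos, "bond symbol not followed by a bonded atom")
    }
    pending <<- NULL
    fresh <<- FALSE
    prev <<- idx
  }
  ring_closure <- function(key, pos) {
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      if (is.na(prev)) parse_err(pos, "ring closure with no current atom")
      ord <- if (!is.null(pending)) pending else if (!is.na(open$order)) open$order
             else default_order(open$atom, prev)
      if (!is.null(pending) && !is.na(open$order) && pending != open$order)
        parse_err(pos, sprintf("conflicting bond symbols on ring closure %s", key))
      add_bond(open$atom, prev, ord, pos)
      pending <<- NULL
    } else {
      if (is.na(prev)) parse_err(pos, "ring opening with no current atom")
      rings[[key]] <<- list(atom = prev,
                            order = if (is.null(pending)) NA_character_ else pending,
                            pos = pos)
      pending <<- NULL
    }
  }

  i <- 1L
  while (i <= n) {
    c1 <- ch[i]
    if (c1 %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      # two-letter organic-subset symbols: Cl, Br
      el <- c1
      if (c1 == "C" && i < n && ch[i + 1L] == "l") { el <- "Cl"; i <- i + 1L }
      if (c1 == "B" && i < n && ch[i + 1L] == "r") { el <- "Br"; i <- i + 1L }
      connect(add_atom(el, FALSE, pos = i), i)
    } else if (c1 %in% c("b", "c", "n", "o", "p", "s")) {
      connect(add_atom(toupper(c1), TRUE, pos = i), i)
    } else if (c1 == "[") {
      j <- i + 1L
      while (j <= n && ch[j] != "]") j <- j + 1L
      if (j > n) parse_err(i, "unclosed bracket atom")
      body <- paste(ch[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket(body, i, strict)
      connect(add_atom(at$element, at$aromatic, at$charge, at$explicit_h, pos = i), i)
      i <- j
    } else if (c1 %in% BOND_SYMBOL) {
      if (!is.null(pending)) parse_err(i, "two consecutive bond symbols")
      pending <- bond_from_symbol(c1)
      pending_pos <- i
    } else if (c1 %in% c("/", "\\")) {
      if (strict) gpcr_stop(sprintf(
        "unsupported feature at position %d: stereo bond '%s'", i, c1),
        "gpcr_unsupported_error")
      # discarded: treat as an unspecified (default-order) bond
    } else if (c1 == "(") {
      if (is.na(prev)) parse_err(i, "branch with no current atom")
      stack <- c(stack, prev)
    } else if (c1 == ")") {
      if (length(stack) == 0L) parse_err(i, "unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("[0-9]", c1)) {
      ring_closure(c1, i)
    } else if (c1 == "%") {
      if (i + 2L > n || !grepl("[0-9]", ch[i + 1L]) || !grepl("[0-9]", ch[i + 2L]))
        parse_err(i, "'%' must be followed by two digits")
      ring_closure(paste0(ch[i + 1L], ch[i + 2L]), i)
      i <- i + 2L
    } else if (c1 == ".") {
      if (!is.null(pending)) parse_err(i, "bond symbol before '.'")
      fresh <- TRUE
      prev <- NA_integer_
    } else if (c1 %in% c(" ", "\t")) {
      parse_err(i, "whitespace inside SMILES")
    } else {
      parse_err(i, sprintf("unexpected character '%s'", c1))
    }
    i <- i + 1L
  }
  if (length(stack) > 0L) parse_err(n, "unbalanced '(': branch never closed")
  if (length(rings) > 0L) {
    keys <- paste(names(rings), collapse = ", ")
    parse_err(rings[[1L]]$pos, sprintf("unmatched ring-closure digit(s): %s", keys))
  }
  if (!is.null(pending)) parse_err(pending_pos, "trailing bond symbol")
  if (length(atoms) == 0L) parse_err(1L, "no atoms")

  build_molgraph(atoms, bonds, smiles)
}

parse_bracket <- function(body, pos, strict) {
  rest <- body
  # isotope
  iso <- regmatches(rest, regexpr("^[0-9]+", rest))
  if (length(iso) == 1L && nzchar(iso)) {
    if (strict) gpcr_stop(sprintf(
      "unsupported feature at position %d: isotope label", pos),
      "gpcr_unsupported_error")
    rest <- sub("^[0-9]+", "", rest)
  }
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[bcnops])", rest))
  if (length(m) == 0L) parse_err(pos, "bracket atom lacks an element symbol")
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  # chirality
  if (grepl("^@", rest)) {
    if (strict) gpcr_stop(sprintf(
      "unsupported feature at position %d: chirality marker", pos),
      "gpcr_unsupported_error")
    rest <- sub("^@+(TH[12]|AL[12])?", "", rest)
  }
  explicit_h <- 0L
  hm <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(hm) == 1L && nzchar(hm)) {
    explicit_h <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    rest <- substring(rest, nchar(hm) + 1L)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("^(\\++[0-9]*|-+[0-9]*)", rest))
  if (length(cm) == 1L && nzchar(cm)) {
    sign <- if (substring(cm, 1L, 1L) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cm)
    mag <- if (nzchar(digits)) as.integer(digits)
           else sum(strsplit(cm, "")[[1]] %in% c("+", "-"))
    charge <- sign * mag
    rest <- substring(rest, nchar(cm) + 1L)
  }
  if (nzchar(rest))
    parse_err(pos, sprintf("unparsed bracket-atom content '%s'", rest))
  list(element = element, aromatic = aromatic, charge = charge,
       explicit_h = explicit_h)
}

build_molgraph <- function(atoms, bonds, smiles) {
  na <- length(atoms)
  el <- vapply(atoms, `[[`, "", "element")
  ar <- vapply(atoms, `[[`, FALSE, "aromatic")
  chg <- vapply(atoms, `[[`, 0L, "charge")
  exh <- vapply(atoms, `[[`, NA_integer_, "explicit_h")

  bdf <- if (length(bonds) == 0L)
    data.frame(a = integer(0), b = integer(0), order = character(0))
  else
    data.frame(a = vapply(bonds, `[[`, 0L, "a"),
               b = vapply(bonds, `[[`, 0L, "b"),
               order = vapply(bonds, `[[`, "", "order"))

  bos <- numeric(na)
  for (k in seq_len(nrow(bdf))) {
    v <- BOND_ORDER_VALUE[[bdf$order[k]]]
    bos[bdf$a[k]] <- bos[bdf$a[k]] + v
    bos[bdf$b[k]] <- bos[bdf$b[k]] + v
  }
  imp <- integer(na)
  for (i in seq_len(na)) {
    imp[i] <- if (!is.na(exh[i])) exh[i]   # bracket atom: explicit count rules
              else implicit_hydrogens(el[i], bos[i], chg[i], ar[i])
  }

  adj <- rep(list(data.frame(nbr = integer(0), order = character(0))), na)
  for (k in seq_len(nrow(bdf))) {
    a <- bdf$a[k]; b <- bdf$b[k]; o <- bdf$order[k]
    adj[[a]] <- rbind(adj[[a]], data.frame(nbr = b, order = o))
    adj[[b]] <- rbind(adj[[b]], data.frame(nbr = a, order = o))
  }

  structure(list(
    atoms = data.frame(element = el, aromatic = ar, charge = chg,
                       implicit_h = imp),
    bonds = bdf,
    adj = adj,
    smiles = smiles
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds, %d component(s): %s\n",
              nrow(x$atoms), nrow(x$bonds), n_components(x), x$smiles))
  invisible(x)
}

# heavy-atom degree of every atom
atom_degrees <- function(graph) {
  vapply(graph$adj, nrow, 0L)
}

n_components <- function(graph) {
  na <- nrow(graph$atoms)
  if (na == 0L) return(0L)
  comp <- integer(na)
  cur <- 0L
  for (s in seq_len(na)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- graph$adj[[v]]$nbr
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  cur
}

# circuit rank: independent cycles = bonds - atoms + components
circuit_rank <- function(graph) {
  nrow(graph$bonds) - nrow(graph$atoms) + n_components(graph)
}

#' Read a .smi ligand file
#'
#' One record per non-empty line: a SMILES string, whitespace, then a ligand
#' identifier. Lines starting with `#` are ignored. IDs must be unique.
#'
#' @param path Path to the `.smi` file.
#' @return data.frame with columns `ligand_id`, `smiles`.
#' @export
read_smi <- function(path) {
  if (!file.exists(path))
    gpcr_stop(sprintf("no such file: %s", path), "gpcr_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(ligand_id = character(0), smiles = character(0)))
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    gpcr_stop(sprintf(".smi line %d lacks 'SMILES<ws>ID'", bad[1L]), "gpcr_io_error")
  ids <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(ids))
    gpcr_stop(sprintf("duplicate ligand id '%s' in %s",
                      ids[duplicated(ids)][1L], path), "gpcr_io_error")
  data.frame(ligand_id = ids, smiles = vapply(parts, `[[`, "", 1L))
}
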