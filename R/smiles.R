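#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic-subset dialect used throughout the package: elements
#' B, C, N, O, P, S, F, Cl, Br, I; aromatic lowercase atoms (b, c, n, o, p, s)
#' plus the bracket atom `[nH]`; branches; ring-closure digits `1`-`9` and
#' `%nn`; explicit bonds `-`, `=`, `#`, `:`. Stereochemistry, isotopes and
#' general bracket atoms are rejected with an unsupported-feature error.
#'
#' A bond written without an explicit symbol between two aromatic atoms is
#' taken as aromatic; otherwise it is single.
#'
#' @param smiles A single SMILES string.
#' @return A `mol_graph`: list with `atoms` (tibble: `idx`, `element`,
#'   `aromatic`, `charge`, `h_explicit`) and `bonds` (tibble: `from`, `to`,
#'   `order`, `aromatic`). Aromatic bonds carry `order = 1.5`.
#' @examples
#' g <- parse_smiles("c1ccccc1O")
#' nrow(g$atoms)
#' ring_count(g)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty SMILES", call. = FALSE)

  el  <- character(0); arom <- logical(0); hexp <- integer(0)
  b_from <- integer(0); b_to <- integer(0); b_sym <- character(0)
  prev_stack <- integer(0)   # open branch points
  prev <- NA_integer_
  pending <- NA_character_   # explicit bond symbol awaiting next atom/closure
  rings <- list()            # label -> list(atom, sym, pos)

  add_atom <- function(sym, aromatic, h) {
    el[[length(el) + 1L]] <<- sym
    arom[[length(arom) + 1L]] <<- aromatic
    hexp[[length(hexp) + 1L]] <<- h
    length(el)
  }
  add_bond <- function(i, j, sym, pos) {
    if (is.na(sym)) {
      aromatic <- arom[i] && arom[j]
    } else if (sym == ":") {
      aromatic <- TRUE
    } else {
      aromatic <- FALSE
    }
    ord <- if (aromatic) 1.5 else switch(ifelse(is.na(sym), "-", sym),
                                         "-" = 1, "=" = 2, "#" = 3)
    b_from[[length(b_from) + 1L]] <<- i
    b_to[[length(b_to) + 1L]] <<- j
    b_sym[[length(b_sym) + 1L]] <<- if (aromatic) ":" else ifelse(is.na(sym), "-", sym)
    attr(b_sym, "orders") <<- c(attr(b_sym, "orders"), ord)
  }

  link <- function(idx, pos) {
    force(idx)  # add_atom must run before add_bond reads the atom tables
    if (!is.na(prev)) add_bond(prev, idx, pending, pos)
    pending <<- NA_character_
    prev <<- idx
  }
  close_ring <- function(label, pos) {
    if (is.na(prev)) stop(sprintf("ring closure '%s' before any atom at position %d", label, pos), call. = FALSE)
    if (!is.null(rings[[label]])) {
      open <- rings[[label]]
      sym <- if (!is.na(pending)) pending else open$sym
      add_bond(open$atom, prev, sym, pos)
      rings[[label]] <<- NULL
    } else {
      rings[[label]] <- list(atom = prev, sym = pending, pos = pos)
      rings <<- rings
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      link(add_atom(two, FALSE, NA_integer_), i); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      link(add_atom(ch, FALSE, NA_integer_), i); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      link(add_atom(toupper(ch), TRUE, NA_integer_), i); i <- i + 1L
    } else if (ch == "[") {
      if (two == "[n" && i + 3L <= n && chars[i + 2L] == "H" && chars[i + 3L] == "]") {
        link(add_atom("N", TRUE, 1L), i); i <- i + 4L
      } else {
        stop(sprintf("unsupported bracket atom at position %d (only [nH] is supported)", i), call. = FALSE)
      }
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop(sprintf("branch open before any atom at position %d", i), call. = FALSE)
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) stop(sprintf("unmatched ')' at position %d", i), call. = FALSE)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("^[1-9]$", ch)) {
      close_ring(ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop(sprintf("malformed %%nn ring closure at position %d", i), call. = FALSE)
      }
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i); i <- i + 3L
    } else {
      stop(sprintf("unsupported SMILES token '%s' at position %d", ch, i), call. = FALSE)
    }
  }
  if (length(prev_stack) > 0L) stop("unmatched '(' left open at end of SMILES", call. = FALSE)
  if (length(rings) > 0L) {
    open <- rings[[1L]]
    stop(sprintf("unmatched ring-closure label '%s' opened at position %d", names(rings)[1L], open$pos), call. = FALSE)
  }
  if (length(el) == 0L) stop("SMILES contains no atoms", call. = FALSE)

  atoms <- tibble::tibble(idx = seq_along(el), element = el,
                          aromatic = arom, charge = 0L, h_explicit = hexp)
  orders <- attr(b_sym, "orders")
  bonds <- tibble::tibble(from = b_from, to = b_to,
                          order = if (is.null(orders)) numeric(0) else orders,
                          aromatic = if (is.null(orders)) logical(0) else orders == 1.5)
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds, %d rings\n",
              nrow(x$atoms), nrow(x$bonds), ring_count(x)))
  invisible(x)
}

#' Number of smallest-set rings (cycle rank) of a molecular graph
#'
#' Cycle rank `|E| - |V| + components`.
#' @param graph A `mol_graph`.
#' @return Integer ring count.
#' @export
ring_count <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  nrow(graph$bonds) - nrow(graph$atoms) + n_components(graph)
}

n_components <- function(graph) {
  n <- nrow(graph$atoms)
  if (n == 0L) return(0L)
  adj <- adjacency_list(graph)
  seen <- logical(n); comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, adj[[v]][!seen[adj[[v]]]])
    }
  }
  comp
}

adjacency_list <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$from[k]; j <- graph$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Implicit hydrogen count per atom. Standard organic-subset valences
# (B 3, C 4, N 3, O 2, P 3, S 2, halogens 1); an aromatic atom consumes one
# extra valence unit beyond its explicit degree (aromatic bonds count 1),
# so benzene carbons get one implicit H and pyridine N none. [nH] is exact.
implicit_h <- function(graph) {
  valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
               F = 1, Cl = 1, Br = 1, I = 1)
  n <- nrow(graph$atoms)
  consumed <- numeric(n)
  for (k in seq_len(nrow(graph$bonds))) {
    ord <- if (graph$bonds$aromatic[k]) 1 else graph$bonds$order[k]
    consumed[graph$bonds$from[k]] <- consumed[graph$bonds$from[k]] + ord
    consumed[graph$bonds$to[k]] <- consumed[graph$bonds$to[k]] + ord
  }
  consumed <- consumed + as.numeric(graph$atoms$aromatic)
  h <- pmax(0, valence[graph$atoms$element] - consumed)
  ifelse(!is.na(graph$atoms$h_explicit), graph$atoms$h_explicit, h)
}

#' Emit a SMILES string for a molecular graph
#'
#' Depth-first traversal with ring-closure digits; aromatic atoms are written
#' lowercase (aromatic N carrying an explicit hydrogen as `[nH]`), double and
#' triple bonds as `=` and `#`, and a non-aromatic single bond between two
#' aromatic atoms explicitly as `-`. Re-parsing the emitted string yields a
#' graph with identical atom, bond and ring counts.
#'
#' @param graph A `mol_graph`.
#' @return A SMILES string.
#' @export
write_smiles <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- nrow(graph$atoms)
  if (n == 0L) stop("empty graph", call. = FALSE)
  bonds <- graph$bonds
  adj <- vector("list", n)  # each entry: matrix with columns (other, bond_row)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]
    adj[[i]] <- rbind(adj[[i]], c(j, k)); adj[[j]] <- rbind(adj[[j]], c(i, k))
  }

  visited <- logical(n)
  classified <- logical(max(nrow(bonds), 1L))
  children <- vector("list", n)    # per atom: list of c(child, bond_row)
  ring_open <- vector("list", n)   # per atom: list of c(label, bond_row)
  next_label <- 1L

  classify <- function(v, from_bond) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1L]; bk <- nb[r, 2L]
      if (!is.na(from_bond) && bk == from_bond) next
      if (classified[bk]) next
      if (!visited[w]) {
        classified[bk] <<- TRUE
        children[[v]][[length(children[[v]]) + 1L]] <<- c(w, bk)
        classify(w, bk)
      } else {
        classified[bk] <<- TRUE
        lab <- next_label; next_label <<- next_label + 1L
        ring_open[[v]][[length(ring_open[[v]]) + 1L]] <<- c(lab, bk)
        ring_open[[w]][[length(ring_open[[w]]) + 1L]] <<- c(lab, bk)
      }
    }
  }

  atom_token <- function(i) {
    e <- graph$atoms$element[i]
    if (graph$atoms$aromatic[i]) {
      if (e == "N" && !is.na(graph$atoms$h_explicit[i]) && graph$atoms$h_explicit[i] >= 1L) "[nH]"
      else tolower(e)
    } else e
  }
  bond_token <- function(k) {
    if (bonds$aromatic[k]) return("")
    if (bonds$order[k] == 2) return("=")
    if (bonds$order[k] == 3) return("#")
    # a bare single bond between two aromatic atoms would re-parse aromatic
    i <- bonds$from[k]; j <- bonds$to[k]
    if (graph$atoms$aromatic[i] && graph$atoms$aromatic[j]) "-" else ""
  }
  ring_label_str <- function(lab) if (lab <= 9L) as.character(lab) else sprintf("%%%02d", lab)

  emit <- function(v) {
    tok <- atom_token(v)
    for (rc in ring_open[[v]]) {
      tok <- paste0(tok, bond_token(rc[2L]), ring_label_str(rc[1L]))
    }
    kids <- children[[v]]
    if (length(kids) > 0L) {
      parts <- vapply(kids, function(kd) paste0(bond_token(kd[2L]), emit(kd[1L])), character(1))
      if (length(parts) > 1L) {
        tok <- paste0(tok, paste0("(", parts[-length(parts)], ")", collapse = ""), parts[length(parts)])
      } else {
        tok <- paste0(tok, parts)
      }
    }
    tok
  }

  out <- character(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    classify(s, NA_integer_)
    out <- c(out, emit(s))
  }
  paste(out, collapse = ".")
}
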