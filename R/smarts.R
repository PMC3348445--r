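## A compact SMARTS-subset parser and matcher.
##
## Supported: organic-subset atoms (C N O S P F Cl Br I B, aromatic c n o s p,
## wildcards * A a), bracket atoms with primitives #n, element symbols,
## charge (+, -, +n, +0), Hn (total hydrogen count), Xn (connections including
## hydrogens), Dn (heavy-atom degree), R / R0 (ring membership), rn (in a ring
## of size n); logical operators ! (not), & (high-priority and, implicit),
## , (or), ; (low-priority and); bond symbols - = # : ~ (default: single or
## aromatic); branches in parentheses and single-digit ring closures.
## Unsupported constructs (recursive SMARTS, stereo, maps) raise an error at
## parse time, so configuration mistakes surface when rules are loaded.

ELEMENT_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                     S = 16, Cl = 17, Br = 35, I = 53)

#' Compile a SMARTS pattern
#'
#' @param s SMARTS string (see package docs for the supported subset).
#' @return A `smarts_pattern` with pattern atoms and bonds.
#' @export
smarts_pattern <- function(s) {
  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  natoms <- 0L
  atoms <- list()
  bonds <- list()   # list of c(i, j, type)
  ringmap <- list() # digit -> c(atom, bondtype)
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  take <- function() { ch <- chars[pos]; pos <<- pos + 1L; ch }

  parse_bracket <- function() {
    # tokens until ']'
    prims <- list(); ops <- character(0)
    repeat {
      ch <- peek()
      if (ch == "") stop("SMARTS parse error (unterminated bracket): ", s)
      if (ch == "]") { take(); break }
      if (ch %in% c("!", "&", ",", ";")) { take(); ops <- c(ops, ch); next }
      if (ch == "$") stop("recursive SMARTS not supported: ", s)
      prim <- parse_primitive()
      prims <- c(prims, list(prim)); ops <- c(ops, "P")
    }
    # build postfix-free evaluator: sequence of (maybe-negated) primitives
    # joined by & (implicit/explicit), ',' and ';' with SMARTS precedence.
    seqs <- list(); cur <- NULL; neg <- FALSE; out <- list()
    # re-tokenise: ops vector holds the stream; walk it with an index into prims
    stream <- list(); pi <- 1L
    for (op in ops) {
      if (op == "P") { stream[[length(stream) + 1L]] <- prims[[pi]]; pi <- pi + 1L }
      else stream[[length(stream) + 1L]] <- op
    }
    structure(list(stream = stream), class = "smarts_atom_expr")
  }

  parse_primitive <- function() {
    ch <- take()
    if (ch == "#") {
      num <- read_number()
      return(list(kind = "elem_num", value = num))
    }
    if (ch %in% c("+", "-")) {
      sign <- if (ch == "+") 1L else -1L
      n <- 1L
      if (grepl("[0-9]", peek())) n <- read_number()
      else while (peek() == ch) { take(); n <- n + 1L }
      return(list(kind = "charge", value = sign * n))
    }
    if (ch == "H") {
      n <- if (grepl("[0-9]", peek())) read_number() else 1L
      return(list(kind = "hcount", value = n))
    }
    if (ch == "X") return(list(kind = "connect", value = read_number()))
    if (ch == "D") return(list(kind = "degree", value = read_number()))
    if (ch == "R") {
      if (grepl("[0-9]", peek())) {
        n <- read_number()
        return(list(kind = if (n == 0) "notring" else "ring", value = n))
      }
      return(list(kind = "ring", value = NA))
    }
    if (ch == "r") return(list(kind = "ringsize", value = read_number()))
    if (ch == "a") return(list(kind = "aromatic"))
    if (ch == "A") return(list(kind = "aliphatic"))
    if (ch == "*") return(list(kind = "any"))
    if (grepl("[A-Z]", ch)) {
      sym <- ch
      if (peek() %in% c("l", "r") && paste0(ch, peek()) %in% names(ELEMENT_NUMBERS))
        sym <- paste0(sym, take())
      if (!sym %in% names(ELEMENT_NUMBERS))
        stop("unknown element in SMARTS: ", sym)
      return(list(kind = "elem_aliph", value = sym))
    }
    if (grepl("[cnosp]", ch))
      return(list(kind = "elem_arom", value = toupper(ch)))
    stop("SMARTS parse error near '", ch, "' in: ", s)
  }

  read_number <- function() {
    digs <- ""
    while (grepl("[0-9]", peek())) digs <- paste0(digs, take())
    if (digs == "") stop("number expected in SMARTS: ", s)
    as.integer(digs)
  }

  add_atom <- function(expr) {
    natoms <<- natoms + 1L
    atoms[[natoms]] <<- expr
    natoms
  }
  simple_expr <- function(...) structure(list(stream = list(...)),
                                         class = "smarts_atom_expr")

  prev_atom_stack <- integer(0)  # branch stack
  prev_atom <- 0L
  pending_bond <- NA_character_

  while (pos <= length(chars)) {
    ch <- peek()
    if (ch %in% c("-", "=", "#", ":", "~")) { pending_bond <- take(); next }
    if (ch == "(") { take(); prev_atom_stack <- c(prev_atom_stack, prev_atom); next }
    if (ch == ")") {
      take()
      if (!length(prev_atom_stack)) stop("unbalanced ')' in SMARTS: ", s)
      prev_atom <- prev_atom_stack[length(prev_atom_stack)]
      prev_atom_stack <- prev_atom_stack[-length(prev_atom_stack)]
      next
    }
    if (grepl("[0-9]", ch)) {
      d <- take()
      if (is.null(ringmap[[d]])) {
        ringmap[[d]] <- c(prev_atom, if (is.na(pending_bond)) "" else pending_bond)
      } else {
        open <- ringmap[[d]]
        bt <- if (!is.na(pending_bond)) pending_bond
              else if (open[2] != "") open[2] else NA_character_
        bonds[[length(bonds) + 1L]] <- list(i = as.integer(open[1]),
                                            j = prev_atom, type = bt)
        ringmap[[d]] <- NULL
      }
      pending_bond <- NA_character_
      next
    }
    newa <- if (ch == "[") {
      take(); add_atom(parse_bracket())
    } else if (ch == "*") {
      take(); add_atom(simple_expr(list(kind = "any")))
    } else if (ch == "a") {
      take(); add_atom(simple_expr(list(kind = "aromatic")))
    } else if (ch == "A") {
      take(); add_atom(simple_expr(list(kind = "aliphatic")))
    } else if (grepl("[A-Z]", ch)) {
      sym <- take()
      if (peek() %in% c("l", "r") &&
          paste0(sym, peek()) %in% names(ELEMENT_NUMBERS))
        sym <- paste0(sym, take())
      if (!sym %in% names(ELEMENT_NUMBERS))
        stop("unknown element in SMARTS: ", sym)
      add_atom(simple_expr(list(kind = "elem_aliph", value = sym)))
    } else if (grepl("[cnosp]", ch)) {
      add_atom(simple_expr(list(kind = "elem_arom", value = toupper(take()))))
    } else stop("SMARTS parse error near '", ch, "' in: ", s)
    if (prev_atom > 0L)
      bonds[[length(bonds) + 1L]] <- list(i = prev_atom, j = newa,
                                          type = pending_bond)
    pending_bond <- NA_character_
    prev_atom <- newa
  }
  if (length(prev_atom_stack))
    stop("unbalanced '(' in SMARTS: ", s)
  if (length(ringmap) && any(!vapply(ringmap, is.null, logical(1))))
    stop("unclosed ring bond in SMARTS: ", s)
  structure(list(smarts = s, atoms = atoms, bonds = bonds, natoms = natoms),
            class = "smarts_pattern")
}

## Evaluate a bracket expression against one molecule atom.
## Precedence: ! > & (implicit) > , > ;
eval_atom_expr <- function(expr, lig, a) {
  stream <- expr$stream
  # split on ';' then on ',' then evaluate &-chains with ! prefixes
  groups <- split_stream(stream, ";")
  for (g in groups) {
    orparts <- split_stream(g, ",")
    ok <- FALSE
    for (p in orparts) if (eval_and_chain(p, lig, a)) { ok <- TRUE; break }
    if (!ok) return(FALSE)
  }
  TRUE
}

split_stream <- function(stream, sep) {
  out <- list(); cur <- list()
  for (tok in stream) {
    if (is.character(tok) && length(tok) == 1 && tok == sep) {
      out[[length(out) + 1L]] <- cur; cur <- list()
    } else cur[[length(cur) + 1L]] <- tok
  }
  out[[length(out) + 1L]] <- cur
  out
}

eval_and_chain <- function(toks, lig, a) {
  neg <- FALSE
  for (tok in toks) {
    if (is.character(tok)) {
      if (tok == "!") { neg <- !neg }
      # "&" is implicit and
      next
    }
    v <- eval_primitive(tok, lig, a)
    if (neg) v <- !v
    neg <- FALSE
    if (!v) return(FALSE)
  }
  TRUE
}

eval_primitive <- function(prim, lig, a) {
  el <- lig$elements[a]
  switch(prim$kind,
    any       = TRUE,
    aromatic  = lig$aromatic[a],
    aliphatic = !lig$aromatic[a],
    elem_num  = identical(unname(ELEMENT_NUMBERS[el]), as.numeric(prim$value)),
    elem_aliph = el == prim$value && !lig$aromatic[a],
    elem_arom  = el == prim$value && lig$aromatic[a],
    charge    = lig$charges[a] == prim$value,
    hcount    = total_h(lig, a) == prim$value,
    degree    = length(heavy_neighbours(lig, a)) == prim$value,
    connect   = length(lig$adj[[a]]) + lig$implicit_h[a] == prim$value,
    ring      = lig$in_ring[a],
    notring   = !lig$in_ring[a],
    ringsize  = any(vapply(lig$rings, function(r)
                  length(r) == prim$value && a %in% r, logical(1))),
    stop("unknown SMARTS primitive")
  )
}

bond_compatible <- function(type, order, aromatic) {
  if (is.na(type)) return((order == 1 && !aromatic) || aromatic)
  switch(type,
    "-" = order == 1 && !aromatic,
    "=" = order == 2 && !aromatic,
    "#" = order == 3 && !aromatic,
    ":" = aromatic,
    "~" = TRUE)
}

#' Match a SMARTS pattern against a ligand
#'
#' Backtracking subgraph match over the topology (conformer-independent).
#'
#' @param ligand a `ligand`.
#' @param pattern a `smarts_pattern` or SMARTS string.
#' @param unique if TRUE (default), keep one match per distinct atom set.
#' @return Integer matrix, one row per match, columns are pattern-atom
#'   positions holding molecule atom indices; zero rows when no match.
#' @export
smarts_match <- function(ligand, pattern, unique = TRUE) {
  if (is.character(pattern)) pattern <- smarts_pattern(pattern)
  np <- pattern$natoms
  if (np == 0L) return(matrix(integer(0), 0, 0))
  # pattern adjacency
  padj <- vector("list", np)
  for (b in pattern$bonds) {
    padj[[b$i]] <- c(padj[[b$i]], list(list(j = b$j, type = b$type)))
    padj[[b$j]] <- c(padj[[b$j]], list(list(j = b$i, type = b$type)))
  }
  # bond lookup in molecule
  bkey <- paste(pmin(ligand$bonds$i, ligand$bonds$j),
                pmax(ligand$bonds$i, ligand$bonds$j))
  border <- ligand$bonds$order; barom <- ligand$bonds$aromatic
  names(border) <- bkey; names(barom) <- bkey
  mol_bond <- function(i, j) {
    k <- paste(min(i, j), max(i, j))
    if (is.na(border[k])) NULL else list(order = unname(border[k]),
                                         aromatic = unname(barom[k]))
  }
  # DFS order over pattern atoms (assume connected)
  order_p <- integer(0); seen <- logical(np); stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE; order_p <- c(order_p, v)
    for (nb in padj[[v]]) if (!seen[nb$j]) stack <- c(stack, nb$j)
  }
  if (length(order_p) != np) stop("disconnected SMARTS patterns unsupported")
  matches <- list()
  assign_vec <- integer(np)
  recurse <- function(k) {
    if (k > np) {
      matches[[length(matches) + 1L]] <<- assign_vec
      return(invisible())
    }
    pa <- order_p[k]
    anchors <- Filter(function(nb) assign_vec[nb$j] > 0L, padj[[pa]])
    cand <- if (length(anchors)) {
      ligand$adj[[assign_vec[anchors[[1]]$j]]]
    } else seq_len(ligand$natoms)
    for (ma in cand) {
      if (ma %in% assign_vec[assign_vec > 0L]) next
      if (!eval_atom_expr(pattern$atoms[[pa]], ligand, ma)) next
      ok <- TRUE
      for (nb in anchors) {
        mb <- mol_bond(ma, assign_vec[nb$j])
        if (is.null(mb) || !bond_compatible(nb$type, mb$order, mb$aromatic)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[pa] <<- ma
      recurse(k + 1L)
      assign_vec[pa] <<- 0L
    }
  }
  recurse(1L)
  if (!length(matches)) return(matrix(integer(0), 0, np))
  m <- do.call(rbind, matches)
  if (unique) m <- m[!duplicated(apply(m, 1, function(r)
    paste(sort(r), collapse = ","))), , drop = FALSE]
  m
}
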