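# Minimal molecular-graph layer: SMILES in, editable graph, SMILES out.
#
# This exists for one reason: applying reaction SMARTS templates to
# substrates requires graph surgery with atom-map bookkeeping, which no
# installed R package provides.  The graphs are also the ground truth for
# the count-based descriptors (H-bond donors/acceptors, rotatable bonds,
# Fsp3) whose conventions are fixed package-wide.  Everything else —
# canonicalization, substructure matching, hashed fingerprints — is
# OpenBabel's job (see ob.R).
#
# Graph shape:
#   atoms: data.frame(elem, arom, charge, hcount, map)
#          hcount NA = implicit (recomputed from valence rules)
#   bonds: data.frame(a1, a2, order)  with order in "1","2","3","ar"
#
# Atom order equals order of appearance in the parsed SMILES, matching the
# atom indices OpenBabel reports for SMARTS matches on the same string.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.KNOWN_ELEMS <- c(.ORGANIC_SUBSET, "H", "Si", "Se", "As", "Na", "K", "Li")

.emptyGraph <- function() {
  list(
    atoms = data.frame(elem = character(0), arom = logical(0),
                       charge = integer(0), hcount = integer(0),
                       map = integer(0), stringsAsFactors = FALSE),
    bonds = data.frame(a1 = integer(0), a2 = integer(0),
                       order = character(0), stringsAsFactors = FALSE)
  )
}

# parse one SMILES string (single fragment unless allowDot).
# smartsMode relaxes bracket-atom semantics for reaction product templates:
# an unspecified H count means "recompute", not "zero hydrogens".
parseSmiles <- function(s, smartsMode = FALSE, allowDot = FALSE) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  g <- .emptyGraph()
  n <- nchar(s)
  i <- 1L
  prev <- NA_integer_
  pending <- NULL                 # pending bond symbol
  stack <- integer(0)
  rings <- list()                 # ring-closure bookkeeping

  addAtom <- function(elem, arom, charge = 0L, hcount = NA_integer_,
                      map = 0L) {
    g$atoms[nrow(g$atoms) + 1L, ] <<- list(elem, arom, charge, hcount, map)
    idx <- nrow(g$atoms)
    if (!is.na(prev)) {
      ord <- pending
      if (is.null(ord))
        ord <- if (g$atoms$arom[prev] && arom) "ar" else "1"
      g$bonds[nrow(g$bonds) + 1L, ] <<- list(prev, idx, ord)
    }
    prev <<- idx
    pending <<- NULL
    idx
  }

  closeRing <- function(num) {
    key <- as.character(num)
    if (is.na(prev)) stop("ring closure before any atom in SMILES: ", s)
    if (!is.null(rings[[key]])) {
      op <- rings[[key]]
      ord <- pending
      if (is.null(ord)) ord <- op$order
      if (is.null(ord))
        ord <- if (g$atoms$arom[op$atom] && g$atoms$arom[prev]) "ar" else "1"
      g$bonds[nrow(g$bonds) + 1L, ] <<- list(op$atom, prev, ord)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- list(atom = prev, order = pending)
    }
    pending <<- NULL
  }

  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- "1"; i <- i + 1L
    } else if (ch == "=") {
      pending <- "2"; i <- i + 1L
    } else if (ch == "#") {
      pending <- "3"; i <- i + 1L
    } else if (ch == ":") {
      pending <- "ar"; i <- i + 1L
    } else if (ch == ".") {
      if (!allowDot) stop("multi-fragment SMILES not supported here: ", s)
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closeRing(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      num <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", num)) stop("bad ring closure '%' in: ", s)
      closeRing(as.integer(num)); i <- i + 3L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom in SMILES: ", s)
      content <- substr(s, i + 1L, i + j - 2L)
      a <- .parseBracketAtom(content, smartsMode, s)
      addAtom(a$elem, a$arom, a$charge, a$hcount, a$map)
      i <- i + j
    } else if (grepl("[A-Z]", ch)) {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        addAtom(two, FALSE); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        addAtom(ch, FALSE); i <- i + 1L
      } else stop("unexpected atom symbol '", ch, "' in SMILES: ", s)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      addAtom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "*") {
      stop("wildcard atoms not supported in assembled structures: ", s)
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", s)
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES: ", s)
  if (length(rings)) stop("unclosed ring bond in SMILES: ", s)
  if (nrow(g$atoms) == 0L) stop("empty SMILES")
  g
}

# bracket atom content, e.g. "nH", "N+", "13CH3", "C@@H", "O-", "N:2"
.parseBracketAtom <- function(content, smartsMode, full) {
  rest <- content
  # isotope
  rest <- sub("^[0-9]+", "", rest)
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|as|se|[bcnops])", rest))
  if (length(m) == 0L) stop("cannot parse bracket atom [", content, "] in: ", full)
  sym <- m
  rest <- substr(rest, nchar(sym) + 1L, nchar(rest))
  arom <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
  elem <- if (arom) {
    up <- toupper(sym)
    if (nchar(sym) == 2L) paste0(substr(up, 1, 1), substr(sym, 2, 2)) else up
  } else sym
  if (!elem %in% .KNOWN_ELEMS) stop("unknown element '", elem, "' in: ", full)
  # chirality (ignored)
  rest <- sub("^@{1,2}(TH[12]|AL[12]|SP[1-3])?", "", rest)
  hcount <- if (smartsMode) NA_integer_ else 0L
  hm <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(hm) == 1L && nzchar(hm)) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substr(hm, 2, nchar(hm)))
    rest <- substr(rest, nchar(hm) + 1L, nchar(rest))
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("^(\\+{1,3}|-{1,3})([0-9]+)?", rest))
  if (length(cm) == 1L && nzchar(cm)) {
    sign <- if (substr(cm, 1, 1) == "+") 1L else -1L
    dig <- regmatches(cm, regexpr("[0-9]+", cm))
    mag <- if (length(dig) && nzchar(dig)) as.integer(dig)
           else nchar(gsub("[0-9]", "", cm))
    charge <- sign * mag
    rest <- substr(rest, nchar(cm) + 1L, nchar(rest))
  }
  map <- 0L
  mm <- regmatches(rest, regexpr("^:[0-9]+$", rest))
  if (length(mm) == 1L && nzchar(mm)) {
    map <- as.integer(substr(mm, 2, nchar(mm)))
    rest <- substr(rest, nchar(mm) + 1L, nchar(rest))
  }
  if (nzchar(rest))
    stop("unsupported bracket atom [", content, "] in: ", full)
  list(elem = elem, arom = arom, charge = charge, hcount = hcount, map = map)
}

# effective hydrogen count per atom (explicit where given, else valence rules)
.atomHcounts <- function(g) {
  na <- nrow(g$atoms)
  if (na == 0L) return(integer(0))
  ordnum <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)
  bosum <- numeric(na)
  deg <- integer(na)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[r]; a2 <- g$bonds$a2[r]
      o <- ordnum[[g$bonds$order[r]]]
      bosum[a1] <- bosum[a1] + o; bosum[a2] <- bosum[a2] + o
      deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
    }
  }
  h <- integer(na)
  for (i in seq_len(na)) {
    if (!is.na(g$atoms$hcount[i])) { h[i] <- g$atoms$hcount[i]; next }
    el <- g$atoms$elem[i]; q <- g$atoms$charge[i]
    if (g$atoms$arom[i]) {
      val <- switch(el, C = 4L, N = 3L, B = 3L, P = 3L, O = 2L, S = 2L, 2L)
      pi1 <- if (el %in% c("C", "N", "B", "P")) 1L else 0L
      h[i] <- max(0L, val - deg[i] - pi1)
    } else {
      bs <- ceiling(bosum[i])
      val <- switch(el,
        C = 4L - abs(q),
        N = 3L + q,
        O = 2L - abs(q) * (q < 0) + q * (q > 0),
        S = { v <- c(2L, 4L, 6L); v <- v[v >= bs]; if (length(v)) v[1] else bs },
        P = if (bs > 3L) 5L else 3L,
        B = 3L,
        F = 1L, Cl = 1L, Br = 1L, I = 1L,
        H = 0L,
        0L)
      if (el %in% c("F", "Cl", "Br", "I") && q == -1L) val <- 0L
      if (el == "O") val <- if (q > 0) 3L else if (q < 0) 1L else 2L
      if (el == "N") val <- if (q > 0) 4L else if (q < 0) 2L else 3L
      h[i] <- max(0L, val - bs)
    }
  }
  h
}

# ---- graph surgery helpers (used by the reaction engine) ------------------

.gRemoveAtoms <- function(g, idx) {
  if (length(idx) == 0L) return(g)
  keep <- setdiff(seq_len(nrow(g$atoms)), idx)
  remap <- integer(nrow(g$atoms))
  remap[keep] <- seq_along(keep)
  g$atoms <- g$atoms[keep, , drop = FALSE]
  rownames(g$atoms) <- NULL
  if (nrow(g$bonds)) {
    ok <- !(g$bonds$a1 %in% idx | g$bonds$a2 %in% idx)
    g$bonds <- g$bonds[ok, , drop = FALSE]
    g$bonds$a1 <- remap[g$bonds$a1]
    g$bonds$a2 <- remap[g$bonds$a2]
    rownames(g$bonds) <- NULL
  }
  g
}

.gDropBond <- function(g, a, b) {
  if (!nrow(g$bonds)) return(g)
  ok <- !((g$bonds$a1 == a & g$bonds$a2 == b) |
          (g$bonds$a1 == b & g$bonds$a2 == a))
  g$bonds <- g$bonds[ok, , drop = FALSE]
  rownames(g$bonds) <- NULL
  g
}

.gAddBond <- function(g, a, b, order) {
  g <- .gDropBond(g, a, b)
  g$bonds[nrow(g$bonds) + 1L, ] <- list(a, b, order)
  g
}

# connected components as a list of atom-index vectors
.gComponents <- function(g) {
  na <- nrow(g$atoms)
  if (na == 0L) return(list())
  adj <- vector("list", na)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[r]; a2 <- g$bonds$a2[r]
      adj[[a1]] <- c(adj[[a1]], a2); adj[[a2]] <- c(adj[[a2]], a1)
    }
  }
  seen <- logical(na)
  comps <- list()
  for (start in seq_len(na)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# logical per bond: TRUE when the bond lies in a ring (i.e. is not a bridge)
.ringBondFlags <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  na <- nrow(g$atoms)
  adj <- vector("list", na)            # list of c(neighbor, bondIdx)
  for (r in seq_len(nb)) {
    adj[[g$bonds$a1[r]]] <- c(adj[[g$bonds$a1[r]]], list(c(g$bonds$a2[r], r)))
    adj[[g$bonds$a2[r]]] <- c(adj[[g$bonds$a2[r]]], list(c(g$bonds$a1[r], r)))
  }
  disc <- integer(na); low <- integer(na); timer <- 0L
  isBridge <- logical(nb)
  # iterative DFS (explicit stack) for bridge finding
  for (root in seq_len(na)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, pe = 0L, it = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$it == 1L) { timer <- timer + 1L; disc[v] <- low[v] <- timer }
      advanced <- FALSE
      nbrs <- adj[[v]]
      while (fr$it <= length(nbrs)) {
        e <- nbrs[[fr$it]]
        fr$it <- fr$it + 1L
        w <- e[1]; be <- e[2]
        if (be == fr$pe) next
        if (disc[w] == 0L) {
          stack[[length(stack)]] <- fr
          stack[[length(stack) + 1L]] <- list(v = w, pe = be, it = 1L)
          advanced <- TRUE
          break
        } else {
          low[v] <- min(low[v], disc[w])
        }
      }
      if (!advanced) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pf <- stack[[length(stack)]]
          low[pf$v] <- min(low[pf$v], low[v])
          if (low[v] > disc[pf$v]) isBridge[fr$pe] <- TRUE
          stack[[length(stack)]] <- pf
        }
      } else {
        # frame already updated in place above
      }
    }
  }
  !isBridge
}

# ---- SMILES writer --------------------------------------------------------

# emits a valid (not canonical) SMILES; canonicalization is OpenBabel's job
writeSmiles <- function(g) {
  comps <- .gComponents(g)
  paste(vapply(comps, function(comp) .writeFragment(g, comp), character(1)),
        collapse = ".")
}

.writeFragment <- function(g, comp) {
  na <- nrow(g$atoms)
  adj <- vector("list", na)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[r]; a2 <- g$bonds$a2[r]
      adj[[a1]] <- c(adj[[a1]], list(c(a2, r)))
      adj[[a2]] <- c(adj[[a2]], list(c(a1, r)))
    }
  }
  root <- comp[1]
  visited <- logical(na)
  bondUsed <- logical(max(1L, nrow(g$bonds)))
  # first pass: spanning tree + ring closure bonds
  order <- integer(0)
  parentBond <- integer(na)
  stack <- root
  visited[root] <- TRUE
  ringBonds <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (e in adj[[v]]) {
      w <- e[1]; b <- e[2]
      if (!visited[w]) {
        visited[w] <- TRUE
        parentBond[w] <- b
        bondUsed[b] <- TRUE
        stack <- c(stack, w)
      } else if (!bondUsed[b]) {
        bondUsed[b] <- TRUE
        ringBonds <- c(ringBonds, b)
      }
    }
  }
  ringNum <- stats::setNames(seq_along(ringBonds), as.character(ringBonds))
  ringAt <- vector("list", na)       # atom -> list of c(bondIdx, num)
  for (b in ringBonds) {
    for (a in c(g$bonds$a1[b], g$bonds$a2[b]))
      ringAt[[a]] <- c(ringAt[[a]], list(c(b, ringNum[[as.character(b)]])))
  }
  hEff <- .atomHcounts(g)

  bondSym <- function(b, from, to) {
    o <- g$bonds$order[b]
    ar1 <- g$atoms$arom[from]; ar2 <- g$atoms$arom[to]
    switch(o,
      "1" = if (ar1 && ar2) "-" else "",
      "2" = "=",
      "3" = "#",
      "ar" = "")
  }
  atomTok <- function(i) {
    el <- g$atoms$elem[i]; ar <- g$atoms$arom[i]
    q <- g$atoms$charge[i]; hc <- g$atoms$hcount[i]
    sym <- if (ar) tolower(el) else el
    if (is.na(hc) && q == 0L && el %in% .ORGANIC_SUBSET) return(sym)
    h <- hEff[i]
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    qstr <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
            else sprintf("%+d", q)
    paste0("[", sym, hstr, qstr, "]")
  }
  ringTok <- function(i) {
    if (is.null(ringAt[[i]])) return("")
    paste(vapply(ringAt[[i]], function(e) {
      b <- e[1]; num <- e[2]
      other <- if (g$bonds$a1[b] == i) g$bonds$a2[b] else g$bonds$a1[b]
      sym <- bondSym(b, i, other)
      d <- if (num > 9) paste0("%", num) else as.character(num)
      paste0(sym, d)
    }, character(1)), collapse = "")
  }

  out <- character(0)
  emit <- function(v, viaBond) {
    if (viaBond > 0L) {
      from <- if (g$bonds$a1[viaBond] == v) g$bonds$a2[viaBond]
              else g$bonds$a1[viaBond]
      out[length(out) + 1L] <<- bondSym(viaBond, from, v)
    }
    out[length(out) + 1L] <<- atomTok(v)
    out[length(out) + 1L] <<- ringTok(v)
    kids <- list()
    for (e in adj[[v]]) {
      w <- e[1]; b <- e[2]
      if (parentBond[w] == b && w != v && b != viaBond)
        kids <- c(kids, list(c(w, b)))
    }
    if (length(kids)) {
      for (k in seq_along(kids)) {
        last <- k == length(kids)
        if (!last) out[length(out) + 1L] <<- "("
        emit(kids[[k]][1], kids[[k]][2])
        if (!last) out[length(out) + 1L] <<- ")"
      }
    }
  }
  emit(root, 0L)
  paste(out, collapse = "")
}
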