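# Reaction-SMARTS application: the primitive that turns a library address
# (reaction, substrate tuple) into a product structure.
#
# OpenBabel performs the reactant-template substructure matching (full SMARTS
# power on that side); the product construction is graph surgery here, with
# semantics modeled on the usual reaction-transform conventions:
#   * reactant-template atoms carrying an atom map survive into the product,
#     keeping their substituents that lie outside the template;
#   * matched but unmapped reactant-template atoms are deleted (leaving
#     groups), together with any disconnected fragments that result;
#   * unmapped product-template atoms are created fresh;
#   * bonds between product atoms are exactly those the product template
#     writes; hydrogen counts on reaction-center atoms are recomputed from
#     valence unless the product template pins them explicitly.
#
# Supported template dialect: atom-mapped components, any OpenBabel SMARTS
# on the reactant side except recursive SMARTS ('$'); the product side must
# be SMILES-like (bracket atoms with optional H count, charge, atom map).

# split "A.B>>P" into component templates, product template, arity
parseReactionSmarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L)
  if (grepl("$", smarts, fixed = TRUE))
    stop("recursive SMARTS ('$') is not supported in reaction templates: ",
         smarts)
  halves <- strsplit(smarts, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2L || !nzchar(halves[1]) || !nzchar(halves[2]))
    stop("reaction SMARTS must have the form 'reactants>>product': ", smarts)
  reactants <- .splitTopLevel(halves[1])
  product <- .stripOuterParens(halves[2])
  if (length(reactants) < 1L)
    stop("no reactant templates in reaction SMARTS: ", smarts)
  for (tpl in reactants)
    if (!.smartsOK(tpl))
      stop("reactant template does not compile as SMARTS: ", tpl)
  maps <- lapply(reactants, .templateAtomMaps)
  allMaps <- unlist(maps)
  dup <- allMaps[allMaps > 0][duplicated(allMaps[allMaps > 0])]
  if (length(dup))
    stop("duplicated atom map(s) on reactant side: ",
         paste(unique(dup), collapse = ", "))
  list(reactants = vapply(reactants, .stripOuterParens, character(1)),
       product = product,
       arity = length(reactants),
       maps = maps)
}

# dot-split at bracket/paren depth zero
.splitTopLevel <- function(s) {
  depth <- 0L; parts <- character(0); cur <- character(0)
  for (ch in strsplit(s, "", fixed = TRUE)[[1]]) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == "." && depth == 0L) {
      parts <- c(parts, paste(cur, collapse = "")); cur <- character(0)
    } else cur <- c(cur, ch)
  }
  c(parts, paste(cur, collapse = ""))
}

.stripOuterParens <- function(s) {
  if (grepl("^\\(.*\\)$", s)) {
    inner <- substr(s, 2L, nchar(s) - 1L)
    depth <- 0L; ok <- TRUE
    for (ch in strsplit(inner, "", fixed = TRUE)[[1]]) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (depth < 0L) { ok <- FALSE; break }
    }
    if (ok && depth == 0L) return(inner)
  }
  s
}

# atom maps per query atom, in order of appearance (0 = unmapped); the
# ordering matches the match vectors OpenBabel returns for the template
.templateAtomMaps <- function(tpl) {
  maps <- integer(0)
  n <- nchar(tpl)
  i <- 1L
  while (i <= n) {
    ch <- substr(tpl, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(tpl, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket in template: ", tpl)
      content <- substr(tpl, i + 1L, i + j - 2L)
      m <- regmatches(content, regexpr(":[0-9]+$", content))
      maps <- c(maps, if (length(m) && nzchar(m))
        as.integer(substr(m, 2L, nchar(m))) else 0L)
      i <- i + j
    } else if (substr(tpl, i, i + 1L) %in% c("Cl", "Br")) {
      maps <- c(maps, 0L); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s", "*", "a", "A")) {
      maps <- c(maps, 0L); i <- i + 1L
    } else {
      i <- i + 1L                     # bonds, digits, parens, operators
    }
  }
  maps
}

# Apply a parsed (or raw) reaction SMARTS to an ordered substrate tuple.
# Returns every distinct canonical product SMILES over all template match
# placements, sorted; callers wanting a single deterministic product take
# the first (lexicographically smallest) entry.
applyReactionSmarts <- function(smarts, substrates, maxMatchCombos = 64L) {
  rx <- if (is.list(smarts)) smarts else parseReactionSmarts(smarts)
  stopifnot(is.character(substrates))
  if (length(substrates) != rx$arity)
    stop("reaction expects ", rx$arity, " substrates, got ",
         length(substrates))
  matches <- vector("list", rx$arity)
  for (i in seq_len(rx$arity)) {
    m <- .smartsMatch(substrates[i], rx$reactants[i], uniqueMatches = TRUE)
    if (length(m) == 0L)
      stop("reactant template ", i, " ('", rx$reactants[i],
           "') does not match substrate at position ", i, ": ",
           substrates[i])
    nq <- length(rx$maps[[i]])
    bad <- vapply(m, function(x) length(x) != nq, logical(1))
    if (any(bad))
      stop("template/match atom count mismatch for component ", i)
    matches[[i]] <- m
  }
  graphs <- lapply(substrates, .parsedGraph)
  sizes <- vapply(graphs, function(g) nrow(g$atoms), integer(1))
  offs <- c(0L, cumsum(sizes))[seq_len(rx$arity)]
  union <- .emptyGraph()
  for (i in seq_len(rx$arity)) {
    union$atoms <- rbind(union$atoms, graphs[[i]]$atoms)
    b <- graphs[[i]]$bonds
    if (nrow(b)) { b$a1 <- b$a1 + offs[i]; b$a2 <- b$a2 + offs[i] }
    union$bonds <- rbind(union$bonds, b)
  }
  rownames(union$atoms) <- NULL; rownames(union$bonds) <- NULL
  pt <- parseSmiles(rx$product, smartsMode = TRUE, allowDot = TRUE)
  ptMapped <- pt$atoms$map > 0L

  combos <- .cartesianIndex(vapply(matches, length, integer(1)),
                            maxMatchCombos)
  products <- character(0)
  for (ci in seq_len(nrow(combos))) {
    gg <- union
    mapTo <- integer(0)                      # map number -> global atom
    matchedByComp <- vector("list", rx$arity)
    deleteSet <- integer(0)
    for (i in seq_len(rx$arity)) {
      mi <- matches[[i]][[combos[ci, i]]] + offs[i]
      matchedByComp[[i]] <- mi
      mp <- rx$maps[[i]]
      for (q in seq_along(mp)) {
        if (mp[q] > 0L) mapTo[as.character(mp[q])] <- mi[q]
        else deleteSet <- c(deleteSet, mi[q])
      }
    }
    # template-controlled region: drop substrate bonds within each match
    for (i in seq_len(rx$arity)) {
      mi <- matchedByComp[[i]]
      if (nrow(gg$bonds)) {
        drop <- gg$bonds$a1 %in% mi & gg$bonds$a2 %in% mi
        gg$bonds <- gg$bonds[!drop, , drop = FALSE]
      }
    }
    # new atoms from the product template
    ptGlobal <- integer(nrow(pt$atoms))
    for (q in seq_len(nrow(pt$atoms))) {
      if (ptMapped[q]) {
        key <- as.character(pt$atoms$map[q])
        if (is.na(mapTo[key]))
          stop("product map :", key, " absent from reactant side")
        ptGlobal[q] <- mapTo[[key]]
        # reaction-center bookkeeping: H recomputed unless pinned
        gg$atoms$hcount[ptGlobal[q]] <- pt$atoms$hcount[q]
        gg$atoms$charge[ptGlobal[q]] <- pt$atoms$charge[q]
      } else {
        gg$atoms[nrow(gg$atoms) + 1L, ] <- list(
          pt$atoms$elem[q], pt$atoms$arom[q], pt$atoms$charge[q],
          pt$atoms$hcount[q], 0L)
        ptGlobal[q] <- nrow(gg$atoms)
      }
    }
    if (nrow(pt$bonds)) {
      for (r in seq_len(nrow(pt$bonds))) {
        gg <- .gAddBond(gg, ptGlobal[pt$bonds$a1[r]],
                        ptGlobal[pt$bonds$a2[r]], pt$bonds$order[r])
      }
    }
    # remove leaving-group atoms, then fragments without product atoms
    deleteSet <- unique(deleteSet)
    keep <- setdiff(seq_len(nrow(gg$atoms)), deleteSet)
    remap <- integer(nrow(gg$atoms)); remap[keep] <- seq_along(keep)
    gg <- .gRemoveAtoms(gg, deleteSet)
    ptNew <- remap[ptGlobal]
    if (any(ptNew == 0L))
      stop("product template atom was deleted; inconsistent templates")
    comps <- .gComponents(gg)
    live <- comps[vapply(comps, function(cp) any(ptNew %in% cp), logical(1))]
    gg <- .gRemoveAtoms(gg, setdiff(seq_len(nrow(gg$atoms)),
                                    sort(unlist(live))))
    smi <- writeSmiles(gg)
    can <- canonicalSmiles(smi)
    if (is.na(can))
      stop("assembled product failed to canonicalize: ", smi)
    products <- c(products, can)
  }
  sort(unique(products))
}

.cartesianIndex <- function(lens, maxRows) {
  grids <- lapply(lens, seq_len)
  g <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  g <- as.matrix(g)
  if (nrow(g) > maxRows) g <- g[seq_len(maxRows), , drop = FALSE]
  g
}
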