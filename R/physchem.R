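# physchem: descriptors, hard property filters, traffic-light banding,
# PAINS substructure screening — the first-stage triage of the cascade.
#
# Descriptor conventions (fixed package-wide; chosen so that the two
# published reference binders of the WDR40 campaign reproduce their printed
# values exactly):
#   HBA  = Lipinski N+O atom count (sulfur never counts),
#   HBD  = number of hydrogens on N or O,
#   rotb = acyclic single bond between two non-terminal heavy atoms,
#          amide C-N excluded,
#   Fsp3 = fraction of carbons with only single, non-aromatic bonds.
# MW, logP (Crippen-type) and topological PSA come from OpenBabel.

# aromatic-marked bonds outside rings (e.g. unmarked biaryl bonds in
# canonical SMILES) are chemically single bonds
.normalizeAromaticBonds <- function(g) {
  if (!nrow(g$bonds)) return(g)
  ring <- .ringBondFlags(g)
  fix <- g$bonds$order == "ar" & !ring
  g$bonds$order[fix] <- "1"
  g
}

.graphCounts <- function(smiles) {
  ckey <- paste0("gc|", smiles)
  cached <- .ob_state[[ckey]]
  if (!is.null(cached)) return(cached)
  g <- .normalizeAromaticBonds(.parsedGraph(smiles))
  h <- .atomHcounts(g)
  heavy <- sum(g$atoms$elem != "H")
  hba <- sum(g$atoms$elem %in% c("N", "O"))
  hbd <- sum(h[g$atoms$elem %in% c("N", "O")])
  nC <- sum(g$atoms$elem == "C")
  deg <- integer(nrow(g$atoms))
  hasMulti <- logical(nrow(g$atoms))      # any double/triple bond on atom
  dblO <- logical(nrow(g$atoms))          # carbon with C=O (amide test)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[r]; a2 <- g$bonds$a2[r]
      deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
      if (g$bonds$order[r] %in% c("2", "3")) {
        hasMulti[c(a1, a2)] <- TRUE
        if (g$bonds$order[r] == "2") {
          if (g$atoms$elem[a1] == "C" && g$atoms$elem[a2] == "O") dblO[a1] <- TRUE
          if (g$atoms$elem[a2] == "C" && g$atoms$elem[a1] == "O") dblO[a2] <- TRUE
        }
      }
    }
  }
  sp3C <- sum(g$atoms$elem == "C" & !g$atoms$arom & !hasMulti)
  fsp3 <- if (nC > 0L) sp3C / nC else 0
  rotb <- 0L
  if (nrow(g$bonds)) {
    ring <- .ringBondFlags(g)
    for (r in seq_len(nrow(g$bonds))) {
      if (g$bonds$order[r] != "1" || ring[r]) next
      a1 <- g$bonds$a1[r]; a2 <- g$bonds$a2[r]
      if (deg[a1] < 2L || deg[a2] < 2L) next
      amide <- (g$atoms$elem[a1] == "C" && dblO[a1] &&
                  g$atoms$elem[a2] == "N") ||
               (g$atoms$elem[a2] == "C" && dblO[a2] &&
                  g$atoms$elem[a1] == "N")
      if (amide) next
      rotb <- rotb + 1L
    }
  }
  out <- list(heavy_atoms = as.integer(heavy), hba = as.integer(hba),
              hbd = as.integer(hbd), fsp3 = fsp3, rotb = as.integer(rotb))
  .ob_state[[ckey]] <- out
  out
}

#' Compute the physicochemical property profile of molecules
#'
#' Eight descriptors per molecule: molecular weight (Da), logP, H-bond
#' donors (H on N/O), H-bond acceptors (Lipinski N+O), rotatable bonds
#' (acyclic single bonds between non-terminal heavy atoms, amides
#' excluded), topological polar surface area (A^2), fraction of sp3
#' carbons, and heavy-atom count.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame, one row per input, columns `smiles`, `mw`, `logp`,
#'   `hbd`, `hba`, `rotb`, `psa`, `fsp3`, `heavy_atoms`.
#' @examples
#' computeProperties("c1ccccc1")  # benzene: hbd 0, hba 0, rotb 0, fsp3 0
#' @export
computeProperties <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- canonicalSmiles(smiles)
  if (anyNA(can))
    stop("unparsable SMILES: ",
         paste(smiles[is.na(can)], collapse = ", "))
  ob <- .obPropTable(smiles)
  counts <- lapply(can, .graphCounts)
  data.frame(
    smiles = smiles,
    mw = ob$MW,
    logp = ob$logP,
    hbd = vapply(counts, `[[`, integer(1), "hbd"),
    hba = vapply(counts, `[[`, integer(1), "hba"),
    rotb = vapply(counts, `[[`, integer(1), "rotb"),
    psa = ob$TPSA,
    fsp3 = vapply(counts, `[[`, numeric(1), "fsp3"),
    heavy_atoms = vapply(counts, `[[`, integer(1), "heavy_atoms"),
    stringsAsFactors = FALSE)
}

#' Traffic-light banding of a property profile
#'
#' Assigns each of logP, MW, PSA, rotatable bonds and Fsp3 a desirability
#' band of 0 (good), 1 or 2 (poor) and sums them.  Band edges follow the
#' first CACHE challenge scheme; boundaries are resolved half-open with the
#' worse band winning at an edge (logP band 1 is [3,4), exactly 4 scores 2;
#' MW band 1 is [400,500); PSA band 1 is [120,140); rotatable-bond rows are
#' 0-7 / 8-10 / >=11; Fsp3 scores 0 above 0.3, 1 in (0.2, 0.3], 2 at or
#' below 0.2).  The experimental K_D and solubility columns of the original
#' scheme are excluded from scoring and deliberately absent here.
#'
#' @param profile data.frame from [computeProperties()] (needs `logp`,
#'   `mw`, `psa`, `rotb`, `fsp3`).
#' @return data.frame with per-property bands `logp_tl`, `mw_tl`, `psa_tl`,
#'   `rotb_tl`, `fsp3_tl` and their sum `total`.
#' @export
assignTrafficLights <- function(profile) {
  band <- function(x, lo, hi) ifelse(x < lo, 0L, ifelse(x < hi, 1L, 2L))
  out <- data.frame(
    logp_tl = band(profile$logp, 3, 4),
    mw_tl = band(profile$mw, 400, 500),
    psa_tl = band(profile$psa, 120, 140),
    rotb_tl = ifelse(profile$rotb <= 7, 0L,
                     ifelse(profile$rotb <= 10, 1L, 2L)),
    fsp3_tl = ifelse(profile$fsp3 > 0.3, 0L,
                     ifelse(profile$fsp3 > 0.2, 1L, 2L)))
  out$total <- out$logp_tl + out$mw_tl + out$psa_tl + out$rotb_tl +
    out$fsp3_tl
  out
}

#' First-stage filter configuration
#'
#' Hard property bounds of the triage: MW 150-500 Da, logP -1 to 5,
#' rotatable bonds <= 10, H-bond donors <= 5, H-bond acceptors <= 12 in
#' round 1 and <= 10 in round 2; traffic-light total <= 2.  PSA and Fsp3
#' feed the traffic lights but are never hard cutoffs.
#'
#' @param round campaign round, 1 or 2 (selects the HBA bound).
#' @param tlMax maximum allowed traffic-light total (default 2; compounds
#'   exceeding it are removed).
#' @return list of bounds consumed by [hardPropertyFilter()] and
#'   [firstFilter()].
#' @export
filterConfig <- function(round = 1L, tlMax = 2L) {
  stopifnot(round %in% c(1L, 2L))
  list(round = as.integer(round),
       mw = c(150, 500), logp = c(-1, 5),
       rotbMax = 10L, hbdMax = 5L,
       hbaMax = if (round == 1L) 12L else 10L,
       tlMax = as.integer(tlMax))
}

#' Hard property filter with per-violation reasons
#'
#' @param profile data.frame from [computeProperties()].
#' @param config a [filterConfig()].
#' @return data.frame with `pass` and `reasons` (';'-joined bound
#'   violations; empty when passing).  PSA and Fsp3 never appear as
#'   reasons.
#' @export
hardPropertyFilter <- function(profile, config = filterConfig()) {
  reasons <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    r <- character(0)
    if (profile$mw[i] < config$mw[1]) r <- c(r, "mw<150")
    if (profile$mw[i] > config$mw[2]) r <- c(r, "mw>500")
    if (profile$logp[i] < config$logp[1]) r <- c(r, "logp<-1")
    if (profile$logp[i] > config$logp[2]) r <- c(r, "logp>5")
    if (profile$rotb[i] > config$rotbMax) r <- c(r, "rotb>10")
    if (profile$hbd[i] > config$hbdMax) r <- c(r, "hbd>5")
    if (profile$hba[i] > config$hbaMax)
      r <- c(r, paste0("hba>", config$hbaMax))
    reasons[[i]] <- r
  }
  data.frame(
    pass = lengths(reasons) == 0L,
    reasons = vapply(reasons, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
}

.painsCatalog <- function(catalogPath = NULL) {
  if (is.null(catalogPath))
    catalogPath <- system.file("extdata", "pains_patterns.tsv",
                               package = "evoscreen")
  if (!nzchar(catalogPath) || !file.exists(catalogPath))
    stop("PAINS catalog unavailable: ", catalogPath)
  lines <- readLines(catalogPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cat <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE)
  if (!all(c("name", "smarts") %in% names(cat)))
    stop("PAINS catalog needs columns: name, smarts")
  cat
}

#' Screen molecules for pan-assay interference (PAINS) substructures
#'
#' Matches every catalog pattern against each molecule and fails those with
#' at least one hit, reporting the matched pattern names.  The bundled
#' catalog covers the classic PAINS substructure classes (quinones,
#' catechols, rhodanines, hydrazone phenols, azo aryls, isothiazolones,
#' alkylidene barbiturates, ...); pass `catalogPath` to use a full
#' published list or a custom SMARTS blocklist in the same two-column TSV
#' format.
#'
#' @param smiles character vector of SMILES.
#' @param catalogPath optional path to a `name<TAB>smarts` catalog.
#' @return data.frame with `smiles`, `pass`, `matches` (';'-joined names).
#' @export
painsScreen <- function(smiles, catalogPath = NULL) {
  cat <- .painsCatalog(catalogPath)
  hits <- lapply(smiles, function(s) {
    if (is.na(canonicalSmiles(s))) stop("unparsable SMILES: ", s)
    m <- vapply(cat$smarts,
                function(p) length(.smartsMatch(s, p)) > 0L, logical(1))
    cat$name[m]
  })
  data.frame(
    smiles = smiles,
    pass = lengths(hits) == 0L,
    matches = vapply(hits, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
}

#' First filtering stage of the triage cascade
#'
#' A molecule survives iff it passes the hard property bounds AND its
#' traffic-light total does not exceed `config$tlMax` (a total of exactly
#' the bound is kept) AND it is PAINS-clean.  Every casualty carries the
#' stage that removed it, checked in that order.
#'
#' @param smiles character vector of SMILES.
#' @param config a [filterConfig()].
#' @param catalogPath optional PAINS catalog override.
#' @return list with `survivors` (character vector of SMILES) and `audit`
#'   (data.frame: smiles, descriptors, TL components, `stage` of rejection
#'   or `"pass"`, `detail`).
#' @export
firstFilter <- function(smiles, config = filterConfig(),
                        catalogPath = NULL) {
  if (length(smiles) == 0L)
    return(list(survivors = character(0), audit = data.frame()))
  prof <- computeProperties(smiles)
  tl <- assignTrafficLights(prof)
  hard <- hardPropertyFilter(prof, config)
  pains <- painsScreen(smiles, catalogPath)
  stage <- rep("pass", length(smiles))
  detail <- rep("", length(smiles))
  for (i in seq_along(smiles)) {
    if (!hard$pass[i]) {
      stage[i] <- "hard_filter"; detail[i] <- hard$reasons[i]
    } else if (tl$total[i] > config$tlMax) {
      stage[i] <- "traffic_light"
      detail[i] <- paste0("tl_total=", tl$total[i])
    } else if (!pains$pass[i]) {
      stage[i] <- "pains"; detail[i] <- pains$matches[i]
    }
  }
  audit <- cbind(prof, tl, stage = stage, detail = detail,
                 stringsAsFactors = FALSE)
  list(survivors = smiles[stage == "pass"], audit = audit)
}
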