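#' Identify ARVC-producing (obligate transmitter) dogs
#'
#' With very low penetrance, carriers of a dominant disease allele are rarely
#' diagnosed themselves; they reveal the allele through affected progeny.
#' A dog is called a transmitter when it is affected itself (it demonstrably
#' carries the allele) or when it has produced affected offspring in litters
#' with at least `min_mates` distinct mates, which excludes single-litter
#' coincidence.
#'
#' @param ped a [pedigree()]
#' @param min_mates minimum number of distinct co-parents of affected
#'   offspring required to call an unaffected parent a transmitter
#'   (default 2, the weakest reading of "several different mates")
#' @return data frame of class `transmitter_calls` with one row per affected
#'   dog and per parent of any affected dog: `id`, `n_affected_offspring`,
#'   `n_distinct_mates_with_affected`, `is_transmitter`, `basis`
#'   (`affected_self` / `multi_mate_producer` / `single_mate_producer`)
#' @export
identify_transmitters <- function(ped, min_mates = 2) {
  stopifnot(min_mates >= 1)
  df <- ped_df(ped)
  aff <- df[df$affection == "affected", , drop = FALSE]
  # one (parent, co-parent) record per affected child per recorded parent
  parent <- c(aff$sire, aff$dam)
  co <- c(aff$dam, aff$sire)
  keep <- !is.na(parent)
  parent <- parent[keep]
  co <- co[keep]
  co[is.na(co)] <- "<unknown>"
  if (length(parent)) {
    n_aff <- tapply(parent, parent, length)
    n_mates <- tapply(co, parent, function(x) length(unique(x)))
    par_ids <- names(n_aff)
  } else {
    n_aff <- n_mates <- integer(0)
    par_ids <- character(0)
  }
  self_aff <- df$affection[match(par_ids, df$id)] == "affected"
  basis <- ifelse(self_aff, "affected_self",
                  ifelse(n_mates >= min_mates, "multi_mate_producer",
                         "single_mate_producer"))
  out <- data.frame(
    id = par_ids,
    n_affected_offspring = as.integer(n_aff),
    n_distinct_mates_with_affected = as.integer(n_mates),
    is_transmitter = self_aff | n_mates >= min_mates,
    basis = basis, stringsAsFactors = FALSE)
  # affected dogs that are not already listed as producers
  rest <- setdiff(aff$id, par_ids)
  if (length(rest))
    out <- rbind(out, data.frame(
      id = rest, n_affected_offspring = 0L,
      n_distinct_mates_with_affected = 0L,
      is_transmitter = TRUE, basis = "affected_self",
      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("transmitter_calls", "data.frame")
  out
}

#' Trace transmitters to their founder sources and group them into lines
#'
#' Each transmitter is traced up through the pedigree along other
#' transmitters/affected dogs until a maximal carrier-evidence ancestor is
#' reached: a transmitter with no transmitting ancestor above it, or one
#' flagged as an import (imports are never traced further even when foreign
#' ancestors are recorded). These maximal dogs are the sources. Two sources
#' belong to the same line of descent when some transmitter descends from
#' both; lines are the connected components of that relation. Walking up
#' from each carrier-evidence dog, a parent that is the only at-risk side is
#' a forced conduit for the allele and is recorded as a bridge (inferred)
#' carrier — the "skipped generations" of a low-penetrance dominant. When
#' both parents are at risk (inbreeding within the line) the conduit cannot
#' be pinned down and no bridge is called.
#'
#' @param ped a [pedigree()]
#' @param transmitters result of [identify_transmitters()]
#' @return object of class `line_assignment`: list with
#'   `sources` (named list, line label -> source ids),
#'   `membership` (named list, id -> character vector of line labels; a dog
#'   carries a label iff a source of that line is the dog or one of its
#'   ancestors), and `bridges` (ids of inferred bridge carriers).
#' @export
trace_to_sources <- function(ped, transmitters) {
  df <- ped_df(ped)
  n <- nrow(df)
  ids <- df$id
  sire_i <- match(df$sire, ids)
  dam_i <- match(df$dam, ids)
  depth <- ped_depth(df)
  topo <- order(depth)                   # parents before children
  levels_up <- split(seq_len(n), depth)  # wave processing per generation
  is_evid <- ids %in% transmitters$id[transmitters$is_transmitter]

  # downward pass: does the dog have a carrier-evidence proper ancestor?
  has_evid_anc <- logical(n)
  parent_flag <- function(i, p_i, flags) {
    v <- logical(length(i))
    k <- !is.na(p_i)
    v[k] <- flags[p_i[k]]
    v
  }
  for (lev in levels_up) {
    has_evid_anc[lev] <-
      parent_flag(lev, sire_i[lev], is_evid | has_evid_anc) |
      parent_flag(lev, dam_i[lev], is_evid | has_evid_anc)
  }
  src_idx <- which(is_evid & (df$import | !has_evid_anc))
  sources <- ids[src_idx]

  # downward reachability: per-dog set of source indices (self included);
  # sets stay small in realistic pedigrees, so this is near-linear
  src_no <- integer(n)
  src_no[src_idx] <- seq_along(src_idx)
  reach <- vector("list", n)
  for (i in topo) {
    r <- if (src_no[i] > 0L) src_no[i] else integer(0)
    s <- sire_i[i]; d <- dam_i[i]
    if (!is.na(s) && length(reach[[s]])) r <- c(r, reach[[s]])
    if (!is.na(d) && length(reach[[d]])) r <- c(r, reach[[d]])
    reach[[i]] <- if (length(r) > 1L) unique(r) else r
  }

  # line grouping: union-find over sources sharing a descendant transmitter
  parent <- seq_along(src_idx)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in which(is_evid)) {
    s <- reach[[i]]
    if (length(s) > 1) for (k in 2:length(s)) {
      ra <- find(s[1]); rb <- find(s[k]); if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(src_idx), find, integer(1))
  comp <- split(sources, roots)
  first_pos <- vapply(comp, function(s) min(match(s, ids)), numeric(1))
  comp <- comp[order(first_pos)]          # stable labels by pedigree order
  labels <- sprintf("line%d", seq_along(comp))
  names(comp) <- labels
  comp_of_src <- integer(length(src_idx)) # source index -> line number
  for (k in seq_along(comp)) comp_of_src[match(comp[[k]], sources)] <- k

  membership <- lapply(reach, function(r) {
    if (!length(r)) character(0) else labels[unique(comp_of_src[r])]
  })
  names(membership) <- ids

  # bridges (inferred carriers): walk up from every carrier-evidence dog;
  # its disease allele came from one parent, so when exactly one parent is
  # at risk (has any source in its ancestry) that parent is a forced
  # conduit. A merely "sandwiched" ancestor is NOT enough - the allele can
  # flow through a co-parent - so both-sides-at-risk stops the walk (the
  # inbreeding confound). Recursion through established bridges is sound
  # because a bridge is itself a deduced carrier.
  at_risk_flag <- lengths(reach) > 0L
  known_carrier <- is_evid
  bridge <- logical(n)
  queue <- which(is_evid)
  while (length(queue)) {
    x <- queue[1]
    queue <- queue[-1]
    ps <- c(sire_i[x], dam_i[x])
    ps <- ps[!is.na(ps)]
    conduit <- ps[at_risk_flag[ps]]
    if (length(conduit) == 1L && !known_carrier[conduit]) {
      known_carrier[conduit] <- TRUE
      bridge[conduit] <- TRUE
      queue <- c(queue, conduit)
    }
  }
  bridges <- ids[bridge]

  structure(list(sources = comp, membership = membership, bridges = bridges),
            class = "line_assignment")
}

#' @export
print.line_assignment <- function(x, ...) {
  cat(sprintf("<line_assignment> %d line(s)\n", length(x$sources)))
  for (l in names(x$sources))
    cat(sprintf("  %s: sources {%s}\n", l, paste(x$sources[[l]], collapse = ", ")))
  cat(sprintf("  bridge carriers: %d\n", length(x$bridges)))
  invisible(x)
}

#' Classify dogs as at-risk or clear-by-pedigree
#'
#' A dog is at risk when a line source is the dog itself or one of its
#' ancestors; every other dog is clear by pedigree — the disease-free section
#' of the breed defined by exclusion. Affected dogs that come out clear are a
#' data inconsistency (the allele should only enter through the sources) and
#' are reported as warnings, never silently reclassified.
#'
#' @param ped a [pedigree()]
#' @param assignment a [trace_to_sources()] result
#' @return object of class `risk_class`: data frame `id`, `risk`
#'   (`at_risk` / `clear_by_pedigree`), `lines` (comma-joined labels), with
#'   attribute `warnings` (character vector of inconsistencies)
#' @export
classify_risk <- function(ped, assignment) {
  df <- ped_df(ped)
  memb <- assignment$membership[df$id]
  memb[vapply(memb, is.null, logical(1))] <- list(character(0))
  memb <- unname(memb)
  n_lab <- lengths(memb)
  risk <- ifelse(n_lab > 0, "at_risk", "clear_by_pedigree")
  out <- data.frame(id = df$id, risk = risk,
                    lines = vapply(memb, paste, character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  bad <- df$affection == "affected" & risk == "clear_by_pedigree"
  warns <- if (any(bad))
    sprintf("affected dog '%s' is clear-by-pedigree: no recorded descent from any source",
            df$id[bad]) else character(0)
  attr(out, "warnings") <- warns
  class(out) <- c("risk_class", "data.frame")
  out
}

#' Summaries bearing on the mode of inheritance
#'
#' Compiles the descriptive evidence used to argue a single-gene autosomal
#' dominant mode: how many affected dogs have exactly one at-risk parental
#' side (dominant-compatible, the outcross pattern) versus both sides at risk
#' (compatible with recessivity only through inbreeding), the sex ratio among
#' affected dogs, and per-litter affected counts.
#'
#' @param ped a [pedigree()]
#' @param assignment a [trace_to_sources()] result
#' @return list with `parental_sides` (counts: single_side, both_sides,
#'   no_side, missing_parent), `sex_counts`, `prop_male_affected`, and
#'   `litter_affected` (table of affected-per-litter counts over litters with
#'   at least one affected)
#' @export
inheritance_mode_report <- function(ped, assignment) {
  df <- ped_df(ped)
  risk <- classify_risk(ped, assignment)
  rmap <- stats::setNames(risk$risk, risk$id)
  aff <- df[df$affection == "affected", , drop = FALSE]
  side <- vapply(seq_len(nrow(aff)), function(i) {
    s <- aff$sire[i]; d <- aff$dam[i]
    if (is.na(s) || is.na(d)) return("missing_parent")
    sr <- rmap[[s]] == "at_risk"; dr <- rmap[[d]] == "at_risk"
    if (sr && dr) "both_sides" else if (sr || dr) "single_side" else "no_side"
  }, character(1))
  lt <- litters(ped)
  lt_aff <- lt$n_affected[lt$n_affected > 0]
  list(
    parental_sides = table(factor(side, levels = c("single_side", "both_sides",
                                                   "no_side", "missing_parent"))),
    sex_counts = table(factor(aff$sex, levels = SEX_LEVELS)),
    prop_male_affected = if (nrow(aff)) mean(aff$sex == "male") else NA_real_,
    n_affected = nrow(aff),
    litter_affected = if (length(lt_aff)) table(lt_aff) else table(integer(0))
  )
}
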