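#' Assign disease-locus carrier status from pedigree logic
#'
#' Affected dogs are obligate carriers (dominant model, no phenocopies).
#' Unaffected transmitters and bridge ancestors connecting carrier-evidence
#' dogs are inferred carriers. Clear-by-pedigree dogs are clear; everyone
#' else is unknown. The marker genotype never vetoes carrier status: an
#' affected wild-type dog is still an obligate carrier — that is precisely
#' the recombination evidence.
#'
#' @param ped a [pedigree()]
#' @param risk a [classify_risk()] result
#' @param transmitters an [identify_transmitters()] result
#' @param assignment optional [trace_to_sources()] result supplying bridge
#'   carriers (recomputed from `transmitters` when omitted)
#' @return data frame of class `carrier_assignment`: `id`, `status`
#'   (`obligate_carrier` / `inferred_carrier` / `clear` / `unknown`),
#'   `provenance` (`affected` / `transmitter` / `bridge` /
#'   `clear_by_pedigree` / `none`)
#' @export
assign_carriers <- function(ped, risk, transmitters, assignment = NULL) {
  df <- ped_df(ped)
  if (is.null(assignment)) assignment <- trace_to_sources(ped, transmitters)
  status <- rep("unknown", nrow(df))
  prov <- rep("none", nrow(df))
  rmap <- stats::setNames(risk$risk, risk$id)
  clear <- rmap[df$id] == "clear_by_pedigree"
  status[clear] <- "clear"
  prov[clear] <- "clear_by_pedigree"
  tr <- transmitters$id[transmitters$is_transmitter]
  br <- df$id %in% assignment$bridges
  status[br] <- "inferred_carrier"; prov[br] <- "bridge"
  is_tr <- df$id %in% tr
  status[is_tr] <- "inferred_carrier"; prov[is_tr] <- "transmitter"
  aff <- df$affection == "affected"
  status[aff] <- "obligate_carrier"; prov[aff] <- "affected"
  out <- data.frame(id = df$id, status = status, provenance = prov,
                    stringsAsFactors = FALSE)
  class(out) <- c("carrier_assignment", "data.frame")
  out
}

#' Assign marker-disease phase (coupling vs repulsion) to carriers
#'
#' The homozygosity rule: a carrier homozygous for the marker mutation must
#' hold the disease allele on a mutant-marker chromosome (coupling, certain);
#' a wild-type carrier must hold it on a wild-type chromosome (repulsion,
#' certain). Marker heterozygotes are intrinsically ambiguous — either
#' chromosome could carry the disease allele — unless phase propagates from a
#' parent: when a carrier child's only carrier parent is marker-homozygous
#' with certain phase, the marker allele that parent transmitted is fixed
#' regardless of any crossover, so the child's disease-bearing haplotype is
#' forced and the parent's phase is inherited with certainty grade
#' `propagated`. Propagation never overwrites a certain call and is not
#' attempted when both parents are carriers (the disease allele's origin
#' would be ambiguous).
#'
#' @param ped a [pedigree()]
#' @param carriers an [assign_carriers()] result
#' @return data frame of class `phase_calls`: `id`, `phase` (`coupling` /
#'   `repulsion` / `ambiguous`), `certainty` (`certain_by_homozygosity` /
#'   `propagated` / `none`), `from_parent` (id of the propagating parent or
#'   `NA`)
#' @export
assign_phase <- function(ped, carriers) {
  df <- ped_df(ped)
  cmap <- stats::setNames(carriers$status, carriers$id)
  is_carrier <- cmap[df$id] %in% c("obligate_carrier", "inferred_carrier")
  phase <- rep(NA_character_, nrow(df))
  cert <- rep(NA_character_, nrow(df))
  from <- rep(NA_character_, nrow(df))
  phase[is_carrier] <- "ambiguous"
  cert[is_carrier] <- "none"
  hom <- is_carrier & df$strn == "HOM"
  wt <- is_carrier & df$strn == "WT"
  phase[hom] <- "coupling"; cert[hom] <- "certain_by_homozygosity"
  phase[wt] <- "repulsion"; cert[wt] <- "certain_by_homozygosity"

  # single-step forced propagation from marker-homozygous certain parents
  idx <- ped_index(ped)
  het_amb <- which(is_carrier & df$strn == "HET" & phase == "ambiguous")
  for (i in het_amb) {
    ps <- c(df$sire[i], df$dam[i])
    ps <- ps[!is.na(ps)]
    if (!length(ps)) next
    pc <- ps[cmap[ps] %in% c("obligate_carrier", "inferred_carrier")]
    if (length(pc) != 1) next            # 0 or 2 carrier parents: ambiguous
    j <- idx[[pc]]
    if (cert[j] == "certain_by_homozygosity" && df$strn[j] %in% c("HOM", "WT")) {
      phase[i] <- phase[j]
      cert[i] <- "propagated"
      from[i] <- pc
    }
  }
  stopifnot(all(phase[hom] == "coupling"), all(phase[wt] == "repulsion"))
  out <- data.frame(id = df$id, phase = phase, certainty = cert,
                    from_parent = from, stringsAsFactors = FALSE)
  out <- out[is_carrier, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phase_calls", "data.frame")
  out
}

#' Detect phase-switch (recombination) events between carrier generations
#'
#' Scans every carrier-parent to carrier-child meiosis with both phases
#' known; a phase mismatch is a recombination event on that meiosis.
#' Grades: `certain` when the child's phase is certain by homozygosity and
#' the parent's phase is either forced by propagation from a marker-
#' homozygous parent while the parent is itself marker-heterozygous (the only
#' configuration in which a crossover is observable), or certain by
#' homozygosity on both endpoints (which Mendelian-consistent genotypes
#' cannot produce, so it flags recombination upstream or a data error);
#' every other known-phase mismatch is graded `possible`. Additionally,
#' certain-phase carriers separated from their nearest phase-known carrier
#' ancestor by more than one meiosis (untyped bridge dogs in between) yield a
#' `possible` event attached to the whole path.
#'
#' @param ped a [pedigree()]
#' @param phases an [assign_phase()] result
#' @param carriers the matching [assign_carriers()] result
#' @return data frame of class `recombination_events`: `parent_id`,
#'   `child_id`, `parent_phase`, `child_phase`, `grade`
#'   (`certain` / `possible`), `n_meioses` (1 for single-meiosis events,
#'   larger for path events), `path` (comma-joined ids for path events)
#' @export
detect_recombination <- function(ped, phases, carriers) {
  df <- ped_df(ped)
  cmap <- stats::setNames(carriers$status, carriers$id)
  pmap <- stats::setNames(phases$phase, phases$id)
  certmap <- stats::setNames(phases$certainty, phases$id)
  strn <- stats::setNames(df$strn, df$id)
  is_carrier <- function(x) !is.na(cmap[x]) &
    cmap[x] %in% c("obligate_carrier", "inferred_carrier")

  events <- list()
  add <- function(p, c, gp, gc, grade, n_meioses = 1L, path = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      parent_id = p, child_id = c, parent_phase = gp, child_phase = gc,
      grade = grade, n_meioses = n_meioses, path = path,
      stringsAsFactors = FALSE)
  }

  kids <- df[!is.na(df$sire) | !is.na(df$dam), , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    ch <- kids$id[i]
    if (!is_carrier(ch)) next
    if (is.na(pmap[ch]) || pmap[ch] == "ambiguous") next
    pars <- c(kids$sire[i], kids$dam[i])
    n_carrier_par <- sum(vapply(pars, function(p)
      !is.na(p) && is_carrier(p), logical(1)))
    for (pa in pars) {
      if (is.na(pa) || !is_carrier(pa)) next
      if (is.na(pmap[pa]) || pmap[pa] == "ambiguous") next
      if (pmap[pa] == pmap[ch]) next
      both_hom_certain <- certmap[pa] == "certain_by_homozygosity" &&
        certmap[ch] == "certain_by_homozygosity"
      forced_het_parent <- strn[pa] == "HET" &&
        certmap[pa] == "propagated" &&
        certmap[ch] == "certain_by_homozygosity"
      # with two carrier parents the child's disease allele could come from
      # either, so the meiosis cannot be pinned down: downgrade to possible
      grade <- if ((both_hom_certain || forced_het_parent) &&
                     n_carrier_par == 1L) "certain" else "possible"
      add(pa, ch, unname(pmap[pa]), unname(pmap[ch]), grade)
    }
  }

  # path events: certain child whose nearest phase-known carrier ancestor is
  # more than one meiosis up a chain of phase-unknown carriers
  idx <- ped_index(ped)
  certain_ids <- phases$id[phases$certainty == "certain_by_homozygosity"]
  for (ch in certain_ids) {
    for (side in c("sire", "dam")) {
      path <- ch
      cur <- df[[side]][idx[[ch]]]
      hops <- 0L
      while (!is.na(cur) && is_carrier(cur) && hops < 25L) {
        hops <- hops + 1L
        path <- c(path, cur)
        known <- !is.na(pmap[cur]) && pmap[cur] != "ambiguous"
        if (known) {
          if (hops > 1L && pmap[cur] != pmap[ch])
            add(cur, ch, unname(pmap[cur]), unname(pmap[ch]), "possible",
                n_meioses = hops, path = paste(rev(path), collapse = ","))
          break
        }
        # continue through the phase-unknown carrier's single carrier parent
        ps <- c(df$sire[idx[[cur]]], df$dam[idx[[cur]]])
        ps <- ps[!is.na(ps) & is_carrier(ps)]
        if (length(ps) != 1) break
        cur <- ps
      }
    }
  }

  out <- if (length(events)) do.call(rbind, events) else
    data.frame(parent_id = character(0), child_id = character(0),
               parent_phase = character(0), child_phase = character(0),
               grade = character(0), n_meioses = integer(0),
               path = character(0))
  rownames(out) <- NULL
  class(out) <- c("recombination_events", "data.frame")
  out
}

#' Meioses informative for recombination detection
#'
#' A meiosis is informative when the transmitting parent is a known carrier,
#' marker-heterozygous, with known (certain or forced) phase, and the child
#' is a known carrier whose own phase is certain by homozygosity. Certain
#' recombination events divided by informative meioses estimates the
#' recombination fraction when co-parents transmit marker alleles
#' equiprobably (see the methods vignette for the derivation).
#'
#' @param ped a [pedigree()]
#' @param phases an [assign_phase()] result
#' @param carriers an [assign_carriers()] result
#' @return data frame `parent_id`, `child_id`, one row per informative meiosis
#' @export
informative_meioses <- function(ped, phases, carriers) {
  df <- ped_df(ped)
  cmap <- stats::setNames(carriers$status, carriers$id)
  pmap <- stats::setNames(phases$phase, phases$id)
  certmap <- stats::setNames(phases$certainty, phases$id)
  strn <- stats::setNames(df$strn, df$id)
  carrier <- function(x) !is.na(cmap[x]) &
    cmap[x] %in% c("obligate_carrier", "inferred_carrier")
  rows <- list()
  kids <- df[!is.na(df$sire) | !is.na(df$dam), , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    ch <- kids$id[i]
    if (!carrier(ch)) next
    if (is.na(certmap[ch]) || certmap[ch] != "certain_by_homozygosity") next
    pars <- c(kids$sire[i], kids$dam[i])
    if (sum(vapply(pars, function(p)
      !is.na(p) && carrier(p), logical(1))) != 1L) next
    for (pa in pars) {
      if (is.na(pa) || !carrier(pa)) next
      if (strn[pa] != "HET") next
      if (is.na(pmap[pa]) || pmap[pa] == "ambiguous") next
      rows[[length(rows) + 1L]] <- data.frame(parent_id = pa, child_id = ch,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = character(0), child_id = character(0))
  rownames(out) <- NULL
  out
}

#' Genotype count tables by group
#'
#' Builds the marker genotype (HOM/HET/WT) count table for the standard
#' rosters — per-line affected cases (dogs whose line membership is exactly
#' that one line), and normals by pedigree (unaffected, clear-by-pedigree) —
#' plus any user-defined groups carried in the phenotype `group` column.
#' Dogs with a user group are excluded from the standard rosters (they come
#' from external studies without full pedigree records); untyped dogs never
#' block table construction and are excluded with a logged count.
#'
#' @param ped a [pedigree()]
#' @param lines a [trace_to_sources()] result
#' @param risk a [classify_risk()] result
#' @return data frame of class `genotype_tables` with rownames naming the
#'   groups and columns `HOM`, `HET`, `WT`, `Total`; attribute `n_untyped`
#'   counts typed-roster dogs dropped for missing genotype
#' @export
genotype_tables_by_group <- function(ped, lines, risk) {
  df <- ped_df(ped)
  memb <- lines$membership[df$id]
  rmap <- stats::setNames(risk$risk, risk$id)
  grouped <- !is.na(df$group)
  typed <- df$strn %in% c("HOM", "HET", "WT")

  count_row <- function(sel) {
    g <- df$strn[sel & typed]
    c(HOM = sum(g == "HOM"), HET = sum(g == "HET"), WT = sum(g == "WT"),
      Total = length(g))
  }
  rows <- list()
  n_untyped <- 0L
  for (l in names(lines$sources)) {
    sel <- df$affection == "affected" & !grouped &
      vapply(memb, function(m) identical(m, l), logical(1))
    rows[[paste0(l, " cases")]] <- count_row(sel)
    n_untyped <- n_untyped + sum(sel & !typed)
  }
  seln <- df$affection == "unaffected" & !grouped &
    rmap[df$id] == "clear_by_pedigree"
  rows[["normal (by pedigree)"]] <- count_row(seln)
  n_untyped <- n_untyped + sum(seln & !typed)
  for (g in unique(stats::na.omit(df$group))) {
    sel <- !is.na(df$group) & df$group == g
    rows[[g]] <- count_row(sel)
    n_untyped <- n_untyped + sum(sel & !typed)
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "n_untyped") <- n_untyped
  class(out) <- c("genotype_tables", "data.frame")
  out
}
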