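#' Simulator configuration
#'
#' Defines the stated world of the gene-dropping simulator: a show-dog
#' population with discrete generations, popular-sire matings, large litters,
#' a dominant disease allele introduced by a small number of imported male
#' founders, and a linked biallelic marker at recombination fraction `theta`.
#' Defaults follow the published Boxer ARVC setting where one exists (mean
#' litter size 6.5, median onset 7 years, near-equal sexes, a handful of
#' import carriers); the remainder are documented modelling choices (see the
#' methods vignette).
#'
#' @param seed integer RNG seed used by [simulate_pedigree()]
#' @param n_founders number of founder dogs
#' @param n_import_carriers founder males carrying one disease allele
#' @param generations number of offspring generations to drop
#' @param mean_litter_size Poisson mean litter size (truncated at 1)
#' @param theta marker-disease recombination fraction in `[0, 0.5]`
#' @param penetrance probability a carrier ever expresses disease
#' @param marker_mut_freq founder frequency of the marker mutation in the
#'   non-import population (default 0.42, loosely matched to the normal rows
#'   of the published genotype table; configurable, not a population claim)
#' @param onset_median_years median age of diagnosis (log-normal median)
#' @param onset_sigma log-scale spread of onset age (default 0.55 spans
#'   roughly 2.3-21 years for the central 95 per cent)
#' @param censor_age_years follow-up horizon: a carrier whose onset falls
#'   beyond it is recorded unaffected
#' @param prop_genotyped fraction of dogs with an observed marker genotype
#' @param import_phase phase of the import carriers' disease haplotype:
#'   `"coupling"` (disease allele on a mutant-marker chromosome),
#'   `"repulsion"`, or `"per_import"` (alternating)
#' @param mates_per_sire dams per sire under the popular-sire scheme
#' @param prop_female_founders fraction of founders that are female
#' @param avoid_carrier_matings steer true-carrier sires toward non-carrier
#'   dams and spread carrier dams one-per-sire (carrier x carrier matings are
#'   rare in the field data and their homozygote fate is not modelled; the
#'   one-per-sire cap also keeps the multi-mate transmitter rule sound)
#' @param avoid_kin_matings forbid matings between dogs sharing a parent
#'   (half/full sibs). Show breeding often inbreeds, so the default is
#'   `FALSE`; the detection-rate calibration world turns it on because
#'   half-sib mates are enriched in their lineage's forced marker allele,
#'   which tilts the co-parent transmission probability away from one half
#' @param imports_affected record import carriers as affected regardless of
#'   penetrance and censoring, modelling founders known to come from the
#'   original disease stock; this makes every source identifiable, the
#'   regime in which the rule-based classification is provably sound
#' @param severity_probs,severity_probs_hom category-1/2/3 sampling weights
#'   for affected dogs that are non-HOM / HOM at the marker (the HOM-biased
#'   weighting reflects the reported association of marker homozygosity with
#'   more severe disease)
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 60L,
                       n_import_carriers = 2L,
                       generations = 4L,
                       mean_litter_size = 6.5,
                       theta = 0.1,
                       penetrance = 0.25,
                       marker_mut_freq = 0.42,
                       onset_median_years = 7,
                       onset_sigma = 0.55,
                       censor_age_years = 10,
                       prop_genotyped = 0.7,
                       import_phase = c("coupling", "repulsion", "per_import"),
                       mates_per_sire = 3L,
                       prop_female_founders = 0.5,
                       avoid_carrier_matings = TRUE,
                       avoid_kin_matings = FALSE,
                       imports_affected = FALSE,
                       severity_probs = c(0.5, 0.3, 0.2),
                       severity_probs_hom = c(0.2, 0.3, 0.5)) {
  import_phase <- match.arg(import_phase)
  cfg <- list(seed = as.integer(seed), n_founders = as.integer(n_founders),
              n_import_carriers = as.integer(n_import_carriers),
              generations = as.integer(generations),
              mean_litter_size = mean_litter_size, theta = theta,
              penetrance = penetrance, marker_mut_freq = marker_mut_freq,
              onset_median_years = onset_median_years,
              onset_sigma = onset_sigma,
              censor_age_years = censor_age_years,
              prop_genotyped = prop_genotyped, import_phase = import_phase,
              mates_per_sire = as.integer(mates_per_sire),
              prop_female_founders = prop_female_founders,
              avoid_carrier_matings = isTRUE(avoid_carrier_matings),
              avoid_kin_matings = isTRUE(avoid_kin_matings),
              imports_affected = isTRUE(imports_affected),
              severity_probs = severity_probs,
              severity_probs_hom = severity_probs_hom)
  stopifnot(cfg$n_founders >= 2, cfg$generations >= 1,
            cfg$mean_litter_size > 0,
            cfg$theta >= 0, cfg$theta <= 0.5,
            cfg$penetrance >= 0, cfg$penetrance <= 1,
            cfg$marker_mut_freq >= 0, cfg$marker_mut_freq <= 1,
            cfg$prop_genotyped >= 0, cfg$prop_genotyped <= 1,
            cfg$onset_median_years > 0, cfg$onset_sigma > 0,
            cfg$censor_age_years > 0, cfg$mates_per_sire >= 1,
            cfg$prop_female_founders > 0, cfg$prop_female_founders < 1)
  if (cfg$n_import_carriers > floor(cfg$n_founders * (1 - cfg$prop_female_founders)))
    stop("n_import_carriers exceeds the number of male founders")
  class(cfg) <- "sim_config"
  cfg
}

# truncated-at-1 Poisson litter sizes
rlitter <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

#' Gene-dropping pedigree simulation
#'
#' Drops a two-locus haplotype (biallelic marker, dominant disease allele)
#' down a generated multi-generation pedigree. Founders receive marker
#' genotypes at Hardy-Weinberg proportions; import carriers additionally
#' carry one disease allele with the configured phase. Each generation every
#' female is mated once under a popular-sire scheme; litter sizes are
#' truncated Poisson. Per gamete a parental haplotype is chosen uniformly
#' and a crossover exchanges the two loci with probability `theta`. Carriers
#' express disease with probability `penetrance`; onset age is log-normal and
#' observed only below the censoring horizon. A fraction `prop_genotyped`
#' of dogs have their marker genotype recorded.
#'
#' @param config a [sim_config()]
#' @return list of class `arvc_sim` with elements
#'   `pedigree` (a [pedigree()] carrying observed phenotypes/genotypes),
#'   `pheno` (phenotype data frame as written by [write_pedigree()]), and
#'   `truth` (ground truth: `dogs` with true haplotypes `m1,d1,m2,d2`,
#'   carrier flags, expression flags and true onset ages; `meioses` with
#'   one row per gamete: `child`, `parent`, `crossover`,
#'   `parent_marker_het`, `parent_carrier`, `founders` ids)
#' @export
simulate_pedigree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders
  n_fem <- round(nf * config$prop_female_founders)
  n_mal <- nf - n_fem

  id <- sprintf("G0_%04d", seq_len(nf))
  sex <- c(rep("male", n_mal), rep("female", n_fem))
  m1 <- stats::rbinom(nf, 1, config$marker_mut_freq)
  m2 <- stats::rbinom(nf, 1, config$marker_mut_freq)
  d1 <- integer(nf)
  d2 <- integer(nf)
  import <- logical(nf)
  if (config$n_import_carriers > 0) {
    imp <- seq_len(config$n_import_carriers)   # first males are the imports
    import[imp] <- TRUE
    ph <- switch(config$import_phase,
                 coupling = rep("coupling", length(imp)),
                 repulsion = rep("repulsion", length(imp)),
                 per_import = rep(c("coupling", "repulsion"),
                                  length.out = length(imp)))
    m1[imp] <- ifelse(ph == "coupling", 1L, 0L)
    d1[imp] <- 1L
  }
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  gen <- rep(0L, nf)
  litter <- rep(NA_character_, nf)

  mei <- list()
  for (g in seq_len(config$generations)) {
    prev <- which(gen == g - 1L)
    dams_i <- prev[sex[prev] == "female"]
    males_i <- prev[sex[prev] == "male"]
    if (!length(dams_i) || !length(males_i)) break
    n_sires <- min(length(males_i),
                   max(1L, ceiling(length(dams_i) / config$mates_per_sire)))
    # popular-sire selection; carrier males get priority, mirroring how a
    # handful of much-used stud dogs historically spread the allele
    carrier_m <- (d1[males_i] + d2[males_i]) > 0
    sires_i <- males_i[order(!carrier_m, stats::runif(length(males_i)))][seq_len(n_sires)]
    # dam -> sire assignment. Carrier dams are spread one-per-sire
    # (non-carrier sires first): a non-carrier stud then never accumulates
    # two carrier mates, so the "affected progeny with several mates" rule
    # cannot fire on a non-carrier, and carrier x carrier matings stay rare
    dams_i <- sample(dams_i)
    if (config$avoid_carrier_matings) {
      carrier <- (d1 + d2) > 0
      cd <- dams_i[carrier[dams_i]]
      nd <- dams_i[!carrier[dams_i]]
      ns <- sires_i[!carrier[sires_i]]
      cs <- sires_i[carrier[sires_i]]
      base <- c(ns, cs)                  # one carrier dam per distinct sire
      sire_cd <- if (length(cd) <= length(base)) base[seq_along(cd)]
        else c(base, rep(if (length(cs)) cs else base,  # overflow: carrier sires
                         length.out = length(cd) - length(base)))
      dams_i <- c(cd, nd)
      sire_for_dam <- c(sire_cd,
                        sample(rep(sires_i, length.out = length(nd))))
    } else {
      sire_for_dam <- rep(sires_i, length.out = length(dams_i))
    }
    if (config$avoid_kin_matings) {
      carrier <- (d1 + d2) > 0
      kin <- function(a, b) {           # share a recorded parent?
        (!is.na(sire[a]) & !is.na(sire[b]) & sire[a] == sire[b]) |
          (!is.na(dam[a]) & !is.na(dam[b]) & dam[a] == dam[b])
      }
      for (pass in 1:3) {
        bad <- which(kin(dams_i, sire_for_dam))
        if (!length(bad)) break
        for (b in bad) {
          # swap sires with a dam of the same carrier status, keeping both
          # new pairs kin-free (preserves the one-carrier-dam-per-sire cap)
          cand <- which(carrier[dams_i] == carrier[dams_i[b]])
          cand <- cand[cand != b]
          ok <- cand[!kin(dams_i[b], sire_for_dam[cand]) &
                       !kin(dams_i[cand], sire_for_dam[b])]
          if (length(ok)) {
            j <- ok[1]
            tmp <- sire_for_dam[b]
            sire_for_dam[b] <- sire_for_dam[j]
            sire_for_dam[j] <- tmp
          }
        }
      }
    }
    lsz <- rlitter(length(dams_i), config$mean_litter_size)
    n_off <- sum(lsz)
    if (n_off == 0) break
    f_i <- rep(sire_for_dam, lsz)          # father index per offspring
    mo_i <- rep(dams_i, lsz)               # mother index per offspring
    lit <- rep(sprintf("L%d_%03d", g, seq_along(dams_i)), lsz)

    gamete <- function(p_i) {
      hsel <- sample(1:2, length(p_i), replace = TRUE)
      cross <- stats::runif(length(p_i)) < config$theta
      tm <- ifelse(hsel == 1L, m1[p_i], m2[p_i])
      dsel <- ifelse(cross, 3L - hsel, hsel)
      td <- ifelse(dsel == 1L, d1[p_i], d2[p_i])
      list(m = tm, d = td, cross = cross)
    }
    gp <- gamete(f_i)
    gm <- gamete(mo_i)

    new_id <- sprintf("G%d_%04d", g, seq_len(n_off))
    mei[[g]] <- data.frame(
      child = c(new_id, new_id),
      parent = c(id[f_i], id[mo_i]),
      crossover = c(gp$cross, gm$cross),
      parent_marker_het = c(m1[f_i] != m2[f_i], m1[mo_i] != m2[mo_i]),
      parent_carrier = c((d1[f_i] + d2[f_i]) > 0, (d1[mo_i] + d2[mo_i]) > 0),
      stringsAsFactors = FALSE)

    id <- c(id, new_id)
    sex <- c(sex, sample(c("male", "female"), n_off, replace = TRUE))
    sire <- c(sire, id[f_i])
    dam <- c(dam, id[mo_i])
    gen <- c(gen, rep(g, n_off))
    litter <- c(litter, lit)
    m1 <- c(m1, gp$m); d1 <- c(d1, gp$d)
    m2 <- c(m2, gm$m); d2 <- c(d2, gm$d)
    import <- c(import, logical(n_off))
  }

  n <- length(id)
  carrier <- (d1 + d2) > 0
  express <- carrier & stats::runif(n) < config$penetrance
  true_onset <- stats::rlnorm(n, meanlog = log(config$onset_median_years),
                              sdlog = config$onset_sigma)
  affected <- express & true_onset < config$censor_age_years
  if (config$imports_affected) {
    # imports are historical cases from the original disease stock: their
    # affection is known regardless of penetrance or follow-up
    affected[import & carrier] <- TRUE
    express[import & carrier] <- TRUE
  }
  typed <- stats::runif(n) < config$prop_genotyped
  nmut <- m1 + m2
  strn_true <- c("WT", "HET", "HOM")[nmut + 1L]
  strn <- ifelse(typed, strn_true, "untyped")
  severity <- rep("unassessed", n)
  cats <- c("cat1", "cat2", "cat3")
  aff_hom <- affected & nmut == 2L
  aff_oth <- affected & nmut < 2L
  if (any(aff_hom))
    severity[aff_hom] <- sample(cats, sum(aff_hom), replace = TRUE,
                                prob = config$severity_probs_hom)
  if (any(aff_oth))
    severity[aff_oth] <- sample(cats, sum(aff_oth), replace = TRUE,
                                prob = config$severity_probs)
  df <- data.frame(
    id = id, sire = sire, dam = dam, sex = sex,
    affection = ifelse(affected, "affected", "unaffected"),
    onset_age = ifelse(affected, round(true_onset, 2), NA_real_),
    severity = severity, strn = strn, litter = litter,
    import = import, group = NA_character_, stringsAsFactors = FALSE)
  ped <- pedigree(df)
  truth <- list(
    dogs = data.frame(id = id, m1 = m1, d1 = d1, m2 = m2, d2 = d2,
                      carrier = carrier, express = express,
                      true_onset = true_onset, strn_true = strn_true,
                      generation = gen, stringsAsFactors = FALSE),
    meioses = if (length(mei)) do.call(rbind, mei) else
      data.frame(child = character(0), parent = character(0),
                 crossover = logical(0), parent_marker_het = logical(0),
                 parent_carrier = logical(0)),
    founders = id[gen == 0L])
  structure(list(pedigree = ped,
                 pheno = df[, c("id", "affection", "onset_age", "severity",
                                "strn", "litter", "import", "group")],
                 truth = truth, config = config),
            class = "arvc_sim")
}

#' @export
print.arvc_sim <- function(x, ...) {
  cat(sprintf("<arvc_sim> %d dogs over %d generations; %d true carriers, %d affected\n",
              n_individuals(x$pedigree), max(x$truth$dogs$generation),
              sum(x$truth$dogs$carrier),
              sum(x$pedigree$individuals$affection == "affected")))
  invisible(x)
}

#' Count crossover meioses in simulator ground truth
#'
#' @param truth the `truth` element of a [simulate_pedigree()] result
#' @param informative_only restrict to meioses whose transmitting parent is
#'   marker-heterozygous and a disease carrier (the only meioses in which a
#'   crossover is in principle observable)
#' @return integer count; `attr(, "n_meioses")` holds the denominator
#' @export
truth_recombination_count <- function(truth, informative_only = FALSE) {
  m <- truth$meioses
  if (informative_only)
    m <- m[m$parent_marker_het & m$parent_carrier, , drop = FALSE]
  structure(sum(m$crossover), n_meioses = nrow(m))
}

#' Deterministic fixture reproducing the published genotype table
#'
#' Builds a minimal plausible pedigree whose rosters reproduce, exactly, the
#' five published rows of marker genotype counts: line-1 cases (10, 13, 0),
#' line-2 cases (6, 8, 10), normals by pedigree (5, 16, 10), Holter-tested
#' cases (5, 14, 7) and Holter-tested normals (6, 3, 4). Topology: one
#' line-1 source import (A) whose affected offspring are the line-1 cases;
#' two line-2 source imports (G, H) whose chains join through a bridge
#' granddaughter and an unaffected transmitter; 31 unrelated clear founders
#' as the normals; the two Holter-tested groups are external-study dogs
#' carried as user-defined groups (the cases descend from their own import
#' so the fixture stays internally consistent). Intermediate mates are left
#' untyped so they never enter the counts.
#'
#' @return list with `pedigree` (a validated [pedigree()]) and `pheno`
#'   (its phenotype table)
#' @export
make_table1_fixture <- function() {
  rows <- list()
  add <- function(id, sire = NA, dam = NA, sex, aff = "unaffected",
                  strn = "untyped", onset = NA_real_, severity = "unassessed",
                  import = FALSE, group = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex, affection = aff,
      onset_age = onset, severity = severity, strn = strn,
      litter = NA_character_, import = import, group = group,
      stringsAsFactors = FALSE)
  }
  kids <- function(prefix, n, sire, dams, strn_counts, aff = "affected",
                   group = NA_character_) {
    # strn_counts: named c(HOM=, HET=, WT=) summing to n
    g <- rep(names(strn_counts), strn_counts)
    dam_seq <- rep(dams, length.out = n)
    for (k in seq_len(n))
      add(sprintf("%s%02d", prefix, k), sire = sire, dam = dam_seq[k],
          sex = if (k %% 2) "male" else "female", aff = aff, strn = g[k],
          onset = if (aff == "affected") 7 else NA_real_,
          group = group)
  }

  # --- line 1: import A, four untyped mates, 23 affected offspring
  add("A", sex = "male", strn = "HOM", import = TRUE)
  for (k in 1:4) add(sprintf("A_mate%d", k), sex = "female")
  kids("L1C", 23, "A", sprintf("A_mate%d", 1:4),
       c(HOM = 10, HET = 13, WT = 0))

  # --- line 2: imports G and H; H's daughter Hd bridges to transmitter T
  add("G", sex = "male", strn = "WT", import = TRUE)
  add("H", sex = "male", strn = "WT", import = TRUE)
  for (k in 1:2) add(sprintf("G_mate%d", k), sex = "female")
  for (k in 1:2) add(sprintf("H_mate%d", k), sex = "female")
  add("H_mate3", sex = "female")
  add("Hd", sire = "H", dam = "H_mate3", sex = "female")   # bridge daughter
  add("T", sire = "G", dam = "Hd", sex = "male")           # joins G and H
  for (k in 1:2) add(sprintf("T_mate%d", k), sex = "female")
  kids("L2G", 10, "G", sprintf("G_mate%d", 1:2), c(HOM = 0, HET = 6, WT = 4))
  kids("L2H", 6, "H", sprintf("H_mate%d", 1:2), c(HOM = 0, HET = 0, WT = 6))
  kids("L2T", 8, "T", sprintf("T_mate%d", 1:2), c(HOM = 6, HET = 2, WT = 0))

  # --- normals by pedigree: 31 unrelated clear founders
  g <- rep(c("HOM", "HET", "WT"), c(5, 16, 10))
  for (k in seq_along(g))
    add(sprintf("N%02d", k), sex = if (k %% 2) "female" else "male", strn = g[k])

  # --- Holter-tested external groups: cases descend from their own import
  add("P", sex = "male", import = TRUE)
  for (k in 1:2) add(sprintf("P_mate%d", k), sex = "female")
  kids("HC", 26, "P", sprintf("P_mate%d", 1:2),
       c(HOM = 5, HET = 14, WT = 7), group = "Holter-tested ARVC cases")
  gn <- rep(c("HOM", "HET", "WT"), c(6, 3, 4))
  for (k in seq_along(gn))
    add(sprintf("HN%02d", k), sex = if (k %% 2) "female" else "male",
        strn = gn[k], group = "Normal (Holter tested)")

  df <- do.call(rbind, rows)
  ped <- pedigree(df)
  list(pedigree = ped,
       pheno = df[, c("id", "affection", "onset_age", "severity", "strn",
                      "litter", "import", "group")])
}
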