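# small pedigree with explicit marker genotypes for carrier/phase rules:
# affected sire S2 (WT), clear dam; HOM affected dog; HET child of WT dam
phase_toy <- function() {
  df <- rbind(
    data.frame(id = c("S1", "S2"), sire = NA, dam = NA, sex = "male",
               affection = "unaffected", strn = "untyped"),
    data.frame(id = "D1", sire = NA, dam = NA, sex = "female",
               affection = "affected", strn = "WT"),      # repulsion dam
    data.frame(id = "D2", sire = NA, dam = NA, sex = "female",
               affection = "affected", strn = "HOM"),     # coupling dam
    data.frame(id = "K1", sire = "S1", dam = "D1", sex = "male",
               affection = "affected", strn = "HET"),     # child of WT carrier
    data.frame(id = "K2", sire = "S2", dam = "D2", sex = "female",
               affection = "affected", strn = "HET"),     # child of HOM carrier
    data.frame(id = "K3", sire = "S1", dam = "D1", sex = "male",
               affection = "affected", strn = "untyped"))
  pedigree(df)
}

toy_carriers <- function(ped) {
  tr <- identify_transmitters(ped)
  la <- trace_to_sources(ped, tr)
  rk <- classify_risk(ped, la)
  list(ca = assign_carriers(ped, rk, tr, la), rk = rk, tr = tr, la = la)
}

test_that("carrier assignment: marker never vetoes, pedigree rules drive status", {
  ped <- fig2_toy()
  df <- ped$individuals
  df$strn[df$id == "GK1"] <- "WT"    # affected wild-type dog
  df$strn[df$id == "g1"] <- "HOM"    # marker mutation in a clear dog
  ped <- pedigree(df)
  x <- toy_carriers(ped)
  ca <- x$ca
  expect_equal(ca$status[ca$id == "GK1"], "obligate_carrier")   # WT, affected
  expect_equal(ca$status[ca$id == "g1"], "clear")               # HOM, clear
  # Hd cannot be pinned down as conduit (T also descends from G): unknown
  expect_equal(ca$status[ca$id == "Hd"], "unknown")
  expect_equal(ca$status[ca$id == "T"], "inferred_carrier")
  expect_equal(ca$provenance[ca$id == "T"], "transmitter")
})

test_that("a bridge ancestor above a clear mate is an inferred carrier", {
  ped <- fig1_toy()
  x <- toy_carriers(ped)
  expect_equal(x$ca$status[x$ca$id == "X"], "inferred_carrier")
  expect_equal(x$ca$provenance[x$ca$id == "X"], "bridge")
})

test_that("phase: homozygosity rule and forced propagation", {
  ped <- phase_toy()
  x <- toy_carriers(ped)
  ph <- assign_phase(ped, x$ca)
  expect_equal(ph$phase[ph$id == "D2"], "coupling")
  expect_equal(ph$certainty[ph$id == "D2"], "certain_by_homozygosity")
  expect_equal(ph$phase[ph$id == "D1"], "repulsion")
  expect_equal(ph$certainty[ph$id == "D1"], "certain_by_homozygosity")
  # oracle: enumerate the transmissible haplotypes of a WT-marker carrier --
  # both chromosomes carry the wild-type marker allele, so the disease allele
  # always arrives on a wild-type chromosome: the HET child is in repulsion
  haps <- list(c(m = 0, d = 1), c(m = 0, d = 0))   # WT carrier chromosomes
  transmissible <- list()
  for (sel in 1:2) for (cross in c(FALSE, TRUE)) {
    other <- 3 - sel
    transmissible[[length(transmissible) + 1L]] <-
      c(m = unname(haps[[sel]]["m"]),
        d = unname(haps[[if (cross) other else sel]]["d"]))
  }
  disease_bearing <- Filter(function(h) h["d"] == 1, transmissible)
  expect_true(all(vapply(disease_bearing, function(h) h[["m"]], numeric(1)) == 0))
  expect_equal(ph$phase[ph$id == "K1"], "repulsion")
  expect_equal(ph$certainty[ph$id == "K1"], "propagated")
  expect_equal(ph$from_parent[ph$id == "K1"], "D1")
  # HET child of HOM carrier dam: coupling propagated
  expect_equal(ph$phase[ph$id == "K2"], "coupling")
  expect_equal(ph$certainty[ph$id == "K2"], "propagated")
  # untyped affected dog: obligate carrier, phase stays ambiguous
  expect_equal(x$ca$status[x$ca$id == "K3"], "obligate_carrier")
  expect_equal(ph$phase[ph$id == "K3"], "ambiguous")
})

test_that("recombination detection: mismatch grading and the no-event cases", {
  # HOM coupling sire with WT repulsion affected offspring -> certain event
  df <- rbind(
    data.frame(id = "S", sire = NA, dam = NA, sex = "male",
               affection = "affected", strn = "HOM"),
    data.frame(id = "D", sire = NA, dam = NA, sex = "female",
               affection = "unaffected", strn = "untyped"),
    data.frame(id = "K", sire = "S", dam = "D", sex = "male",
               affection = "affected", strn = "WT"))
  ped <- pedigree(df)
  x <- toy_carriers(ped)
  ph <- assign_phase(ped, x$ca)
  ev <- detect_recombination(ped, ph, x$ca)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$grade, "certain")
  expect_equal(ev$parent_id, "S")
  expect_equal(ev$child_id, "K")

  # coupling parent, coupling child: no event
  df$strn[df$id == "K"] <- "HOM"
  ped2 <- pedigree(df)
  x2 <- toy_carriers(ped2)
  ev2 <- detect_recombination(ped2, assign_phase(ped2, x2$ca), x2$ca)
  expect_equal(nrow(ev2), 0)
})

test_that("line-1 pattern (all cases HOM/HET, coupling throughout) yields no events", {
  sim <- simulate_pedigree(sim_config(seed = 21, theta = 0, penetrance = 1,
                                      prop_genotyped = 1,
                                      censor_age_years = 1e6,
                                      n_founders = 24, generations = 3,
                                      imports_affected = TRUE))
  p <- run_pipeline(sim$pedigree)
  # complete linkage in coupling: every affected dog carries the marker
  aff <- sim$pedigree$individuals$affection == "affected"
  expect_true(all(sim$pedigree$individuals$strn[aff] %in% c("HOM", "HET")))
  expect_equal(sum(p$ev$grade == "certain"), 0)
})

test_that("phase calls never contradict the homozygosity rule (all runs)", {
  for (seed in c(3, 14)) {
    sim <- simulate_pedigree(sim_config(seed = seed, theta = 0.2,
                                        penetrance = 0.6, prop_genotyped = 0.8,
                                        n_founders = 24, generations = 3,
                                        imports_affected = TRUE))
    p <- run_pipeline(sim$pedigree)
    df <- sim$pedigree$individuals
    strn <- stats::setNames(df$strn, df$id)
    hom <- p$ph[strn[p$ph$id] == "HOM", ]
    wt <- p$ph[strn[p$ph$id] == "WT", ]
    expect_true(all(hom$phase == "coupling"))
    expect_true(all(wt$phase == "repulsion"))
  }
})

test_that("certain events always correspond to a true crossover meiosis", {
  n_events <- 0
  for (seed in 31:40) {
    sim <- simulate_pedigree(sim_config(seed = seed, theta = 0.15,
                                        penetrance = 1, prop_genotyped = 1,
                                        censor_age_years = 1e6,
                                        marker_mut_freq = 0.5,
                                        n_founders = 24, generations = 3,
                                        imports_affected = TRUE))
    p <- run_pipeline(sim$pedigree)
    certain <- p$ev[p$ev$grade == "certain", ]
    mt <- sim$truth$meioses
    for (i in seq_len(nrow(certain))) {
      hit <- mt$crossover[mt$child == certain$child_id[i] &
                            mt$parent == certain$parent_id[i]]
      expect_true(hit)
    }
    n_events <- n_events + nrow(certain)
  }
  expect_gt(n_events, 0)   # the check must have had something to bite on
})

test_that("genotype tables: per-line case rosters, normals, user groups", {
  fx <- make_table1_fixture()
  p <- run_pipeline(fx$pedigree)
  tab <- genotype_tables_by_group(fx$pedigree, p$la, p$rk)
  expect_equal(unname(unlist(tab["line1 cases", ])), c(10, 13, 0, 23))
  expect_equal(unname(unlist(tab["line2 cases", ])), c(6, 8, 10, 24))
  expect_equal(unname(unlist(tab["normal (by pedigree)", ])), c(5, 16, 10, 31))
  expect_equal(unname(unlist(tab["Holter-tested ARVC cases", ])), c(5, 14, 7, 26))
  expect_equal(unname(unlist(tab["Normal (Holter tested)", ])), c(6, 3, 4, 13))
  # the external-study import line contributes an empty roster, not an error
  expect_equal(unname(unlist(tab["line3 cases", ])), c(0, 0, 0, 0))
})

test_that("untyped dogs are excluded from tables with a logged count", {
  ped <- fig1_toy()
  df <- ped$individuals
  df$strn[df$id == "BK1"] <- "HET"
  ped <- pedigree(df)            # other dogs untyped
  p <- run_pipeline(ped)
  tab <- genotype_tables_by_group(ped, p$la, p$rk)
  expect_equal(unname(unlist(tab["line1 cases", ])), c(0, 1, 0, 1))
  expect_gt(attr(tab, "n_untyped"), 0)
})
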