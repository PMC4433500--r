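test_that("transmitter rules: multi-mate producers, single litters, affected selves", {
  # sire with affected pups from 3 dams
  df <- data.frame(
    id = c("S", "D1", "D2", "D3", "K1", "K2", "K3", "U"),
    sire = c(NA, NA, NA, NA, "S", "S", "S", NA),
    dam = c(NA, NA, NA, NA, "D1", "D2", "D3", NA),
    sex = c("male", rep("female", 3), rep("male", 3), "female"),
    affection = c(rep("unaffected", 4), rep("affected", 3), "unaffected"))
  tr <- identify_transmitters(pedigree(df), min_mates = 2)
  s <- tr[tr$id == "S", ]
  expect_true(s$is_transmitter)
  expect_equal(s$basis, "multi_mate_producer")
  expect_equal(s$n_distinct_mates_with_affected, 3)
  expect_equal(s$n_affected_offspring, 3)
  # each dam produced from a single mate: not transmitters
  d <- tr[tr$id == "D1", ]
  expect_false(d$is_transmitter)
  expect_equal(d$basis, "single_mate_producer")
  # affected dogs are transmitters by affected_self even without progeny
  k <- tr[tr$id == "K1", ]
  expect_true(k$is_transmitter)
  expect_equal(k$basis, "affected_self")
  # an affected dam with one litter: affected_self, still a transmitter
  df$affection[df$id == "D1"] <- "affected"
  tr2 <- identify_transmitters(pedigree(df), min_mates = 2)
  expect_equal(tr2$basis[tr2$id == "D1"], "affected_self")
  expect_true(tr2$is_transmitter[tr2$id == "D1"])
  # dogs with no affected offspring and unaffected themselves are absent
  expect_false("U" %in% tr$id)
})

test_that("line-1 topology: single import source {A}", {
  ped <- fig1_toy()
  la <- trace_to_sources(ped, identify_transmitters(ped))
  expect_length(la$sources, 1)
  expect_equal(la$sources$line1, "A")
  # the bridge dog X (unaffected, single mate) is recorded as inferred carrier
  expect_true("X" %in% la$bridges)
  expect_setequal(la$membership[["BK1"]], "line1")
})

test_that("line-2 topology: chains joining onto two imports give source {G, H}", {
  ped <- fig2_toy()
  la <- trace_to_sources(ped, identify_transmitters(ped))
  expect_length(la$sources, 1)
  expect_setequal(la$sources$line1, c("G", "H"))
  # Hd sits between H and T, but T's other parent (G) is also at risk, so
  # the allele conduit cannot be pinned down: no bridge call
  expect_false("Hd" %in% la$bridges)
})

test_that("a disjoint affected family forms its own line", {
  df <- rbind(
    fig1_toy()$individuals,
    data.frame(id = c("Z", "z1", "z2", "ZK1", "ZK2"),
               sire = c(NA, NA, NA, "Z", "Z"),
               dam = c(NA, NA, NA, "z1", "z2"),
               sex = c("male", "female", "female", "male", "female"),
               affection = c("unaffected", "unaffected", "unaffected",
                             "affected", "affected"),
               onset_age = NA_real_, severity = "unassessed",
               strn = "untyped", litter = NA_character_, import = FALSE,
               group = NA_character_))
  ped <- pedigree(df)
  la <- trace_to_sources(ped, identify_transmitters(ped))
  expect_length(la$sources, 2)
  expect_equal(la$sources$line2, "Z")
  expect_setequal(la$membership[["ZK1"]], "line2")
})

test_that("classify_risk: exclusion rule, mixed lines, inconsistency warnings", {
  ped <- fig2_toy()
  la <- trace_to_sources(ped, identify_transmitters(ped))
  rk <- classify_risk(ped, la)
  expect_equal(rk$risk[rk$id == "g1"], "clear_by_pedigree")   # mate, no source
  expect_equal(rk$risk[rk$id == "TK1"], "at_risk")
  expect_length(attr(rk, "warnings"), 0)

  # consistency with ancestors(): at_risk(x) <=> sources intersect anc(x)+{x}
  src <- unlist(la$sources)
  for (id in ped$individuals$id) {
    expected <- length(intersect(src, c(id, ancestors(ped, id)))) > 0
    expect_equal(rk$risk[rk$id == id] == "at_risk", expected)
  }

  # an affected dog with no descent from any source draws a warning
  df <- ped$individuals
  df <- rbind(df, data.frame(id = "stray", sire = NA, dam = NA, sex = "male",
                             affection = "affected", onset_age = NA_real_,
                             severity = "unassessed", strn = "untyped",
                             litter = NA_character_, import = FALSE,
                             group = NA_character_))
  ped2 <- pedigree(df)
  la2 <- trace_to_sources(ped2, identify_transmitters(ped2))
  # stray is its own affected_self source; remove it from sources by marking
  # it non-transmitter via min_mates (still affected -> transmitter); instead
  # check the warning path with an explicitly empty assignment
  rk2 <- classify_risk(ped2, la)
  expect_match(attr(rk2, "warnings"), "stray", all = FALSE)
})

test_that("membership is monotone under source-set union", {
  ped <- fig2_toy()
  la <- trace_to_sources(ped, identify_transmitters(ped))
  # dogs reached from G's side or H's side are all members of the merged line
  expect_setequal(la$membership[["GK1"]], "line1")
  expect_setequal(la$membership[["HK1"]], "line1")
  expect_setequal(la$membership[["TK1"]], "line1")
})

test_that("simulation soundness: transmitters are true carriers, no true carrier is clear", {
  for (seed in 1:6) {
    sim <- simulate_pedigree(sim_config(seed = seed, n_founders = 20,
                                        generations = 3, penetrance = 0.4,
                                        n_import_carriers = 2,
                                        imports_affected = TRUE))
    truth <- sim$truth$dogs
    p <- run_pipeline(sim$pedigree)
    carriers <- truth$id[truth$carrier]
    # soundness: every transmitter call is a true carrier
    expect_true(all(p$tr$id[p$tr$is_transmitter] %in% carriers))
    # no true carrier classified clear-by-pedigree
    clear <- p$rk$id[p$rk$risk == "clear_by_pedigree"]
    expect_length(intersect(clear, carriers), 0)
  }
})

test_that("inheritance_mode_report counts parental sides and sexes", {
  ped <- fig1_toy()
  la <- trace_to_sources(ped, identify_transmitters(ped))
  rep <- inheritance_mode_report(ped, la)
  # every affected toy dog has an at-risk sire and a clear dam
  expect_equal(unname(rep$parental_sides["single_side"]), 4)
  expect_equal(unname(rep$parental_sides["both_sides"]), 0)
  expect_equal(rep$n_affected, 4)
  expect_equal(rep$prop_male_affected, 0.5)

  # simulated dominant pedigree with outcrossing: affected dogs never *require*
  # both parental sides at risk
  sim <- simulate_pedigree(sim_config(seed = 9, n_founders = 24,
                                      generations = 3, penetrance = 0.5))
  la2 <- trace_to_sources(sim$pedigree, identify_transmitters(sim$pedigree))
  rep2 <- inheritance_mode_report(sim$pedigree, la2)
  expect_equal(unname(rep2$parental_sides["no_side"]), 0)
})
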