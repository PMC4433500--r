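# Shared toy pedigrees and the standard inference pipeline.

# run the full descent/linkage pipeline on a pedigree
run_pipeline <- function(ped, min_mates = 2) {
  tr <- identify_transmitters(ped, min_mates = min_mates)
  la <- trace_to_sources(ped, tr)
  rk <- classify_risk(ped, la)
  ca <- assign_carriers(ped, rk, tr, la)
  ph <- assign_phase(ped, ca)
  list(tr = tr, la = la, rk = rk, ca = ca, ph = ph,
       ev = detect_recombination(ped, ph, ca),
       im = informative_meioses(ped, ph, ca))
}

# line-1-like topology: import A heads the line; producers B (a grandson of A
# reached through an unaffected bridge dog) and A himself; affected
# descendants from several mates
fig1_toy <- function() {
  df <- rbind(
    data.frame(id = "A", sire = NA, dam = NA, sex = "male",
               affection = "unaffected", import = TRUE),
    data.frame(id = c("a1", "a2", "b1", "b2"), sire = NA, dam = NA,
               sex = "female", affection = "unaffected", import = FALSE),
    data.frame(id = "X", sire = "A", dam = "a1", sex = "male",
               affection = "unaffected", import = FALSE),     # bridge
    data.frame(id = "AK1", sire = "A", dam = "a1", sex = "female",
               affection = "affected", import = FALSE),
    data.frame(id = "AK2", sire = "A", dam = "a2", sex = "male",
               affection = "affected", import = FALSE),
    data.frame(id = "B", sire = "X", dam = "b1", sex = "male",
               affection = "unaffected", import = FALSE),     # producer
    data.frame(id = "c1", sire = NA, dam = NA, sex = "female",
               affection = "unaffected", import = FALSE),
    data.frame(id = "c2", sire = NA, dam = NA, sex = "female",
               affection = "unaffected", import = FALSE),
    data.frame(id = "BK1", sire = "B", dam = "c1", sex = "female",
               affection = "affected", import = FALSE),
    data.frame(id = "BK2", sire = "B", dam = "c2", sex = "male",
               affection = "affected", import = FALSE))
  pedigree(df)
}

# line-2-like topology: two imports G and H heading chains that join through
# H's unaffected daughter onto transmitter T
fig2_toy <- function() {
  df <- rbind(
    data.frame(id = c("G", "H"), sire = NA, dam = NA, sex = "male",
               affection = "unaffected", import = TRUE),
    data.frame(id = c("g1", "g2", "h1", "h2", "h3", "t1", "t2"),
               sire = NA, dam = NA, sex = "female",
               affection = "unaffected", import = FALSE),
    data.frame(id = "GK1", sire = "G", dam = "g1", sex = "male",
               affection = "affected", import = FALSE),
    data.frame(id = "GK2", sire = "G", dam = "g2", sex = "female",
               affection = "affected", import = FALSE),
    data.frame(id = "HK1", sire = "H", dam = "h1", sex = "male",
               affection = "affected", import = FALSE),
    data.frame(id = "HK2", sire = "H", dam = "h2", sex = "female",
               affection = "affected", import = FALSE),
    data.frame(id = "Hd", sire = "H", dam = "h3", sex = "female",
               affection = "unaffected", import = FALSE),     # bridge
    data.frame(id = "T", sire = "G", dam = "Hd", sex = "male",
               affection = "unaffected", import = FALSE),
    data.frame(id = "TK1", sire = "T", dam = "t1", sex = "male",
               affection = "affected", import = FALSE),
    data.frame(id = "TK2", sire = "T", dam = "t2", sex = "female",
               affection = "affected", import = FALSE))
  pedigree(df)
}

# write a pedigree to temp PED/CSV files, returning the two paths
write_temp_pedigree <- function(ped) {
  pp <- tempfile(fileext = ".ped")
  cp <- tempfile(fileext = ".csv")
  write_pedigree(ped, pp, cp)
  c(ped = pp, pheno = cp)
}
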