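test_that("a donor inside the distance window gives exactly one H-bond", {
  p <- make_pocket(n_donors = 1, planted_pi_offsets = 0.0, seed = 1)
  hb <- detect_hbonds(p$model, list(res_name = "CBX"))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$heavy_distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$pi_kind, "carboxylate")
  expect_equal(hb$pi_distance, 0, tolerance = 1e-9)
})

test_that("donors outside the cutoff are not reported", {
  p <- make_pocket(n_donors = 1, planted_pi_offsets = 0.5,
                   donor_distance = 3.8, seed = 2)
  hb <- detect_hbonds(p$model, list(res_name = "CBX"), max_heavy_distance = 3.5)
  expect_equal(nrow(hb), 0L)
  hb2 <- detect_hbonds(p$model, list(res_name = "CBX"), max_heavy_distance = 4.0)
  expect_equal(nrow(hb2), 1L)
})

test_that("planted pi offsets are recovered exactly and averaged correctly", {
  p <- make_pocket(n_donors = 2, planted_pi_offsets = c(0.5, 1.5), seed = 3)
  hb <- detect_hbonds(p$model, list(res_name = "CBX"))
  expect_equal(sort(hb$pi_distance), c(0.5, 1.5), tolerance = 1e-9)
  expect_equal(average_pi_distortion(hb), 1.0, tolerance = 1e-9)

  p2 <- make_pocket(n_donors = 1, planted_pi_offsets = 0.74, seed = 4)
  hb2 <- detect_hbonds(p2$model, list(res_name = "CBX"))
  expect_equal(average_pi_distortion(hb2), 0.74, tolerance = 1e-9)
})

test_that("averaging errors out when no bond carries a pi-plane", {
  hb <- data.frame(pi_distance = NA_real_, pi_kind = NA_character_)
  expect_error(average_pi_distortion(hb), "no hydrogen bonds")
})

test_that("H-bond detection equals brute-force enumeration on seeded pockets", {
  for (s in 1:20) {
    set.seed(s)
    p <- make_pocket(n_donors = sample(1:5, 1),
                     planted_pi_offsets = runif(5, 0, 1.6),
                     ligand_template = sample(c("carboxylate", "gppg"), 1),
                     n_metals = sample(0:2, 1), chains = sample(1:2, 1),
                     jitter_sd = 0.05, seed = s + 1000)
    hb <- detect_hbonds(p$model, list(res_name = p$truth$ligand_res_name,
                                      chain = "A"))
    lig_keep <- p$model$atoms$res_name == p$truth$ligand_res_name &
      p$model$atoms$chain == "A"
    expected <- oracle_hbond_pairs(p$model, lig_keep, 2.4, 3.5)
    got <- sort(paste(hb$ligand_atom, hb$partner_chain, hb$partner_res_num,
                      hb$partner_atom, round(hb$heavy_distance, 9), sep = "|"))
    expect_identical(got, expected)
  }
})

test_that("peptide-amide pi groups are built from backbone neighbours", {
  ## dipeptide with a ligand oxygen H-bonded to the backbone N of residue 2;
  ## residue-1 amide plane (CA, C, O, N2) is the z = 0 plane here
  atoms <- data.frame(
    name = c("CA", "C", "O", "N", "CA", "O1"),
    chain = "A",
    res_name = c("GLY", "GLY", "GLY", "GLY", "GLY", "LIG"),
    res_num = c(1, 1, 1, 2, 2, 90),
    x = c(0, 1.5, 2.1, 2.2, 3.6, 2.2),
    y = c(0, 0, 1.1, -1.2, -1.4, -2.0),
    z = c(0, 0, 0, 0, 0.4, 2.8),
    element = c("C", "C", "O", "N", "C", "O"),
    is_hetero = c(rep(FALSE, 5), TRUE), stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  hb <- detect_hbonds(m, list(res_name = "LIG"), ligand_pi_groups = list())
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$pi_kind, "peptide_amide")
  expect_equal(hb$pi_side, "protein")
  ## partner is the ligand O at z = 2.8 above the planar amide
  expect_equal(hb$pi_distance, 2.8, tolerance = 1e-9)
})

test_that("direct contacts and chain averaging reproduce constructed values", {
  mk <- function(d_a, d_b) {
    atoms <- rbind(
      data.frame(name = "O1", chain = c("A", "B"), res_name = "LIG",
                 res_num = 90, x = c(0, 50), y = 0, z = 0, element = "O",
                 is_hetero = TRUE, stringsAsFactors = FALSE),
      data.frame(name = "OG", chain = c("A", "B"), res_name = "SER",
                 res_num = 10, x = c(d_a, 50 + d_b), y = 0, z = 0,
                 element = "O", is_hetero = FALSE, stringsAsFactors = FALSE))
    structure_model(atoms)
  }
  ct <- contact_table(mk(2.8, 2.8), "LIG")
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$mean_distance, 2.8, tolerance = 1e-9)
  ct2 <- contact_table(mk(2.8, 3.0), "LIG")
  expect_equal(ct2$mean_distance, 2.9, tolerance = 1e-9)
  expect_equal(ct2$chains, "A,B")
  ## mean always equals the mean of the per-chain list
  per <- as.numeric(strsplit(ct2$per_chain_distances, ",")[[1]])
  expect_equal(mean(per), ct2$mean_distance, tolerance = 1e-9)
})

test_that("water and magnesium bridges are flagged with the right label", {
  atoms <- rbind(
    data.frame(name = "O1", chain = "A", res_name = "LIG", res_num = 90,
               x = 0, y = 0, z = 0, element = "O", is_hetero = TRUE,
               stringsAsFactors = FALSE),
    data.frame(name = "O", chain = "A", res_name = "HOH", res_num = 301,
               x = 2.8, y = 0, z = 0, element = "O", is_hetero = TRUE,
               stringsAsFactors = FALSE),
    data.frame(name = "MG", chain = "A", res_name = "MG", res_num = 401,
               x = 0, y = 2.1, z = 0, element = "MG", is_hetero = TRUE,
               stringsAsFactors = FALSE),
    data.frame(name = "OG", chain = "A", res_name = "SER", res_num = 10,
               x = 5.6, y = 0, z = 0, element = "O", is_hetero = FALSE,
               stringsAsFactors = FALSE),
    data.frame(name = "OD1", chain = "A", res_name = "ASP", res_num = 11,
               x = 0, y = 4.2, z = 0, element = "O", is_hetero = FALSE,
               stringsAsFactors = FALSE))
  ct <- contact_table(structure_model(atoms), "LIG", cutoff = 4.0,
                      bridge_cutoff = 3.5)
  expect_setequal(ct$bridged_via, c("water", "magnesium"))
  water_row <- ct[ct$bridged_via == "water", ]
  expect_equal(water_row$protein_atom, "OG")
  expect_equal(water_row$mean_distance, 2.8, tolerance = 1e-9)  # OG-to-water leg
  mg_row <- ct[ct$bridged_via == "magnesium", ]
  expect_equal(mg_row$protein_atom, "OD1")
  expect_equal(mg_row$mean_distance, 2.1, tolerance = 1e-9)     # OD1-to-Mg leg
})

test_that("direct contacts equal brute-force enumeration on seeded pockets", {
  for (s in 1:15) {
    p <- make_pocket(n_donors = 4, planted_pi_offsets = c(0.2, 0.6, 1.0, 1.3),
                     ligand_template = "gppg", n_metals = 1,
                     chains = 2, jitter_sd = 0.08, seed = s + 2000)
    ct <- contact_table(p$model, "GPG", cutoff = 4.0)
    direct <- ct[ct$bridged_via == "direct", ]
    got <- character()
    for (i in seq_len(nrow(direct))) {
      chs <- strsplit(direct$chains[i], ",")[[1]]
      ds <- as.numeric(strsplit(direct$per_chain_distances[i], ",")[[1]])
      got <- c(got, paste(chs, direct$protein_res_num[i], direct$protein_atom[i],
                          direct$ligand_atom[i], round(ds, 9), sep = "|"))
    }
    expect_identical(sort(got), oracle_direct_contacts(p$model, "GPG", 4.0))
  }
})

test_that("contact table ordering is deterministic", {
  p <- make_pocket(n_donors = 3, planted_pi_offsets = c(0.1, 0.7, 1.2),
                   chains = 2, jitter_sd = 0.02, seed = 5)
  ct <- contact_table(p$model, "CBX")
  ord <- order(ct$protein_res_num, ct$protein_atom, ct$ligand_atom)
  expect_equal(ord, seq_len(nrow(ct)))
  ct2 <- contact_table(p$model, "CBX")
  expect_identical(ct, ct2)
})

test_that("octahedral metal shells are recovered and cutoffs respected", {
  p <- make_pocket(n_donors = 0, n_metals = 1, seed = 6)
  mc <- metal_coordination(p$model, "MG", coordination_cutoff = 2.6)
  expect_equal(nrow(mc), 6L)
  expect_equal(unique(round(mc$distance, 9)), 2.1)
  expect_setequal(unique(mc$source), "water")
  ## shell waters at 2.1 excluded by a tighter cutoff
  mc2 <- metal_coordination(p$model, "MG", coordination_cutoff = 2.0)
  expect_equal(nrow(mc2), 0L)
  ## absent metal: empty result, not an error
  expect_equal(nrow(metal_coordination(p$model, "ZN")), 0L)
})

test_that("metal shells equal brute-force distance scans on seeded pockets", {
  for (s in 1:10) {
    p <- make_pocket(n_donors = 2, planted_pi_offsets = c(0.4, 1.1),
                     n_metals = 2, chains = 2, jitter_sd = 0.1, seed = s + 3000)
    mc <- metal_coordination(p$model, "MG", coordination_cutoff = 2.6)
    got <- sort(paste(mc$metal_serial, mc$chain, mc$res_num, mc$atom,
                      round(mc$distance, 9), sep = "|"))
    expect_identical(got, oracle_metal_shell(p$model, "MG", 2.6))
  }
})
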