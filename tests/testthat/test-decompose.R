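test_that("square-planar and carbonyl complexes decompose to the expected parts", {
  rec <- decompose_complex("N[Pt](N)(Cl)Cl")
  expect_equal(rec$metal_symbol, "Pt")
  expect_equal(sort(rec$ligand_smiles), c("Cl", "Cl", "N", "N"))
  expect_equal(rec$coordination_number, 4L)
  expect_equal(nrow(rec$bond_descriptors), 4L)

  rec2 <- decompose_complex("[Fe](C#O)(C#O)(C#O)")
  expect_equal(rec2$metal_symbol, "Fe")
  expect_length(rec2$ligand_smiles, 3L)
  expect_equal(rec2$coordination_number, 3L)
  expect_true(all(rec2$ligand_smiles == "C#O"))
})

test_that("coordination number counts metal-incident edges, not ligands", {
  # bidentate chelates: 3 ligands, CN 6
  rec <- decompose_complex("[Co]%10%11(NCCN%10)(NCCN%11)(Cl)Cl")
  expect_equal(rec$coordination_number, 6L)
  expect_length(rec$ligand_smiles, 4L)
  # independent oracle: metal degree in the raw parsed graph
  mol <- parse_smiles("[Co]%10%11(NCCN%10)(NCCN%11)(Cl)Cl")
  mi <- which(mol$atoms$element == "Co")
  expect_equal(rec$coordination_number,
               sum(mol$bonds$a1 == mi | mol$bonds$a2 == mi))
})

test_that("counterion fragments are dropped but the metal fragment never is", {
  expect_message(rec <- decompose_complex("N[Pt](N)(Cl)Cl.[Na+].[Na+]"),
                 "counterion")
  expect_equal(rec$metal_symbol, "Pt")
  expect_length(rec$counterions, 2L)
  expect_equal(rec$coordination_number, 4L)
  expect_length(rec$ligand_smiles, 4L)
})

test_that("decomposition error contracts hold", {
  expect_error(decompose_complex("CCO"), "missing metal")
  expect_error(decompose_complex("[Fe](C#O)[Fe]"), "multinuclear")
  expect_error(decompose_complex("C((C"))
})

test_that("heavy atoms are conserved through metal deletion", {
  cases <- c("N[Pt](N)(Cl)Cl", "[Fe](C#O)(C#O)(C#O)",
             "[Co]%10%11(NCCN%10)(NCCN%11)(Cl)Cl",
             "[Ru](n1ccccc1)(n1ccccc1)(Cl)Cl")
  for (smi in cases) {
    rec <- decompose_complex(smi)
    ligand_atoms <- sum(vapply(rec$ligand_smiles, oracle_heavy_atoms, integer(1)))
    expect_equal(ligand_atoms + 1L, rec$n_heavy, info = smi)
  }
})

test_that("bond order labels are recorded per metal-incident edge", {
  rec <- decompose_complex("[Ti](=O)(Cl)Cl")
  expect_equal(sort(rec$bond_descriptors$order), c("double", "single", "single"))
})

test_that("class-support filtering keeps only well-populated labels", {
  df <- data.frame(x = seq_len(120),
                   label = c(rep(4L, 100), rep(9L, 20)))
  kept <- filter_by_class_support(df, min_count = 50)
  expect_equal(unique(kept$label), 4L)
  expect_equal(nrow(kept), 100L)
  expect_equal(kept$x, 1:100)  # order preserved
  expect_identical(filter_by_class_support(df, min_count = 1), df)
  empty <- df[0, ]
  expect_equal(nrow(filter_by_class_support(empty, 10)), 0L)
  # list + labels form
  recs <- as.list(letters[1:5])
  labs <- c(1, 1, 1, 2, 2)
  expect_equal(filter_by_class_support(recs, 3, labels = labs), recs[1:3])
})

test_that("component strings round-trip through parse_complex_string", {
  rec <- decompose_complex("N[Pt](N)(Cl)Cl")
  cs <- complex_to_component_string(rec)
  expect_equal(cs, "N.N.Cl.Cl.[Pt]")
  back <- parse_complex_string(cs)
  expect_equal(back$metal_symbol, rec$metal_symbol)
  expect_equal(sort(back$ligand_smiles), sort(rec$ligand_smiles))

  single <- decompose_complex("[Zn]%10%11NCCN%10CCN%11")
  expect_equal(complex_to_component_string(single), "NCCNCCN.[Zn]")
})

test_that("decompose -> component string -> fingerprint works end to end", {
  ds <- suppressWarnings(generate_complexes(40, seed = 33, counterion_prob = 0.5))
  for (i in seq_len(nrow(ds))) {
    rec <- suppressMessages(decompose_complex(ds$complex_smiles[i]))
    expect_equal(rec$coordination_number, ds$cn[i])
    expect_equal(rec$metal_symbol, ds$metal[i])
    fp_direct <- suppressWarnings(electrum_fingerprint(ds$component_string[i]))
    fp_rt <- suppressWarnings(
      electrum_fingerprint(complex_to_component_string(rec)))
    expect_identical(fp_rt$combined, fp_direct$combined, info = ds$complex_smiles[i])
  }
})
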