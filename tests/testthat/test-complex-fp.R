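test_that("component strings split into metal and ligands regardless of position", {
  inp <- parse_complex_string("N.N.Cl.Cl.[Pt]")
  expect_equal(inp$metal_symbol, "Pt")
  expect_equal(inp$ligand_smiles, c("N", "N", "Cl", "Cl"))
  inp2 <- parse_complex_string("[Pt].N.N.Cl.Cl")
  expect_equal(inp2$metal_symbol, "Pt")
  expect_equal(sort(inp2$ligand_smiles), sort(inp$ligand_smiles))
})

test_that("component-string error contracts hold", {
  expect_error(parse_complex_string("CCO"), "missing metal")
  expect_error(parse_complex_string("[Fe].[Fe].C#O"), "multinuclear")
  expect_error(parse_complex_string("N..Cl.[Pt]"), "empty component")
  expect_error(parse_complex_string("CC[Fe]CC.N.[Pt]"), "metalloligand")
  expect_error(parse_complex_string("[Pt]"), "no ligand")
  expect_message(parse_complex_string("N.N.[Pt+2]"), "ignored")
})

test_that("combined fingerprint has the documented widths", {
  fp <- electrum_fingerprint("N.N.Cl.Cl.[Pt]")
  expect_length(fp$combined, 598L)
  expect_length(fp$ligand_part, 512L)
  expect_length(fp$metal_part, 86L)
  expect_equal(sum(fp$metal_part), 78L)  # Pt
  expect_identical(fp$combined[513:598], fp$metal_part)
  expect_length(electrum_fingerprint("C.[Zn]", size = 256)$combined, 256L + 86L)
  expect_length(electrum_fingerprint("C.[Zn]", size = 1024)$combined, 1024L + 86L)
})

test_that("ligand summation is permutation-invariant", {
  expect_identical(electrum_fingerprint("C.N.[Zn]")$combined,
                   electrum_fingerprint("N.C.[Zn]")$combined)
  set.seed(11)
  ligs <- c("O", "N", "Cl", "C#O", "NCCN")
  ref <- electrum_fingerprint(paste(c(ligs, "[Ru]"), collapse = "."))$combined
  for (i in 1:10) {
    shuffled <- paste(c(sample(ligs), "[Ru]"), collapse = ".")
    expect_identical(electrum_fingerprint(shuffled)$combined, ref)
  }
})

test_that("repeated ligands add exactly", {
  one <- electrum_fingerprint("C#O.[Fe]")
  two <- electrum_fingerprint("C#O.C#O.[Fe]")
  three <- electrum_fingerprint("C#O.C#O.C#O.[Fe]")
  expect_equal(two$ligand_part, 2L * one$ligand_part)
  expect_equal(three$ligand_part, 3L * one$ligand_part)
  expect_identical(two$metal_part, one$metal_part)
})

test_that("cis and trans diamminedichloroplatinum collapse to one fingerprint", {
  cis <- electrum_fingerprint("N.N.Cl.Cl.[Pt]")
  trans <- electrum_fingerprint("Cl.N.Cl.N.[Pt]")
  expect_identical(cis$combined, trans$combined)
  # stereo-marked full-complex spellings decompose to the same fingerprint
  a <- decompose_complex("N[Pt@SP1](N)(Cl)Cl")
  b <- decompose_complex("N[Pt@SP2](N)(Cl)Cl")
  expect_identical(electrum_fingerprint(complex_to_component_string(a))$combined,
                   electrum_fingerprint(complex_to_component_string(b))$combined)
})

test_that("ligands-only baseline discards the metal entirely", {
  a <- ligands_only_fingerprint("N.N.Cl.Cl.[Pt]")
  b <- ligands_only_fingerprint("N.N.Cl.Cl.[Pd]")
  expect_identical(a, b)
  expect_length(a, 512L)
  expect_gt(sum(a), 0L)
})

test_that("atomic baseline appends the raw atomic number", {
  a <- atomic_fingerprint("N.N.Cl.Cl.[Pt]")
  b <- atomic_fingerprint("N.N.Cl.Cl.[Pd]")
  expect_length(a, 513L)
  expect_equal(unname(a[513]), 78)
  expect_equal(unname(b[513]), 46)
  expect_equal(a[1:512], b[1:512])
})

test_that("batch encoding rejects bad rows without aborting", {
  strings <- c("N.N.Cl.Cl.[Pt]", "not a smiles ((", "C.[Zn]")
  mat <- fingerprint_matrix(strings, on_error = "reject")
  expect_equal(nrow(mat), 2L)
  rej <- attr(mat, "rejects")
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "parse error")
  expect_error(fingerprint_matrix(strings, on_error = "stop"))
})
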