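test_that("parser recovers atoms, bonds, charges and implicit hydrogens", {
  m <- parse_smiles("N[Pt](N)(Cl)Cl")
  expect_equal(nrow(m$atoms), 5L)
  expect_equal(nrow(m$bonds), 4L)
  expect_equal(m$atoms$element, c("N", "Pt", "N", "Cl", "Cl"))
  # N bonded to the metal keeps only two implicit H; no valence "fixing"
  expect_equal(m$atoms$hcount[1], 2L)
  expect_equal(m$atoms$hcount[4], 0L)
  expect_equal(m$atoms$degree[2], 4L)

  benz <- parse_smiles("c1ccccc1")
  expect_true(all(benz$atoms$aromatic))
  expect_true(all(benz$atoms$in_ring))
  expect_equal(benz$atoms$hcount, rep(1L, 6))

  pyr <- parse_smiles("n1ccccc1")
  expect_equal(pyr$atoms$hcount[1], 0L)

  ions <- parse_smiles("[Fe+2].[OH-].[NH4+]")
  expect_equal(ions$atoms$charge, c(2L, -1L, 1L))
  expect_equal(ions$atoms$hcount, c(0L, 1L, 4L))
  expect_equal(max(ions$atoms$component), 3L)

  # multiple default valences: sulfur
  expect_equal(parse_smiles("S")$atoms$hcount, 2L)
  expect_equal(parse_smiles("O=S=O")$atoms$hcount[2], 0L)
})

test_that("stereo annotations are accepted and discarded", {
  a <- parse_smiles("F/C=C/F")
  b <- parse_smiles("F/C=C\\F")
  c <- parse_smiles("FC=CF")
  expect_equal(a$bonds$order, c$bonds$order)
  expect_equal(b$bonds$order, c$bonds$order)
  expect_equal(parse_smiles("[C@@H](N)(C)O")$atoms$hcount[1], 1L)
})

test_that("ring closures handle %nn numbering, reuse and explicit orders", {
  # two ring bonds plus two direct donor bonds from the two chelates
  chel <- parse_smiles("[Co]%10%11(NCCN%10)NCCN%11")
  expect_equal(chel$atoms$degree[1], 4L)
  trischel <- parse_smiles("[Co]123(NCCN1)(NCCN2)NCCN3")
  expect_equal(trischel$atoms$degree[1], 6L)
  reuse <- parse_smiles("c1ccccc1-c1ccccn1")
  expect_equal(nrow(reuse$bonds), 13L)
  expect_error(parse_smiles("C=1CCCCC1"), NA)
})

test_that("malformed strings raise parse errors carrying the input", {
  for (bad in c("", "C(C", "C1CC", "N)", "[Pt", "C%1C", "Xx", "[Zz]", "C..C")) {
    expect_error(parse_smiles(bad))
  }
  expect_error(parse_smiles("C(C"), "C\\(C")
})

test_that("writer round-trips graphs including rings, charges and chelates", {
  for (smi in c("c1ccccc1", "N[Pt](N)(Cl)Cl", "[Co]%10%11(NCCN%10)(NCCN%11)(Cl)Cl",
                "OC(C)=CC(C)=O", "[Fe+2].[OH-].O=C=O", "n1ccccc1-c2ccccn2",
                "[C-]#N", "C$C")) {
    m <- parse_smiles(smi)
    m2 <- parse_smiles(write_smiles(m))
    expect_equal(nrow(m2$atoms), nrow(m$atoms), info = smi)
    expect_equal(nrow(m2$bonds), nrow(m$bonds), info = smi)
    expect_equal(sort(m2$atoms$element), sort(m$atoms$element), info = smi)
    expect_equal(sort(m2$bonds$order), sort(m$bonds$order), info = smi)
    expect_equal(sort(m2$atoms$charge), sort(m$atoms$charge), info = smi)
  }
})

test_that("bracket atoms keep their declared hydrogen count through a round trip", {
  m <- parse_smiles("[OH-].[NH4+].[SiH3]C")
  m2 <- parse_smiles(write_smiles(m))
  expect_equal(sort(m2$atoms$hcount), sort(m$atoms$hcount))
})

test_that("randomized spellings parse back to the same graph", {
  set.seed(101)
  m <- parse_smiles("OC(C)=CC(C)=O")
  for (i in 1:25) {
    sp <- write_smiles(m, shuffle = TRUE)
    m2 <- parse_smiles(sp)
    expect_equal(nrow(m2$atoms), 7L)
    expect_equal(sort(table(m2$atoms$element)), sort(table(m$atoms$element)))
    expect_equal(sort(m2$bonds$order), sort(m$bonds$order))
  }
})

test_that("atom counts agree with an independent toolkit on simple organics", {
  suppressMessages({
    requireNamespace("ChemmineR")
    requireNamespace("ChemmineOB")
  })
  cases <- c("OCC", "c1ccccc1N", "CC(=O)OC", "N#CC")
  sdf <- ChemmineR::smiles2sdf(setNames(cases, paste0("m", seq_along(cases))))
  for (i in seq_along(cases)) {
    ours <- parse_smiles(cases[i])$atoms$element
    theirs <- sub("_.*", "", rownames(ChemmineR::atomblock(sdf[[i]])))
    theirs <- theirs[theirs != "H"]
    expect_equal(sort(ours), sort(theirs), info = cases[i])
  }
})
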