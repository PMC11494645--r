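test_that("SMILES parse/write round-trips exactly", {
  cases <- c("CCO", "O=NN(C)C", "c1ccccc1N(C)N=O", "Cc1ccc(Cl)cc1",
             "[CH3:1][N:2]([CH3:3])[N:4]=[O:5]", "[O-]C(=O)C", "[Na+]",
             "C1CCNCC1", "OO", "O=NN(CCO)Cc1ccccc1")
  for (s in cases) {
    w <- write_smiles(parse_smiles(s))
    expect_identical(write_smiles(parse_smiles(w)), w, info = s)
  }
})

test_that("implicit hydrogen counts agree with RDKit on a fixture set", {
  cases <- c("CCO", "O=NN(C)C", "c1ccccc1N(C)N=O", "Cc1ccc(Cl)cc1",
             "C1CCNCC1", "OO", "O=NN(C)C(=O)OC", "CC(=O)OCC",
             "O=NN(c1ccccc1)c1ccccc1", "C1COCCN1")
  script <- paste(
    "import sys; from rdkit import Chem",
    "for s in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(s)",
    "    print(sum(a.GetTotalNumHs() for a in m.GetAtoms()), m.GetNumAtoms())",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(cases)), stdout = TRUE))
  expect_length(out, length(cases))
  ref <- do.call(rbind, lapply(strsplit(out, " "), as.integer))
  for (k in seq_along(cases)) {
    mol <- parse_smiles(cases[k])
    expect_equal(sum(mol$atoms$hcount), ref[k, 1], info = cases[k])
    expect_equal(mol_natoms(mol), ref[k, 2], info = cases[k])
  }
})

test_that("kekulized benzene rings are normalised to the aromatic form", {
  a <- parse_smiles("C1=CC=CC=C1")
  expect_true(all(a$atoms$aromatic))
  expect_true(all(a$bonds$order == 1.5))
  expect_identical(canonical_smiles(write_smiles(a, keep_maps = FALSE)),
                   canonical_smiles("c1ccccc1"))
})

test_that("explicit [H] atoms fold into neighbour hydrogen counts", {
  m <- parse_smiles("C([H])([H])O")
  expect_equal(mol_natoms(m), 2)
  expect_equal(sum(m$atoms$hcount), 4)  # CH3-OH as heavy-atom graph
  h2 <- parse_smiles("[H][H]")
  expect_equal(mol_natoms(h2), 0)
})

test_that("malformed and valence-illegal SMILES raise parse errors", {
  expect_error(parse_smiles("not_a_smiles"), class = "nitrosaminer_parse_error")
  expect_error(parse_smiles("C(C"), class = "nitrosaminer_parse_error")
  expect_error(parse_smiles("C1CC"), class = "nitrosaminer_parse_error")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), class = "nitrosaminer_parse_error")
  expect_error(parse_smiles(""), class = "nitrosaminer_parse_error")
})

test_that("canonical SMILES identifies equal molecules written differently", {
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_identical(canonical_smiles("O=NN(C)c1ccccc1"),
                   canonical_smiles("c1ccccc1N(C)N=O"))
  expect_false(canonical_smiles("CCO") == canonical_smiles("CCN"))
  # open-valence fragments keep their hydrogen counts distinct
  expect_false(canonical_smiles("[CH3]") == canonical_smiles("[CH2]"))
  expect_false(canonical_smiles("[CH3]") == canonical_smiles("C"))
})

test_that("mol_canonical is invariant under atom renumbering", {
  set.seed(11)
  for (s in c("O=NN(C)CCO", "Cc1ccc(Cl)cc1", "O=NN(C)C(=O)OC")) {
    mol <- parse_smiles(s)
    ref <- mol_canonical(mol)
    for (k in 1:5) {
      perm <- sample(mol_natoms(mol))
      expect_identical(mol_canonical(renumber_mol(mol, perm)), ref, info = s)
    }
  }
})

test_that("subgraph extraction keeps attributes and induced bonds", {
  mol <- parse_smiles("O=NN(C)CCO")
  sub <- subgraph_mol(mol, 1:3)  # O=N-N fragment
  expect_equal(mol_natoms(sub), 3)
  expect_equal(nrow(sub$bonds), 2)
  expect_setequal(sub$atoms$element, c("O", "N", "N"))
  comps <- mol_components(parse_smiles("CCO") )
  expect_length(comps, 1)
})
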