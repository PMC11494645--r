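test_that("substrate classes follow substituent typing", {
  cases <- list(
    list("O=NN(C)C", "dialkyl", FALSE),          # NDMA
    list("O=NN(c1ccccc1)c1ccccc1", "diaryl", FALSE),
    list("O=NN(C)C(=O)OC", "alkyl-carbamate", FALSE),
    list("O=NN(C)CCO", "dialkyl", TRUE),         # beta-oxy flag, not a class
    list("O=NN(C)c1ccccc1", "alkyl-aryl", FALSE),
    list("O=NN(C)C(=O)C", "alkyl-amide", FALSE),
    list("O=NN(C)C(=O)N(C)C", "alkyl-urea", FALSE),
    list("O=NN(C)S(=O)(=O)C", "alkyl-sulfonyl", FALSE),
    list("O=NN(C)C(=N)N", "alkyl-guanidine", FALSE),
    # electron-poor label wins over the aryl partner
    list("O=NN(c1ccccc1)C(=O)OC", "alkyl-carbamate", FALSE)
  )
  for (cs in cases) {
    sc <- classify_substrate(cs[[1]])
    expect_identical(sc$fine_label, cs[[2]], info = cs[[1]])
    expect_identical(sc$beta_oxy, cs[[3]], info = cs[[1]])
  }
  expect_identical(classify_substrate("O=NN(C)C")$coarse_label, "C1")
  expect_error(classify_substrate("CNC"), class = "nitrosaminer_precondition_error")
})

test_that("substrate classification is invariant under renumbering", {
  set.seed(5)
  for (s in c("O=NN(C)CCO", "O=NN(c1ccccc1)C(=O)OC", "O=NN(C)S(=O)(=O)C")) {
    mol <- parse_smiles(s)
    ref <- classify_substrate(mol)
    for (k in 1:5) {
      got <- classify_substrate(renumber_mol(mol, sample(mol_natoms(mol))))
      expect_identical(got$fine_label, ref$fine_label, info = s)
      expect_identical(got$beta_oxy, ref$beta_oxy, info = s)
    }
  }
})

test_that("reagent classification respects synonyms and precedence", {
  expect_identical(classify_reagents(mk_record("C>>C", reagent_names = c("Na2S2O4", "NaOH"))),
                   "S-based reductant")  # reductant outranks base
  expect_identical(classify_reagents(mk_record("C>>C", reagent_names = "LiAlH4")),
                   "hydride reductant")
  expect_identical(classify_reagents(mk_record("C>>C", reagent_names = "unobtainium")),
                   "unclassified")
  expect_identical(classify_reagents(mk_record("C>>C", reagent_names = "Sodium Dithionite")),
                   "S-based reductant")
  expect_identical(classify_reagents(mk_record("C>>C", temperature_c = 80)),
                   "thermal only")
  expect_identical(classify_reagents(mk_record("C>>C")), "unclassified")
  expect_error(load_reagent_taxonomy(tempfile()), class = "nitrosaminer_config_error")
})

test_that("transformation rules label the worked reactions", {
  expect_identical(classify_transformation(mk_mapped(DENITROSATION_RXN)),
                   "reduction to amine/denitrosation")
  expect_identical(classify_transformation(mk_mapped(HYDRAZINE_RXN)),
                   "reduction to hydrazine")
  fh <- mk_mapped(paste0(
    "[O:1]=[N:2][N:3]([CH3:4])[c:5]1[cH:6][cH:7][cH:8][cH:9][cH:10]1>>",
    "[CH3:4][NH:3][c:5]1[cH:6][cH:7][c:8]([N:2]=[O:1])[cH:9][cH:10]1"))
  expect_identical(classify_transformation(fh), "Fischer-Hepp rearrangement")
  tn <- mk_mapped(paste0(
    "[CH3:1][N:2]([CH3:3])[N:4]=[O:5].[CH3:6][NH:7][CH3:8]>>",
    "[CH3:1][NH:2][CH3:3].[CH3:6][N:7]([CH3:8])[N:4]=[O:5]"))
  expect_identical(classify_transformation(tn), "transnitrosation")
  dz <- mk_mapped(paste0(
    "[CH3:1][N:2]([N:3]=[O:4])[C:5](=[O:6])[CH3:7]>>",
    "[CH3:1][N+:2]#[N:3].[O-:4][C:5](=[O:6])[CH3:7]"))
  expect_identical(classify_transformation(dz), "diazonium formation")
  nx <- mk_mapped(paste0(
    "[CH3:1][N:2]([CH3:3])[N:4]=[O:5].[OH:6][OH:7]>>",
    "[CH3:1][N:2]([CH3:3])[N+:4](=[O:5])[O-:6].[OH2:7]"))
  expect_identical(classify_transformation(nx), "oxidation to N-nitramine")
  # not consumed -> precondition error
  expect_error(classify_transformation(mk_mapped(IDENTITY_RXN)),
               class = "nitrosaminer_precondition_error")
})

test_that("streamlining drops thin classes and conserves counts", {
  mk_rows <- function(cls, n_sub, transfos, n_rows) {
    tibble::tibble(
      record_id = paste0(cls, seq_len(n_rows)),
      substrate_smiles = paste0(cls, "_s", rep_len(seq_len(n_sub), n_rows)),
      substrate_fine = cls, substrate_coarse = cls, beta_oxy = FALSE,
      reagent_class = "unclassified",
      transformation = rep_len(transfos, n_rows))
  }
  good <- mk_rows("A", 12, c("t1", "t2", "t3"), 20)
  few_subs <- mk_rows("B", 9, c("t1", "t2", "t3"), 15)       # < 10 substrates
  few_trans <- mk_rows("C", 12, c("t1", "t2"), 14)           # < 3 transformations
  all3 <- rbind(good, few_subs, few_trans)
  sl <- streamline(all3)
  expect_setequal(sl$dropped_classes, c("B", "C"))
  expect_equal(sl$n_lost, 29)
  expect_equal(nrow(sl$kept) + sl$n_lost, nrow(all3))
  expect_equal(unique(sl$kept$substrate_coarse), "A")

  empty <- streamline(all3[0, ])
  expect_equal(empty$n_lost, 0)
  expect_error(streamline(all3, min_substrates = 0),
               class = "nitrosaminer_argument_error")
})
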