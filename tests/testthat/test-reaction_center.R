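test_that("bond and atom changes match hand tallies", {
  ch <- detect_changes(mk_mapped(DENITROSATION_RXN))
  expect_equal(nrow(ch$bond_changes), 1)
  expect_equal(ch$bond_changes$kind, "broken")
  expect_setequal(c(ch$bond_changes$a1, ch$bond_changes$a2), c(2, 4))
  h <- ch$atom_changes[ch$atom_changes$property == "implicit_h_count", ]
  expect_setequal(h$map_index, c(2, 4))

  ch2 <- detect_changes(mk_mapped(HYDRAZINE_RXN))
  expect_setequal(c(ch2$bond_changes$a1, ch2$bond_changes$a2), c(4, 5))
  h2 <- ch2$atom_changes[ch2$atom_changes$property == "implicit_h_count", ]
  expect_setequal(h2$map_index, c(4, 5))

  chI <- detect_changes(mk_mapped(IDENTITY_RXN))
  expect_equal(nrow(chI$bond_changes), 0)
  expect_equal(nrow(chI$atom_changes), 0)
})

test_that("atoms mapped on one side only are reported as lost/appeared", {
  m <- mk_mapped("[CH3:1][N:2]([CH3:3])[N:4]=[O:5]>>[CH3:1][NH:2][CH3:3].[NH:4]=[O:6]")
  ch <- detect_changes(m)
  expect_true(any(ch$atom_changes$property == "lost_from_products" &
                    ch$atom_changes$map_index == 5))
  expect_true(any(ch$atom_changes$property == "appeared_in_products" &
                    ch$atom_changes$map_index == 6))
  # duplicate indices violate the contract
  bad <- mk_mapped("[CH3:1][N:2]([CH3:2])[N:4]=[O:5]>>[CH3:1][NH:2][CH3:3].[NH:4]=[O:5]")
  expect_error(detect_changes(bad), class = "nitrosaminer_contract_error")
})

test_that("center expansion follows the depth laws", {
  m <- mk_mapped(DENITROSATION_RXN)
  ch <- detect_changes(m)
  expect_equal(expand_center(m, ch, 0)$core_atoms, c(2, 4))
  expect_equal(expand_center(m, ch, 1)$core_atoms, 1:5)
  expect_equal(expand_center(m, ch, 99)$core_atoms, 1:5)  # saturation
  expect_error(expand_center(m, ch, -1), class = "nitrosaminer_argument_error")

  enc0 <- encode_center(expand_center(m, ch, 0))
  enc1 <- encode_center(expand_center(m, ch, 1))
  expect_false(enc0 == enc1)
})

test_that("center encodings are canonical and empty centers encode as '>>'", {
  m <- mk_mapped(DENITROSATION_RXN)
  renum <- mk_mapped("[N:4](=[O:5])[N:2]([CH3:3])[CH3:1]>>[NH:4]=[O:5].[CH3:3][NH:2][CH3:1]")
  expect_identical(encode_center(expand_center(m, depth = 1)),
                   encode_center(expand_center(renum, depth = 1)))
  expect_identical(encode_center(expand_center(mk_mapped(IDENTITY_RXN), depth = 1)),
                   ">>")
})

test_that("consumption verdicts follow the match-alteration definition", {
  expect_true(fg_consumed(mk_mapped(DENITROSATION_RXN))$consumed)
  expect_true(fg_consumed(mk_mapped(HYDRAZINE_RXN))$consumed)
  sp <- fg_consumed(mk_mapped(SPECTATOR_RXN))
  expect_false(sp$consumed)
  expect_false(sp$no_substrate)
  idv <- fg_consumed(mk_mapped(IDENTITY_RXN))
  expect_false(idv$consumed)
  # a reaction with no substrate match at all
  none <- fg_consumed(mk_mapped("[CH3:1][OH:2]>>[CH3:1][OH:2]"))
  expect_false(none$consumed)
  expect_true(none$no_substrate)
  # empty-change law: no changes => not consumed for any query
  q <- fg_query("alcohol", "[#8;H1][#6]")
  expect_false(fg_consumed(mk_mapped(IDENTITY_RXN), q)$consumed)
})

test_that("fg_consumed agrees with the re-embedding oracle on worked cases", {
  for (rxn in c(DENITROSATION_RXN, HYDRAZINE_RXN, SPECTATOR_RXN, IDENTITY_RXN)) {
    m <- mk_mapped(rxn)
    expect_equal(fg_consumed(m)$consumed, consumption_oracle(m)$consumed, info = rxn)
  }
})
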