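# Brute-force consumption oracle, independent of fg_consumed's change-set
# path: each reactant FG match is re-embedded into the products via map
# indices and the induced subgraphs (bonds among match atoms, charges,
# hydrogen counts) are compared; any non-reproduced match means consumption.

consumption_oracle <- function(mapped, query = nsa_query()) {
  pt <- do.call(rbind, lapply(seq_along(mapped$products), function(k) {
    a <- mapped$products[[k]]$atoms
    if (!nrow(a)) return(NULL)
    data.frame(mol = k, atom = seq_len(nrow(a)), map = a$map,
               charge = a$charge, hcount = a$hcount)
  }))
  find_product_atom <- function(m) {
    hit <- which(pt$map == m)
    if (!length(hit)) NULL else pt[hit[1], ]
  }
  any_consumed <- FALSE
  any_match <- FALSE
  for (mol in mapped$reactants) {
    if (!mol_natoms(mol)) next
    for (match in match_pattern(query, mol)) {
      any_match <- TRUE
      maps <- mol$atoms$map[match]
      if (any(maps == 0)) next
      intact <- TRUE
      embed <- lapply(maps, find_product_atom)
      if (any(vapply(embed, is.null, FALSE))) {
        intact <- FALSE
      } else {
        for (i in seq_along(match)) {
          ra <- mol$atoms[match[i], ]
          pa <- mapped$products[[embed[[i]]$mol]]$atoms[embed[[i]]$atom, ]
          if (ra$charge != pa$charge || ra$hcount != pa$hcount) intact <- FALSE
        }
        for (i in seq_along(match)) {
          for (j in seq_along(match)) {
            if (i >= j) next
            ob <- bond_order_between(mol, match[i], match[j])
            pb <- if (embed[[i]]$mol == embed[[j]]$mol) {
              bond_order_between(mapped$products[[embed[[i]]$mol]],
                                 embed[[i]]$atom, embed[[j]]$atom)
            } else 0
            if (ob != pb) intact <- FALSE
          }
        }
      }
      if (!intact) any_consumed <- TRUE
    }
  }
  list(consumed = any_consumed, no_substrate = !any_match)
}
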