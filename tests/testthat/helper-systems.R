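# shared builders for small reference systems

bondmat <- function(n, bonds = list()) {
  B <- matrix(0L, n, n)
  for (b in bonds) {
    B[b[1], b[2]] <- B[b[2], b[1]] <- as.integer(b[3])
  }
  B
}

# ethylamine + propanoic acid on the standard indexing
simple_pair_system <- function() {
  smiles_to_system("CCN.CCC(=O)O", atom_order = c(1, 2, 6, 3, 4, 5, 7, 8))
}

# N-ethylpropanamide as a 7-atom product fragment
amide_product_system <- function() {
  smiles_to_system("CCC(=O)NCC")
}

# small atom arrays used across oracle tests
toy_arrays <- function() {
  list(
    CO = atom_array(c("C", "O")),
    CN = atom_array(c("C", "N")),
    OO = atom_array(c("O", "O")),
    CCO = atom_array(c("C", "C", "O")),
    CNO = atom_array(c("C", "N", "O")),
    CCNO = atom_array(c("C", "C", "N", "O")),
    CCCNO = atom_array(c("C", "C", "C", "N", "O"))
  )
}

tri_rows_sorted <- function(m) {
  m <- m[do.call(order, lapply(seq_len(ncol(m)), function(c) m[, c])), ,
         drop = FALSE]
  dimnames(m) <- NULL
  m
}
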