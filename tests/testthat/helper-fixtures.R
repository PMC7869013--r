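# shared tiny fixtures; everything is generated in code

tiny_config <- function(epochs = 2L, seed = 3L, ...) {
  ssnet_config(window_sizes = c(3L, 5L), n_conv = 2L, channels = 4L,
               protein_embed_dim = 6L, ligand_embed_dim = 5L,
               final_hidden_dim = 4L, n_bits = 16L, seed = seed,
               epochs = epochs, ...)
}

tiny_weights <- function(cfg, seed = 7) {
  set.seed(seed)
  ssnet:::.init_weights(cfg)
}

tiny_tensor <- function(n = 40, seed = 11) {
  set.seed(seed)
  build_protein_tensor(decompose_chain(make_coil_trace(n)))
}

random_bits <- function(n_bits = 16, p = 0.4, seed = 5) {
  set.seed(seed)
  as.numeric(runif(n_bits) < p)
}

# PDB text fixture: two models, altlocs, a HETATM and an insertion code
pdb_fixture_lines <- function() {
  atom <- function(serial, name, resname, chain, resno, x, y, z, occ = 1,
                   alt = " ", icode = " ", rec = "ATOM  ") {
    sprintf("%s%5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            rec, serial, sprintf(" %-3s", name), alt, resname, chain, resno,
            icode, x, y, z, occ, 10)
  }
  c("HEADER    SYNTHETIC FIXTURE",
    "MODEL        1",
    atom(1, "N", "ALA", "A", 1, 0, 0, 0),            # not CA: skipped
    atom(2, "CA", "ALA", "A", 1, 1, 2, 3),
    atom(3, "CA", "GLY", "A", 2, 4, 5, 6, occ = 0.4, alt = "A"),
    atom(4, "CA", "GLY", "A", 2, 7, 8, 9, occ = 0.6, alt = "B"),  # higher occ wins
    atom(5, "CA", "SER", "A", 3, 1, 1, 1, occ = 0.5, alt = "A"),  # occ tie ->
    atom(6, "CA", "SER", "A", 3, 2, 2, 2, occ = 0.5, alt = "B"),  # altloc A wins
    atom(7, "CA", "THR", "A", 3, 3, 3, 3, icode = "A"),           # insertion code
    atom(8, "CA", "VAL", "B", 1, 9, 9, 9),
    sprintf("HETATM%5d  CA  HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f", 9, 99,
            5, 5, 5, 1, 10),
    "ENDMDL",
    "MODEL        2",
    atom(10, "CA", "ALA", "A", 1, 50, 50, 50),
    "ENDMDL",
    "END")
}
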