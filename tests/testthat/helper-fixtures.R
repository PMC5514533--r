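# Shared fixtures, built once per test run. All fixtures are deterministic
# functions of their specs; no files are read beyond the packaged charge
# table.

default_charges <- default_charge_table()

# 9-bp toy complex with one serine hydroxyl hydrogen probe 2.0 A from the
# N7 acceptor of the adenine at position 5
toy9 <- build_toy_complex(fixture_spec(
  sequence = "GCGCAGCGC", seed = 7,
  probe_atoms = list(list(resid = "SER", atom = "HG", base_pos = 5,
                          base_atom = "N7", distance = 2.0))))

# two-probe 9-bp complex used for multibody training
toy9b <- build_toy_complex(fixture_spec(
  sequence = "ATATTGCAT", seed = 3,
  probe_atoms = list(
    list(resid = "ARG", atom = "HH11", base_pos = 6, base_atom = "O6",
         distance = 2.5),
    list(resid = "GLY", atom = "H", base_pos = 4, base_atom = "O4",
         distance = 2.2))))

mb_pot <- train_mb_potential(list(toy9, toy9b))

# 7-bp toy complex for full-length enumeration oracles
toy7 <- build_toy_complex(fixture_spec(
  sequence = "GCGAAGC", seed = 7,
  probe_atoms = list(list(resid = "SER", atom = "HG", base_pos = 4,
                          base_atom = "N7", distance = 2.0))))

# single hydrogen probe at a chosen distance from the N7 of position 5
toy_hbond_probe <- function(distance, sequence = "GCGCAGCGC") {
  build_toy_complex(fixture_spec(
    sequence = sequence, seed = 7,
    probe_atoms = list(list(resid = "SER", atom = "HG", base_pos = 5,
                            base_atom = "N7", distance = distance))))
}

# aromatic ring probe with its nearest ring-atom pair at a chosen distance
toy_ring_probe <- function(distance) {
  build_toy_complex(fixture_spec(
    sequence = "GCGCAGCGC", seed = 7,
    probe_atoms = list(list(resid = "PHE", atom = "RING", base_pos = 5,
                            base_atom = "N7", distance = distance))))
}

# contact-detection fixture: two single-atom probes whose global minimum
# distance to the duplex is `distance`, touching only base pairs 4..8 of a
# 12-bp duplex
toy_contact <- function(distance) {
  build_toy_complex(fixture_spec(
    sequence = "ACGTACGTACGT", seed = 1,
    probe_atoms = list(
      list(resid = "ALA", atom = "CB1", base_pos = 4, base_atom = "C7",
           distance = distance, clear = "heavy", allowed = 4:8,
           support = FALSE),
      list(resid = "ALA", atom = "CB1", base_pos = 8, base_atom = "C7",
           distance = distance, clear = "heavy", allowed = 4:8,
           support = FALSE))))
}

window9 <- binding_site(3, 7, flank = 0, duplex_length = 9)
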