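# Builders for small in-code fixtures used across test files.

make_ensemble <- function(energies, compound_id = "cmp", charge = 0L,
                          phase = "aqueous",
                          tautomer_id = sprintf("t%02d", seq_along(energies))) {
  n <- length(energies)
  data.frame(compound_id = rep_len(compound_id, n),
             charge = rep_len(as.integer(charge), n),
             tautomer_id = rep_len(tautomer_id, n),
             phase = rep_len(phase, n),
             energy = energies, stringsAsFactors = FALSE)
}

# A two-charge-state microstate table for one compound, from explicit
# per-state tautomer energies.
make_compound_ms <- function(compound_id, parent_charge, parent_energies,
                             product_energies, phase = "aqueous") {
  rbind(make_ensemble(parent_energies, compound_id, parent_charge, phase),
        make_ensemble(product_energies, compound_id, parent_charge - 1L,
                      phase))
}

random_ensemble <- function(n = sample(1:8, 1L)) {
  make_ensemble(round(runif(n, -2000, -1000), 6))
}
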