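# Shared fixtures: random sequence generators and small file writers.

random_cds <- function(len, seed, probs = c(A = 0.25, C = 0.25, G = 0.25,
                                            U = 0.25), id = "rnd") {
  set.seed(seed)
  cds_record(id, paste(sample(names(probs), len, TRUE, prob = probs),
                       collapse = ""))
}

random_protein <- function(len, seed, id = "prot") {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  protein_record(id, paste(sample(aa, len, TRUE), collapse = ""))
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# single-carbon-atom model rows, for analytic SASA checks
carbon_atoms <- function(x, y = 0, z = 0, chain = "A") {
  data.frame(chain = chain, resno = seq_along(x), resid = "ALA",
             elety = "CA", element = "C", x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}
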