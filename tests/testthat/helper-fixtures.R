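# Shared fixtures for the suite. Sequences are written 5'->3'.

# mature miR-16-5p (the DNA copy doubles as the complement of the fully
# modified anti-miR-16 analyte in the ligation worked example)
MIR16_RNA <- "UAGCAGCACGUAAAUAUUGGCG"
MIR16_DNA <- "TAGCAGCACGTAAATATTGGCG"
AMO_MIR16 <- wbspcr::revcomp(MIR16_DNA)  # the antagomir analyte

# the shipped ligation oligos for the anti-miR-16 analyte
PS_LIGATOR <- "TTAAACCATAGCAGCACG"   # 5' tail TTAAACCA + 10-nt core, 3'-PS
BPS_LIGATOR <- "TAAATATTGGCGAACCAGT" # 12-nt core + 3' tail AACCAGT, 5'-BPS

random_template <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

noiseless_model <- function(...) {
  wbspcr::assay_model(noise_sd = 0, ...)
}

# tiny grid fixture: 2 x 3 window with one invalid cell
small_grid <- function() {
  v <- matrix(c(1, 2, 3, 4, 5, NA), nrow = 2)
  m <- !is.na(v)
  wbspcr::value_grid(v, m, assay_id = "toy")
}
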