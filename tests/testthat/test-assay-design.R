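test_that("palindrome blocklist entries are their own reverse complements", {
  for (m in palindrome_blocklist()) {
    expect_equal(tolower(revcomp(m)), m)
  }
})

test_that("RT primer defaults to an 8-nt TRS reverse-complementing the 3' terminus", {
  rt <- design_rt_primer(MIR16_RNA)
  expect_s3_class(rt, "rt_primer_design")
  expect_equal(rt$trs_length, 8L)
  n <- nchar(MIR16_DNA)
  expect_identical(rt$trs, revcomp(substr(MIR16_DNA, n - 7L, n)))
  expect_identical(rt$full_sequence, paste0(rt$generic_tail, rt$trs))
  expect_gte(rt$tm_estimate, 50)
  expect_error(design_rt_primer("ACGTACGTAC"), "too short")
})

test_that("blocklisted TRS termini resolve by single-nucleotide adjustment", {
  # position the motif so the default 8-nt TRS would end in it: the TRS 3'
  # tetramer is the reverse complement of template positions n-7..n-4, and
  # every blocklisted motif is self-reverse-complementary
  for (motif in palindrome_blocklist()) {
    template <- paste0("TACGTCAGGATCTG", toupper(motif), "TTCA")  # 22 nt
    rt <- design_rt_primer(template)
    expect_true(rt$trs_length %in% c(7L, 9L),
                info = paste("motif", motif, "gave length", rt$trs_length))
    expect_false(substr(rt$trs, rt$trs_length - 3L, rt$trs_length) |>
                   tolower() %in% palindrome_blocklist())
    # the +1 extension is tried before the -1 removal
    ext <- revcomp(substr(template, nchar(template) - 8L, nchar(template)))
    ext_clean <- !(tolower(substr(ext, 6L, 9L)) %in% palindrome_blocklist())
    if (ext_clean) expect_equal(rt$trs_length, 9L)
  }
})

test_that("forward primer carries the anti-primer complement and respects overlap rules", {
  rt <- design_rt_primer(MIR16_DNA)
  fwd <- design_forward_primer(MIR16_DNA, rt)
  expect_identical(fwd$generic_region, "CTCCCTCCCTCGATTT")
  expect_identical(fwd$generic_region, revcomp(anti_primer()$core))
  expect_gte(fwd$gene_specific_length, 12L)
  expect_lte(fwd$overlap_with_rt, 3L)
  # maximality: one nucleotide more would break overlap or palindrome rules
  n <- nchar(MIR16_DNA)
  e_next <- fwd$gene_specific_length + 1L
  over_next <- max(0L, e_next - (n - rt$trs_length))
  tet_next <- tolower(substr(MIR16_DNA, e_next - 3L, e_next))
  expect_true(over_next > 3L || tet_next %in% palindrome_blocklist())
})

test_that("forward design fails when no 12-nt region satisfies the overlap cap", {
  # 17-nt template with a 12-nt TRS leaves at most 8 positions for the
  # gene-specific region under a 3-nt overlap cap
  template <- "GATCCATGACCTGGAAC"
  rt <- design_rt_primer(template, trs_length = 12L)
  expect_equal(rt$trs_length, 12L)
  expect_error(design_forward_primer(template, rt), "no gene-specific region")
})

test_that("the miR-16 ligator worked example reproduces the shipped oligos", {
  lig <- design_ligators(AMO_MIR16, junction_offset = -1)
  expect_identical(lig$ps_core, "TAGCAGCACG")     # 10 nt
  expect_identical(lig$bps_core, "TAAATATTGGCG")  # 12 nt
  expect_identical(lig$ps_ligator, PS_LIGATOR)
  expect_identical(lig$bps_ligator, BPS_LIGATOR)
  expect_identical(paste0(lig$ps_core, lig$bps_core), revcomp(AMO_MIR16))
  expect_identical(paste0(lig$ps_core, lig$bps_core), MIR16_DNA)
  expect_true(validation_passed(validate_assay(lig)))
})

test_that("ligator edge cases: palindromic analytes warn, short analytes fail", {
  pal <- strrep("ACGT", 4)  # 16-nt self-reverse-complementary analyte
  expect_warning(lig <- design_ligators(pal), "self-reverse-complementary")
  expect_identical(lig$ps_core, revcomp(lig$bps_core))
  expect_error(design_ligators("ACGTACGTACGT"), "too short")
  # a junction pushed to the edge starves one core
  expect_error(design_ligators(AMO_MIR16, junction_offset = -5), "core shorter")
})

test_that("designer output always validates (closure over random templates)", {
  set.seed(202)
  n_default_trs <- 0L
  for (i in 1:100) {
    template <- random_template(sample(18:25, 1))
    assay <- tryCatch(design_assay(template), error = function(e) NULL)
    # random templates can be undesignable (palindrome-saturated); the
    # designer must either error cleanly or emit a fully rule-compliant set
    if (is.null(assay)) next
    report <- validate_assay(assay)
    expect_true(validation_passed(report),
                info = paste("template", template))
    expect_gte(assay$forward$gene_specific_length, 12L)
    expect_lte(assay$forward$overlap_with_rt, 3L)
    if (assay$rt$trs_length == 8L) n_default_trs <- n_default_trs + 1L
  }
  # the 8-nt default dominates; adjustments are the exception
  expect_gt(n_default_trs, 80L)
})

test_that("validation detects injected rule violations", {
  assay <- design_assay(MIR16_DNA)
  # force a 4-nt overlap by lengthening the gene-specific region claim
  broken <- assay
  broken$forward$gene_specific_length <-
    nchar(MIR16_DNA) - assay$rt$trs_length + 4L
  rep1 <- validate_assay(broken)
  expect_false(rep1$pass[rep1$rule == "forward_rt_overlap"])
  expect_false(validation_passed(rep1))

  # anti-primer complementarity broken
  broken2 <- assay
  broken2$forward$generic_region <- "AAAAAAAAAAAAAAAA"
  rep2 <- validate_assay(broken2)
  expect_false(rep2$pass[rep2$rule == "anti_primer_complementarity"])

  # ligator pair with a 1-nt gap at the junction
  lig <- design_ligators(AMO_MIR16, junction_offset = -1)
  lig$bps_core <- substr(lig$bps_core, 2L, nchar(lig$bps_core))
  rep3 <- validate_assay(lig)
  expect_false(rep3$pass[rep3$rule == "ligator_core_coverage"])
})

test_that("design export produces annotated FASTA and tidy tables", {
  assay <- design_assay(MIR16_DNA)
  tab <- tidy(assay)
  expect_true(all(c("rt_primer", "forward_primer", "anti_primer") %in% tab$part))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_design_fasta(assay, fa)
  reread <- read_templates(fa)
  expect_equal(unname(reread[["rt_primer"]]), assay$rt$full_sequence)
})
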