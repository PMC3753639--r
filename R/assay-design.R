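#' Palindromic 3'-terminal tetramers to avoid
#'
#' Primer 3' termini ending in one of these self-reverse-complementary
#' tetramers promote primer-dimer artifacts; the designer adjusts the
#' target-recognition sequence (TRS) length until the terminus is clean.
#'
#' @return Character vector of 8 lowercase tetramers.
#' @export
palindrome_blocklist <- function() {
  c("ccgg", "aatt", "ggcc", "ttaa", "atat", "tata", "cgcg", "gcgc")
}

terminal_tetramer <- function(x) {
  x <- as_dna(x)
  tolower(substr(x, nchar(x) - 3L, nchar(x)))
}

#' Quencher-labelled anti-primer
#'
#' In the anti-primer quenching readout, unincorporated fluorophore-labelled
#' forward primers are quenched by an anti-primer complementary to the forward
#' primer's generic 5' tail, so fluorescence tracks double-stranded product.
#'
#' @param core Anti-primer core sequence, 5'->3'.
#' @param quencher Quencher label name.
#' @return An object of class `anti_primer`.
#' @export
anti_primer <- function(core = "AAATCGAGGGAGGGAG", quencher = "BHQ2") {
  structure(list(core = as_dna(core), quencher = quencher),
            class = "anti_primer")
}

#' Generic 5' tails shipped with the RT-primer designer
#'
#' The RT primer's generic 5' tail raises the melting temperature of the
#' otherwise very short primer and lets it serve as the reverse primer in the
#' PCR step. Each candidate tail is screened against the template for
#' complementary runs before use.
#'
#' @return Named character vector of candidate tails.
#' @export
default_tail_library <- function() {
  c(tailA = "GTCGGCAATGCAGGAGTC",
    tailB = "CACGCAGGACTTAGGTGC",
    tailC = "GGCACTTGACCTAGGCAGA")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K).
.nn_params <- local({
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  list(dH = dH, dS = dS)
})

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor duplex model with unified thermodynamic
#' parameters, entropic salt correction (0.368 x pairs x ln[Na+]) and the
#' standard c/4 concentration term for non-self-complementary duplexes.
#'
#' @param x Primer sequence (DNA/RNA).
#' @param primer_nM Primer concentration in nM (default 250).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' nn_tm("GTCGGCAATGCAGGAGTC")
nn_tm <- function(x, primer_nM = 250, na_mM = 50) {
  x <- as_dna(x)
  n <- nchar(x)
  stopifnot(n >= 2)
  steps <- substring(x, seq_len(n - 1L), seq.int(2L, n))
  dH <- sum(.nn_params$dH[steps])
  dS <- sum(.nn_params$dS[steps])
  ends <- substr(x, 1L, 1L)
  ends <- c(ends, substr(x, n, n))
  for (e in ends) {
    if (e %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                    { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- primer_nM * 1e-9
  tm_k <- dH * 1000 / (dS + 1.987 * log(ct / 4))
  tm_k - 273.15
}

#' Design the RT/reverse primer for a small-RNA assay
#'
#' The RT primer carries a generic 5' tail and a 3' target-recognition
#' sequence (TRS), the reverse complement of the template's 3' terminus. The
#' TRS is 8 nt by default and may range 6-12 nt; if the candidate TRS ends in
#' a palindromic tetramer, the length is adjusted (+1 nt first, then -1 nt,
#' then a scan over 6-12) until the 3' terminus is clean. The tail is chosen
#' from `tails` so that the full primer reaches `min_tm` and the tail has no
#' complementary run of 6 nt or more against the template.
#'
#' @param template Small-RNA template, 5'->3', 16-30 nt (RNA or DNA).
#' @param trs_length Preferred TRS length (default 8).
#' @param tails Candidate generic tails; see [default_tail_library()].
#' @param tail Optional explicit tail overriding the library.
#' @param min_tm Minimum acceptable melting temperature of the full primer
#'   in degrees Celsius (default 50).
#' @return An object of class `rt_primer_design` with fields `template`,
#'   `trs`, `trs_length`, `generic_tail`, `full_sequence`, `tm_estimate`.
#' @export
#' @examples
#' design_rt_primer("UAGCAGCACGUAAAUAUUGGCG")
design_rt_primer <- function(template, trs_length = 8L,
                             tails = default_tail_library(), tail = NULL,
                             min_tm = 50) {
  t <- as_dna(template)
  n <- nchar(t)
  if (n < 16L) stop("template too short for RT-primer design (< 16 nt)", call. = FALSE)
  if (n > 30L) stop("template longer than 30 nt is not a small-RNA template", call. = FALSE)
  candidates <- unique(c(trs_length, trs_length + 1L, trs_length - 1L, 6:12))
  candidates <- candidates[candidates >= 6L & candidates <= 12L & candidates <= n]
  chosen <- NULL
  for (L in candidates) {
    trs <- revcomp(substr(t, n - L + 1L, n))
    if (!(terminal_tetramer(trs) %in% palindrome_blocklist())) {
      chosen <- list(L = L, trs = trs)
      break
    }
  }
  if (is.null(chosen)) {
    stop("no TRS length in 6-12 nt clears the palindrome blocklist", call. = FALSE)
  }
  pool <- if (is.null(tail)) tails else c(user = as_dna(tail))
  picked <- NULL
  for (i in seq_along(pool)) {
    tl <- as_dna(pool[[i]])
    if (max_complementary_run(tl, t) >= 6L) next
    full <- paste0(tl, chosen$trs)
    if (nn_tm(full) >= min_tm) { picked <- tl; break }
  }
  if (is.null(picked)) {
    stop("no candidate tail satisfies the hybridization and Tm constraints",
         call. = FALSE)
  }
  full <- paste0(picked, chosen$trs)
  structure(
    list(template = t, trs = chosen$trs, trs_length = chosen$L,
         generic_tail = picked, full_sequence = full,
         tm_estimate = nn_tm(full)),
    class = "rt_primer_design"
  )
}

#' Design the fluorophore-labelled forward primer
#'
#' The forward primer carries a generic 5' region (reverse complement of the
#' anti-primer core, enabling quenching of unincorporated primer) and a 3'
#' gene-specific region in the sense of the template's 5' portion. The
#' gene-specific region must span at least 12 nt, overlap the RT primer's TRS
#' footprint by at most 3 template positions, and end in a non-palindromic
#' tetramer; subject to those constraints the region is maximal (anchored at
#' the template 5' end).
#'
#' @param template The small-RNA template used for the RT primer.
#' @param rt The matching [design_rt_primer()] result.
#' @param anti An [anti_primer()].
#' @param min_specific Minimum gene-specific length (default 12).
#' @param max_overlap Maximum overlap with the TRS footprint in template
#'   positions (default 3).
#' @return An object of class `forward_primer_design` with fields
#'   `generic_region`, `gene_specific_region`, `gene_specific_length`,
#'   `overlap_with_rt`, `full_sequence`.
#' @export
design_forward_primer <- function(template, rt, anti = anti_primer(),
                                  min_specific = 12L, max_overlap = 3L) {
  t <- as_dna(template)
  n <- nchar(t)
  stopifnot(inherits(rt, "rt_primer_design"), inherits(anti, "anti_primer"))
  if (rt$template != t) {
    stop("RT primer was designed for a different template", call. = FALSE)
  }
  L <- rt$trs_length
  e_max <- min(n, n - L + max_overlap)
  chosen_e <- NA_integer_
  for (e in seq.int(e_max, min_specific)) {
    if (e < min_specific) break
    gene <- substr(t, 1L, e)
    if (!(terminal_tetramer(gene) %in% palindrome_blocklist())) {
      chosen_e <- e
      break
    }
  }
  if (is.na(chosen_e)) {
    stop("no gene-specific region of >= ", min_specific,
         " nt with <= ", max_overlap, " nt RT overlap and clean 3' end exists",
         call. = FALSE)
  }
  gene <- substr(t, 1L, chosen_e)
  generic <- revcomp(anti$core)
  structure(
    list(template = t, generic_region = generic, gene_specific_region = gene,
         gene_specific_length = chosen_e,
         overlap_with_rt = max(0L, chosen_e - (n - L)),
         full_sequence = paste0(generic, gene)),
    class = "forward_primer_design"
  )
}

#' Design a complete small-RNA RT-qPCR assay
#'
#' Convenience wrapper running [design_rt_primer()] and
#' [design_forward_primer()] with a shared [anti_primer()].
#'
#' @inheritParams design_rt_primer
#' @inheritParams design_forward_primer
#' @param ... Passed to [design_rt_primer()].
#' @return An object of class `smallrna_assay`: list with `template`, `rt`,
#'   `forward`, `anti`.
#' @export
#' @examples
#' a <- design_assay("UAGCAGCACGUAAAUAUUGGCG")
#' a$rt$trs_length
design_assay <- function(template, anti = anti_primer(), ...) {
  t <- as_dna(template)
  rt <- design_rt_primer(t, ...)
  fwd <- design_forward_primer(t, rt, anti)
  structure(list(template = t, rt = rt, forward = fwd, anti = anti),
            class = "smallrna_assay")
}

#' Design a chemical-ligation qPCR (CL-qPCR) ligator pair
#'
#' CL-qPCR detects heavily modified oligonucleotides (e.g. fully
#' 2'-MOE-modified antagomirs) that resist reverse transcription: two DNA
#' oligos hybridize side-by-side on the analyte, a 3'-phosphorothioate (PS)
#' on the upstream oligo attacks the 5'-biphenylsulphonyl (BPS) leaving group
#' of the downstream oligo, and the resulting carbon-sulphur-linked product
#' is quantified by PCR. The two target-binding cores are obtained by
#' splitting the reverse complement of the analyte at a junction (default
#' `floor(n/2)`, shiftable with `junction_offset`); PCR-primer landing tails
#' are appended outside the cores.
#'
#' @param analyte Analyte sequence, 5'->3', at least 16 nt.
#' @param junction_offset Integer shift of the junction from `floor(n/2)`.
#' @param ps_tail 5' tail of the PS ligator (default the shipped landing
#'   site).
#' @param bps_tail 3' tail of the BPS ligator.
#' @param min_core Minimum core length (default 8).
#' @return An object of class `ligator_pair` with fields `analyte`,
#'   `ps_core`, `bps_core`, `ps_tail`, `bps_tail`, `ps_ligator`,
#'   `bps_ligator`, `junction_index`, `ligated_product`, `palindromic`.
#' @export
#' @examples
#' # miR-16 as the complement of a fully modified anti-miR-16 analyte
#' lig <- design_ligators(revcomp("UAGCAGCACGUAAAUAUUGGCG"), junction_offset = -1)
#' lig$ps_ligator
design_ligators <- function(analyte, junction_offset = 0L,
                            ps_tail = "TTAAACCA", bps_tail = "AACCAGT",
                            min_core = 8L) {
  a <- as_dna(analyte)
  n <- nchar(a)
  if (n < 16L) stop("analyte too short for ligator design (< 16 nt)", call. = FALSE)
  rc <- revcomp(a)
  j <- n %/% 2L + as.integer(junction_offset)
  ps_core <- substr(rc, 1L, j)
  bps_core <- substr(rc, j + 1L, n)
  if (nchar(ps_core) < min_core || nchar(bps_core) < min_core) {
    stop("ligator core shorter than ", min_core, " nt at junction ", j,
         call. = FALSE)
  }
  ps_tail <- as_dna(ps_tail); bps_tail <- as_dna(bps_tail)
  palindromic <- identical(a, rc)
  if (palindromic) {
    warning("analyte is self-reverse-complementary; ligator cores are each ",
            "other's reverse complements", call. = FALSE)
  }
  structure(
    list(analyte = a, ps_core = ps_core, bps_core = bps_core,
         ps_tail = ps_tail, bps_tail = bps_tail,
         ps_ligator = paste0(ps_tail, ps_core),
         bps_ligator = paste0(bps_core, bps_tail),
         junction_index = j,
         ligated_product = paste0(ps_tail, ps_core, bps_core, bps_tail),
         palindromic = palindromic),
    class = "ligator_pair"
  )
}

#' @export
print.rt_primer_design <- function(x, ...) {
  cat(sprintf("<rt_primer_design> 5'-%s|%s-3' (TRS %d nt, Tm %.1f C)\n",
              x$generic_tail, x$trs, x$trs_length, x$tm_estimate))
  invisible(x)
}

#' @export
print.forward_primer_design <- function(x, ...) {
  cat(sprintf("<forward_primer_design> 5'-%s|%s-3' (%d nt specific, %d nt RT overlap)\n",
              x$generic_region, x$gene_specific_region,
              x$gene_specific_length, x$overlap_with_rt))
  invisible(x)
}

#' @export
print.smallrna_assay <- function(x, ...) {
  cat("<smallrna_assay> template", x$template, "\n")
  print(x$rt); print(x$forward)
  cat(sprintf("  anti-primer 5'-%s-%s-3'\n", x$anti$core, x$anti$quencher))
  invisible(x)
}

#' @export
print.ligator_pair <- function(x, ...) {
  cat(sprintf("<ligator_pair> for analyte 5'-%s-3'\n", x$analyte))
  cat(sprintf("  PS-ligator  5'-%s-PS-3'  (core %d nt)\n", x$ps_ligator, nchar(x$ps_core)))
  cat(sprintf("  BPS-ligator 5'-BPS-%s-3' (core %d nt)\n", x$bps_ligator, nchar(x$bps_core)))
  invisible(x)
}

validation_row <- function(rule, pass, detail) {
  tibble::tibble(rule = rule, pass = pass, detail = detail)
}

#' Validate an assay design against the design rules
#'
#' Produces an itemized pass/fail report for a small-RNA assay
#' (`smallrna_assay`, or a bare `rt_primer_design`) or a CL-qPCR
#' `ligator_pair`. The checks mirror the designer's own rules, so designer
#' output always validates; the report is mainly useful for auditing manual
#' edits.
#'
#' @param design A `smallrna_assay`, `rt_primer_design` or `ligator_pair`
#'   (plain lists with the same fields are accepted, so edited designs can be
#'   re-checked).
#' @param max_overlap,min_specific,min_core Rule thresholds (defaults 3, 12,
#'   8).
#' @return A tibble with columns `rule`, `pass`, `detail` and attribute
#'   `overall` (TRUE iff all rules pass); class `assay_validation`.
#' @export
validate_assay <- function(design, max_overlap = 3L, min_specific = 12L,
                           min_core = 8L) {
  rows <- list()
  add <- function(rule, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- validation_row(rule, isTRUE(pass), detail)
  }
  block <- palindrome_blocklist()

  if (!is.null(design$ps_core)) {
    # ligator pair
    rc <- revcomp(design$analyte)
    add("ligator_core_coverage",
        identical(paste0(design$ps_core, design$bps_core), rc),
        "PS + BPS cores concatenate to the analyte reverse complement")
    add("ligator_core_lengths",
        nchar(design$ps_core) >= min_core && nchar(design$bps_core) >= min_core,
        sprintf("cores %d/%d nt, minimum %d", nchar(design$ps_core),
                nchar(design$bps_core), min_core))
    add("ligator_tail_hybridization",
        max_complementary_run(design$ps_tail, design$analyte) < 6L &&
          max_complementary_run(design$bps_tail, design$analyte) < 6L,
        "tails have no >= 6 nt complementary run against the analyte")
  } else {
    rt <- if (!is.null(design$rt)) design$rt else design
    template <- design$template %||% rt$template
    if (!is.null(rt$trs)) {
      n <- nchar(template); L <- rt$trs_length
      add("trs_length_bounds", L >= 6L && L <= 12L,
          sprintf("TRS %d nt within 6-12", L))
      add("trs_identity",
          identical(rt$trs, revcomp(substr(template, n - L + 1L, n))),
          "TRS is the reverse complement of the template 3' terminus")
      add("rt_3prime_palindrome",
          !(terminal_tetramer(rt$full_sequence) %in% block),
          sprintf("RT primer 3' tetramer -%s", terminal_tetramer(rt$full_sequence)))
      add("rt_tail_hybridization",
          max_complementary_run(rt$generic_tail, template) < 6L,
          "generic tail has no >= 6 nt complementary run against the template")
    }
    fwd <- design$forward
    if (!is.null(fwd)) {
      add("forward_specific_length",
          fwd$gene_specific_length >= min_specific,
          sprintf("gene-specific region %d nt, minimum %d",
                  fwd$gene_specific_length, min_specific))
      n <- nchar(template); L <- rt$trs_length
      true_overlap <- max(0L, fwd$gene_specific_length - (n - L))
      add("forward_rt_overlap", true_overlap <= max_overlap,
          sprintf("overlap %d nt, maximum %d", true_overlap, max_overlap))
      add("forward_3prime_palindrome",
          !(terminal_tetramer(fwd$full_sequence) %in% block),
          sprintf("forward primer 3' tetramer -%s",
                  terminal_tetramer(fwd$full_sequence)))
      if (!is.null(design$anti)) {
        add("anti_primer_complementarity",
            identical(fwd$generic_region, revcomp(design$anti$core)),
            "forward generic region is the reverse complement of the anti-primer core")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "overall") <- all(out$pass)
  class(out) <- c("assay_validation", class(out))
  out
}

#' Overall pass/fail of a validation report
#' @param report An `assay_validation` tibble.
#' @return Logical scalar.
#' @export
validation_passed <- function(report) isTRUE(attr(report, "overall"))

#' Tidy methods for assay designs
#'
#' One-row tibble summaries in the broom style.
#'
#' @param x A design object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-designs
NULL

#' @rdname tidy-designs
#' @method tidy rt_primer_design
#' @export
tidy.rt_primer_design <- function(x, ...) {
  tibble::tibble(part = "rt_primer", sequence = x$full_sequence,
                 trs = x$trs, trs_length = x$trs_length,
                 tail = x$generic_tail, tm = x$tm_estimate)
}

#' @rdname tidy-designs
#' @method tidy forward_primer_design
#' @export
tidy.forward_primer_design <- function(x, ...) {
  tibble::tibble(part = "forward_primer", sequence = x$full_sequence,
                 gene_specific = x$gene_specific_region,
                 gene_specific_length = x$gene_specific_length,
                 overlap_with_rt = x$overlap_with_rt)
}

#' @rdname tidy-designs
#' @method tidy smallrna_assay
#' @export
tidy.smallrna_assay <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$rt), template = x$template, .before = 1),
    dplyr::mutate(tidy(x$forward), template = x$template, .before = 1),
    tibble::tibble(template = x$template, part = "anti_primer",
                   sequence = x$anti$core)
  )
}

#' @rdname tidy-designs
#' @method tidy ligator_pair
#' @export
tidy.ligator_pair <- function(x, ...) {
  tibble::tibble(
    part = c("ps_ligator", "bps_ligator", "ligated_product"),
    sequence = c(x$ps_ligator, x$bps_ligator, x$ligated_product),
    core = c(x$ps_core, x$bps_core, NA),
    tail = c(x$ps_tail, x$bps_tail, NA),
    junction_index = x$junction_index
  )
}

#' Write designs as annotated FASTA
#'
#' @param design A `smallrna_assay` or `ligator_pair`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_design_fasta <- function(design, path) {
  tab <- tidy(design)
  lines <- unlist(purrr::map2(tab$part, tab$sequence,
                              function(p, s) c(paste0(">", p), s)))
  writeLines(lines, path)
  invisible(path)
}
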