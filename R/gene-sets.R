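#' Built-in gene-set catalog for the RA robustness analysis
#'
#' Two gene sets drive the trajectory analysis: the RA metabolic network genes
#' (the feedback machinery that senses and corrects RA level changes) and the
#' hox genes (direct RA targets, read out as the phenotypic outcome of a
#' perturbation). Identifiers follow the Xenopus laevis homeolog convention
#' (`.L` / `.S` chromosome copies).
#'
#' @return A named list of character vectors: `ra_network` (16 ids) and
#'   `hox` (6 ids).
#' @examples
#' ra_gene_sets()$hox
#' @export
ra_gene_sets <- function() {
  list(
    ra_network = c(
      "aldh1a2.L", "aldh1a3.L", "crabp2.L", "crabp2.S",
      "cyp26a1.L", "cyp26a1.S", "cyp26c1.L", "cyp26c1.S",
      "dhrs3.L", "rbp1.L", "rdh10.L", "rdh10.S",
      "rdh13.L", "rdh14.L", "sdr16c5.L", "stra6.L"
    ),
    hox = c(
      "hoxa1.L", "hoxa1.S", "hoxa3.S", "hoxb1.S", "hoxb4.S", "hoxd4.L"
    )
  )
}

# RA network members whose transcription rises when RA rises (degraders /
# suppressors of signaling); the remainder are planted as RA producers or
# transporters that fall when RA rises.
ra_network_up_with_ra <- function() {
  c("cyp26a1.L", "cyp26a1.S", "cyp26c1.L", "cyp26c1.S", "dhrs3.L")
}
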