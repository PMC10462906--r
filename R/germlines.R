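# Bundled synthetic germline segment set. These are synthetic stand-in
# segments (stop-free in reading frame, fixed lengths) named after common
# human IGHV/IGHJ genes so that gene-level and subgroup-level logic can be
# exercised without an external germline database. All V segments are 240 nt
# (FWR1 through FWR3), all J segments 36 nt (FWR4); the junction (which
# carries the conserved Cys104/Trp118 codons) sits between them.

.TOY_V <- c(
  "IGHV1-2" = "TATTCGAAAGGCGGAGCGTACATTTATCATCGCTCAGCGGGCTCGAATCCCTGCACTCATGAATGGGGCATCGCGTCGAAGTTGCCACCCACGCTCGGGGAAATTGAGATGCGCTTCCTGAACTCCATTAGAGCGACATCCTACTTGCTCCCAACAACGGGTACTCCGCGCAGCTATTCTTGCACTGCAGCACAAGCTGAAAGTGCCCAACGTAGGATTGGAGGGCCAGAGTATCGGGCG",
  "IGHV1-18" = "TTGATGCGAGTCCTACCCCGACTGCCGGTCCACTCGCTCGGTAATCCACTCAGTCAATACCGCTATTACCCAAATGGGCGTGGGGCCGCGTGTGCGCGGATGTACATCGTATCTAGTACCCAGCACAGTGTTGTCGACGTGCGATGTGCCCTGTGTATTGATAGAGTCCGTAGGAAAGTATTACCACGACGTCACTGCCTGATGATGGGTGAGCTTTGTGTCGGCCCTCAGGACAATTTA",
  "IGHV1-46" = "CATGCAGGTCATCTGTCGCACTATAGTTATACTAAGACGTTCCAGGCATCCAGGAAGGCACCCGTTAACACGATGAGCGTTCTATGCTGGAAACAAGGTCGCACGGGCCTCCTGTTTTTAACGGTTCAAAAGCAGATCGGATGTCTCAGTTCGGGATATTATCCACCGTTATTACTCATTGAGTCGCCGAGTTGCAAGTTGCTGGCTATTCAGGACCTTATCTTCGCTGCGCCCATAGAC",
  "IGHV1-69" = "CGAGACGTAAAGGTTTATTTTGCTAAAGACGAGCTCCAAAAGAGACACGAATCGGTACTAAAATTCCCTGTTAAGTCGCATGGTGCACGTCACGGATCACGATGGGGCGAATACTCTCATCTCGTTAACGTCTGTCCCGGCCACAGTCGCGAGTTTAGGCTGTGGTCCTGCAGTAGTCCCCGTAGTATTTTGTCGCTGAACGCCACGGGCAGGAAATTAGATTATATACTCTACCGTACG",
  "IGHV2-5" = "ATTATGGCGCCCAACTTTTCATATATCTTCCCATCCCCCACTATTTGGATACTCAGGATGCGAAGCTGCCCTTGGATAACCCTCGCCGCGATGTCCGGCAGTCTTTATTTCCTTGCCGTGGCCGCACATTGGGGACGCACTCGTTCATTACTATCTCCTGGATGTGGCTCGCAACCGACGATCAATAAGATCCACGCGGGTTCTCGCAGGGCTGCCCCCATAATTGAGCTTTTACTCGAG",
  "IGHV2-70" = "GTCGCGTTGCAGAGGTCCGTGTTTTCAGTGCCAAAGCAGTACCGGGTAATTTTCAGTCAACTCGAAGAGCATGTCCCCCTGCGAAGTGGATCACCTCTCTACGGCGTGGGACGAACCAACAATCGTGAATCCTTTCCCATGACGAGCGACTACACCAATGACTTCGGATCGTTGACTCCTCCTGGAGATACGATTACAGGCTGCTTTCGGGAGAATGCTTCCCCTGTGACCGCAGTGGGC",
  "IGHV3-23" = "TTCATGCGGCCTGGCCAAAGGCGAGGTATAGCAAAGCCATTAATGCATAAATGGGGATATCTATCCAAACTGTGTACAGAACTTTCTAGGTTTCTTCCAATGCCCACGAGCGCGTGTTGTCCCCGAATCAATAATGAAAAGTACGGAGAGGGGCCCTCTTCGGCAGTCAATACAATCCGAGGGAGCGATTGCCTAGGAAATCGTCTGAGCAGTTGTATCACGCACAATGGCCTCAACTAT",
  "IGHV3-30" = "AGGAGCTTTACCGGAGTAAGGAAAATATTGTGCATTGGACTTTTGAACGACCATAGAGCGGCAGGAGTTATCCCCGGTGGCCGCCACGTGCACCCTGAAGGTCAGGCCCGGGAAGGAGCCATGTCAACCGTCTTGATGCGTAATCGCGTCGGTTTCCTGTTGCCGATGCCTACGCGGGCTGCCTCTCTGATTCTGTGCGAGTCTGCAATTAGCATGTGGGTTGTGGTTTTGTACCATGCC",
  "IGHV3-74" = "GAGATAGGGTTGTTACAAAGGTTGCCGCTCTTGCACCCTCACTTGTTGAGATGTTTTCGTTTGAGGAGGAGAATTAAGTCGAGCTGGGGACTTGTTATTATAATCAGCGAGTCCAACACAGTTCGGCTGGGAAGAAAGCTCCCGTTGCCCCGTGGTGATAGACAGGAATGGGATATAGTACGGTACCGGGCCCCAAAGGGTCCCTACCGGTATATTGAAGATAGAACCACTGGAAACTTT",
  "IGHV4-34" = "CTACCGGCTGATCAGTTTAGTATGACGGGGAAAGTATCAATAATAGTATCGACGAACTCGTTATCGTGCTATCTCTACCTTAGTGACACTCGGTTGACGCTATTCCCGCCCTGCGGCAGACCCCTCCGTAATGAGGGTAATGCCGGTACTGGTACGCCAATGCTAGAAATTTACACTACTCATAAAAGACCTGGGTTCCCCCCTACGGCCGCTACCTTTATTCTGCATTACGGGCGCATG",
  "IGHV4-59" = "GTCACGTCCACAAGCGACGTGCGTCCCCCTCGGCGAACCGCCCTGCTGGTGGACACGGCTTCATATACATTGCCTAAACTCGACGCGTGTACGATCGTCTGCTGTGCCGGGCCGATTGTAACGCGTGCGTGGCTGCTCGGACAGAATATCGAGAAATTAGCTATTTCTCAGCTCCTGCAGTGGTTCCCTTCGTCTACGTGGCCGCGCGTGACGCTTCGCTTTCTCGATTACTTCTCCTGC",
  "IGHV5-51" = "TATCCCAAGGGGTTCAGACCTCATGGCATTAGGCCGAAATTCCATACACTCTGGGAGCTGGCACCCTTACGACTCAAGCGCGCAGTGTCCTATATACTTCGATACCTGACCGAGCTGTATTATGGGATAACTGAGCGTAGGACGAATTCGAAATTCTGTCGTTACGTTACAAACTCATTAGGACCGTCACCACGCAGGCCAGCCACTTGGCCGGAACGATTGATCGTCATCCGGATGGAC"
)

.TOY_J <- c(
  "IGHJ1" = "ACGCCCTATTGCCTACGCCGCAGGTTCTCCTTCCCT",
  "IGHJ4" = "GGAGATGAGATGTCAGGCCGCCAAGCGGCTAGACAT",
  "IGHJ5" = "TTAGACATTTCGTATGACCACCAGATTGCTGGCAGG",
  "IGHJ6" = "GAATTACGAGGTGTGCGTCGACGCAATGAAGCGCCG"
)

.TOY_D <- c(
  "IGHD1" = "AAAAATCTTCGTCTGCTC",
  "IGHD2" = "TAAGAGGGCTGGGCG",
  "IGHD3" = "GGATAAATGTGTTCGATG",
  "IGHD4" = "AACCTGCTCAGCAATGCTGGAGCG",
  "IGHD5" = "CACGGACCACATGCATTGTTA",
  "IGHD6" = "AGCAACAGGCCAAGTTCACGC"
)

# Fixed region layout (0-based, half-open) on the 240-nt V segment.
.V_REGIONS <- list(
  fwr1 = c(0L, 75L),
  cdr1 = c(75L, 99L),
  fwr2 = c(99L, 150L),
  cdr2 = c(150L, 174L),
  fwr3 = c(174L, 240L)
)
.V_LEN <- 240L
.J_LEN <- 36L

#' Bundled synthetic germline segments
#'
#' Returns the package's synthetic IGHV/IGHJ/IGHD segment set used by the
#' repertoire generator and by lineage-tree root construction. Segments are
#' synthetic sequences (not real germline alleles) with fixed lengths:
#' V = 240 nt covering FWR1-FWR3, J = 36 nt covering FWR4.
#'
#' @return list with character vectors `v`, `j`, `d` (named by gene) and the
#'   region layout `v_regions` (0-based, half-open intervals on the V
#'   segment).
#' @export
toy_germlines <- function() {
  list(v = .TOY_V, j = .TOY_J, d = .TOY_D, v_regions = .V_REGIONS)
}
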