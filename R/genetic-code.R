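#' The invertebrate mitochondrial genetic code (translation table 5)
#'
#' Returns the codon table used throughout the package: NCBI translation
#' table 5, in which AGA/AGG encode serine, ATA methionine and TGA
#' tryptophan, leaving TAA and TAG as the only stop codons (62 sense
#' codons). For relative synonymous codon usage the leucine and serine
#' codons are split into their two codon boxes — Leu1 (CUN), Leu2 (UUR),
#' Ser1 (AGN), Ser2 (UCN) — so every sense codon belongs to exactly one
#' synonymous family.
#'
#' @return Data frame with one row per codon (DNA alphabet): `codon`,
#'   `aa` (one-letter amino acid, `*` for stop), `family` (RSCU family
#'   label), `family_size`, `is_stop`.
#' @examples
#' ct <- mito_codon_table()
#' sum(!ct$is_stop)  # 62 sense codons
#' @export
mito_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # translation table 5 in TCAG order
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIMMTTTTNNKKSSSS",   # ATT..AGG (ATA=M, AGA/AGG=S)
    "VVVVAAAADDEEGGGG"), "")[[1]]
  names(aa) <- codons
  fam <- character(64); names(fam) <- codons
  fam[substr(codons, 1, 2) == "CT"] <- "Leu1"
  fam[codons %in% c("TTA", "TTG")] <- "Leu2"
  fam[substr(codons, 1, 2) == "AG"] <- "Ser1"
  fam[substr(codons, 1, 2) == "TC"] <- "Ser2"
  aa_names <- c(F = "Phe", Y = "Tyr", C = "Cys", W = "Trp", P = "Pro",
                H = "His", Q = "Gln", R = "Arg", I = "Ile", M = "Met",
                T = "Thr", N = "Asn", K = "Lys", V = "Val", A = "Ala",
                D = "Asp", E = "Glu", G = "Gly", `*` = "Stop")
  rest <- fam == ""
  fam[rest] <- aa_names[aa[rest]]
  out <- data.frame(codon = codons, aa = unname(aa), family = unname(fam),
                    stringsAsFactors = FALSE)
  out$is_stop <- out$aa == "*"
  fs <- table(out$family[!out$is_stop])
  out$family_size <- ifelse(out$is_stop, 0L, as.integer(fs[out$family]))
  out
}

# display helper: DNA codon -> RNA codon
codon_to_rna <- function(codon) chartr("T", "U", codon)
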