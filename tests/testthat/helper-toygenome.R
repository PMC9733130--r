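# A small synthetic genome with four transcripts exercising every branch
# of promoter extraction: plain plus strand, chromosome-start clipping,
# single exon (no intron), and minus strand. A known motif is planted in
# chosen promoter regions so presence/absence is exact by construction.

# non-palindromic so the reverse complement never matches the motif itself
toy_motif <- "AACGTGATCCGA"
toy_motif_rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(toy_motif, "")[[1]])),
                      collapse = "")

make_toy_genome <- function() {
  set.seed(81)
  chrlen <- 9000L
  chr <- sample(c("A", "C", "G", "T"), chrlen, replace = TRUE)
  # avoid accidental occurrences in either orientation, then plant deliberately
  genome_str <- paste(chr, collapse = "")
  for (pat in c(toy_motif, toy_motif_rc)) {
    while (grepl(pat, genome_str, fixed = TRUE)) {
      pos <- regexpr(pat, genome_str, fixed = TRUE)
      chr[pos] <- if (chr[pos] == "A") "C" else "A"
      genome_str <- paste(chr, collapse = "")
    }
  }
  # plant forward at 6500 (inside txPlus's upstream window only) and the
  # reverse complement in txMinus's first intron, so the sense-strand
  # promoters of exactly txPlus and txMinus carry the motif
  chr[6500:6511] <- strsplit(toy_motif, "")[[1]]
  chr[2150:2161] <- strsplit(toy_motif_rc, "")[[1]]
  paste(chr, collapse = "")
}

write_toy_annotation <- function(gff_path) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tmRNA\t7001\t7800\t.\t+\t.\tID=txPlus",
    "chr1\ttoy\texon\t7001\t7200\t.\t+\t.\tParent=txPlus",
    "chr1\ttoy\texon\t7501\t7800\t.\t+\t.\tParent=txPlus",
    "chr1\ttoy\tmRNA\t100\t400\t.\t+\t.\tID=txClip",
    "chr1\ttoy\texon\t100\t200\t.\t+\t.\tParent=txClip",
    "chr1\ttoy\texon\t300\t400\t.\t+\t.\tParent=txClip",
    "chr1\ttoy\tmRNA\t5000\t5400\t.\t+\t.\tID=txSingle",
    "chr1\ttoy\texon\t5000\t5400\t.\t+\t.\tParent=txSingle",
    "chr1\ttoy\tmRNA\t2000\t2600\t.\t-\t.\tID=txMinus",
    "chr1\ttoy\texon\t2400\t2600\t.\t-\t.\tParent=txMinus",
    "chr1\ttoy\texon\t2000\t2100\t.\t-\t.\tParent=txMinus"
  )
  writeLines(lines, gff_path)
  gff_path
}

toy_promoters <- function() {
  genome <- make_toy_genome()
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 toy", genome), fa)
  gff <- write_toy_annotation(tempfile(fileext = ".gff3"))
  list(promoters = extract_promoters(gff, fa), genome = genome)
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}
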