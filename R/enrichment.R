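# Promoter-motif enrichment. Promoters are defined as up to 6000 nt
# upstream of the annotated TSS plus the first intron (in transcript
# order), joined by a 20-N linker so motif hits cannot span the junction.
# Motif occurrences come from an external FIMO-style scan; the statistics
# here are hypergeometric enrichment against the scanned universe, with
# BH correction across motifs within each transcript cluster.

#' Extract promoter sequences from a GFF3 annotation and genome FASTA
#'
#' For each transcript, takes the `upstream` nucleotides 5' of the
#' annotated transcription start site (clipped at the chromosome edge),
#' concatenates a linker of `linker` Ns and the first intron (the gap
#' between exon 1 and exon 2 in transcript order), and reports the result
#' on the transcript's sense strand (reverse-complemented for minus-strand
#' transcripts). Single-exon transcripts get the upstream segment only,
#' with no linker.
#'
#' @param annotation Path to a GFF3 file, or a `GRanges` imported from
#'   one. Transcript features (`type` of `mRNA` or `transcript`) must
#'   carry an `ID`; exons must carry a `Parent`.
#' @param genome Path to a FASTA file, or a `Biostrings::DNAStringSet`
#'   named by chromosome.
#' @param upstream Upstream window size in nucleotides (default 6000).
#' @param linker Number of Ns between upstream segment and first intron.
#' @return A tibble with columns `transcript_id`, `sequence`, `chrom`,
#'   `strand`, `upstream_start`, `upstream_end`, `intron_start`,
#'   `intron_end` (1-based inclusive; `NA` when there is no intron).
#'   Transcripts on contigs absent from the genome are skipped with a
#'   warning.
#' @export
extract_promoters <- function(annotation, genome, upstream = 6000L,
                              linker = 20L) {
  if (is.character(annotation)) {
    annotation <- rtracklayer::import(annotation, format = "gff3")
  }
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  feat_type <- as.character(annotation$type)
  tx <- annotation[feat_type %in% c("mRNA", "transcript")]
  exons <- annotation[feat_type == "exon"]
  if (length(tx) == 0L) abort("no mRNA/transcript features in the annotation.")
  exon_parent <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))

  rows <- lapply(seq_along(tx), function(i) {
    t1 <- tx[i]
    id <- t1$ID
    chrom <- as.character(GenomicRanges::seqnames(t1))
    if (!chrom %in% names(genome)) {
      warning("skipping ", id, ": contig ", chrom, " not in genome",
              call. = FALSE)
      return(NULL)
    }
    chrlen <- length(genome[[chrom]])
    strand <- as.character(GenomicRanges::strand(t1))
    plus <- strand != "-"
    tss <- if (plus) GenomicRanges::start(t1) else GenomicRanges::end(t1)

    if (plus) {
      up_start <- max(1L, tss - upstream)
      up_end <- tss - 1L
    } else {
      up_start <- tss + 1L
      up_end <- min(chrlen, tss + upstream)
    }
    if (up_end < up_start) {
      up_seq <- Biostrings::DNAString("")
      up_start <- NA_integer_; up_end <- NA_integer_
    } else {
      up_seq <- Biostrings::subseq(genome[[chrom]], up_start, up_end)
    }

    ex <- exons[exon_parent == id]
    intron_start <- NA_integer_; intron_end <- NA_integer_
    intron_seq <- NULL
    if (length(ex) >= 2L) {
      ord <- order(GenomicRanges::start(ex), decreasing = !plus)
      ex <- ex[ord]
      if (plus) {
        intron_start <- GenomicRanges::end(ex[1]) + 1L
        intron_end <- GenomicRanges::start(ex[2]) - 1L
      } else {
        intron_start <- GenomicRanges::end(ex[2]) + 1L
        intron_end <- GenomicRanges::start(ex[1]) - 1L
      }
      if (intron_end >= intron_start) {
        intron_seq <- Biostrings::subseq(genome[[chrom]], intron_start, intron_end)
      } else {
        intron_start <- NA_integer_; intron_end <- NA_integer_
      }
    }

    # promoter order is transcript order: upstream, linker, first intron —
    # each segment reverse-complemented individually on the minus strand
    if (!plus) {
      up_seq <- Biostrings::reverseComplement(up_seq)
      if (!is.null(intron_seq)) {
        intron_seq <- Biostrings::reverseComplement(intron_seq)
      }
    }
    joined <- if (is.null(intron_seq)) {
      up_seq
    } else {
      Biostrings::xscat(up_seq, paste(rep("N", linker), collapse = ""), intron_seq)
    }

    tibble(
      transcript_id = id,
      sequence = as.character(joined),
      chrom = chrom, strand = strand,
      upstream_start = up_start, upstream_end = up_end,
      intron_start = intron_start, intron_end = intron_end
    )
  })
  dplyr::bind_rows(rows)
}

#' Load a FIMO-style motif scan into a presence/absence table
#'
#' Reads the tab-separated occurrence table produced by a motif scanner,
#' keeps occurrences at or below the per-occurrence p-value threshold
#' (default 5e-5) and collapses them to per-promoter presence/absence for
#' each motif.
#'
#' @param path Path to the scan TSV (comment lines starting with `#`
#'   ignored). Must contain columns `motif_id`, `sequence_name` and
#'   `p-value` (or `p_value`); extra columns are ignored.
#' @param universe Character vector of all scanned promoter ids (the
#'   background). Defaults to the sequence names present in the file,
#'   but passing the full scanned set explicitly is strongly preferred:
#'   promoters with no occurrence at all otherwise vanish from the
#'   background.
#' @param p_thresh Per-occurrence p-value cutoff.
#' @return A list of class `motif_table` with elements `universe`
#'   (character) and `hits` (tibble `motif_id`, `transcript_id`, distinct).
#' @export
load_fimo <- function(path, universe = NULL, p_thresh = 5e-5) {
  raw <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- sub("^#\\s*", "", names(raw))
  names(raw)[names(raw) == "p-value"] <- "p_value"
  names(raw)[names(raw) == "pattern name"] <- "motif_id"
  names(raw)[names(raw) == "sequence name"] <- "sequence_name"
  need <- c("motif_id", "sequence_name", "p_value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("motif scan is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  hits <- raw |>
    filter(.data$p_value <= p_thresh) |>
    dplyr::transmute(motif_id = as.character(.data$motif_id),
                     transcript_id = as.character(.data$sequence_name)) |>
    distinct()
  if (is.null(universe)) universe <- unique(as.character(raw$sequence_name))
  if (!all(hits$transcript_id %in% universe)) {
    abort("scan contains sequences outside the declared universe.")
  }
  structure(list(universe = universe, hits = hits), class = "motif_table")
}

#' Construct a motif presence/absence table directly
#'
#' @param universe Character vector of all promoter ids scanned.
#' @param hits Tibble/data frame with columns `motif_id`, `transcript_id`.
#' @return A `motif_table` object, as from [load_fimo()].
#' @export
motif_table <- function(universe, hits) {
  hits <- distinct(tibble(motif_id = as.character(hits$motif_id),
                          transcript_id = as.character(hits$transcript_id)))
  if (!all(hits$transcript_id %in% universe)) {
    abort("`hits` reference promoters outside `universe`.")
  }
  structure(list(universe = universe, hits = hits), class = "motif_table")
}

#' Hypergeometric motif enrichment in a transcript cluster
#'
#' For each motif, tests whether the cluster contains more promoters with
#' at least one motif occurrence than expected from the occurrence rate in
#' the whole universe: the upper-tail hypergeometric probability
#' P(X >= k) with k hits among the n cluster promoters, K hits among the
#' M universe promoters. p-values are BH-corrected across motifs within
#' the cluster.
#'
#' @param cluster Character vector of transcript ids (must be a subset of
#'   the table's universe, and at least `min_cluster` of them).
#' @param table A `motif_table`.
#' @param min_cluster Minimum cluster size (default 10).
#' @return A tibble with columns `motif_id`, `k`, `n`, `K`, `M`,
#'   `p_value`, `q_value`, sorted by p-value.
#' @export
motif_enrichment <- function(cluster, table, min_cluster = 10L) {
  cluster <- unique(cluster)
  if (!all(cluster %in% table$universe)) {
    abort("cluster contains transcripts outside the scanned universe.")
  }
  if (length(cluster) < min_cluster) {
    abort(paste0("cluster has fewer than ", min_cluster, " transcripts."))
  }
  M <- length(table$universe)
  n <- length(cluster)
  by_motif <- split(table$hits$transcript_id, table$hits$motif_id)
  res <- purrr::imap_dfr(by_motif, function(promoters, motif) {
    K <- length(unique(promoters))
    k <- length(intersect(promoters, cluster))
    p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
    tibble(motif_id = motif, k = k, n = n, K = K, M = M, p_value = min(p, 1))
  })
  res$q_value <- bh_qvalues(res$p_value)
  arrange(res, .data$p_value)
}

#' Welch comparisons of rhythmicity and expression by motif presence
#'
#' Within a transcript cluster, splits transcripts into motif-present and
#' motif-absent groups for each motif and compares their RP24 scores and
#' median expression levels with Welch's unequal-variance t-test. Groups
#' smaller than 2 are reported as untestable.
#'
#' @param cluster Character vector of transcript ids.
#' @param table A `motif_table`.
#' @param stats Score table with columns `transcript_id`, `rp24`,
#'   `median_expr` (one row per transcript; filter to one condition
#'   first).
#' @return A tibble with per-motif group sizes and, for each of the two
#'   response variables, the t statistic and two-sided p (`NA` with
#'   `testable = FALSE` when a group is too small).
#' @export
motif_effect_tests <- function(cluster, table, stats) {
  stats <- stats[stats$transcript_id %in% cluster, ]
  if (anyDuplicated(stats$transcript_id)) {
    abort("`stats` must have one row per transcript; filter to one condition.")
  }
  by_motif <- split(table$hits$transcript_id, table$hits$motif_id)
  welch <- function(x, y) {
    if (sum(!is.na(x)) < 2L || sum(!is.na(y)) < 2L) {
      return(c(NA_real_, NA_real_))
    }
    res <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) c(NA_real_, NA_real_) else c(unname(res$statistic), res$p.value)
  }
  purrr::imap_dfr(by_motif, function(promoters, motif) {
    present <- stats[stats$transcript_id %in% promoters, ]
    absent <- stats[!stats$transcript_id %in% promoters, ]
    rp <- welch(present$rp24[is.finite(present$rp24)],
                absent$rp24[is.finite(absent$rp24)])
    ex <- welch(present$median_expr, absent$median_expr)
    tibble(
      motif_id = motif,
      n_present = nrow(present), n_absent = nrow(absent),
      testable = nrow(present) >= 2L && nrow(absent) >= 2L,
      t_rp24 = rp[1], p_rp24 = rp[2],
      t_expr = ex[1], p_expr = ex[2]
    )
  })
}
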