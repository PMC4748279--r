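# Genomic feature summaries contrasting lincRNAs with protein-coding
# transcripts: exon lengths, exon counts per transcript, and GC content
# of the spliced transcript sequence.

read_gtf_exons <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0) stop("GTF contains no exon features")
  biotype <- exons$transcript_biotype
  if (is.null(biotype)) biotype <- exons$gene_biotype
  if (is.null(biotype))
    stop("GTF exons need a transcript_biotype (or gene_biotype) attribute")
  all_tx <- unique(gr$transcript_id[!is.na(gr$transcript_id)])
  no_exon <- setdiff(all_tx, unique(exons$transcript_id))
  if (length(no_exon) > 0)
    warning("transcript(s) without exon lines skipped: ",
            paste(no_exon, collapse = ", "))
  df <- as.data.frame(exons)
  data.frame(transcript = exons$transcript_id,
             biotype = biotype,
             seqname = as.character(df$seqnames),
             start = df$start,
             end = df$end,
             length = df$width,
             stringsAsFactors = FALSE)
}

#' Exon length and exon count summaries per biotype
#'
#' Exon coordinates follow the GTF convention (1-based, closed), so an
#' exon's length is end - start + 1. For each biotype the proportion of
#' transcripts having k exons is reported for every observed k.
#'
#' @param gtf_path GTF file with exon features whose transcripts carry a
#'   \code{transcript_biotype} (or \code{gene_biotype}) attribute, e.g.
#'   \code{lincRNA} vs \code{protein_coding}.
#' @return List with \code{exon_lengths} (data frame: \code{biotype},
#'   \code{transcript}, \code{length}) and \code{exon_count_proportions}
#'   (data frame: \code{biotype}, \code{n_exons}, \code{n_transcripts},
#'   \code{proportion}).
#' @export
exon_summaries <- function(gtf_path) {
  ex <- read_gtf_exons(gtf_path)
  lengths <- ex[order(ex$biotype, ex$transcript),
                c("biotype", "transcript", "length")]
  rownames(lengths) <- NULL
  per_tx <- aggregate(list(n_exons = ex$start),
                      by = list(biotype = ex$biotype,
                                transcript = ex$transcript), FUN = length)
  props <- do.call(rbind, lapply(split(per_tx, per_tx$biotype), function(d) {
    tab <- table(d$n_exons)
    data.frame(biotype = d$biotype[1], n_exons = as.integer(names(tab)),
               n_transcripts = as.integer(tab),
               proportion = as.numeric(tab) / nrow(d))
  }))
  rownames(props) <- NULL
  list(exon_lengths = lengths, exon_count_proportions = props)
}

#' GC content of spliced transcripts
#'
#' Concatenates each transcript's exonic sequence (GTF coordinates
#' against the FASTA) and reports (G+C)/(A+C+G+T); ambiguous bases are
#' excluded from both numerator and denominator. GC fraction is
#' strand-symmetric, so minus-strand transcripts are not
#' reverse-complemented.
#'
#' @param fasta_path genome FASTA.
#' @param gtf_path GTF with exon features (see
#'   \code{\link{exon_summaries}}).
#' @return Data frame with columns \code{transcript}, \code{biotype},
#'   \code{gc}.
#' @export
gc_content <- function(fasta_path, gtf_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ex <- read_gtf_exons(gtf_path)
  res <- lapply(split(ex, ex$transcript), function(d) {
    sq <- d$seqname[1]
    if (!sq %in% names(seqs))
      stop(sprintf("transcript '%s': sequence '%s' absent from FASTA",
                   d$transcript[1], sq))
    if (any(d$start < 1) || any(d$end > Biostrings::width(seqs[sq])))
      stop(sprintf("transcript '%s': exon outside sequence bounds",
                   d$transcript[1]))
    d <- d[order(d$start), , drop = FALSE]
    spliced <- paste0(substring(as.character(seqs[[sq]]), d$start, d$end),
                      collapse = "")
    lf <- Biostrings::letterFrequency(Biostrings::DNAString(spliced),
                                      c("A", "C", "G", "T"))
    counts <- setNames(as.numeric(lf), c("A", "C", "G", "T"))
    denom <- sum(counts)
    data.frame(transcript = d$transcript[1], biotype = d$biotype[1],
               gc = if (denom == 0) NA_real_
                    else unname((counts["G"] + counts["C"]) / denom))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
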