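#' Construct a gene model
#'
#' @param gene_id identifier
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param exons data.frame `start`, `end` of the CDS exons in genomic
#'   coordinates (1-based inclusive); total length must be a multiple of 3
#' @param gene_start,gene_end full gene span
#' @param gene_seq plus-strand sequence of `[gene_start, gene_end]`
#'   (character or `DNAString`)
#' @return a [GeneModel-class]
#' @export
geneModel <- function(gene_id, chrom, strand, exons, gene_start, gene_end,
                      gene_seq) {
  if (is.character(gene_seq)) gene_seq <- Biostrings::DNAString(gene_seq)
  new("GeneModel", geneId = gene_id, chrom = as.character(chrom),
      strand = strand, exons = as.data.frame(exons),
      geneStart = gene_start, geneEnd = gene_end, geneSeq = gene_seq)
}

#' Read a gene model from an exon table and FASTA
#'
#' The exon table is tab-separated with a header
#' `gene_id chrom strand start end` (one row per CDS exon); the FASTA holds
#' one record whose sequence is the plus strand of the gene span and whose
#' name is `<gene_id>:<gene_start>-<gene_end>`.
#'
#' @param exon_path,fasta_path file paths
#' @return a [GeneModel-class]
#' @export
readGeneModel <- function(exon_path, fasta_path) {
  ex <- read.table(exon_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(ex)))
    stop("exon table needs columns: ", paste(need, collapse = ", "))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- names(seqs)[1]
  m <- regmatches(nm, regexec("^(\\S+):(\\d+)-(\\d+)", nm))[[1]]
  if (length(m) != 4)
    stop("FASTA record name must be '<gene_id>:<start>-<end>', got: ", nm)
  geneModel(gene_id = ex$gene_id[1], chrom = ex$chrom[1],
            strand = ex$strand[1],
            exons = ex[, c("start", "end")],
            gene_start = as.numeric(m[3]), gene_end = as.numeric(m[4]),
            gene_seq = seqs[[1]])
}

#' Write a gene model to the exon-table + FASTA interchange format
#'
#' @param gene_model a [GeneModel-class]
#' @param exon_path,fasta_path output paths
#' @export
writeGeneModel <- function(gene_model, exon_path, fasta_path) {
  ex <- data.frame(gene_id = gene_model@geneId, chrom = gene_model@chrom,
                   strand = gene_model@strand,
                   start = gene_model@exons$start,
                   end = gene_model@exons$end)
  write.table(ex, exon_path, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(gene_model@geneSeq)
  names(seqs) <- sprintf("%s:%d-%d", gene_model@geneId,
                         as.integer(gene_model@geneStart),
                         as.integer(gene_model@geneEnd))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(c(exon_path, fasta_path))
}

#' Synthetic myostatin-like gene model
#'
#' A fully synthetic three-exon gene model emulating the structure of the
#' porcine myostatin locus on chromosome 15 (real coordinates
#' 94,620,269-94,628,630; the true gene sequence is not bundled). The CDS
#' is 1,128 bp (376 codons) with codon 274 = `GAA` (glutamic acid), so that
#' the substitution G>T at CDS position 820 creates a premature stop
#' (`c.820G>T`, `p.E274*`). The sequence is generated deterministically
#' from a stop-free codon alphabet; it is a structural stand-in, not the
#' real myostatin sequence.
#'
#' @param strand `"+"` (default) or `"-"`; the minus-strand variant places
#'   the same CDS on the reverse strand for strand-handling tests
#' @return a [GeneModel-class]
#' @examples
#' gm <- syntheticMstnModel()
#' mstnStopVariant()  # the genomic coordinates of c.820G>T
#' @export
syntheticMstnModel <- function(strand = "+") {
  safe <- c("GCT", "GAT", "CTG", "AAA", "TCC", "GGA", "ATC", "GTG",
            "CAA", "GAG", "TTC", "CAC")
  n_codons <- 376L
  codons <- rep(safe, length.out = n_codons)
  codons[1] <- "ATG"
  codons[274] <- "GAA"
  codons[n_codons] <- "TAA"
  cds <- paste(codons, collapse = "")
  gene_start <- 94620269; gene_end <- 94628630
  exon_lens <- c(372L, 374L, 382L)
  starts <- c(94620269, 94622000, 94627000)
  exons <- data.frame(start = starts, end = starts + exon_lens - 1)
  span <- gene_end - gene_start + 1
  backbone <- substr(paste(rep("ACGGTCTA", ceiling(span / 8)),
                           collapse = ""), 1, span)
  plus_cds <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  # lay the (plus-strand image of the) CDS into the exons, 5'->3' genomic
  off <- 0L
  for (i in seq_len(3)) {
    piece <- substr(plus_cds, off + 1L, off + exon_lens[i])
    substr(backbone, exons$start[i] - gene_start + 1,
           exons$end[i] - gene_start + 1) <- piece
    off <- off + exon_lens[i]
  }
  geneModel("MSTN_synthetic", "15", strand, exons, gene_start, gene_end,
            backbone)
}

#' @rdname syntheticMstnModel
#' @details `mstnStopVariant()` returns the genomic record of the
#'   premature-stop substitution on the plus-strand synthetic model:
#'   chromosome 15, the position whose CDS coordinate is 820, ref `G`,
#'   alt `T`.
#' @export
mstnStopVariant <- function() {
  data.frame(chrom = "15", pos = 94627073, ref = "G", alt = "T",
             stringsAsFactors = FALSE)
}
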