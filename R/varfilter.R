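#' Read a multi-sample VCF into site and genotype tables
#'
#' Parses a VCF 4.x via `vcfR`, decomposing multi-allelic sites into
#' biallelic records (one row per ALT allele; genotype dosage counts copies
#' of that allele). Site metrics `QD, FS, MQ, MQRankSum, ReadPosRankSum`
#' are pulled from INFO where present.
#'
#' @param path path to an (uncompressed or bgzipped) VCF
#' @return list with `sites` (data.frame `chrom, pos, ref, alt` + metric
#'   columns) and `genotypes` (integer matrix sites x samples, ALT-allele
#'   dosage 0/1/2, `NA` missing)
#' @export
readVcfVariants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  metrics <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  info <- lapply(metrics, function(m)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = m))))
  names(info) <- metrics
  sites <- list(); genos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      row <- data.frame(chrom = fix[i, "CHROM"],
                        pos = as.numeric(fix[i, "POS"]),
                        ref = fix[i, "REF"], alt = alts[k],
                        stringsAsFactors = FALSE)
      for (m in metrics) row[[m]] <- info[[m]][i]
      sites[[length(sites) + 1L]] <- row
      g <- gt[i, ]
      dose <- vapply(g, function(x) {
        if (is.na(x) || grepl("\\.", x)) return(NA_integer_)
        sum(as.integer(strsplit(x, "[/|]")[[1]]) == k)
      }, integer(1))
      genos[[length(genos) + 1L]] <- dose
    }
  }
  sites <- do.call(rbind, sites)
  genotypes <- do.call(rbind, genos)
  colnames(genotypes) <- colnames(gt)
  rownames(sites) <- NULL
  list(sites = sites, genotypes = genotypes)
}

#' GATK-style site hard filter
#'
#' Flags a variant as failing iff any present metric violates its printed
#' threshold: `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`, `MQRankSum < -12.5`,
#' `ReadPosRankSum < -8.0`. Inequalities are strict, so values exactly at a
#' threshold pass. A missing metric cannot fail its clause; it is flagged
#' in `missing_metrics`.
#'
#' @param sites data.frame with any of the metric columns above
#' @return `sites` with added columns `pass` (logical), `fail_reason`
#'   (comma-separated metric names, `""` if passing) and `missing_metrics`
#' @examples
#' siteHardFilter(data.frame(QD = c(1.9, 2.0), FS = 0, MQ = 50,
#'                           MQRankSum = 0, ReadPosRankSum = 0))$pass
#' @export
siteHardFilter <- function(sites) {
  rules <- list(QD = function(x) x < 2.0, FS = function(x) x > 60.0,
                MQ = function(x) x < 40.0,
                MQRankSum = function(x) x < -12.5,
                ReadPosRankSum = function(x) x < -8.0)
  n <- nrow(sites)
  fail <- matrix(FALSE, n, length(rules),
                 dimnames = list(NULL, names(rules)))
  miss <- matrix(FALSE, n, length(rules),
                 dimnames = list(NULL, names(rules)))
  for (m in names(rules)) {
    if (m %in% names(sites)) {
      x <- as.numeric(sites[[m]])
      miss[, m] <- is.na(x)
      fail[, m] <- !is.na(x) & rules[[m]](x)
    } else miss[, m] <- TRUE
  }
  sites$pass <- rowSums(fail) == 0
  sites$fail_reason <- apply(fail, 1, function(f)
    paste(names(rules)[f], collapse = ","))
  sites$missing_metrics <- apply(miss, 1, function(f)
    paste(names(rules)[f], collapse = ","))
  sites
}

#' Recessive candidate-variant filter
#'
#' Retains variants whose genotypes segregate as expected for a fully
#' penetrant recessive mutation: all affected individuals homozygous for
#' one shared allele (tolerating up to `max_het_cases` heterozygous calls),
#' all obligate-carrier parents heterozygous (tolerating up to
#' `max_homref_carriers` calls homozygous for the other allele, the
#' relaxation motivated by low sequencing depth limiting heterozygote
#' detection), and all unaffected controls homozygous for the allele not
#' seen in the affected group. Missing genotypes never count against a
#' clause but are tallied.
#'
#' @param sites data.frame of biallelic sites (`chrom, pos, ref, alt`, ...)
#' @param genotypes integer matrix sites x samples, ALT dosage 0/1/2/NA
#' @param groups named list with character vectors `cases`, `carriers`,
#'   `controls` of sample ids (must not overlap)
#' @param max_het_cases,max_homref_carriers tolerances, 0 (strict) or 1
#'   (relaxed)
#' @return the retained rows of `sites`, with `case_allele` (`"ref"` or
#'   `"alt"`), per-group missing-call counts and the exception counts used
#' @export
candidateFilter <- function(sites, genotypes, groups,
                            max_het_cases = 0L, max_homref_carriers = 0L) {
  for (nm in c("cases", "carriers", "controls"))
    if (is.null(groups[[nm]])) stop("groups needs element '", nm, "'")
  all_ids <- unlist(groups[c("cases", "carriers", "controls")])
  if (anyDuplicated(all_ids))
    stop("overlapping group membership: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  miss <- setdiff(all_ids, colnames(genotypes))
  if (length(miss))
    stop("sample ids not in VCF: ", paste(head(miss, 5), collapse = ", "))
  keep <- logical(nrow(sites))
  allele <- character(nrow(sites))
  nh <- integer(nrow(sites)); nr <- integer(nrow(sites))
  nmiss <- matrix(0L, nrow(sites), 3,
                  dimnames = list(NULL, c("cases", "carriers", "controls")))
  for (i in seq_len(nrow(sites))) {
    gc <- genotypes[i, groups$cases]
    gk <- genotypes[i, groups$carriers]
    gn <- genotypes[i, groups$controls]
    nmiss[i, ] <- c(sum(is.na(gc)), sum(is.na(gk)), sum(is.na(gn)))
    gc <- gc[!is.na(gc)]; gk <- gk[!is.na(gk)]; gn <- gn[!is.na(gn)]
    for (h in c(2L, 0L)) {  # shared case allele as dosage of ALT
      het_exc <- sum(gc == 1)
      if (any(gc == (2L - h)) || het_exc > max_het_cases) next
      hom_exc <- sum(gk == (2L - h))
      if (any(gk == h) || hom_exc > max_homref_carriers) next
      if (any(gn != (2L - h))) next
      keep[i] <- TRUE
      allele[i] <- if (h == 2L) "alt" else "ref"
      nh[i] <- het_exc; nr[i] <- hom_exc
      break
    }
  }
  out <- sites[keep, , drop = FALSE]
  out$case_allele <- allele[keep]
  out$n_het_cases <- nh[keep]
  out$n_homother_carriers <- nr[keep]
  out$missing_cases <- nmiss[keep, "cases"]
  out$missing_carriers <- nmiss[keep, "carriers"]
  out$missing_controls <- nmiss[keep, "controls"]
  rownames(out) <- NULL
  out
}

#' Annotate the coding consequence of an SNV
#'
#' Maps a genomic single-nucleotide variant onto a [GeneModel-class],
#' honouring strand, and reports the affected region and — for CDS
#' variants — the codon change with HGVS-like `c.` and `p.` strings.
#' A premature stop (`stop_gained`) truncates the protein at the reported
#' codon.
#'
#' @param chrom,pos,ref,alt the variant (1-based position; single bases)
#' @param gene_model a [GeneModel-class]
#' @return one-row data.frame: `region` (`intergenic`/`intronic`/`CDS`),
#'   `consequence` (`synonymous`/`missense`/`stop_gained`/`stop_lost`, NA
#'   outside CDS), `cds_pos`, `codon_index`, `aa_ref`, `aa_alt`, `hgvs_c`,
#'   `hgvs_p`
#' @examples
#' gm <- syntheticMstnModel()
#' annotateConsequence("15", 94627073, "G", "T", gm)  # p.E274*
#' @export
annotateConsequence <- function(chrom, pos, ref, alt, gene_model) {
  if (length(chrom) > 1) {
    return(do.call(rbind, Map(annotateConsequence, chrom, pos, ref, alt,
                              MoreArgs = list(gene_model = gene_model))))
  }
  if (nchar(ref) != 1 || nchar(alt) != 1)
    stop("only SNVs are supported by consequence annotation (got ",
         ref, ">", alt, ")")
  if (ref == alt) stop("alt allele equals ref")
  blank <- data.frame(region = "intergenic", consequence = NA_character_,
                      cds_pos = NA_integer_, codon_index = NA_integer_,
                      aa_ref = NA_character_, aa_alt = NA_character_,
                      hgvs_c = NA_character_, hgvs_p = NA_character_,
                      stringsAsFactors = FALSE)
  if (as.character(chrom) != gene_model@chrom ||
      pos < gene_model@geneStart || pos > gene_model@geneEnd)
    return(blank)
  e <- gene_model@exons[order(gene_model@exons$start), , drop = FALSE]
  hit <- which(pos >= e$start & pos <= e$end)
  if (!length(hit)) {
    blank$region <- "intronic"
    return(blank)
  }
  genome_base <- as.character(
    Biostrings::subseq(gene_model@geneSeq,
                       pos - gene_model@geneStart + 1,
                       pos - gene_model@geneStart + 1))
  if (genome_base != ref)
    stop("ref allele ", ref, " does not match gene sequence base ",
         genome_base, " at ", chrom, ":", pos)
  lens <- e$end - e$start + 1
  if (gene_model@strand == "+") {
    cds_pos <- sum(lens[seq_len(hit - 1)]) + (pos - e$start[hit] + 1)
    refc <- ref; altc <- alt
  } else {
    nex <- nrow(e)
    after <- if (hit < nex) sum(lens[(hit + 1):nex]) else 0
    cds_pos <- after + (e$end[hit] - pos + 1)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    refc <- comp[[ref]]; altc <- comp[[alt]]
  }
  cds <- cdsSequence(gene_model)
  codon_index <- ceiling(cds_pos / 3)
  off <- (codon_index - 1L) * 3L
  codon_ref <- as.character(Biostrings::subseq(cds, off + 1, off + 3))
  within <- cds_pos - off
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- altc
  gcode <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gcode[codon_ref])
  aa_alt <- unname(gcode[codon_alt])
  consequence <-
    if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gained"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  data.frame(region = "CDS", consequence = consequence,
             cds_pos = as.integer(cds_pos), codon_index = codon_index,
             aa_ref = aa_ref, aa_alt = aa_alt,
             hgvs_c = paste0("c.", cds_pos, refc, ">", altc),
             hgvs_p = paste0("p.", aa_ref, codon_index,
                             if (aa_alt == "*") "*" else aa_alt),
             stringsAsFactors = FALSE)
}

#' Tabulate candidate variants by consequence class
#'
#' @param annotations data.frame from [annotateConsequence()] (one row per
#'   candidate)
#' @return named integer vector over the classes `intergenic, intronic,
#'   synonymous, missense, stop_gained, stop_lost`; sums to the candidate
#'   count
#' @export
tabulateCandidates <- function(annotations) {
  classes <- c("intergenic", "intronic", "synonymous", "missense",
               "stop_gained", "stop_lost")
  out <- setNames(integer(length(classes)), classes)
  if (!nrow(annotations)) return(out)
  lab <- ifelse(annotations$region == "CDS", annotations$consequence,
                annotations$region)
  tab <- table(factor(lab, levels = classes))
  out[names(tab)] <- as.integer(tab)
  out
}
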