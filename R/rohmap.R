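#' Filter a SNP panel to informative autosomal markers
#'
#' Retains only SNPs that map to autosomes and are neither fixed
#' (monomorphic across all samples) nor completely heterozygous, the
#' standard pre-filter before case/control homozygosity mapping.
#'
#' @param genotypes integer matrix, samples x SNPs, codes 0 (hom A1),
#'   1 (het), 2 (hom A2), `NA` missing; column names are SNP ids
#' @param map data.frame with columns `snp`, `chrom`, `pos` matching the
#'   genotype columns; chromosomes named `X`, `Y`, `MT` (case-insensitive)
#'   are treated as non-autosomal
#' @return list `genotypes` (reduced matrix), `map` (reduced map),
#'   `n_retained`, `n_dropped` (named: non_autosomal, monomorphic,
#'   all_heterozygous)
#' @export
filterInformative <- function(genotypes, map) {
  genotypes <- .checkGenoInput(genotypes, map)
  sexchr <- toupper(as.character(map$chrom)) %in% c("X", "Y", "MT", "M")
  mono <- apply(genotypes, 2, function(g) {
    g <- g[!is.na(g)]
    length(g) > 0 && (all(g == 0) || all(g == 2))
  })
  allhet <- apply(genotypes, 2, function(g) {
    g <- g[!is.na(g)]
    length(g) > 0 && all(g == 1)
  })
  keep <- !(sexchr | mono | allhet)
  if (!any(keep)) stop("no informative autosomal SNPs remain")
  list(genotypes = genotypes[, keep, drop = FALSE],
       map = map[keep, , drop = FALSE],
       n_retained = sum(keep),
       n_dropped = c(non_autosomal = sum(sexchr),
                     monomorphic = sum(mono & !sexchr),
                     all_heterozygous = sum(allhet & !sexchr & !mono)))
}

.checkGenoInput <- function(genotypes, map = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0, 1, 2, NA)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(map)) {
    if (ncol(genotypes) != nrow(map))
      stop("genotype columns must match map rows")
    sp <- split(map$pos, map$chrom)
    if (any(vapply(sp, function(p) is.unsorted(p, strictly = TRUE), TRUE)))
      stop("positions must be strictly increasing within chromosome")
  }
  genotypes
}

# per-SNP predicate: all non-missing cases homozygous for one shared allele,
# tolerating up to `allow_case_het` cases that are het or hom-other.
# Returns the shared allele code (0 or 2) or NA if the SNP does not qualify.
.sharedCaseAllele <- function(cases, allow_case_het = 0L) {
  g <- cases[!is.na(cases)]
  if (!length(g)) return(NA_integer_)  # all-missing: compatible with nothing
  for (hom in c(0L, 2L)) {
    if (sum(g != hom) <= allow_case_het && sum(g == hom) > 0)
      return(hom)
  }
  NA_integer_
}

#' Classify one SNP for homozygosity mapping
#'
#' A SNP is `case_shared_hom` when all non-missing cases are homozygous for
#' the same allele; it is additionally `control_informative` when at least
#' one control is heterozygous or homozygous for the other allele, i.e. the
#' SNP can distinguish the shared case haplotype from the controls.
#'
#' @param case_codes,control_codes integer vectors of 0/1/2/NA codes
#' @return list `status` (one of `"case_shared_hom_informative"`,
#'   `"case_shared_hom_only"`, `"not_shared"`), `shared_allele` (0/2 or NA),
#'   `all_missing` flag
#' @export
classifySnp <- function(case_codes, control_codes) {
  if (!length(case_codes)) stop("need at least one case")
  if (all(is.na(case_codes)))
    return(list(status = "not_shared", shared_allele = NA_integer_,
                all_missing = TRUE))
  hom <- .sharedCaseAllele(case_codes, 0L)
  if (is.na(hom))
    return(list(status = "not_shared", shared_allele = NA_integer_,
                all_missing = FALSE))
  ctl <- control_codes[!is.na(control_codes)]
  informative <- any(ctl == 1) || any(ctl == (2L - hom))
  list(status = if (informative) "case_shared_hom_informative" else
         "case_shared_hom_only",
       shared_allele = hom, all_missing = FALSE)
}

#' Longest shared homozygous segments in cases
#'
#' Per chromosome, finds maximal runs of consecutive SNPs at which all
#' non-missing cases are homozygous for the same allele (the signature of a
#' segment identical by descent around a recessive mutation), and ranks the
#' runs by SNP count. Missing case genotypes are compatible with a run but
#' are counted and reported. Segment bp span is `last - first` position.
#'
#' @param genotypes samples x SNPs code matrix (ideally after
#'   [filterInformative()])
#' @param map matching SNP map (`snp`, `chrom`, `pos`)
#' @param case_ids row names of the case samples; all other rows are
#'   controls
#' @param allow_case_het per-SNP tolerance: number of cases allowed to be
#'   heterozygous (or homozygous for the other allele) without breaking the
#'   run (0 = strict)
#' @return data.frame of segments ranked by `n_snps` (ties: bp span, then
#'   chromosome and position): `chrom, start_snp, end_snp, start_bp, end_bp,
#'   n_snps, span_mbp, n_control_sharing, n_missing_case_calls`; zero rows
#'   when no SNP qualifies
#' @export
longestSharedSegment <- function(genotypes, map, case_ids,
                                 allow_case_het = 0L) {
  genotypes <- .checkGenoInput(genotypes, map)
  if (is.null(rownames(genotypes)))
    stop("genotype matrix needs sample row names")
  if (!all(case_ids %in% rownames(genotypes)))
    stop("case ids missing from genotype matrix")
  cases <- genotypes[case_ids, , drop = FALSE]
  controls <- genotypes[setdiff(rownames(genotypes), case_ids), ,
                        drop = FALSE]
  shared <- vapply(seq_len(ncol(cases)), function(j)
    .sharedCaseAllele(cases[, j], as.integer(allow_case_het)),
    integer(1))
  qual <- !is.na(shared)
  segs <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    r <- rle(qual[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- idx[starts[k]]; i2 <- idx[ends[k]]
      snps <- i1:i2
      n_ctl_sharing <- if (nrow(controls)) {
        sum(vapply(seq_len(nrow(controls)), function(s)
          all(controls[s, snps] == shared[snps], na.rm = TRUE), TRUE))
      } else 0L
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chr,
        start_snp = map$snp[i1], end_snp = map$snp[i2],
        start_bp = map$pos[i1], end_bp = map$pos[i2],
        n_snps = length(snps),
        span_mbp = segmentSpanMbp(map$pos[i1], map$pos[i2]),
        n_control_sharing = n_ctl_sharing,
        n_missing_case_calls = sum(is.na(cases[, snps])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(0), start_snp = character(0),
                      end_snp = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      span_mbp = numeric(0), n_control_sharing = integer(0),
                      n_missing_case_calls = integer(0)))
  out <- do.call(rbind, segs)
  bp <- out$end_bp - out$start_bp
  out <- out[order(-out$n_snps, -bp, out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment length in Mbp
#'
#' `(last - first) / 1e6`, rounded to one decimal — the convention under
#' which the mapped interval 86,745,668..95,062,143 reads as 8.3 Mbp.
#'
#' @param first_bp,last_bp 1-based positions, `last_bp >= first_bp`
#' @return numeric, Mbp to one decimal
#' @export
segmentSpanMbp <- function(first_bp, last_bp) {
  if (any(last_bp < first_bp)) stop("negative segment span")
  round((last_bp - first_bp) / 1e6, 1)
}

#' Per-group consensus genotype rows
#'
#' The summary-line rule used to render case and control groups in a
#' homozygosity-mapping figure: per group and SNP, if any animal is
#' heterozygous the consensus is `het`; else if all non-missing animals are
#' homozygous for the same allele the consensus is that allele
#' (`hom_a1`/`hom_a2`); discordant homozygotes give `discordant`, and an
#' all-missing group gives `missing`.
#'
#' @param genotypes samples x SNPs code matrix with sample row names
#' @param groups named list of sample-id character vectors
#' @return character matrix, groups x SNPs
#' @export
summaryRows <- function(genotypes, groups) {
  genotypes <- .checkGenoInput(genotypes)
  out <- matrix(NA_character_, length(groups), ncol(genotypes),
                dimnames = list(names(groups), colnames(genotypes)))
  for (g in seq_along(groups)) {
    sub <- genotypes[groups[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) "missing"
      else if (any(x == 1)) "het"
      else if (all(x == 0)) "hom_a1"
      else if (all(x == 2)) "hom_a2"
      else "discordant"
    })
  }
  out
}
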