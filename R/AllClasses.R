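#' @import methods
#' @importFrom stats rnorm runif rbinom rpois rbeta rchisq dnorm pnorm qnorm
#'   pchisq rmultinom sd var quantile setNames aggregate chisq.test
#'   model.matrix optimize complete.cases
#' @importFrom utils read.table write.table head
#' @importFrom Rcpp evalCpp
#' @useDynLib lethalmap, .registration = TRUE
NULL

#' Pedigree of a closed breeding population
#'
#' An ordered pedigree: every parent appears before any of its offspring.
#' Construct with [validatePedigree()], which checks identifiers, sex
#' consistency and acyclicity and performs the topological sort.
#'
#' @slot records data.frame with columns `id`, `sire`, `dam` (character,
#'   `NA` = unknown), `sex` (`"M"`/`"F"`/`NA`), `litter` (character or
#'   `NA`) and `generation` (integer or `NA`), in topological order.
#'
#' @seealso [inbreeding()], [aMatrix()], [pedigreeSummary()]
#' @export
setClass("Pedigree", representation(records = "data.frame"))

setValidity("Pedigree", function(object) {
  df <- object@records
  need <- c("id", "sire", "dam", "sex", "litter", "generation")
  if (!all(need %in% names(df)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$id)) return("duplicated individual ids")
  pos <- match(df$id, df$id)
  sp <- match(df$sire, df$id)
  dp <- match(df$dam, df$id)
  if (any(!is.na(df$sire) & is.na(sp) | !is.na(df$dam) & is.na(dp)))
    return("parent id not present in pedigree")
  if (any(sp >= seq_len(nrow(df)), na.rm = TRUE) ||
      any(dp >= seq_len(nrow(df)), na.rm = TRUE))
    return("pedigree is not topologically ordered (parent after offspring)")
  TRUE
})

#' @describeIn Pedigree number of individuals
#' @param x,object a `Pedigree`
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@records))

#' @describeIn Pedigree individual identifiers, in pedigree order
#' @export
setGeneric("pedIds", function(x) standardGeneric("pedIds"))

#' @rdname Pedigree
#' @export
setMethod("pedIds", "Pedigree", function(x) x@records$id)

#' @describeIn Pedigree the underlying records table
#' @param row.names,optional,... passed on conventionally, unused
#' @export
setMethod("as.data.frame", "Pedigree",
          function(x, row.names = NULL, optional = FALSE, ...) x@records)

setMethod("show", "Pedigree", function(object) {
  df <- object@records
  nf <- sum(is.na(df$sire) & is.na(df$dam))
  cat("Pedigree with", nrow(df), "individuals (", nf, "founders )\n")
  if (!all(is.na(df$generation)))
    cat("  generations:", max(df$generation, na.rm = TRUE) + 1L, "\n")
})

#' Simulated population
#'
#' Container for one realisation of the forward simulator: the pedigree, the
#' per-individual pair of marker haplotypes, causal-locus genotypes, stage
#' survival flags and phenotypes.
#'
#' @slot pedigree a [Pedigree-class]
#' @slot map data.frame: `snp`, `chrom`, `pos` (bp, 1-based, increasing
#'   within chromosome), `a1`, `a2`
#' @slot hap1,hap2 integer matrices (individuals x markers) of allele codes
#'   0/1 for the two gametic haplotypes
#' @slot causalGenotype integer vector, copies (0/1/2) of the lethal T allele
#' @slot causalLocus list(chrom, pos, ibd_window_bp)
#' @slot phenotypes data.frame of per-individual phenotypes and covariates
#' @slot stageFlags logical matrix (individuals x stages birth/wt40/wt110)
#' @export
setClass("Population", representation(
  pedigree = "Pedigree", map = "data.frame",
  hap1 = "matrix", hap2 = "matrix",
  causalGenotype = "integer", causalLocus = "list",
  phenotypes = "data.frame", stageFlags = "matrix"))

setValidity("Population", function(object) {
  n <- length(object@pedigree)
  if (nrow(object@hap1) != n || nrow(object@hap2) != n)
    return("haplotype rows must match pedigree size")
  if (length(object@causalGenotype) != n)
    return("causalGenotype length must match pedigree size")
  if (ncol(object@hap1) != nrow(object@map))
    return("haplotype columns must match map rows")
  if (any(object@causalGenotype < 0 | object@causalGenotype > 2))
    return("causal genotypes must be 0, 1 or 2")
  TRUE
})

setMethod("show", "Population", function(object) {
  g <- object@causalGenotype
  cat("Population:", length(object@pedigree), "individuals,",
      nrow(object@map), "markers\n")
  cat("  causal genotype counts: GG =", sum(g == 0), " GT =", sum(g == 1),
      " TT =", sum(g == 2), "\n")
  cat("  T allele frequency at birth:",
      round(mean(g) / 2, 4), "\n")
})

#' @describeIn Population genotype matrix (0/1/2 counts of allele 2) at the
#'   simulated markers, individuals x markers
#' @param x,object a `Population`
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname Population
#' @export
setMethod("genotypeMatrix", "Population", function(x) {
  g <- x@hap1 + x@hap2
  dimnames(g) <- list(pedIds(x@pedigree), x@map$snp)
  g
})

#' @describeIn Population the SNP map
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname Population
#' @export
setMethod("snpMap", "Population", function(x) x@map)

#' @describeIn Population phenotype table
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname Population
#' @export
setMethod("phenotypes", "Population", function(x) x@phenotypes)

#' @describeIn Population causal-locus genotypes (copies of T)
#' @export
setGeneric("causalGenotypes", function(x) standardGeneric("causalGenotypes"))

#' @rdname Population
#' @export
setMethod("causalGenotypes", "Population",
          function(x) setNames(x@causalGenotype, pedIds(x@pedigree)))

#' @describeIn Population stage survival flags (logical matrix)
#' @export
setGeneric("stageFlags", function(x) standardGeneric("stageFlags"))

#' @rdname Population
#' @export
setMethod("stageFlags", "Population", function(x) x@stageFlags)

#' Posterior of the monogenic segregation model
#'
#' Returned by [gibbsSegregation()]. Holds thinned post-burn-in draws of the
#' model parameters, their summaries, and per-individual posterior genotype
#' probabilities under the allele-labelling constraint `a >= 0`.
#'
#' @slot draws data.frame with columns `q`, `mu`, `a`, `d`, `sigma2e`
#'   (relabelled so that `a >= 0`), one row per retained draw
#' @slot summary data.frame: posterior mean, sd and central 95% interval per
#'   parameter, plus the posterior share of phenotypic variance at the locus
#' @slot genotypeProb matrix (individuals x 3) of posterior genotype
#'   probabilities, columns `GG`, `GT`, `TT` (T = allele increasing the trait)
#' @export
setClass("MonogenicPosterior", representation(
  draws = "data.frame", summary = "data.frame", genotypeProb = "matrix"))

setValidity("MonogenicPosterior", function(object) {
  if (ncol(object@genotypeProb) != 3) return("genotypeProb must have 3 columns")
  s <- rowSums(object@genotypeProb)
  if (any(abs(s - 1) > 1e-6)) return("genotype probabilities must sum to 1")
  TRUE
})

setMethod("show", "MonogenicPosterior", function(object) {
  cat("Monogenic segregation posterior (", nrow(object@draws), "draws )\n")
  print(round(object@summary, 4))
})

#' @describeIn MonogenicPosterior posterior summary table
#' @param object a `MonogenicPosterior`
#' @export
setGeneric("posteriorSummary", function(object) standardGeneric("posteriorSummary"))

#' @rdname MonogenicPosterior
#' @export
setMethod("posteriorSummary", "MonogenicPosterior", function(object) object@summary)

#' @describeIn MonogenicPosterior retained parameter draws
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname MonogenicPosterior
#' @export
setMethod("posteriorDraws", "MonogenicPosterior", function(object) object@draws)

#' @describeIn MonogenicPosterior per-individual genotype probabilities
#' @export
setGeneric("genotypeProbabilities",
           function(object) standardGeneric("genotypeProbabilities"))

#' @rdname MonogenicPosterior
#' @export
setMethod("genotypeProbabilities", "MonogenicPosterior",
          function(object) object@genotypeProb)

#' Protein-coding gene model with sequence context
#'
#' Exon structure plus the genomic sequence of the gene span, sufficient to
#' map a genomic SNV to a CDS coordinate and translate the affected codon.
#' Build directly, from files with [readGeneModel()], or use the bundled
#' [syntheticMstnModel()].
#'
#' @slot geneId character
#' @slot chrom character, chromosome the gene lies on
#' @slot strand `"+"` or `"-"`
#' @slot exons data.frame `start`, `end`: CDS exon intervals in genomic
#'   coordinates, 1-based inclusive, stored in genomic order
#' @slot geneStart,geneEnd numeric, full gene span (may exceed the CDS)
#' @slot geneSeq `DNAString` of the plus strand of `[geneStart, geneEnd]`
#' @export
setClass("GeneModel", representation(
  geneId = "character", chrom = "character", strand = "character",
  exons = "data.frame", geneStart = "numeric", geneEnd = "numeric",
  geneSeq = "ANY"))

setValidity("GeneModel", function(object) {
  e <- object@exons
  if (!all(c("start", "end") %in% names(e))) return("exons need start/end")
  if (any(e$end < e$start)) return("exon end < start")
  if (nrow(e) > 1) {
    e <- e[order(e$start), ]
    if (any(e$start[-1] <= e$end[-nrow(e)])) return("exons overlap")
  }
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  L <- sum(e$end - e$start + 1)
  if (L %% 3 != 0) return("CDS length must be divisible by 3")
  if (min(e$start) < object@geneStart || max(e$end) > object@geneEnd)
    return("exons outside gene span")
  if (length(object@geneSeq) != object@geneEnd - object@geneStart + 1)
    return("geneSeq length must equal the gene span")
  TRUE
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "on", object@chrom,
      paste0("(", object@strand, ")"), "\n")
  cat("  ", nrow(object@exons), "CDS exons,",
      sum(object@exons$end - object@exons$start + 1), "bp CDS,",
      "span", object@geneStart, "-", object@geneEnd, "\n")
})

#' @describeIn GeneModel spliced CDS sequence (5' to 3' on the coding strand)
#' @param object a `GeneModel`
#' @export
setGeneric("cdsSequence", function(object) standardGeneric("cdsSequence"))

#' @rdname GeneModel
#' @export
setMethod("cdsSequence", "GeneModel", function(object) {
  e <- object@exons[order(object@exons$start), , drop = FALSE]
  parts <- lapply(seq_len(nrow(e)), function(i)
    Biostrings::subseq(object@geneSeq,
                       e$start[i] - object@geneStart + 1,
                       e$end[i] - object@geneStart + 1))
  cds <- do.call(Biostrings::xscat, parts)
  if (object@strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
})
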