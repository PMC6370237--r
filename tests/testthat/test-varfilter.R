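test_that("site hard filter uses strict inequalities exactly as printed", {
  ok <- data.frame(QD = 2.0, FS = 60.0, MQ = 40.0, MQRankSum = -12.5,
                   ReadPosRankSum = -8.0)
  expect_true(siteHardFilter(ok)$pass)    # boundary values pass
  bad <- data.frame(QD = c(1.9, 25, 25, 25, 25),
                    FS = c(3, 60.01, 3, 3, 3),
                    MQ = c(60, 60, 39.99, 60, 60),
                    MQRankSum = c(0, 0, 0, -12.51, 0),
                    ReadPosRankSum = c(0, 0, 0, 0, -8.01))
  out <- siteHardFilter(bad)
  expect_false(any(out$pass))
  expect_equal(out$fail_reason,
               c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"))
  # missing metric cannot fail its clause but is flagged
  m <- siteHardFilter(data.frame(QD = NA, FS = 3, MQ = 60,
                                 MQRankSum = 0, ReadPosRankSum = 0))
  expect_true(m$pass)
  expect_match(m$missing_metrics, "QD")
})

test_that("hard filter equals brute-force clause evaluation", {
  set.seed(8)
  tab <- data.frame(QD = runif(300, 0, 5), FS = runif(300, 0, 120),
                    MQ = runif(300, 20, 70), MQRankSum = runif(300, -20, 5),
                    ReadPosRankSum = runif(300, -12, 4))
  out <- siteHardFilter(tab)
  want <- !(tab$QD < 2 | tab$FS > 60 | tab$MQ < 40 |
              tab$MQRankSum < -12.5 | tab$ReadPosRankSum < -8)
  expect_equal(out$pass, want)
})

make_vcf_tables <- function(gmat, ids) {
  n <- nrow(gmat)
  sites <- data.frame(chrom = "15", pos = seq_len(n) * 100,
                      ref = "G", alt = "T", stringsAsFactors = FALSE)
  colnames(gmat) <- ids
  list(sites = sites, genotypes = gmat)
}

test_that("candidateFilter retains the causal pattern and applies
           tolerances", {
  ids <- c(paste0("ca", 1:3), paste0("pk", 1:2), paste0("co", 1:2))
  grp <- list(cases = paste0("ca", 1:3), carriers = paste0("pk", 1:2),
              controls = paste0("co", 1:2))
  perfect <- matrix(c(2, 2, 2, 1, 1, 0, 0), 1)
  one_het <- matrix(c(1, 2, 2, 1, 1, 0, 0), 1)
  v <- make_vcf_tables(rbind(perfect, one_het), ids)
  strict <- candidateFilter(v$sites, v$genotypes, grp)
  expect_equal(strict$pos, 100)
  expect_equal(strict$case_allele, "alt")
  relaxed <- candidateFilter(v$sites, v$genotypes, grp, max_het_cases = 1)
  expect_equal(relaxed$pos, c(100, 200))
  expect_error(candidateFilter(v$sites, v$genotypes,
                               list(cases = "ca1", carriers = "ca1",
                                    controls = "co1")), "overlapping")
})

test_that("candidateFilter equals the brute-force predicate over all
           genotype assignments of a small cohort", {
  # 3 cases, 2 carriers, 2 controls; enumerate all 3^7 dosage assignments
  ids <- c(paste0("ca", 1:3), paste0("pk", 1:2), paste0("co", 1:2))
  grp <- list(cases = paste0("ca", 1:3), carriers = paste0("pk", 1:2),
              controls = paste0("co", 1:2))
  cfgs <- as.matrix(expand.grid(rep(list(0:2), 7)))
  v <- make_vcf_tables(cfgs, ids)
  for (tol in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    got <- candidateFilter(v$sites, v$genotypes, grp,
                           max_het_cases = tol[1],
                           max_homref_carriers = tol[2])
    want <- which(vapply(seq_len(nrow(cfgs)), function(i)
      oracle_candidate(cfgs[i, 1:3], cfgs[i, 4:5], cfgs[i, 6:7],
                       tol[1], tol[2]), TRUE))
    expect_equal(match(got$pos, v$sites$pos), want)
  }
})

test_that("strict candidates are a subset of relaxed candidates", {
  set.seed(40)
  ids <- c(paste0("ca", 1:5), paste0("pk", 1:3), paste0("co", 1:4))
  grp <- list(cases = paste0("ca", 1:5), carriers = paste0("pk", 1:3),
              controls = paste0("co", 1:4))
  g <- matrix(sample(c(0:2, NA), 500 * 12, replace = TRUE,
                     prob = c(0.35, 0.2, 0.35, 0.1)), 500, 12)
  v <- make_vcf_tables(g, ids)
  strict <- candidateFilter(v$sites, v$genotypes, grp)
  relaxed <- candidateFilter(v$sites, v$genotypes, grp,
                             max_het_cases = 1, max_homref_carriers = 1)
  expect_true(all(strict$pos %in% relaxed$pos))
})

test_that("stop-gain annotation reproduces the c.820G>T worked example", {
  gm <- syntheticMstnModel()
  v <- mstnStopVariant()
  ann <- annotateConsequence(v$chrom, v$pos, v$ref, v$alt, gm)
  expect_equal(ann$region, "CDS")
  expect_equal(ann$consequence, "stop_gained")
  expect_equal(ann$cds_pos, 820L)
  expect_equal(ann$codon_index, 274L)
  expect_equal(ann$hgvs_c, "c.820G>T")
  expect_equal(ann$hgvs_p, "p.E274*")
  # same CDS change annotated identically on the minus-strand model
  gmm <- syntheticMstnModel("-")
  e <- gmm@exons
  pos_minus <- e$end[1] - (820 - (1128 - 372)) + 1   # CDS 820 in exon 1
  annm <- annotateConsequence("15", pos_minus, "C", "A", gmm)
  expect_equal(annm$hgvs_p, "p.E274*")
})

test_that("third-position GAA>GAG is synonymous and all single-base
           changes of the codon match the genetic code", {
  gm <- syntheticMstnModel()
  base <- 94627073  # genomic position of CDS 820 (codon GAA)
  syn <- annotateConsequence("15", base + 2, "A", "G", gm)
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$aa_ref, "E")
  code <- Biostrings::GENETIC_CODE
  for (off in 0:2) for (alt in setdiff(c("A", "C", "G", "T"),
                                       substr("GAA", off + 1, off + 1))) {
    ann <- annotateConsequence("15", base + off,
                               substr("GAA", off + 1, off + 1), alt, gm)
    codon_alt <- "GAA"
    substr(codon_alt, off + 1, off + 1) <- alt
    aa <- unname(code[codon_alt])
    want <- if (aa == "E") "synonymous" else if (aa == "*") "stop_gained"
    else "missense"
    expect_equal(ann$consequence, want)
    expect_equal(ann$aa_alt, aa)
  }
})

test_that("regions and errors: intergenic, intronic, ref mismatch, indel", {
  gm <- syntheticMstnModel()
  expect_equal(annotateConsequence("15", 1000, "A", "T", gm)$region,
               "intergenic")
  expect_equal(annotateConsequence("1", 94627073, "G", "T", gm)$region,
               "intergenic")
  intron_pos <- 94621000
  expect_equal(annotateConsequence("15", intron_pos, "A", "C", gm)$region,
               "intronic")
  expect_error(annotateConsequence("15", 94627073, "GA", "G", gm), "SNV")
  expect_error(annotateConsequence("15", 94627073, "A", "T", gm),
               "does not match")
})

test_that("a stop_gained call truncates: alt protein is a strict prefix", {
  gm <- syntheticMstnModel()
  cds <- cdsSequence(gm)
  prot_ref <- Biostrings::translate(cds)
  alt_cds <- as.character(cds)
  substr(alt_cds, 820, 820) <- "T"
  prot_alt <- Biostrings::translate(Biostrings::DNAString(alt_cds))
  stop_at <- regexpr("\\*", as.character(prot_alt))
  expect_equal(as.integer(stop_at), 274)
  expect_equal(substr(as.character(prot_alt), 1, 273),
               substr(as.character(prot_ref), 1, 273))
})

test_that("tabulateCandidates sums to the candidate count per class", {
  empty <- tabulateCandidates(data.frame(region = character(0),
                                         consequence = character(0)))
  expect_true(all(empty == 0))
  ann <- data.frame(
    region = c("intergenic", "intronic", "intronic", "CDS", "CDS"),
    consequence = c(NA, NA, NA, "stop_gained", "missense"))
  tab <- tabulateCandidates(ann)
  expect_equal(unname(tab["intergenic"]), 1L)
  expect_equal(unname(tab["intronic"]), 2L)
  expect_equal(unname(tab["stop_gained"]), 1L)
  expect_equal(sum(tab), nrow(ann))
})

test_that("gene model validity and file round trip", {
  expect_error(geneModel("g", "1", "+",
                         data.frame(start = 10, end = 13),  # 4 bp CDS
                         1, 100, strrep("A", 100)), "divisible by 3")
  gm <- syntheticMstnModel()
  ex <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fa")
  writeGeneModel(gm, ex, fa)
  gm2 <- readGeneModel(ex, fa)
  expect_equal(as.character(cdsSequence(gm2)),
               as.character(cdsSequence(gm)))
  expect_equal(gm2@exons$start, gm@exons$start)
})
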