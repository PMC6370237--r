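# File interchange for simulated populations: pedigree/phenotype CSV,
# PLINK-style PED/MAP, wide genotype TSV, staged cohort counts, and a small
# VCF around the causal locus with case/carrier/control sample groups.

.writeVcf <- function(sites, genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMSMappingQuality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MappingQualityRankSumTest\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"ReadPosRankSumTest\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")), con)
  gtstr <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (i in seq_len(nrow(sites))) {
    info <- paste(sprintf("%s=%s",
                          c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
                          c(sites$QD[i], sites$FS[i], sites$MQ[i],
                            sites$MQRankSum[i], sites$ReadPosRankSum[i])),
                  collapse = ";")
    g <- genotypes[i, ]
    gs <- ifelse(is.na(g), "./.", gtstr[as.character(g)])
    writeLines(paste(c(sites$chrom[i], sites$pos[i],
                       if (is.null(sites$id)) "." else sites$id[i],
                       sites$ref[i], sites$alt[i], "100", "PASS", info,
                       "GT", gs), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the standard artifact files for a simulated population
#'
#' Writes, under `outdir`: `pedigree.csv`, `phenotypes.csv`, PLINK-style
#' `genotypes.ped`/`genotypes.map`, a wide `genotypes.tsv` (0/1/2 codes),
#' `cohort_counts.tsv` (causal genotype counts among animals alive at each
#' stage), a `variants.vcf` around the causal locus (the causal stop-gain
#' plus intronic / intergenic / metric-failing / segregation-failing decoy
#' variants, with case, carrier and control sample columns) and the
#' synthetic gene model (`gene_model.tsv`, `gene.fa`).
#'
#' @param pop a [Population-class]
#' @param outdir output directory (created if needed)
#' @param n_cases,n_controls sample-group sizes for the VCF (cases are
#'   affected TT animals, carriers their dams, controls unaffected GG)
#' @param seed seed for decoy-variant genotypes
#' @return invisible named character vector of written paths
#' @export
emitArtifacts <- function(pop, outdir, n_cases = 10, n_controls = 10,
                          seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable")
  ped <- pop@pedigree
  df <- as.data.frame(ped)
  ph <- phenotypes(pop)
  paths <- c(pedigree = file.path(outdir, "pedigree.csv"),
             phenotypes = file.path(outdir, "phenotypes.csv"),
             ped = file.path(outdir, "genotypes.ped"),
             map = file.path(outdir, "genotypes.map"),
             tsv = file.path(outdir, "genotypes.tsv"),
             cohorts = file.path(outdir, "cohort_counts.tsv"),
             vcf = file.path(outdir, "variants.vcf"),
             gene_exons = file.path(outdir, "gene_model.tsv"),
             gene_fasta = file.path(outdir, "gene.fa"))
  writePedigree(ped, paths["pedigree"])
  write.table(ph, paths["phenotypes"], sep = ",", quote = FALSE,
              row.names = FALSE)

  map <- snpMap(pop)
  geno <- genotypeMatrix(pop)
  writeGenotypes(geno, map, paths["ped"], paths["map"],
                 sex = df$sex, affected = ph$affected)
  writeGenotypesTsv(geno, paths["tsv"])

  g <- pop@causalGenotype
  fl <- stageFlags(pop)
  cc <- do.call(rbind, lapply(colnames(fl), function(st) {
    gs <- g[fl[, st]]
    data.frame(stage = st, n_GG = sum(gs == 0), n_GT = sum(gs == 1),
               n_TT = sum(gs == 2))
  }))
  write.table(cc, paths["cohorts"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## VCF around the causal locus
  set.seed(.streamSeed(seed, "vcf_decoys"))
  gm <- syntheticMstnModel()
  aff_tt <- df$id[g == 2 & ph$affected == 1]
  cases <- head(aff_tt, n_cases)
  carriers <- unique(df$dam[match(cases, df$id)])
  carriers <- carriers[!is.na(carriers)]
  ctl_pool <- setdiff(df$id[g == 0 & ph$affected == 0], carriers)
  controls <- head(ctl_pool, n_controls)
  prefix <- function(p, x) if (length(x)) paste0(p, x) else character(0)
  samples <- c(prefix("case_", cases), prefix("carrier_", carriers),
               prefix("control_", controls))
  ids <- c(cases, carriers, controls)
  gt_true <- g[match(ids, df$id)]
  ok <- c(QD = 25.0, FS = 3.0, MQ = 60.0, MQRankSum = 0.2,
          ReadPosRankSum = 0.4)
  mkrow <- function(chrom, pos, ref, alt, id, metrics = ok) {
    cbind(data.frame(chrom = chrom, pos = pos, id = id, ref = ref,
                     alt = alt, stringsAsFactors = FALSE),
          as.data.frame(as.list(metrics)))
  }
  cv <- mstnStopVariant()
  hwe_geno <- function(q) rbinom(length(ids), 1, q) + rbinom(length(ids), 1, q)
  sites <- rbind(
    mkrow(cv$chrom, cv$pos, cv$ref, cv$alt, "causal_stop"),
    mkrow("15", 94622100, "C", "A", "decoy_intronic"),
    mkrow("15", 93000000, "T", "C", "decoy_intergenic"),
    mkrow("15", 94100000, "G", "A", "decoy_lowQD",
          replace(ok, "QD", 1.5)),
    mkrow("15", 94300000, "A", "G", "decoy_one_case_het"))
  gmat <- rbind(
    gt_true,                               # causal: perfect segregation
    hwe_geno(0.4),                         # intronic decoy, random
    hwe_geno(0.3),                         # intergenic decoy, random
    gt_true,                               # fails the site hard filter
    { gg <- gt_true; gg[1] <- 1L; gg })    # one case het: fails strict
  colnames(gmat) <- samples
  .writeVcf(sites, gmat, paths["vcf"])
  writeGeneModel(gm, paths["gene_exons"], paths["gene_fasta"])
  invisible(paths)
}

#' Write / read genotypes in PLINK-style PED/MAP
#'
#' `.map`: chromosome, SNP id, genetic position (0), bp position.
#' `.ped`: family, individual, sire, dam, sex, phenotype, then two
#' space-separated allele columns (`1`/`2`; `0 0` = missing) per marker.
#' Codes count copies of allele 2.
#'
#' @param genotypes samples x SNPs integer code matrix with row names
#' @param map data.frame `snp, chrom, pos`
#' @param ped_path,map_path output paths
#' @param sex,affected optional per-sample columns for the PED fields
#' @export
writeGenotypes <- function(genotypes, map, ped_path, map_path,
                           sex = NULL, affected = NULL) {
  write.table(data.frame(map$chrom, map$snp, 0, map$pos),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  n <- nrow(genotypes)
  sexcode <- if (is.null(sex)) rep(0, n) else
    ifelse(is.na(sex), 0, ifelse(sex == "M", 1, 2))
  phen <- if (is.null(affected)) rep(-9, n) else
    ifelse(is.na(affected), -9, affected + 1)
  al <- c(`0` = "1 1", `1` = "1 2", `2` = "2 2")
  lines <- vapply(seq_len(n), function(i) {
    gg <- genotypes[i, ]
    alleles <- ifelse(is.na(gg), "0 0", al[as.character(gg)])
    paste(c("FAM", rownames(genotypes)[i], "0", "0", sexcode[i], phen[i],
            alleles), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' @rdname writeGenotypes
#' @return `readGenotypes`: list `genotypes` (samples x SNPs codes),
#'   `map` (`snp, chrom, pos`)
#' @export
readGenotypes <- function(ped_path, map_path) {
  map <- read.table(map_path, sep = "\t",
                    col.names = c("chrom", "snp", "cm", "pos"),
                    colClasses = c("character", "character", "numeric",
                                   "numeric"))
  lines <- readLines(ped_path)
  toks <- strsplit(lines, " +")
  m <- nrow(map)
  geno <- t(vapply(toks, function(tk) {
    a <- matrix(as.integer(tk[-(1:6)]), nrow = 2)
    code <- as.integer(colSums(a == 2L))
    code[a[1, ] == 0L | a[2, ] == 0L] <- NA_integer_
    code
  }, integer(m)))
  rownames(geno) <- vapply(toks, `[[`, "", 2)
  colnames(geno) <- map$snp
  list(genotypes = geno, map = map[, c("snp", "chrom", "pos")])
}

#' Write / read the wide genotype TSV (rows = individuals, columns = SNPs)
#'
#' @param genotypes samples x SNPs integer code matrix
#' @param path file path
#' @export
writeGenotypesTsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesTsv
#' @export
readGenotypesTsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}
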