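#' Validate and order a pedigree
#'
#' Checks a raw pedigree table (duplicated ids, missing parents, self or
#' cyclic ancestry, parent-sex conflicts), adds any parent that appears only
#' in the `sire`/`dam` columns as a founder record, and returns the records
#' topologically sorted so every parent precedes its offspring.
#'
#' @param records data.frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`, `litter`, `generation`. Unknown parents are `NA`, `""` or `"0"`.
#' @return a [Pedigree-class]
#' @examples
#' ped <- validatePedigree(data.frame(id = c("o", "s", "d"),
#'                                    sire = c("s", NA, NA),
#'                                    dam  = c("d", NA, NA)))
#' pedIds(ped)  # founders first
#' @export
validatePedigree <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("id", "sire", "dam") %in% names(records)))
    stop("pedigree needs columns id, sire, dam")
  blank <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  id <- as.character(records$id)
  sire <- blank(records$sire)
  dam <- blank(records$dam)
  if (anyNA(id) || any(id %in% c("", "0")))
    stop("missing or invalid individual id")
  if (anyDuplicated(id))
    stop("duplicated pedigree ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(sire == id, na.rm = TRUE) || any(dam == id, na.rm = TRUE)) {
    bad <- id[which(sire == id | dam == id)]
    stop("individual recorded as its own parent: ",
         paste(bad, collapse = ", "))
  }
  sex <- if ("sex" %in% names(records)) blank(records$sex) else
    rep(NA_character_, length(id))
  litter <- if ("litter" %in% names(records)) blank(records$litter) else
    rep(NA_character_, length(id))
  gen <- if ("generation" %in% names(records))
    as.integer(records$generation) else rep(NA_integer_, length(id))

  # phantom parents become founders of unknown litter/generation
  extra <- setdiff(unique(c(sire, dam)), c(id, NA))
  if (length(extra)) {
    exsex <- ifelse(extra %in% sire, "M", "F")
    id <- c(extra, id)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
    sex <- c(exsex, sex)
    litter <- c(rep(NA_character_, length(extra)), litter)
    gen <- c(rep(NA_integer_, length(extra)), gen)
  }

  # sex consistency: ids used as sire must not be recorded female and v.v.
  sires <- unique(sire[!is.na(sire)])
  dams <- unique(dam[!is.na(dam)])
  both <- intersect(sires, dams)
  if (length(both))
    stop("id used both as sire and as dam: ", paste(both, collapse = ", "))
  conf <- c(sires[sex[match(sires, id)] %in% "F"],
            dams[sex[match(dams, id)] %in% "M"])
  if (length(conf))
    stop("parent sex conflict for: ", paste(conf, collapse = ", "))

  # Kahn topological sort over the parent -> offspring DAG
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    stop("pedigree contains an ancestry cycle involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  df <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                   litter = litter, generation = gen,
                   stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(df) <- NULL
  new("Pedigree", records = df)
}

#' Pedigree structure summary
#'
#' Counts of the standard pedigree categories (records, litters, sires,
#' dams, sires of sires, dams of sires, sires of dams, dams of dams,
#' generations), the shape in which pedigree structure is reported for
#' variance-component analyses of nucleus herds.
#'
#' @param ped a [Pedigree-class]
#' @return named integer vector
#' @export
pedigreeSummary <- function(ped) {
  df <- as.data.frame(ped)
  sires <- unique(df$sire[!is.na(df$sire)])
  dams <- unique(df$dam[!is.na(df$dam)])
  pof <- function(ids, col) {
    i <- match(ids, df$id)
    length(unique(df[[col]][i][!is.na(df[[col]][i])]))
  }
  c(records = nrow(df),
    litters = length(unique(df$litter[!is.na(df$litter)])),
    sires = length(sires), dams = length(dams),
    sires_of_sire = pof(sires, "sire"), dams_of_sire = pof(sires, "dam"),
    sires_of_dam = pof(dams, "sire"), dams_of_dam = pof(dams, "dam"),
    generations = if (all(is.na(df$generation))) NA_integer_ else
      length(unique(df$generation[!is.na(df$generation)])))
}

# parent indices (0 = unknown) for an ordered pedigree
.parentIndex <- function(ped) {
  df <- as.data.frame(ped)
  si <- match(df$sire, df$id); si[is.na(si)] <- 0L
  di <- match(df$dam, df$id); di[is.na(di)] <- 0L
  list(sire = si, dam = di, id = df$id)
}

# tabular-method numerator relationship matrix over the whole pedigree
.aMatrixFull <- function(ped) {
  p <- .parentIndex(ped)
  n <- length(p$id)
  A <- matrix(0, n, n, dimnames = list(p$id, p$id))
  for (i in seq_len(n)) {
    s <- p$sire[i]; d <- p$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' Wright's inbreeding coefficient for every individual, computed by the
#' tabular method: `F_i = a(sire_i, dam_i) / 2`, with unknown parents
#' treated as unrelated non-inbred founders.
#'
#' @param ped a [Pedigree-class]
#' @return named numeric vector of F, in pedigree order
#' @export
inbreeding <- function(ped) {
  A <- .aMatrixFull(ped)
  setNames(diag(A) - 1, rownames(A))
}

#' Numerator relationship matrix
#'
#' Additive (numerator) relationship matrix A by the tabular method.
#' Diagonal entries are `1 + F`. Relationships are always accumulated over
#' the full ancestry; `ids` only restricts the returned rows/columns.
#'
#' @param ped a [Pedigree-class]
#' @param ids optional character vector of individuals to return
#' @return dense symmetric matrix with id dimnames
#' @examples
#' ped <- validatePedigree(data.frame(id = c("s", "d", "o"),
#'                                    sire = c(NA, NA, "s"),
#'                                    dam  = c(NA, NA, "d")))
#' aMatrix(ped)["s", "o"]  # 0.5
#' @export
aMatrix <- function(ped, ids = NULL) {
  A <- .aMatrixFull(ped)
  if (is.null(ids)) return(A)
  miss <- setdiff(ids, rownames(A))
  if (length(miss))
    stop("ids not in pedigree: ", paste(head(miss, 5), collapse = ", "))
  A[ids, ids, drop = FALSE]
}

#' Read / write the pedigree CSV interchange format
#'
#' Columns `id,sire,dam,sex,litter,generation`; `0` or empty marks an
#' unknown parent.
#'
#' @param path file path
#' @return `readPedigree`: a validated [Pedigree-class]
#' @export
readPedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", colClasses = "character")
  if ("generation" %in% names(df))
    df$generation <- suppressWarnings(as.integer(df$generation))
  validatePedigree(df)
}

#' @rdname readPedigree
#' @param ped a [Pedigree-class]
#' @export
writePedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
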