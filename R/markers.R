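#' Encode biallelic allele pairs as {-1, 0, 1} marker covariates
#'
#' A1A1 is coded 1, A2A2 is coded -1, and the heterozygote (either order)
#' is coded 0.
#'
#' @param a1,a2 Character vectors/matrices of allele symbols, each entry
#'   `"A1"` or `"A2"`; `a1` and `a2` are the two alleles of each genotype.
#' @return Integer vector/matrix of the same shape.
#' @export
#' @examples
#' encode_alleles(c("A1", "A2", "A2"), c("A1", "A1", "A2"))  # 1 0 -1
encode_alleles <- function(a1, a2) {
  ok <- c("A1", "A2")
  bad <- setdiff(unique(c(a1, a2)), ok)
  if (length(bad))
    stop("unknown allele symbol(s): ", paste(bad, collapse = ", "))
  x <- (a1 == "A1") + (a2 == "A1") - 1L
  storage.mode(x) <- "integer"
  dim(x) <- dim(a1)
  x
}

#' Mean-center the columns of a marker matrix
#'
#' Subtracts each column's mean and stores the means so they can be
#' re-applied at prediction time.  Idempotent up to numerical noise.
#'
#' @param X Numeric matrix (typically a {-1,0,1} genotype matrix).
#' @return List of class `centered_matrix`: `values` (centered matrix),
#'   `column_means`.
#' @export
center_columns <- function(X) {
  X <- as.matrix(X)
  cm <- colMeans(X)
  structure(list(values = sweep(X, 2, cm), column_means = cm),
            class = "centered_matrix")
}

#' Mean-center a phenotype vector
#'
#' @param y Numeric vector.
#' @return List with `values` (centered) and `mean`.
#' @export
center_phenotype <- function(y) {
  m <- mean(y)
  list(values = y - m, mean = m)
}

#' Drop zero-variance marker columns
#'
#' Columns holding a single distinct value carry no information and break
#' adaptive weighting; they are removed before fitting.  Errors if every
#' column is constant.
#'
#' @param X Genotype matrix.
#' @return List: `X` (filtered matrix), `kept_indices` (positions in the
#'   original column order).
#' @export
filter_zero_variance <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1L)
  if (!any(keep)) stop("all marker columns are constant; no usable markers")
  list(X = X[, keep, drop = FALSE], kept_indices = which(unname(keep)))
}

#' @rdname read_tables
#' @param pop A `population` with trait values attached.
#' @param dir Output directory (created if needed).
#' @export
write_tables <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  X <- genotypes(pop, "all")
  geno <- data.table::data.table(id = rownames(X))
  for (j in seq_len(ncol(X))) geno[[colnames(X)[j]]] <- X[, j]
  data.table::fwrite(geno, file.path(dir, "genotypes.tsv"), sep = "\t")
  ped <- pop$pedigree
  data.table::fwrite(
    data.table::data.table(id = ped$id, sire = ped$sire, dam = ped$dam,
                           family_id = ped$family_id,
                           phenotyped = as.integer(ped$phenotyped)),
    file.path(dir, "pedigree.tsv"), sep = "\t")
  if (!is.null(pop$phenotype))
    data.table::fwrite(
      data.table::data.table(id = names(pop$phenotype), y = pop$phenotype),
      file.path(dir, "phenotypes.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::as.data.table(
      pop$map$markers[, c("marker_id", "chrom", "pos_cm")]),
    file.path(dir, "map.tsv"), sep = "\t")
  if (!is.null(pop$tgv))
    data.table::fwrite(
      data.table::data.table(id = names(pop$tgv), tgv = pop$tgv,
                             tbv = pop$tbv[names(pop$tgv)]),
      file.path(dir, "truth.tsv"), sep = "\t")
  if (!is.null(pop$qtl))
    data.table::fwrite(
      data.table::data.table(marker_id = pop$qtl$marker_id, a = pop$qtl$a,
                             d = pop$qtl$d, p = pop$qtl$p),
      file.path(dir, "qtl.tsv"), sep = "\t")
  invisible(dir)
}

#' Read / write the TSV table dialect
#'
#' `write_tables()` persists a simulated population as the canonical
#' tab-separated tables (genotypes, pedigree, phenotypes, map, truth,
#' qtl); `read_tables()` reads them back, validating genotype coding and
#' id consistency.  The write-then-read round trip is the identity on
#' values and ids, with row order preserved.
#'
#' @param paths Directory containing the tables, or a named list of file
#'   paths (`genotypes`, `pedigree`, `phenotypes`, `map`).
#' @return `read_tables()`: list with `genotypes` (integer matrix, rows =
#'   ids), `phenotypes` (named vector or NULL), `pedigree` (data.frame),
#'   `map` (data.frame), and `truth`/`qtl` when present.
#' @export
read_tables <- function(paths) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    d <- paths
    paths <- list(genotypes = file.path(d, "genotypes.tsv"),
                  pedigree = file.path(d, "pedigree.tsv"),
                  phenotypes = file.path(d, "phenotypes.tsv"),
                  map = file.path(d, "map.tsv"),
                  truth = file.path(d, "truth.tsv"),
                  qtl = file.path(d, "qtl.tsv"))
  }
  geno <- data.table::fread(paths$genotypes, sep = "\t", data.table = FALSE)
  ids <- as.character(geno[[1L]])
  X <- as.matrix(geno[, -1L, drop = FALSE])
  storage.mode(X) <- "integer"
  rownames(X) <- ids
  bad <- which(!(X %in% c(-1L, 0L, 1L)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(X)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(X)) + 1L
    stop("genotype value ", X[i, j], " outside {-1,0,1} at row '", ids[i],
         "', marker '", colnames(X)[j], "'")
  }
  out <- list(genotypes = X)
  if (!is.null(paths$pedigree) && file.exists(paths$pedigree)) {
    ped <- data.table::fread(paths$pedigree, sep = "\t", data.table = FALSE,
                             colClasses = list(character = 1:4))
    ped$phenotyped <- as.logical(ped$phenotyped)
    missing_ids <- setdiff(ped$id, ids)
    if (length(missing_ids))
      stop("pedigree ids absent from genotypes: ",
           paste(head(missing_ids, 5L), collapse = ", "))
    out$pedigree <- ped
  }
  if (!is.null(paths$phenotypes) && file.exists(paths$phenotypes)) {
    phe <- data.table::fread(paths$phenotypes, sep = "\t", data.table = FALSE,
                             colClasses = list(character = 1L))
    missing_ids <- setdiff(phe$id, ids)
    if (length(missing_ids))
      stop("phenotype ids absent from genotypes: ",
           paste(head(missing_ids, 5L), collapse = ", "))
    y <- phe$y
    names(y) <- phe$id
    out$phenotypes <- y
  }
  if (!is.null(paths$map) && file.exists(paths$map)) {
    map <- data.table::fread(paths$map, sep = "\t", data.table = FALSE,
                             colClasses = list(character = 1L))
    if (nrow(map) != ncol(X))
      stop("map has ", nrow(map), " markers but genotypes have ", ncol(X))
    out$map <- map
  }
  for (nm in c("truth", "qtl"))
    if (!is.null(paths[[nm]]) && file.exists(paths[[nm]]))
      out[[nm]] <- data.table::fread(paths[[nm]], sep = "\t",
                                     data.table = FALSE)
  out
}

#' Read a genotype matrix from TSV or PLINK .raw
#'
#' The PLINK `.raw` additive format codes genotypes as 0/1/2 A1-allele
#' dosages; these are mapped to the {-1,0,1} covariate coding via
#' `x = dosage - 1`.
#'
#' @param path File path.
#' @param format `"tsv"` (canonical dialect) or `"plink-raw"`.
#' @return Integer genotype matrix with row ids.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink-raw")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_tables(list(genotypes = path))$genotypes)
  raw <- data.table::fread(path, data.table = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  keep <- setdiff(colnames(raw), meta)
  X <- as.matrix(raw[, keep, drop = FALSE]) - 1L
  storage.mode(X) <- "integer"
  if (any(!(X %in% c(-1L, 0L, 1L))))
    stop("plink-raw dosages outside {0,1,2}")
  rownames(X) <- as.character(raw$IID)
  X
}
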