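#' @importFrom utils write.table read.table write.csv read.csv
NULL

#' Write / read occurrence tables
#'
#' Plain CSV with columns lon, lat and (optionally) region and year.
#'
#' @param occ data.frame with at least lon and lat
#' @param path file path
#' @export
writeOccurrencesCsv <- function(occ, path) {
  stopifnot(all(c("lon", "lat") %in% names(occ)))
  write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeOccurrencesCsv
#' @export
readOccurrencesCsv <- function(path) read.csv(path)

#' Write / read a single raster layer as an ESRI ASCII grid
#'
#' @param mat numeric matrix (row 1 = northern-most row)
#' @param path file path
#' @param cellsize,xll,yll grid geometry of the text header
#' @export
writeAsciiGrid <- function(mat, path, cellsize = 1, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
    paste("xllcorner", xll), paste("yllcorner", yll),
    paste("cellsize", cellsize), "NODATA_value -9999"), con)
  m <- mat
  m[is.na(m)] <- -9999
  write.table(format(m, digits = 10, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2]); names(vals) <- tolower(kv[, 1])
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  stopifnot(nrow(m) == vals[["nrows"]], ncol(m) == vals[["ncols"]])
  m
}

#' Write an EnvStack as one ASCII grid per layer
#'
#' @param env an \linkS4class{EnvStack}
#' @param dir output directory (created if needed)
#' @export
writeEnvStack <- function(env, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in layerNames(env))
    writeAsciiGrid(getLayer(env, nm), file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' @rdname writeEnvStack
#' @export
readEnvStack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc layers in ", dir)
  mats <- lapply(files, readAsciiGrid)
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)),
               dimnames = list(NULL, NULL, sub("\\.asc$", "", basename(files))))
  new("EnvStack", layers = arr)
}

#' Write genotypes as a 0/1/2 matrix TSV (individuals x SNPs)
#'
#' Missing calls are written as NA.  Companion writers emit the population
#' map and the ancestry Q-matrix.
#'
#' @param G a \linkS4class{GenotypeCalls}
#' @param path file path
#' @export
writeGeno012 <- function(G, path) {
  m <- t(genoCalls(G))
  write.table(cbind(individual = rownames(m), as.data.frame(m)), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGeno012
#' @export
writePopMap <- function(G, path) {
  write.table(data.frame(individual = colnames(genoCalls(G)),
                         population = popLabels(G)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGeno012
#' @export
writeQMatrix <- function(G, path) {
  Q <- ancestryQ(G)
  if (is.null(Q)) stop("no ancestry coefficients attached")
  write.table(cbind(individual = colnames(genoCalls(G)),
                    as.data.frame(Q)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 0/1/2 TSV plus population map and Q-matrix into GenotypeCalls
#'
#' @param genoPath TSV written by \code{writeGeno012}
#' @param popPath TSV written by \code{writePopMap}
#' @param qPath optional TSV written by \code{writeQMatrix}
#' @param locus optional locus id per SNP (defaults to one locus per SNP)
#' @export
readGeno012 <- function(genoPath, popPath, qPath = NULL, locus = NULL) {
  tab <- read.table(genoPath, header = TRUE, sep = "\t",
                    check.names = FALSE)
  ind <- tab$individual
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- ind
  pm <- read.table(popPath, header = TRUE, sep = "\t")
  pop <- pm$population[match(ind, pm$individual)]
  Q <- NULL
  if (!is.null(qPath)) {
    qt <- read.table(qPath, header = TRUE, sep = "\t")
    Q <- as.matrix(qt[match(ind, qt$individual), -1, drop = FALSE])
  }
  if (is.null(locus)) locus <- rownames(m)
  GenotypeCalls(m, population = pop, locus = locus, Q = Q)
}

#' Write genotypes as a plain-text GT-only biallelic VCF
#'
#' Minimal VCFv4.2 with the GT FORMAT field only; CHROM is the RAD-locus id
#' and POS the SNP position, so locus grouping survives a round trip.
#'
#' @param G a \linkS4class{GenotypeCalls}
#' @param path output path (uncompressed .vcf)
#' @export
writeVcfGt <- function(G, path) {
  g <- genoCalls(G)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g)), collapse = "\t")), con)
  body <- cbind(locusMap(G),
                SummarizedExperiment::rowData(G)$position,
                rownames(g), "A", "T", ".", "PASS", ".", "GT", gt)
  write.table(body, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
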