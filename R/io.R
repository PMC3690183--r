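#' Read and write GCTA-style phenotype files
#'
#' `.phen` files are whitespace-delimited with columns family id, individual
#' id, value; missing values are written as `NA`.
#'
#' @param data Tibble with `fid`, `iid` and the trait column.
#' @param path Output path.
#' @param trait Trait column to write.
#' @return `write_phen` returns `path` invisibly; `read_phen` returns a
#'   tibble with `fid`, `iid`, `value`.
#' @export
write_phen <- function(data, path, trait) {
  stopifnot(all(c("fid", "iid", trait) %in% names(data)))
  out <- data.frame(data$fid, data$iid,
                    ifelse(is.na(data[[trait]]), "NA",
                           fmt_num(data[[trait]])))
  write.table(out, path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_phen
#' @export
read_phen <- function(path) {
  x <- read.table(path, header = FALSE,
                  col.names = c("fid", "iid", "value"),
                  colClasses = c("character", "character", "character"),
                  na.strings = "NA")
  tibble(fid = x$fid, iid = x$iid, value = as.numeric(x$value))
}

#' Read and write covariate tables
#'
#' Tab-separated, header line, first two columns `fid` and `iid`, remaining
#' columns quantitative covariates (sex, age, principal components, ...).
#'
#' @param data Tibble with `fid`, `iid` and covariate columns.
#' @param path File path.
#' @return `write_covar` returns `path` invisibly; `read_covar` a tibble.
#' @export
write_covar <- function(data, path) {
  stopifnot(all(c("fid", "iid") %in% names(data)))
  write.table(as.data.frame(data), path, quote = FALSE, row.names = FALSE,
              sep = "\t")
  invisible(path)
}

#' @rdname write_covar
#' @export
read_covar <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       colClasses = c("character", "character",
                                      rep(NA, max(0, count_cols(path) - 2)))))
}

count_cols <- function(path) {
  length(strsplit(readLines(path, n = 1), "\t")[[1]])
}

#' Read and write twin-pair tables
#'
#' Tab-separated with header: `pair_id`, `zygosity` (MZ/DZ), `t1_twin1`,
#' `t2_twin1`, `t1_twin2`, `t2_twin2`.
#'
#' @param data A `twin_dataset` tibble.
#' @param path File path.
#' @return `write_twins` returns `path` invisibly; `read_twins` a
#'   `twin_dataset`.
#' @export
write_twins <- function(data, path) {
  cols <- c("pair_id", "zygosity", "t1_twin1", "t2_twin1", "t1_twin2", "t2_twin2")
  stopifnot(all(cols %in% names(data)))
  write.table(as.data.frame(data)[cols], path, quote = FALSE,
              row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_twins
#' @export
read_twins <- function(path) {
  x <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           rep("numeric", 4))))
  class(x) <- c("twin_dataset", class(x))
  x
}

#' Write genotypes as a minimal VCF
#'
#' One pseudo-chromosome, positions taken from the SNP metadata, unphased
#' diploid GT field derived from the dosage (count of ALT alleles); missing
#' dosages become `./.`.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ids <- rownames(geno$dosage)
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=pleiokit",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno$dosage)), function(j) {
    d <- geno$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(geno$info$chrom[j], geno$info$pos[j], geno$info$snp_id[j],
            geno$info$ref[j], geno$info$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write and read genotypes in PLINK text format
#'
#' `<prefix>.ped` carries one line per individual (fid, iid, 0 0 0 -9, then
#' two alleles per SNP, `0 0` when missing); `<prefix>.map` carries
#' chromosome, SNP id, genetic distance 0 and position.
#'
#' @param geno A `genotype_matrix`.
#' @param prefix Path prefix.
#' @return `write_plink` returns `prefix` invisibly; `read_plink` a
#'   `genotype_matrix` (dosage = count of the alternate allele).
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  info <- geno$info
  write.table(data.frame(info$chrom, info$snp_id, 0L, info$pos),
              paste0(prefix, ".map"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  ref <- info$ref; alt <- info$alt
  ids <- rownames(geno$dosage)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(geno$dosage))) {
    d <- geno$dosage[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, alt, ref))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, alt, ref))
    writeLines(paste(c(ids[i], ids[i], "0", "0", "0", "-9",
                       rbind(a1, a2)), collapse = " "), con)
  }
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos"),
                    colClasses = c("character", "character", "numeric",
                                   "integer"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    colClasses = "character")
  m <- nrow(map)
  al <- as.matrix(ped[, 7:(6 + 2 * m), drop = FALSE])
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  # alternate allele = the non-reference allele observed at the SNP; code
  # dosage as its count, taking the lexicographically later allele as ALT
  dosage <- matrix(NA_integer_, nrow(ped), m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    ref[j] <- alleles[1]
    alt[j] <- if (length(alleles) > 1) alleles[2] else alleles[1]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dosage[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    dosage[miss, j] <- NA_integer_
  }
  rownames(dosage) <- ped[[2]]
  colnames(dosage) <- map$snp_id
  info <- tibble(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                 ref = ref, alt = alt, p = NA_real_,
                 freq = colMeans(dosage, na.rm = TRUE) / 2)
  structure(list(dosage = dosage, info = info,
                 subpop = rep(1L, nrow(dosage))),
            class = "genotype_matrix")
}

#' Read genotypes from a VCF written by [write_vcf()]
#'
#' Minimal GT-field parser for biallelic, unphased or phased diploid calls.
#'
#' @param path VCF path (plain text or gzipped).
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort("no #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t")
  m <- length(parts)
  dosage <- matrix(NA_integer_, length(ids), m)
  info <- tibble(snp_id = character(m), chrom = character(m), pos = integer(m),
                 ref = character(m), alt = character(m), p = NA_real_,
                 freq = NA_real_)
  for (j in seq_len(m)) {
    f <- parts[[j]]
    info$chrom[j] <- f[1]; info$pos[j] <- as.integer(f[2])
    info$snp_id[j] <- f[3]; info$ref[j] <- f[4]; info$alt[j] <- f[5]
    gt <- sub(":.*", "", f[-(1:9)])
    gt <- gsub("\\|", "/", gt)
    dosage[, j] <- ifelse(gt %in% c("./.", "."), NA_integer_,
                          (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1"))
  }
  rownames(dosage) <- ids
  colnames(dosage) <- info$snp_id
  info$freq <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, info = info, subpop = rep(1L, length(ids))),
            class = "genotype_matrix")
}
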