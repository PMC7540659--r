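#' Read a PLINK .bed/.bim/.fam file set
#'
#' Reads genotypes stored in the binary PLINK 1 format (SNP-major .bed with
#' the 0x6c 0x1b 0x01 magic) into an allele-content matrix.  Allele content
#' counts copies of the .bim A1 allele by default (0, 1, 2); missing calls
#' become `NA` — no sentinel value ever enters arithmetic.
#'
#' @param prefix path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist
#' @param count_allele which bim allele the content counts: `"A1"` (default)
#'   or `"A2"` (flips orientation, content -> 2 - content)
#' @return an object of class `genotypes`: list with
#'   \describe{
#'     \item{geno}{integer matrix, samples x SNPs, entries 0/1/2/`NA`,
#'       dimnames = sample ids (fam order) and SNP ids}
#'     \item{map}{data frame `snp_id`, `chrom`, `pos_bp`, `a1`, `a2`
#'       (the SNP map, bim order, 1-based positions)}
#'   }
#' @export
read_genotypes <- function(prefix, count_allele = c("A1", "A2")) {
  count_allele <- match.arg(count_allele)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = c("character", "character",
                                             "numeric", "integer",
                                             "character", "character"))
  names(bim_df) <- c("chrom", "snp_id", "cm", "pos_bp", "a1", "a2")
  map <- validate_snp_map(bim_df[, c("snp_id", "chrom", "pos_bp", "a1", "a2")])
  n <- nrow(fam_df); m <- nrow(bim_df)
  ids <- as.character(fam_df[[2L]])
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3L] != as.raw(0x01))
    stop("sample-major .bed not supported")
  bps <- ceiling(n / 4)            # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop("dimension mismatch: .bed holds ", length(raw) - 3L,
         " data bytes but .fam/.bim imply ", bps * m)
  # decode 2-bit codes: 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  body <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, nrow = 4L * bps, ncol = m)
  shift <- c(1L, 4L, 16L, 64L)
  for (k in 1:4)
    codes[seq.int(k, by = 4L, length.out = bps), ] <- (body %/% shift[k]) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)       # indexed by code + 1
  geno <- matrix(lut[codes + 1L], n, m, dimnames = list(ids, map$snp_id))
  if (count_allele == "A2") geno <- 2L - geno
  structure(list(geno = geno, map = map), class = "genotypes")
}

#' Write a genotype set as PLINK .bed/.bim/.fam
#'
#' @param G a `genotypes` object
#' @param prefix output path prefix
#' @param count_allele orientation the matrix is coded in (see
#'   [read_genotypes()])
#' @return `prefix`, invisibly
#' @export
write_genotypes <- function(G, prefix, count_allele = c("A1", "A2")) {
  count_allele <- match.arg(count_allele)
  stopifnot(inherits(G, "genotypes"))
  geno <- G$geno
  if (count_allele == "A2") geno <- 2L - geno
  n <- nrow(geno); m <- ncol(geno)
  fam_df <- data.frame(fid = rownames(geno), iid = rownames(geno),
                       pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam_df, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  map <- G$map
  bim_df <- data.frame(map$chrom, map$snp_id, 0, map$pos_bp,
                       if (is.null(map$a1)) "A" else map$a1,
                       if (is.null(map$a2)) "B" else map$a2)
  utils::write.table(bim_df, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bps <- ceiling(n / 4)
  code <- matrix(1L, 4L * bps, m)               # 01 = missing padding
  x <- geno
  cc <- ifelse(is.na(x), 1L, c(3L, 2L, 0L)[x + 1L])  # content 0->11,1->10,2->00
  code[seq_len(n), ] <- cc
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, bps, m)
  for (k in 1:4)
    bytes <- bytes + code[seq.int(k, by = 4L, length.out = bps), , drop = FALSE] * shift[k]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

validate_snp_map <- function(map) {
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  if (any(map$pos_bp <= 0L)) stop("SNP positions must be strictly positive")
  if (anyDuplicated(map$snp_id) > 0L) stop("duplicated snp_id in map")
  map
}

#' Read a pedigree CSV and sort it topologically
#'
#' Expects columns `animal`, `sire`, `dam`; `0`, empty, or `NA` denote an
#' unknown parent.  Parents referenced but never listed as animals are added
#' as founders.  Output order guarantees parents precede offspring (required
#' by [build_A()]); cyclic pedigrees (an animal its own ancestor) are
#' rejected.
#'
#' @param path CSV file path, or a data frame already in memory
#' @return data frame `animal`, `sire`, `dam` (character, `NA` = unknown),
#'   topologically ordered, class `c("pedigree", "data.frame")`
#' @export
read_pedigree <- function(path) {
  ped <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  clean <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  an <- clean(ped$animal); si <- clean(ped$sire); da <- clean(ped$dam)
  if (anyNA(an)) stop("missing animal id in pedigree")
  if (anyDuplicated(an) > 0L) stop("duplicated animal id in pedigree")
  founders <- setdiff(stats::na.omit(c(si, da)), an)
  an <- c(founders, an)
  si <- c(rep(NA_character_, length(founders)), si)
  da <- c(rep(NA_character_, length(founders)), da)
  n <- length(an)
  sidx <- match(si, an); didx <- match(da, an)
  # Kahn's algorithm: repeatedly emit animals whose parents are all emitted
  emitted <- logical(n); order_out <- integer(0)
  parent_done <- function(p) is.na(p) | emitted[ifelse(is.na(p), 1L, p)]
  repeat {
    ready <- !emitted & parent_done(sidx) & parent_done(didx)
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    emitted[ready] <- TRUE
  }
  if (!all(emitted))
    stop("cyclic pedigree: animal is its own ancestor (",
         paste(utils::head(an[!emitted], 5L), collapse = ", "), ")")
  out <- data.frame(animal = an[order_out], sire = si[order_out],
                    dam = da[order_out], stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Write per-SNP association records as TSV
#'
#' One row per SNP with a stable, Manhattan-plot-ready column order:
#' `snp_id, chrom, pos_bp, effect, se, lrt, p, q, method, trait`.
#'
#' @param records data frame of association records (missing columns are
#'   filled with `NA`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_assoc <- function(records, path) {
  cols <- c("snp_id", "chrom", "pos_bp", "effect", "se", "lrt", "p", "q",
            "method", "trait")
  records <- as.data.frame(records)
  for (cl in setdiff(cols, names(records)))
    records[[cl]] <- rep(NA, nrow(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association TSV written by [write_assoc()]
#' @param path file path
#' @return data frame of association records
#' @export
read_assoc <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(snp_id = "character", chrom = "character"))
}

#' Default run configuration
#'
#' Central knobs of the pipeline with the study's default values: QC
#' thresholds (sample call rate >= 0.90, SNP missingness < 0.05, MAF > 0.05),
#' correction level, pFDR level 0.05, QTL-region gap 1 Mb, annotation window
#' 1 Mb, EM-REML tolerances, and the allele-content orientation switch.
#'
#' @param ... named overrides of any default entry
#' @return a named list of class `run_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    sample_call_rate = 0.90,
    snp_missing_max  = 0.05,
    maf_min          = 0.05,
    correction_level = "chromosome",   # or "genome"
    pfdr             = 0.05,
    region_gap_bp    = 1e6,
    annotation_window_bp = 1e6,
    em_tol           = 1e-6,
    em_maxit         = 500L,
    count_allele     = "A1",
    freq_from        = "observed",     # or "mu" (mu-hat / 2)
    rfi_slopes       = "nested",       # batch-specific; or "common"
    metabolic_exponent = 0.75,
    mid_fattening_day  = 43,
    seed             = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  frac <- c("sample_call_rate", "snp_missing_max", "maf_min", "pfdr")
  for (nm in frac)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("config ", nm, " must lie in (0, 1)")
  if (cfg$region_gap_bp <= 0 || cfg$annotation_window_bp <= 0)
    stop("region gap and annotation window must be > 0")
  if (!cfg$correction_level %in% c("genome", "chromosome"))
    stop("correction_level must be 'genome' or 'chromosome'")
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#' @param path YAML file; entries override [default_config()]
#' @return validated `run_config`
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}
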