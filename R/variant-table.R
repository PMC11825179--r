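#' Construct a variant table
#'
#' A `variant_table` is the central container for a multi-sample SNP matrix:
#' a site table (`chrom`, `pos`, `ref`, `alt`), an integer genotype matrix
#' (sites x samples, coded 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing)
#' and optional per-site numeric INFO annotations.
#'
#' Sites must be sorted by chromosome block and strictly increasing position
#' within each chromosome. Phase is ignored throughout: genotypes are stored
#' as unphased allele doses.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes integer matrix, `nrow(sites)` x `length(samples)`.
#' @param samples character vector of sample identifiers (column order of
#'   `genotypes`).
#' @param info optional data.frame of per-site numeric annotations (e.g.
#'   `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`), `nrow(sites)` rows.
#' @param validate logical; check invariants (default `TRUE`).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, genotypes, samples, info = NULL,
                          validate = TRUE) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.character(samples)
  colnames(genotypes) <- samples
  vt <- structure(
    list(sites = sites, genotypes = genotypes, samples = samples,
         info = info),
    class = "variant_table"
  )
  if (validate) validate_variant_table(vt)
  vt
}

validate_variant_table <- function(vt) {
  sites <- vt$sites
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites)))
    stop("sites must have columns chrom, pos, ref, alt", call. = FALSE)
  if (nrow(sites) != nrow(vt$genotypes))
    stop("genotype matrix has ", nrow(vt$genotypes),
         " rows but sites table has ", nrow(sites), call. = FALSE)
  if (ncol(vt$genotypes) != length(vt$samples))
    stop("genotype matrix has ", ncol(vt$genotypes),
         " columns but there are ", length(vt$samples), " samples",
         call. = FALSE)
  if (!is.null(vt$info) && nrow(vt$info) != nrow(sites))
    stop("info table must have one row per site", call. = FALSE)
  if (nrow(sites) > 1L) {
    # chrom blocks contiguous, pos strictly increasing within chrom
    ch <- as.character(sites$chrom)
    blocks <- rle(ch)$values
    if (anyDuplicated(blocks))
      stop("sites are not grouped by chromosome", call. = FALSE)
    dp <- diff(sites$pos)
    same <- ch[-1L] == ch[-length(ch)]
    if (any(same & dp <= 0))
      stop("positions not strictly increasing within chromosome",
           call. = FALSE)
  }
  bad <- vt$genotypes[!is.na(vt$genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  invisible(vt)
}

#' Number of sites in a variant table
#' @param vt a `variant_table`.
#' @return integer site count.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table: ", n_sites(x), " sites x ", length(x$samples),
      " samples\n", sep = "")
  cat("chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  if (!is.null(x$info))
    cat("info fields:", paste(names(x$info), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a variant table to a set of sites
#'
#' @param vt a `variant_table`.
#' @param keep logical or integer index over sites; order is preserved.
#' @return `variant_table` restricted to the selected sites.
#' @export
subset_sites <- function(vt, keep) {
  if (is.logical(keep)) keep <- which(keep)
  variant_table(
    sites = vt$sites[keep, , drop = FALSE],
    genotypes = vt$genotypes[keep, , drop = FALSE],
    samples = vt$samples,
    info = if (is.null(vt$info)) NULL else vt$info[keep, , drop = FALSE],
    validate = FALSE
  )
}

.info_fields <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Read a VCF file into a variant table
#'
#' Parses a VCF 4.x file (plain or bgzipped). All records are retained,
#' including multiallelic and non-SNP records, which are flagged in the site
#' table (`is_snp`, `is_biallelic`) for [filter_biallelic_snps()]. Missing
#' genotypes (`./.`) become `NA`; genotypes containing alleles other than 0/1
#' (possible only at multiallelic records, which are removed by the filter
#' step) also become `NA`. Phase separators are ignored.
#'
#' @param path path to a VCF file.
#' @param region optional region string `"chrom"` or `"chrom:start-end"`
#'   (1-based, closed) to subset after reading.
#' @return A `variant_table`. Numeric INFO fields QD, FS, MQ, MQRankSum and
#'   ReadPosRankSum are carried in `$info` when present; a raw SnpEff `ANN`
#'   string column is carried as `$info$ANN` when present.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  samples <- colnames(v@gt)[-1L]
  if (is.null(samples)) samples <- character(0)
  nrec <- nrow(fix)
  if (is.null(nrec) || nrec == 0L) {
    return(variant_table(
      sites = data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         is_snp = logical(0), is_biallelic = logical(0),
                         stringsAsFactors = FALSE),
      genotypes = matrix(integer(0), nrow = 0, ncol = length(samples)),
      samples = samples
    ))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  is_biallelic <- !grepl(",", alt, fixed = TRUE) & alt != "."
  is_snp <- is_biallelic & nchar(ref) == 1L & nchar(alt) == 1L &
    ref != alt & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    is_snp = is_snp, is_biallelic = is_biallelic,
    stringsAsFactors = FALSE
  )
  if (anyNA(sites$pos))
    stop("malformed VCF: non-numeric POS at record ",
         which(is.na(sites$pos))[1L], call. = FALSE)
  geno <- .parse_gt(v, nrec, samples)
  info <- .parse_info(v)
  vt <- variant_table(sites, geno, samples, info = info)
  if (!is.null(region)) vt <- .subset_region(vt, region)
  vt
}

.parse_gt <- function(v, nrec, samples) {
  if (length(samples) == 0L)
    return(matrix(integer(0), nrow = nrec, ncol = 0))
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- code[g]
  out <- matrix(as.integer(out), nrow = nrec, ncol = length(samples))
  colnames(out) <- samples
  out
}

.parse_info <- function(v) {
  raw <- v@fix[, "INFO"]
  if (all(is.na(raw) | raw == ".")) return(NULL)
  cols <- list()
  for (f in .info_fields) {
    if (any(grepl(paste0("(^|;)", f, "="), raw))) {
      val <- suppressWarnings(vcfR::extract.info(v, element = f,
                                                 as.numeric = FALSE))
      num <- suppressWarnings(as.numeric(val))
      if (any(!is.na(val) & is.na(num)))
        stop("non-numeric value for INFO field ", f, call. = FALSE)
      cols[[f]] <- num
    }
  }
  if (any(grepl("(^|;)ANN=", raw)))
    cols[["ANN"]] <- vcfR::extract.info(v, element = "ANN",
                                        as.numeric = FALSE)
  if (length(cols) == 0L) return(NULL)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

.subset_region <- function(vt, region) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1L]]
  if (length(m) == 0L) stop("cannot parse region: ", region, call. = FALSE)
  keep <- vt$sites$chrom == m[2L]
  if (m[3L] != "") {
    keep <- keep & vt$sites$pos >= as.integer(m[4L]) &
      vt$sites$pos <= as.integer(m[5L])
  }
  subset_sites(vt, keep)
}

#' Write a variant table as a plain-text VCF 4.2 file
#'
#' Coordinates, alleles and genotypes round-trip bit-exactly through
#' [read_vcf()]. Numeric INFO fields present in `vt$info` are emitted.
#'
#' @param vt a `variant_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  hdr <- c("##fileformat=VCFv4.2")
  info_cols <- intersect(.info_fields, names(vt$info))
  for (f in info_cols)
    hdr <- c(hdr, sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", f, f))
  if ("ANN" %in% names(vt$info))
    hdr <- c(hdr, "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">")
  hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", vt$samples),
                      collapse = "\t"))
  n <- n_sites(vt)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  info_str <- rep(".", n)
  if (length(info_cols) || "ANN" %in% names(vt$info)) {
    parts <- lapply(c(info_cols, intersect("ANN", names(vt$info))), function(f) {
      v <- vt$info[[f]]
      ifelse(is.na(v), NA_character_, paste0(f, "=", v))
    })
    info_str <- apply(do.call(cbind, parts), 1L, function(r)
      if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
  }
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[vt$genotypes + 1L],
                   nrow = n, ncol = length(vt$samples))
  gt_chr[is.na(gt_chr)] <- "./."
  body <- paste(vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref,
                vt$sites$alt, ".", ".", info_str, "GT", sep = "\t")
  if (length(vt$samples))
    body <- paste(body, apply(gt_chr, 1L, paste, collapse = "\t"),
                  sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Keep only biallelic SNPs
#'
#' Removes indels, multiallelic records and any record whose REF or ALT is
#' not a single A/C/G/T base. Site order is preserved.
#'
#' @param vt a `variant_table` from [read_vcf()] (or any table with single
#'   base `ref`/`alt` columns).
#' @return filtered `variant_table` with the flag columns dropped.
#' @export
filter_biallelic_snps <- function(vt) {
  s <- vt$sites
  if ("is_snp" %in% names(s)) {
    keep <- s$is_snp
  } else {
    keep <- nchar(s$ref) == 1L & nchar(s$alt) == 1L &
      !grepl(",", s$alt, fixed = TRUE) & s$ref != s$alt &
      s$ref %in% c("A", "C", "G", "T") & s$alt %in% c("A", "C", "G", "T")
  }
  out <- subset_sites(vt, keep)
  out$sites$is_snp <- NULL
  out$sites$is_biallelic <- NULL
  out
}

#' Apply GATK-style hard filters on site annotations
#'
#' A site is removed iff any clause of the standard hard-filter expression
#' fires: `QD < 2.0 || FS > 60.0 || MQ < 40.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0`. An absent (NA) annotation never triggers removal.
#'
#' @param vt a `variant_table`.
#' @param qd_min,fs_max,mq_min,mqranksum_min,readposranksum_min clause
#'   thresholds.
#' @return filtered `variant_table`.
#' @export
apply_hard_filter <- function(vt, qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                              mqranksum_min = -12.5,
                              readposranksum_min = -8.0) {
  info <- vt$info
  n <- n_sites(vt)
  if (is.null(info) || n == 0L) return(vt)
  clause <- function(field, fail) {
    v <- info[[field]]
    if (is.null(v)) return(rep(FALSE, n))
    if (!is.numeric(v)) stop("INFO field ", field, " is not numeric",
                             call. = FALSE)
    out <- fail(v)
    out[is.na(out)] <- FALSE
    out
  }
  drop <- clause("QD", function(v) v < qd_min) |
    clause("FS", function(v) v > fs_max) |
    clause("MQ", function(v) v < mq_min) |
    clause("MQRankSum", function(v) v < mqranksum_min) |
    clause("ReadPosRankSum", function(v) v < readposranksum_min)
  subset_sites(vt, !drop)
}

#' Filter sites by per-population missingness
#'
#' A site is removed iff, in any population of the panel, the fraction of
#' missing genotypes among that population's members strictly exceeds
#' `max_missing_frac`. Failing sites are dropped globally so all populations
#' share one site set.
#'
#' @param vt a `variant_table`.
#' @param panel a [sample_panel()] covering every sample in `vt`.
#' @param max_missing_frac maximum tolerated missing fraction (default 0.20).
#' @return filtered `variant_table`.
#' @export
filter_missingness <- function(vt, panel, max_missing_frac = 0.20) {
  missing_panel <- setdiff(vt$samples, names(panel$assignments))
  if (length(missing_panel))
    stop("samples absent from panel: ",
         paste(missing_panel, collapse = ", "), call. = FALSE)
  if (n_sites(vt) == 0L) return(vt)
  drop <- rep(FALSE, n_sites(vt))
  for (pop in names(panel$populations)) {
    members <- intersect(panel$populations[[pop]], vt$samples)
    if (length(members) == 0L) next
    g <- vt$genotypes[, members, drop = FALSE]
    frac <- rowMeans(is.na(g))
    drop <- drop | frac > max_missing_frac
  }
  subset_sites(vt, !drop)
}

# Coordinate key for matching site tables; positions are formatted as
# plain integers so numeric and integer columns compare equal.
site_key <- function(chrom, pos) {
  paste(chrom, sprintf("%.0f", as.numeric(pos)), sep = "\r")
}
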