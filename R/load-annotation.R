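#' Effect-class vocabulary
#'
#' Variants are binned into mutational-load categories from their SnpEff /
#' Sequence Ontology annotation terms. Loss-of-function (LoF) comprises
#' stop-gained and splice acceptor/donor disruptions; missense and
#' synonymous map from the standard vocabulary; intergenic variants serve
#' as the neutral class; every other recognized term maps to `other`.
#' Deleterious nonsynonymous SNPs (dnsSNP, Grantham distance >= 150) are a
#' flagged subset of missense.
#'
#' @name effect_classes
NULL

.effect_map <- c(
  stop_gained = "LoF",
  splice_acceptor_variant = "LoF",
  splice_donor_variant = "LoF",
  missense_variant = "missense",
  synonymous_variant = "synonymous",
  intergenic_region = "intergenic",
  intergenic_variant = "intergenic"
)

# Recognized terms that carry no load class here; mapped to "other"
# silently (an unknown term still maps to "other" but with a warning).
.known_other <- c(
  "intron_variant", "upstream_gene_variant", "downstream_gene_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant", "start_lost", "stop_lost",
  "stop_retained_variant", "splice_region_variant",
  "non_coding_transcript_variant", "non_coding_transcript_exon_variant",
  "initiator_codon_variant", "frameshift_variant",
  "conservative_inframe_deletion", "conservative_inframe_insertion",
  "disruptive_inframe_deletion", "disruptive_inframe_insertion",
  "gene_fusion", "intragenic_variant"
)

.severity <- c(LoF = 4L, missense = 3L, synonymous = 2L, intergenic = 1L,
               other = 0L)

#' Classify variant effect annotations
#'
#' Maps raw annotation terms to load classes (see [effect_classes]) and
#' flags dnsSNPs among missense variants when amino-acid change columns are
#' present. When a site carries several annotations (multi-transcript), the
#' most severe class is kept, severity order LoF > missense > synonymous >
#' intergenic > other. Unrecognized terms raise a warning and map to
#' `other`; they are never dropped.
#'
#' @param annotations data.frame with columns `chrom`, `pos`, `term` and
#'   optionally `aa_ref`, `aa_alt` (one- or three-letter codes; empty or NA
#'   when not applicable).
#' @param dnssnp_threshold Grantham cutoff, inclusive (default 150).
#' @return data.frame with one row per site: `chrom`, `pos`, `class`,
#'   `term`, `aa_ref`, `aa_alt`, `grantham`, `dnssnp`.
#' @export
classify_effects <- function(annotations, dnssnp_threshold = 150) {
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "term") %in% names(ann)))
  if (!"aa_ref" %in% names(ann)) ann$aa_ref <- NA_character_
  if (!"aa_alt" %in% names(ann)) ann$aa_alt <- NA_character_
  ann$aa_ref[!is.na(ann$aa_ref) & ann$aa_ref == ""] <- NA_character_
  ann$aa_alt[!is.na(ann$aa_alt) & ann$aa_alt == ""] <- NA_character_
  cls <- unname(.effect_map[ann$term])
  unknown <- is.na(cls) & !(ann$term %in% .known_other)
  if (any(unknown))
    warning("unrecognized effect term(s) mapped to 'other': ",
            paste(unique(ann$term[unknown]), collapse = ", "),
            call. = FALSE)
  cls[is.na(cls)] <- "other"
  ann$class <- cls
  # most severe annotation per site
  key <- site_key(ann$chrom, ann$pos)
  ord <- order(match(ann$chrom, unique(ann$chrom)), ann$pos,
               -.severity[ann$class])
  ann <- ann[ord, ]
  key <- key[ord]
  ann <- ann[!duplicated(key), , drop = FALSE]
  g <- rep(NA_real_, nrow(ann))
  dns <- rep(FALSE, nrow(ann))
  has_aa <- ann$class == "missense" & !is.na(ann$aa_ref) & !is.na(ann$aa_alt)
  if (any(has_aa)) {
    gr <- grantham(ann$aa_ref[has_aa], ann$aa_alt[has_aa],
                   dnssnp_threshold = dnssnp_threshold)
    g[has_aa] <- gr$distance
    dns[has_aa] <- gr$dnssnp
  }
  out <- data.frame(chrom = ann$chrom, pos = ann$pos, class = ann$class,
                    term = ann$term, aa_ref = ann$aa_ref,
                    aa_alt = ann$aa_alt, grantham = g, dnssnp = dns,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a flat effect-annotation TSV
#'
#' Expected columns (tab-separated, with header): `chrom`, `pos`, `term`
#' and optionally `aa_ref`, `aa_alt`.
#'
#' @param path file path.
#' @return raw annotation data.frame suitable for [classify_effects()].
#' @export
read_effects <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Extract effect annotations from a SnpEff ANN INFO field
#'
#' Pulls the effect term (and amino-acid change, `p.Xxx123Yyy` style) of
#' every ANN entry at each site of a variant table read with [read_vcf()].
#' `&`-joined terms within one entry are split. The result feeds
#' [classify_effects()], which resolves multi-transcript annotations by
#' severity.
#'
#' @param vt a `variant_table` whose `$info$ANN` column is present.
#' @return raw annotation data.frame (`chrom`, `pos`, `term`, `aa_ref`,
#'   `aa_alt`).
#' @export
effects_from_ann <- function(vt) {
  ann <- vt$info$ANN
  if (is.null(ann))
    stop("variant table has no ANN INFO field", call. = FALSE)
  rows <- list()
  for (i in seq_along(ann)) {
    if (is.na(ann[i])) next
    for (entry in strsplit(ann[i], ",", fixed = TRUE)[[1L]]) {
      fields <- strsplit(entry, "|", fixed = TRUE)[[1L]]
      if (length(fields) < 2L) next
      terms <- strsplit(fields[2L], "&", fixed = TRUE)[[1L]]
      aa_ref <- aa_alt <- NA_character_
      if (length(fields) >= 11L && grepl("^p\\.", fields[11L])) {
        m <- regmatches(fields[11L],
                        regexec("^p\\.([A-Za-z]{3})[0-9]+([A-Za-z]{3})$",
                                fields[11L]))[[1L]]
        if (length(m) == 3L) { aa_ref <- m[2L]; aa_alt <- m[3L] }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = vt$sites$chrom[i], pos = vt$sites$pos[i], term = terms,
        aa_ref = aa_ref, aa_alt = aa_alt, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      term = character(0), aa_ref = character(0),
                      aa_alt = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Polarize alleles to ancestral/derived with an outgroup
#'
#' An allele is called ancestral iff (i) it equals the outgroup allele at
#' that site and (ii) its frequency in the focal population strictly
#' exceeds 0.5. The other allele is derived. Sites where the outgroup
#' allele is absent or matches neither REF nor ALT, or where the frequency
#' condition fails (<= 0.5), are UNRESOLVED and excluded from all
#' derived-allele statistics. Derived-allele counts `m` and called-allele
#' counts `s` are tabulated for every population in the panel.
#'
#' @param vt a biallelic `variant_table`.
#' @param outgroup data.frame with columns `chrom`, `pos`, `allele`
#'   (A/C/G/T).
#' @param panel a [sample_panel()].
#' @param focal_population population whose allele frequency drives the
#'   majority rule; `NULL` (default) pools all samples, i.e. a
#'   species-level frequency.
#' @return An object of class `polarized_table`: `$sites` (chrom, pos, ref,
#'   alt, `ancestral` in {"ref","alt"} or NA for UNRESOLVED), and matrices
#'   `$m`, `$s` (sites x populations; NA at unresolved sites).
#' @export
polarize <- function(vt, outgroup, panel, focal_population = NULL) {
  og <- as.data.frame(outgroup, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "allele") %in% names(og)))
  badbase <- !is.na(og$allele) & !(og$allele %in% c("A", "C", "G", "T"))
  if (any(badbase))
    stop("outgroup allele not in {A,C,G,T} at ",
         og$chrom[badbase][1L], ":", og$pos[badbase][1L], call. = FALSE)
  key_vt <- site_key(vt$sites$chrom, vt$sites$pos)
  key_og <- site_key(og$chrom, og$pos)
  og_allele <- og$allele[match(key_vt, key_og)]

  if (is.null(focal_population)) {
    focal_members <- vt$samples
  } else {
    if (!focal_population %in% names(panel$populations))
      stop("unknown focal population: ", focal_population, call. = FALSE)
    focal_members <- intersect(panel$populations[[focal_population]],
                               vt$samples)
  }
  gf <- vt$genotypes[, focal_members, drop = FALSE]
  n_f <- 2 * rowSums(!is.na(gf))
  j_f <- rowSums(gf, na.rm = TRUE)
  f_alt <- ifelse(n_f > 0, j_f / n_f, NA_real_)

  ancestral <- rep(NA_character_, n_sites(vt))
  ref_anc <- !is.na(og_allele) & og_allele == vt$sites$ref &
    !is.na(f_alt) & (1 - f_alt) > 0.5
  alt_anc <- !is.na(og_allele) & og_allele == vt$sites$alt &
    !is.na(f_alt) & f_alt > 0.5
  ancestral[ref_anc] <- "ref"
  ancestral[alt_anc] <- "alt"

  pops <- names(panel$populations)
  m <- s <- matrix(NA_real_, nrow = n_sites(vt), ncol = length(pops),
                   dimnames = list(NULL, pops))
  for (p in pops) {
    members <- intersect(panel$populations[[p]], vt$samples)
    g <- vt$genotypes[, members, drop = FALSE]
    n_al <- 2 * rowSums(!is.na(g))
    j <- rowSums(g, na.rm = TRUE)
    # derived is alt when ancestral is ref, and vice versa
    m[, p] <- ifelse(is.na(ancestral), NA_real_,
                     ifelse(ancestral == "ref", j, n_al - j))
    s[, p] <- ifelse(is.na(ancestral), NA_real_, n_al)
  }
  polarized_table(
    sites = data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
                       ref = vt$sites$ref, alt = vt$sites$alt,
                       ancestral = ancestral, stringsAsFactors = FALSE),
    m = m, s = s)
}

#' Construct a polarized table directly from counts
#'
#' Lower-level constructor used by [polarize()] and by simulations or tests
#' that already have per-site derived (`m`) and called (`s`) allele counts
#' per population.
#'
#' @param sites data.frame with at least `chrom`, `pos` and an `ancestral`
#'   column ("ref"/"alt"/NA).
#' @param m,s numeric matrices, sites x populations, with matching
#'   population column names; `0 <= m <= s` where defined.
#' @return an object of class `polarized_table`.
#' @export
polarized_table <- function(sites, m, s) {
  m <- as.matrix(m); s <- as.matrix(s)
  stopifnot(nrow(sites) == nrow(m), nrow(m) == nrow(s),
            identical(colnames(m), colnames(s)))
  ok <- !is.na(m) & !is.na(s)
  if (any(m[ok] < 0) || any(m[ok] > s[ok]))
    stop("derived counts must satisfy 0 <= m <= s", call. = FALSE)
  structure(list(sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 m = m, s = s, populations = colnames(m)),
            class = "polarized_table")
}

#' @export
print.polarized_table <- function(x, ...) {
  cat("polarized_table: ", nrow(x$sites), " sites, ",
      sum(!is.na(x$sites$ancestral)), " resolved; populations: ",
      paste(x$populations, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-sample derived-allele dose matrix
#'
#' Converts the ref/alt genotype coding into derived-allele dose (0, 1, 2)
#' using the ancestral calls of a polarized table. Note that at sites where
#' the derived allele is REF, a hom-ref genotype is a derived homozygote
#' (dose 2). Unresolved sites and missing genotypes are NA.
#'
#' @param vt a `variant_table`.
#' @param polar a `polarized_table` over the same sites (same order).
#' @return integer matrix, sites x samples.
#' @export
derived_dose <- function(vt, polar) {
  stopifnot(nrow(polar$sites) == n_sites(vt))
  anc <- polar$sites$ancestral
  g <- vt$genotypes
  dose <- g
  flip <- which(!is.na(anc) & anc == "alt")
  dose[flip, ] <- 2L - g[flip, , drop = FALSE]
  dose[is.na(anc), ] <- NA_integer_
  dose
}

#' Tabulate per-individual derived mutational load
#'
#' For each individual and category (LoF, missense, dnsSNP, synonymous),
#' counts heterozygous sites (`n_het`) and derived-homozygous sites
#' (`n_hom`); `n_total = n_het + n_hom` is the number of sites carrying at
#' least one derived allele. dnsSNP is a subset of missense. Unresolved
#' sites and missing genotypes are skipped.
#'
#' @param vt a `variant_table`.
#' @param effects classified effects from [classify_effects()].
#' @param polar a `polarized_table` over the same sites as `vt`.
#' @param panel a [sample_panel()].
#' @param categories categories to tabulate.
#' @return list with data.frames `$individual` (sample, population,
#'   category, n_het, n_hom, n_total) and `$population` (per-population
#'   totals and per-individual means).
#' @export
tabulate_load <- function(vt, effects, polar, panel,
                          categories = c("LoF", "missense", "dnsSNP",
                                         "synonymous")) {
  dose <- derived_dose(vt, polar)
  masks <- category_site_masks(vt, effects, categories)
  rows <- list()
  for (cat in categories) {
    mask <- masks[[cat]]
    d <- dose[mask, , drop = FALSE]
    n_het <- colSums(d == 1L, na.rm = TRUE)
    n_hom <- colSums(d == 2L, na.rm = TRUE)
    rows[[cat]] <- data.frame(
      sample = vt$samples,
      population = unname(panel$assignments[vt$samples]),
      category = cat, n_het = n_het, n_hom = n_hom,
      n_total = n_het + n_hom, row.names = NULL,
      stringsAsFactors = FALSE)
  }
  ind <- do.call(rbind, c(rows, make.row.names = FALSE))
  pop <- do.call(rbind, lapply(split(ind, ind[c("population", "category")], drop = TRUE),
                               function(d) data.frame(
                                 population = d$population[1L],
                                 category = d$category[1L],
                                 mean_het = mean(d$n_het),
                                 mean_hom = mean(d$n_hom),
                                 mean_total = mean(d$n_total),
                                 total = sum(d$n_total),
                                 stringsAsFactors = FALSE)))
  rownames(pop) <- NULL
  list(individual = ind, population = pop)
}

#' Per-category site masks over a variant table
#'
#' Maps classified effects onto the sites of a variant table and returns
#' one logical mask per category (`dnsSNP` selects flagged missense
#' sites). Used to pick the site sets for [rxy()], [rohf_statistics()]
#' and [sfs()].
#'
#' @param vt a `variant_table`.
#' @param effects classified effects from [classify_effects()].
#' @param categories categories to build masks for.
#' @return named list of logical vectors over the sites of `vt`.
#' @export
category_site_masks <- function(vt, effects,
                                categories = c("LoF", "missense", "dnsSNP",
                                               "synonymous", "intergenic")) {
  key_vt <- site_key(vt$sites$chrom, vt$sites$pos)
  key_ef <- site_key(effects$chrom, effects$pos)
  idx <- match(key_vt, key_ef)
  cls <- effects$class[idx]
  dns <- effects$dnssnp[idx]
  out <- list()
  for (cat in categories) {
    out[[cat]] <- if (cat == "dnsSNP") !is.na(dns) & dns
    else !is.na(cls) & cls == cat
  }
  out
}

#' Homozygous share of the derived load
#'
#' Per individual: `2 n_hom / (2 n_hom + n_het)`, the fraction of an
#' individual's derived alleles (in a category) that sit in homozygous
#' state. Undefined (NA) when the individual carries no derived allele in
#' the category.
#'
#' @param load result of [tabulate_load()].
#' @param category optional single category to restrict to.
#' @return list with `$individual` (sample, population, category, ratio)
#'   and `$population` (mean ratio over individuals with a defined value).
#' @export
hom_load_ratio <- function(load, category = NULL) {
  ind <- load$individual
  if (!is.null(category)) ind <- ind[ind$category %in% category, ]
  denom <- 2 * ind$n_hom + ind$n_het
  ind$ratio <- ifelse(denom > 0, 2 * ind$n_hom / denom, NA_real_)
  ind <- ind[, c("sample", "population", "category", "ratio")]
  pop <- do.call(rbind, lapply(split(ind, ind[c("population", "category")], drop = TRUE),
                               function(d) data.frame(
                                 population = d$population[1L],
                                 category = d$category[1L],
                                 mean_ratio = mean(d$ratio, na.rm = TRUE),
                                 stringsAsFactors = FALSE)))
  rownames(pop) <- NULL
  list(individual = ind, population = pop)
}

#' Read a per-site outgroup-allele TSV (chrom, pos, allele)
#' @param path file path (tab-separated, with header).
#' @return data.frame for [polarize()].
#' @export
read_outgroup <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
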