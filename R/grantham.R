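#' @title Grantham amino-acid distances
#' @description The Grantham (1974) physicochemical distance between two
#' amino acids combines side-chain composition `c` (atomic weight ratio of
#' hetero elements to carbon), polarity `p` and molecular volume `v`:
#'
#'   D(i, j) = rho * sqrt(alpha (c_i - c_j)^2 + beta (p_i - p_j)^2 +
#'                        gamma (v_i - v_j)^2)
#'
#' with the published constants alpha = 1.833, beta = 0.1018,
#' gamma = 0.000399 and the scale factor rho = 50.723 chosen so the mean
#' distance over all amino-acid pairs is 100. Distances of at least 150 mark
#' radical substitutions: a missense variant with Grantham distance >= 150
#' is classed as a deleterious nonsynonymous SNP (dnsSNP).
#' @name grantham
NULL

# Grantham (1974) property values: composition, polarity, molecular volume.
.grantham_properties <- data.frame(
  aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
         "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE
)

.grantham_env <- new.env(parent = emptyenv())

#' Grantham distance matrix
#'
#' Recomputes the 20 x 20 Grantham distance matrix from the published
#' amino-acid property values (see [grantham]). The matrix is symmetric
#' with a zero diagonal; unrounded distances are returned (the published
#' table is these values rounded to integers).
#'
#' @return numeric 20 x 20 matrix with one-letter amino-acid dimnames.
#' @export
grantham_matrix <- function() {
  if (!is.null(.grantham_env$mat)) return(.grantham_env$mat)
  pr <- .grantham_properties
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399; rho <- 50.723
  dc <- outer(pr$c, pr$c, "-")
  dp <- outer(pr$p, pr$p, "-")
  dv <- outer(pr$v, pr$v, "-")
  m <- rho * sqrt(alpha * dc^2 + beta * dp^2 + gamma * dv^2)
  dimnames(m) <- list(pr$aa, pr$aa)
  .grantham_env$mat <- m
  m
}

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

.normalize_aa <- function(aa) {
  aa <- as.character(aa)
  out <- ifelse(nchar(aa) == 3, unname(.aa3to1[paste0(
    toupper(substr(aa, 1, 1)), tolower(substr(aa, 2, 3)))]),
    toupper(aa))
  bad <- is.na(out) | !(out %in% .grantham_properties$aa)
  if (any(bad))
    stop("nonstandard amino acid(s): ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Grantham distance between two amino acids
#'
#' @param aa1,aa2 amino acids, one-letter or three-letter codes
#'   (vectorized).
#' @param dnssnp_threshold distance at or above which a substitution is
#'   flagged deleterious (default 150, inclusive).
#' @return data.frame with `distance` and logical `dnssnp`.
#' @export
grantham <- function(aa1, aa2, dnssnp_threshold = 150) {
  a1 <- .normalize_aa(aa1)
  a2 <- .normalize_aa(aa2)
  m <- grantham_matrix()
  d <- m[cbind(a1, a2)]
  data.frame(aa1 = a1, aa2 = a2, distance = d,
             dnssnp = d >= dnssnp_threshold,
             stringsAsFactors = FALSE)
}
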