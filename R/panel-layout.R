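#' Construct a sample panel
#'
#' Maps each sample to exactly one population.
#'
#' @param assignments named character vector: names are sample identifiers,
#'   values are population labels.
#' @return An object of class `sample_panel` with `$assignments` and
#'   `$populations` (label -> ordered member vector).
#' @export
sample_panel <- function(assignments) {
  assignments <- unlist(assignments)
  if (is.null(names(assignments)) || any(names(assignments) == ""))
    stop("assignments must be a named vector (sample -> population)",
         call. = FALSE)
  if (anyDuplicated(names(assignments)))
    stop("every sample must be assigned to exactly one population",
         call. = FALSE)
  pops <- split(names(assignments), factor(assignments,
                                           levels = unique(assignments)))
  if (any(lengths(pops) == 0L))
    stop("empty population in panel", call. = FALSE)
  structure(list(assignments = assignments, populations = pops),
            class = "sample_panel")
}

#' Read a sample panel from a two-column headerless TSV (sample, population)
#' @param path file path.
#' @return a [sample_panel()].
#' @export
read_sample_panel <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  sample_panel(stats::setNames(df$population, df$sample))
}

#' Write a sample panel to TSV
#' @param panel a [sample_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_panel <- function(panel, path) {
  utils::write.table(
    data.frame(sample = names(panel$assignments),
               population = unname(panel$assignments)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a genome layout
#'
#' Chromosome lengths plus the set of chromosomes treated as autosomes.
#' `L_AUTOSOME`, the denominator of F_ROH, is the summed length of the
#' autosomes only.
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @param autosomes character vector of autosome names (default: all
#'   chromosomes in `lengths`).
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(lengths, autosomes = names(lengths)) {
  if (is.null(names(lengths)))
    stop("lengths must be named by chromosome", call. = FALSE)
  if (any(lengths <= 0)) stop("chromosome lengths must be positive",
                              call. = FALSE)
  if (!all(autosomes %in% names(lengths)))
    stop("autosomes not present in lengths: ",
         paste(setdiff(autosomes, names(lengths)), collapse = ", "),
         call. = FALSE)
  structure(list(lengths = lengths, autosomes = autosomes),
            class = "genome_layout")
}

#' Total autosome length of a layout
#' @param layout a [genome_layout()].
#' @return numeric, summed autosome length in bp.
#' @export
autosome_length <- function(layout) {
  sum(layout$lengths[layout$autosomes])
}

#' Read a genome layout from a two-column TSV (chrom, length)
#' @param path file path.
#' @param autosomes optional autosome subset (default: every chromosome).
#' @return a [genome_layout()].
#' @export
read_genome_layout <- function(path, autosomes = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  lens <- stats::setNames(df$length, df$chrom)
  genome_layout(lens, autosomes = if (is.null(autosomes)) names(lens)
                else autosomes)
}

#' Write a genome layout to TSV
#' @param layout a [genome_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(
    data.frame(chrom = names(layout$lengths),
               length = unname(layout$lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
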