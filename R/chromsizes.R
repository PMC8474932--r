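#' Chromosome sizes table
#'
#' Construct the genome table used to validate contact records and to place
#' simulated contacts. Each chromosome carries a length in base pairs and a
#' role flag (`"autosome"`, `"chrX"` or `"other"`). Exactly one chromosome
#' must be flagged `chrX`.
#'
#' @param name character vector of chromosome names.
#' @param length integer vector of lengths in bp (> 0).
#' @param role character vector, one of `"autosome"`, `"chrX"`, `"other"`.
#'   Defaults to `"chrX"` for a chromosome named `"chrX"`, `"autosome"`
#'   otherwise.
#' @return object of class `chrom_sizes`: a data.frame with columns `name`,
#'   `length`, `role`.
#' @examples
#' chrom_sizes(c("chr1", "chrX"), c(195e6, 171e6))
#' @export
chrom_sizes <- function(name, length,
                        role = ifelse(name == "chrX", "chrX", "autosome")) {
  name <- as.character(name)
  length <- as.numeric(length)
  role <- as.character(role)
  if (anyDuplicated(name)) abort("duplicated chromosome names")
  if (any(!is.finite(length)) || any(length <= 0))
    abort("chromosome lengths must be positive")
  if (!all(role %in% c("autosome", "chrX", "other")))
    abort("role must be 'autosome', 'chrX' or 'other'")
  if (sum(role == "chrX") != 1L)
    abort("exactly one chromosome must be flagged chrX")
  structure(data.frame(name = name, length = length, role = role,
                       stringsAsFactors = FALSE),
            class = c("chrom_sizes", "data.frame"))
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp. No header.
#'
#' @param path file path.
#' @param ... passed to [chrom_sizes()] (e.g. `role`).
#' @return a `chrom_sizes` object.
#' @export
read_chrom_sizes <- function(path, ...) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "length"),
                           stringsAsFactors = FALSE)
  chrom_sizes(tab$name, tab$length, ...)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("Genome table:", nrow(x), "chromosomes\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# internal helpers
chrom_length <- function(genome, chrom) {
  genome$length[match(chrom, genome$name)]
}
autosomes <- function(genome) genome$name[genome$role == "autosome"]
x_chrom <- function(genome) genome$name[genome$role == "chrX"]
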