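#' Chromosome sizes
#'
#' A named vector of chromosome lengths in base pairs. Lengths must be
#' positive integers and names unique; the order given is preserved, so
#' iteration over chromosomes is reproducible.
#'
#' @param lengths numeric vector of chromosome lengths in bp. May be named;
#'   otherwise `names` must be supplied.
#' @param names optional character vector of chromosome names.
#' @return A `chrom_sizes` object (named numeric vector).
#' @examples
#' chrom_sizes(c(chr1 = 2e6, chr2 = 1e6))
#' @export
chrom_sizes <- function(lengths, names = NULL) {
  if (!is.null(names)) names(lengths) <- names
  nm <- base::names(lengths)
  if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
    stop("every chromosome must be named")
  if (anyDuplicated(nm))
    stop("duplicated chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  len <- as.numeric(lengths)
  if (any(!is.finite(len)) || any(len <= 0) || any(len != floor(len)))
    stop("chromosome lengths must be positive integers")
  structure(setNames(len, nm), class = "chrom_sizes")
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a tab-separated file with columns name, length.
#' @return A [chrom_sizes()] object.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("malformed chrom.sizes line ", bad[1], " in ", path)
  chrom_sizes(as.numeric(vapply(parts, `[[`, "", 2L)),
              names = vapply(parts, `[[`, "", 1L))
}

#' Write a chrom.sizes file
#'
#' @param sizes a [chrom_sizes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste0(names(sizes), "\t", format_bp(unname(sizes))), path)
  invisible(path)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("chrom_sizes: ", length(x), " chromosome(s), ",
      format_bp(sum(x)), " bp total\n", sep = "")
  for (i in seq_along(x))
    cat("  ", names(x)[i], "\t", format_bp(unname(x[i])), "\n", sep = "")
  invisible(x)
}

# integer-style formatting without scientific notation
format_bp <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
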