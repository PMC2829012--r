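# The tag library container: per-gene aggregated tag counts with known tag
# formation probabilities.  Zero-count genes are retained (more than half of
# the genes in a typical SAGE library have zero counts); genes with phi = 0
# are unobservable and rejected at construction.

#' Construct a tag library
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param count Nonnegative integer aggregated tag counts per gene.
#' @param phi Tag formation probabilities in (0, 1], same length.
#' @return A `tag_library` object: list with `gene_id`, `t`, `phi`, `t_tot`
#'   (total tag count) and `l` (number of genes).
#' @examples
#' tag_library(c("a", "b"), c(10, 10), c(1, 0.5))
#' @export
tag_library <- function(gene_id, count, phi) {
  gene_id <- as.character(gene_id)
  if (length(gene_id) == 0) stop("empty library")
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1])
  }
  if (length(count) != length(gene_id) || length(phi) != length(gene_id)) {
    stop("gene_id, count and phi must have equal length")
  }
  if (anyNA(count) || any(count < 0) || any(count != floor(count))) {
    stop("counts must be nonnegative integers")
  }
  if (anyNA(phi) || any(phi <= 0) || any(phi > 1)) {
    bad <- which(is.na(phi) | phi <= 0 | phi > 1)[1]
    stop("phi must lie in (0, 1]; offending gene: ", gene_id[bad])
  }
  structure(
    list(gene_id = gene_id, t = as.integer(round(count)), phi = as.numeric(phi),
         t_tot = as.integer(sum(count)), l = length(gene_id)),
    class = "tag_library"
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat("Tag library:", x$l, "genes,", x$t_tot, "tags\n")
  cat("  zero-count genes:", sum(x$t == 0L), "\n")
  cat("  phi range: [", format(min(x$phi), digits = 4), ", ",
      format(max(x$phi), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Read a tag library from TSV
#'
#' The file must have a header and either a `phi` column or a `k` column
#' (number of AE sites, all assumed unambiguous) combined with a cleavage
#' probability `p`, from which phi is computed under the geometric model.
#'
#' @param path TSV file with columns `gene_id`, `count`, and `phi` or `k`.
#' @param p Cleavage probability, required when the file carries `k`.
#' @return A [tag_library()].
#' @export
read_tag_library <- function(path, p = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "count")
  if (!all(need %in% names(df))) {
    stop("library file must have columns 'gene_id' and 'count'")
  }
  if (anyNA(df$count) || !is.numeric(df$count)) {
    stop("malformed count on line ",
         which(is.na(suppressWarnings(as.numeric(df$count))))[1] + 1L)
  }
  bad <- which(df$count < 0 | df$count != floor(df$count))
  if (length(bad)) stop("negative or non-integer count on line ", bad[1] + 1L)
  if ("phi" %in% names(df)) {
    bad <- which(is.na(df$phi) | df$phi <= 0 | df$phi > 1)
    if (length(bad)) {
      stop("phi outside (0, 1] on line ", bad[1] + 1L,
           " (gene ", df$gene_id[bad[1]], ")")
    }
    phi <- df$phi
  } else if ("k" %in% names(df)) {
    if (is.null(p)) stop("file has a 'k' column: cleavage probability 'p' is required")
    phi <- vapply(df$k, tag_formation_prob, numeric(1), p = p)
  } else {
    stop("library file needs a 'phi' column, or a 'k' column plus 'p'")
  }
  tag_library(df$gene_id, df$count, phi)
}

#' Write a tag library as TSV
#'
#' phi is written with enough digits to round-trip exactly.
#'
#' @param lib A [tag_library()].
#' @param path Output file.
#' @export
write_tag_library <- function(lib, path) {
  df <- data.frame(
    gene_id = lib$gene_id, count = lib$t,
    phi = sprintf("%.17g", lib$phi), stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
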