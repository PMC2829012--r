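# Geometric model of tag formation under incomplete anchoring-enzyme (AE)
# digestion.  Sites are indexed 1..k from the 3' most site; the AE cleaves
# each site independently with probability p, and only the 3' most cleaved
# site yields an observable tag.

#' Probability that a tag forms at a given AE site
#'
#' Under independent cleavage with probability `p` per site, the 3' most
#' cleaved site produces the tag, so a tag forms at site `j` (counting from
#' the 3' end) exactly when sites `1..j-1` are missed and site `j` is cut:
#' a geometric probability `(1 - p)^(j - 1) * p`.
#'
#' @param j Site index (integer >= 1), 1 = 3' most site. May be a vector.
#' @param p Cleavage probability of the anchoring enzyme, in (0, 1].
#' @return Numeric vector of per-site tag probabilities.
#' @examples
#' site_tag_prob(1, 0.55)
#' site_tag_prob(2, 0.92)  # the upstream-tag case p * (1 - p)
#' @export
site_tag_prob <- function(j, p) {
  check_cleavage_prob(p)
  if (length(j) == 0 || anyNA(j) || any(j < 1) || any(j != floor(j))) {
    stop("'j' must be integer site indices >= 1 (1 = 3' most site)")
  }
  (1 - p)^(j - 1) * p
}

#' Per-gene tag formation probability
#'
#' Sums the geometric site probabilities over the gene's unambiguous AE
#' sites.  If all `k` sites are unambiguous this equals `1 - (1 - p)^k`.
#' A gene with no unambiguous site can never be observed and is an error;
#' such genes must be excluded before analysis.
#'
#' @param k Number of AE sites on the gene's transcript (integer >= 1).
#' @param p Cleavage probability, in (0, 1].
#' @param unambiguous Logical vector of length `k`, `TRUE` where site `j`
#'   yields an unambiguous tag. Default: all sites unambiguous.
#' @return The tag formation probability, a value in (0, 1].
#' @examples
#' tag_formation_prob(2, 0.5)                           # 1 - 0.5^2
#' tag_formation_prob(2, 0.92, c(FALSE, TRUE))          # only site 2 counts
#' @export
tag_formation_prob <- function(k, p, unambiguous = NULL) {
  check_cleavage_prob(p)
  if (length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    stop("'k' must be a single integer >= 1")
  }
  if (is.null(unambiguous)) unambiguous <- rep(TRUE, k)
  if (length(unambiguous) != k) {
    stop("'unambiguous' must have one flag per site (length ", k, ")")
  }
  if (!any(unambiguous)) {
    stop("gene has no unambiguous AE site: it is unobservable and must be excluded")
  }
  sum(site_tag_prob(which(unambiguous), p))
}

#' Simulate per-gene AE site structures
#'
#' Draws the number of AE sites per gene as `1 + Poisson(site_mean)` (the
#' offset guarantees at least one site) and flags every site unambiguous,
#' matching the generating protocol used throughout the simulation study.
#'
#' @param n_genes Number of genes.
#' @param site_mean Mean of the Poisson component of the site count.
#' @param seed Optional integer seed (uses R's RNG); `NULL` leaves the
#'   current stream untouched.
#' @return A data frame of class `site_structures` with columns `gene_id`,
#'   `k` and a list column `unambiguous`.
#' @export
simulate_site_structures <- function(n_genes, site_mean = 2, seed = NULL) {
  if (n_genes < 1) stop("'n_genes' must be >= 1")
  if (site_mean <= 0) stop("'site_mean' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  k <- 1L + rpois(n_genes, site_mean)
  structure(
    data.frame(
      gene_id = sprintf("g%0*d", nchar(n_genes), seq_len(n_genes)),
      k = k,
      unambiguous = I(lapply(k, function(ki) rep(TRUE, ki))),
      stringsAsFactors = FALSE
    ),
    class = c("site_structures", "data.frame")
  )
}

#' Tag formation probabilities for a table of site structures
#'
#' @param structures A `site_structures` data frame (see
#'   [simulate_site_structures()] or [read_site_structures()]).
#' @param p Cleavage probability.
#' @return Numeric vector of phi values aligned with the table rows.
#' @export
phi_from_structures <- function(structures, p) {
  check_cleavage_prob(p)
  vapply(
    seq_len(nrow(structures)),
    function(i) {
      tag_formation_prob(structures$k[i], p, structures$unambiguous[[i]])
    },
    numeric(1)
  )
}

#' Write site structures as TSV
#'
#' Columns: `gene_id`, `k`, and the per-site 0/1 ambiguity flags joined with
#' commas (1 = unambiguous), sites ordered from the 3' end.
#'
#' @param structures A `site_structures` data frame.
#' @param path Output file.
#' @export
write_site_structures <- function(structures, path) {
  flags <- vapply(
    structures$unambiguous,
    function(f) paste(as.integer(f), collapse = ","),
    character(1)
  )
  df <- data.frame(
    gene_id = structures$gene_id, k = structures$k,
    unambiguous = flags, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read site structures from TSV
#'
#' @param path File written by [write_site_structures()].
#' @return A `site_structures` data frame.
#' @export
read_site_structures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character"))
  flags <- lapply(strsplit(df$unambiguous, ",", fixed = TRUE),
                  function(f) as.integer(f) == 1L)
  bad <- which(lengths(flags) != df$k)
  if (length(bad)) {
    stop("flag list length does not match k on line ", bad[1] + 1L)
  }
  structure(
    data.frame(gene_id = df$gene_id, k = df$k, unambiguous = I(flags),
               stringsAsFactors = FALSE),
    class = c("site_structures", "data.frame")
  )
}

check_cleavage_prob <- function(p) {
  if (length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    stop("cleavage probability 'p' must be a single value in (0, 1]")
  }
  invisible(p)
}
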