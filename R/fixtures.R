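# Named fixture scenarios: small on-disk libraries with ground-truth
# sidecars, generated deterministically from a seed.

fixture_kinds <- c("toy3", "protocol_l1000", "protocol_l6178",
                   "twofold_pair", "unequal_p_pair")

write_truth <- function(dir, kind, gene_id, m, ...) {
  extras <- list(...)
  df <- data.frame(gene_id = gene_id, m = sprintf("%.17g", m),
                   stringsAsFactors = FALSE)
  for (nm in names(extras)) df[[nm]] <- sprintf("%.17g", extras[[nm]])
  write.table(df, file.path(dir, paste0(kind, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

write_meta <- function(dir, kind, meta) {
  writeLines(paste(names(meta), unname(meta), sep = ": "),
             file.path(dir, paste0(kind, "_meta.txt")))
}

#' Generate a named fixture scenario on disk
#'
#' Scenarios:
#' \describe{
#'   \item{`toy3`}{A 3-gene, 100-tag library with known truth.}
#'   \item{`protocol_l1000`}{One library under the l = 1000 protocol
#'     defaults (15,000 tags, p = 0.55, five-bin abundance profile).}
#'   \item{`protocol_l6178`}{As above with l = 6178 and per-bin gene
#'     counts 1181/3678/1173/133/13.}
#'   \item{`twofold_pair`}{Two equal-phi libraries in which gene `mark`'s
#'     proportion is doubled in library B.}
#'   \item{`unequal_p_pair`}{Tag-level pair with equal expression but
#'     cleavage probabilities 0.92 vs 0.96; tags 1..12 derive from one AE
#'     position upstream (k = 1), the rest from the 3' site (k = 0).}
#' }
#' Each scenario writes a library TSV (two for pairs), a `*_truth.tsv`
#' sidecar with the generating proportions and phi, and a `*_meta.txt`
#' key-value sidecar.  Identical kind + seed give byte-identical files.
#'
#' @param kind One of the scenario names above.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Character vector of the files written.
#' @export
make_fixture <- function(kind, dir, seed = 1L) {
  if (!kind %in% fixture_kinds) {
    stop("unknown fixture kind '", kind, "'; choices: ",
         paste(fixture_kinds, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib_path <- function(suffix = "") {
    file.path(dir, paste0(kind, "_library", suffix, ".tsv"))
  }

  if (kind == "toy3") {
    m <- c(0.5, 0.3, 0.2)
    phi <- c(0.9, 0.5, 0.7)
    lib <- simulate_library(m, phi, 100, seed = seed,
                            gene_id = c("g1", "g2", "g3"))
    write_tag_library(lib, lib_path())
    write_truth(dir, kind, lib$gene_id, m, phi = phi)
    write_meta(dir, kind, c(kind = kind, seed = seed, n_tags = 100))
  } else if (kind %in% c("protocol_l1000", "protocol_l6178")) {
    cfg <- if (kind == "protocol_l1000") {
      protocol_config(seed = seed)
    } else {
      protocol_config(l = 6178,
                      bin_gene_counts = c(1181, 3678, 1173, 133, 13),
                      seed = seed)
    }
    structures <- simulate_site_structures(cfg$l, cfg$site_mean,
                                           seed = cfg$seed)
    phi <- phi_from_structures(structures, cfg$p)
    truth <- build_synthetic_m(cfg, seed = cfg$seed + 1L)
    lib <- simulate_library(truth$m, phi, cfg$n_tags, seed = cfg$seed + 2L,
                            gene_id = structures$gene_id)
    write_tag_library(lib, lib_path())
    write_truth(dir, kind, lib$gene_id, truth$m, phi = phi)
    write_meta(dir, kind, c(kind = kind, seed = seed, n_tags = cfg$n_tags,
                            p = cfg$p, l = cfg$l))
  } else if (kind == "twofold_pair") {
    l <- 100
    set.seed(seed)
    m_a <- exp(runif(l, log(1e-3), log(1e-2)))
    m_a[1] <- 0.005
    m_a <- m_a / sum(m_a)
    m_b <- m_a
    m_b[1] <- 2 * m_b[1]
    m_b <- m_b / sum(m_b)
    structures <- simulate_site_structures(l, 2, seed = seed + 1L)
    phi <- phi_from_structures(structures, 0.55)
    ids <- c("mark", structures$gene_id[-1])
    lib_a <- simulate_library(m_a, phi, 20000, seed = seed + 2L, gene_id = ids)
    lib_b <- simulate_library(m_b, phi, 20000, seed = seed + 3L, gene_id = ids)
    write_tag_library(lib_a, lib_path("_a"))
    write_tag_library(lib_b, lib_path("_b"))
    write_truth(dir, kind, ids, m_a, m_b = m_b, phi = phi)
    write_meta(dir, kind, c(kind = kind, seed = seed, n_tags = 20000,
                            p = 0.55, marked_gene = "mark"))
  } else if (kind == "unequal_p_pair") {
    l <- 60
    k_up <- c(rep(1L, 12), rep(0L, l - 12))
    m <- rep(1 / l, l)
    p_a <- 0.92
    p_b <- 0.96
    phi_a <- p_a * (1 - p_a)^k_up
    phi_b <- p_b * (1 - p_b)^k_up
    ids <- sprintf("tag%02d", seq_len(l))
    lib_a <- simulate_library(m, phi_a, 100000, seed = seed, gene_id = ids)
    lib_b <- simulate_library(m, phi_b, 100000, seed = seed + 1L,
                              gene_id = ids)
    write_tag_library(lib_a, lib_path("_a"))
    write_tag_library(lib_b, lib_path("_b"))
    write_truth(dir, kind, ids, m, phi_a = phi_a, phi_b = phi_b,
                k_upstream = k_up)
    write_meta(dir, kind, c(kind = kind, seed = seed, n_tags = 100000,
                            p_a = p_a, p_b = p_b))
  }
  list.files(dir, pattern = paste0("^", kind, "_"), full.names = TRUE)
}
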