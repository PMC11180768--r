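# LD reference panel: pairwise r^2 lookups backed by either a 0/1 haplotype
# matrix or a precomputed square r^2 matrix.

#' Construct an LD reference panel
#'
#' @param haplotypes optional 0/1 matrix, rows = haplotypes, columns =
#'   variants (column names = variant ids). Pairwise r^2 is the squared
#'   Pearson correlation of allele indicators across haplotypes.
#' @param r2 optional square symmetric matrix of pairwise r^2 with variant ids
#'   as dimnames; exactly one of `haplotypes`/`r2` must be given.
#' @param sites data.frame with `variant_id`, `chrom`, `pos` for every panel
#'   variant.
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(haplotypes = NULL, r2 = NULL, sites) {
  if (is.null(haplotypes) == is.null(r2))
    stopf("supply exactly one of 'haplotypes' or 'r2'")
  stopifnot(is.data.frame(sites),
            all(c("variant_id", "chrom", "pos") %in% names(sites)))
  sites$variant_id <- as.character(sites$variant_id)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.numeric(sites$pos)
  if (anyDuplicated(sites$variant_id)) stopf("duplicate panel variant ids")
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (is.null(colnames(haplotypes)))
      colnames(haplotypes) <- sites$variant_id
    if (!identical(sort(colnames(haplotypes)), sort(sites$variant_id)))
      stopf("haplotype columns and sites disagree")
    if (!all(haplotypes %in% c(0, 1))) stopf("haplotypes must be 0/1")
  } else {
    r2 <- as.matrix(r2)
    if (nrow(r2) != ncol(r2) || is.null(rownames(r2)))
      stopf("r2 must be a square matrix with variant-id dimnames")
    if (!identical(sort(rownames(r2)), sort(sites$variant_id)))
      stopf("r2 dimnames and sites disagree")
    if (any(r2 < -1e-8 | r2 > 1 + 1e-8)) stopf("r2 values outside [0,1]")
  }
  structure(list(haplotypes = haplotypes, r2 = r2, sites = sites),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  backing <- if (!is.null(x$haplotypes))
    sprintf("%d haplotypes", nrow(x$haplotypes)) else "precomputed r2"
  cat(sprintf("<ld_panel> %d variant(s), %s\n", nrow(x$sites), backing))
  invisible(x)
}

#' Panel variant ids
#' @param panel `ld_panel`.
#' @export
panel_variants <- function(panel) panel$sites$variant_id

#' Pairwise r-squared between panel variants
#'
#' @param panel `ld_panel`.
#' @param ids1,ids2 variant-id vectors; `ids2` defaults to `ids1`.
#' @return matrix of r^2 values (`ids1` rows by `ids2` columns). Monomorphic
#'   variants get r^2 = 0 off-diagonal and 1 on the diagonal.
#' @export
ld_r2 <- function(panel, ids1, ids2 = ids1) {
  stopifnot(inherits(panel, "ld_panel"))
  missing <- setdiff(c(ids1, ids2), panel_variants(panel))
  if (length(missing) > 0)
    stopf("variant(s) absent from LD panel: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  if (!is.null(panel$r2)) return(panel$r2[ids1, ids2, drop = FALSE])
  h1 <- panel$haplotypes[, ids1, drop = FALSE]
  h2 <- panel$haplotypes[, ids2, drop = FALSE]
  sd1 <- apply(h1, 2, stats::sd)
  sd2 <- apply(h2, 2, stats::sd)
  r <- suppressWarnings(stats::cor(h1, h2))
  r[!is.finite(r)] <- 0
  r2 <- r * r
  # monomorphic self-correlation: define r2(i,i) = 1
  for (id in intersect(ids1[sd1 == 0], ids2[sd2 == 0]))
    r2[id, id] <- 1
  dimnames(r2) <- list(ids1, ids2)
  r2
}

#' Read an LD panel from text files
#'
#' Either a haplotype matrix file (whitespace-delimited 0/1, rows =
#' haplotypes, no header) with a sidecar site table, or a square r^2 matrix
#' file whose first row and column carry variant ids.
#'
#' @param haplotypes_path path to the haplotype matrix file.
#' @param r2_path path to the square r^2 matrix (tab-separated, id header and
#'   id first column).
#' @param sites_path tab-separated site table with columns
#'   `variant_id, chrom, pos` (required with `haplotypes_path`; optional with
#'   `r2_path`, where missing positions default to the id order).
#' @return An [ld_panel].
#' @export
read_ld_panel <- function(haplotypes_path = NULL, r2_path = NULL,
                          sites_path = NULL) {
  if (!is.null(haplotypes_path)) {
    if (is.null(sites_path))
      stopf("a haplotype panel requires a sites table")
    sites <- utils::read.table(sites_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    hap <- as.matrix(utils::read.table(haplotypes_path, header = FALSE))
    colnames(hap) <- sites$variant_id
    return(ld_panel(haplotypes = hap, sites = sites))
  }
  if (is.null(r2_path)) stopf("supply haplotypes_path or r2_path")
  m <- utils::read.table(r2_path, header = TRUE, sep = "\t",
                         row.names = 1, check.names = FALSE)
  m <- as.matrix(m)
  if (!is.null(sites_path)) {
    sites <- utils::read.table(sites_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(variant_id = rownames(m), chrom = "1",
                        pos = seq_len(nrow(m)), stringsAsFactors = FALSE)
  }
  ld_panel(r2 = m, sites = sites)
}

#' Write an LD panel's haplotypes and sites as text
#' @param panel `ld_panel` backed by haplotypes.
#' @param haplotypes_path,sites_path output paths.
#' @export
write_ld_panel <- function(panel, haplotypes_path, sites_path) {
  stopifnot(inherits(panel, "ld_panel"), !is.null(panel$haplotypes))
  utils::write.table(panel$haplotypes, haplotypes_path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(panel$sites, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(haplotypes_path)
}
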