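#' Binned intra-chromosomal contact matrix
#'
#' A symmetric, non-negative matrix of contact counts over contiguous bins of
#' one chromosome, carrying its bin resolution and balancing state.
#'
#' @param mat square numeric matrix (symmetric, non-negative).
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @param balanced has the matrix been balanced?
#' @param scaling per-bin scaling vector applied during balancing (or `NULL`).
#' @export
contact_matrix <- function(mat, resolution, chrom = "chrS", balanced = FALSE,
                           scaling = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-9) stop("contact matrix must be symmetric")
  if (min(mat, na.rm = TRUE) < 0) stop("contact matrix must be non-negative")
  structure(list(mat = mat, resolution = as.numeric(resolution), chrom = chrom,
                 balanced = isTRUE(balanced), scaling = scaling),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %g bp, %s\n", x$chrom, nrow(x$mat),
              x$resolution, if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

#' Write a contact matrix as sparse upper-triangle triplet text
#'
#' Format: `bin_i<TAB>bin_j<TAB>count` with 0-based bins, upper triangle
#' (i <= j), plus a companion `chrom.sizes`-style file.
#'
#' @param m a [contact_matrix()].
#' @param path output triplet file; the chrom.sizes companion gets the same
#'   path with suffix `.chrom.sizes`.
#' @export
write_contacts <- function(m, path) {
  idx <- which(upper.tri(m$mat, diag = TRUE) & m$mat != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   count = m$mat[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("%s\t%d", m$chrom, as.integer(nrow(m$mat) * m$resolution)),
             paste0(path, ".chrom.sizes"))
  invisible(path)
}

#' Read a sparse triplet contact matrix
#'
#' @param path triplet file written by [write_contacts()] (0-based upper
#'   triangle).
#' @param resolution bin size in bp.
#' @param n_bins bin count; if `NULL`, read from the `.chrom.sizes` companion.
#' @param chrom chromosome name (default from companion file).
#' @export
read_contacts <- function(path, resolution, n_bins = NULL, chrom = NULL) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("bin_i", "bin_j", "count"))
  if (is.null(n_bins) || is.null(chrom)) {
    cs <- utils::read.table(paste0(path, ".chrom.sizes"), sep = "\t",
                            col.names = c("chrom", "size"))
    if (is.null(n_bins)) n_bins <- as.integer(cs$size[1] / resolution)
    if (is.null(chrom)) chrom <- cs$chrom[1]
  }
  mat <- matrix(0, n_bins, n_bins)
  mat[cbind(df$bin_i + 1L, df$bin_j + 1L)] <- df$count
  mat[cbind(df$bin_j + 1L, df$bin_i + 1L)] <- df$count
  contact_matrix(mat, resolution, chrom = chrom)
}

#' Write per-bin tracks as bedGraph (0-based, half-open)
#' @param bins data.frame with `chrom`, `start`, `end`.
#' @param values numeric per-bin values.
#' @param path output path.
#' @export
write_bedgraph <- function(bins, values, path) {
  utils::write.table(data.frame(bins$chrom, bins$start, bins$end, values),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#' @param path bedGraph file (0-based, half-open intervals).
#' @export
read_bedgraph <- function(path) {
  utils::read.table(path, sep = "\t",
                    col.names = c("chrom", "start", "end", "value"))
}

#' Write loop anchors as BEDPE
#' @param loops data.frame with 1-based `bin_i`, `bin_j`.
#' @param resolution bin size in bp.
#' @param path output path.
#' @param chrom chromosome name.
#' @export
write_bedpe <- function(loops, resolution, path, chrom = "chrS") {
  df <- data.frame(chrom, (loops$bin_i - 1L) * resolution, loops$bin_i * resolution,
                   chrom, (loops$bin_j - 1L) * resolution, loops$bin_j * resolution)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BEDPE loop list back to 1-based bin pairs
#' @param path BEDPE file.
#' @param resolution bin size in bp.
#' @export
read_bedpe <- function(path, resolution) {
  df <- utils::read.table(path, sep = "\t")
  data.frame(bin_i = df[[2]] / resolution + 1L, bin_j = df[[5]] / resolution + 1L)
}
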