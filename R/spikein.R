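#' Spike-in ChIP-seq depth-normalization scale factors
#'
#' With mouse chromatin spiked into each human sample, sequencing-depth
#' differences are corrected by scaling each sample to the smallest
#' spike-in depth: \eqn{f = m/s}, where \eqn{m} is the minimum
#' mouse-aligned read count across samples and \eqn{s} the sample's own
#' mouse-aligned count. The sample with the fewest mouse reads gets
#' \eqn{f = 1}; every other sample is subsampled to the fraction
#' \eqn{f \in (0, 1]} of its human-aligned reads
#' (`target_reads = round(f * human_reads)`). Actual BAM subsampling is
#' downstream of this package; the table carries the fraction and expected
#' count.
#'
#' @param counts data frame with columns `sample_id`, `mouse_reads`,
#'   `human_reads` (one row per sample, all mouse counts > 0).
#' @return data frame of class `spikein_table` with added columns
#'   `scale_factor` and `target_reads`.
#' @examples
#' compute_scale_factors(data.frame(
#'   sample_id = c("A", "B"),
#'   mouse_reads = c(2e6, 4e6),
#'   human_reads = c(10e6, 12e6)
#' ))
#' @export
compute_scale_factors <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("sample_id", "mouse_reads", "human_reads")
  if (!all(need %in% names(counts)))
    stop("counts needs columns sample_id, mouse_reads, human_reads")
  if (nrow(counts) < 1L) stop("at least one sample required")
  if (any(!is.finite(counts$mouse_reads)) || any(counts$mouse_reads <= 0))
    stop("normalization error: a sample has no mouse-aligned reads ",
         "(spike-in failed)")
  if (any(!is.finite(counts$human_reads)) || any(counts$human_reads < 0))
    stop("human_reads must be non-negative")
  m <- min(counts$mouse_reads)
  counts$scale_factor <- m / counts$mouse_reads
  counts$target_reads <- round(counts$scale_factor * counts$human_reads)
  structure(counts, class = c("spikein_table", "data.frame"))
}

#' Read / write spike-in tables as TSV
#'
#' Columns: `sample_id`, `mouse_reads`, `human_reads` on input;
#' `scale_factor`, `target_reads` added on output.
#'
#' @param path TSV file path.
#' @param tab a `spikein_table`.
#' @return `read_spikein_tsv` returns a data frame;
#'   `write_spikein_tsv` returns `path` invisibly.
#' @export
read_spikein_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_spikein_tsv
#' @export
write_spikein_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
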