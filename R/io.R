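## Plain-text interchange: Bismark-style CpG reports, BED, count and edge
## tables. All genomic coordinates are 0-based half-open.

#' Write per-sample CpG reports
#'
#' One TSV per sample (chrom, pos0, strand, count_meth, count_unmeth),
#' strand-pooled (`strand = "+"`), mirroring a cytosine report with merged
#' CpG evidence.
#'
#' @param cpg a `cpg_table`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_cpg_reports <- function(cpg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(nrow(cpg$samples)), function(j) {
    s <- cpg$samples$sample[j]
    path <- file.path(dir, paste0(s, ".cpg.tsv"))
    write_tsv(data.frame(chrom = cpg$chrom, pos0 = cpg$pos, strand = "+",
                         count_meth = cpg$meth[, s],
                         count_unmeth = cpg$total[, s] - cpg$meth[, s]),
              path)
    path
  }, character(1))
  invisible(paths)
}

#' Read per-sample CpG reports into a `cpg_table`
#'
#' @param paths named character vector (names = sample ids) of report TSVs.
#' @param samples sample metadata data frame (sample, condition, stage,
#'   replicate) matching the names.
#' @return A `cpg_table`.
#' @export
read_cpg_reports <- function(paths, samples) {
  stopifnot(!is.null(names(paths)), all(samples$sample %in% names(paths)))
  tabs <- lapply(paths[samples$sample], read_tsv)
  ref <- tabs[[1]][, c("chrom", "pos0")]
  meth <- vapply(tabs, function(t) {
    stopifnot(identical(t$pos0, ref$pos0))
    as.integer(t$count_meth)
  }, integer(nrow(ref)))
  total <- vapply(tabs, function(t)
    as.integer(t$count_meth + t$count_unmeth), integer(nrow(ref)))
  colnames(meth) <- colnames(total) <- samples$sample
  structure(list(chrom = ref$chrom, pos = ref$pos0, region_id = NULL,
                 meth = meth, total = total, samples = samples),
            class = "cpg_table")
}

#' Write intervals as BED6(+)
#'
#' @param df data frame with chrom/start/end and optional name/score/extra
#'   columns.
#' @param path output path.
#' @param name,score column names to use for the BED name/score fields.
#' @param extra extra column names appended after the strand field.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path, name = NULL, score = NULL,
                      extra = character()) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if (!is.null(name)) df[[name]] else ".",
                    score = if (!is.null(score))
                      round(pmin(1000, df[[score]])) else 0,
                    strand = ".", stringsAsFactors = FALSE)
  for (e in extra) bed[[e]] <- df[[e]]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED(6+) file
#'
#' @param path BED path.
#' @param extra names for columns after the sixth.
#' @return Data frame with chrom/start/end/name/score/strand (+ extras).
#' @export
read_bed <- function(path, extra = character()) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand", extra)[seq_len(ncol(df))]
  df
}
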