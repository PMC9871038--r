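#' @importFrom stats pnorm pf pt rnorm rpois rbeta rbinom rbinom rnbinom runif
#'   kmeans p.adjust fisher.test prcomp sd var setNames aggregate quantile
#'   median rgamma
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals (e.g. the k-means
#' restarts) never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a stream-specific 31-bit seed from a master seed (double-precision
## modular arithmetic: exact well below 2^53)
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  k <- match(stream, c(
    "methylome", "expression", "peaks", "network", "kmeans_dmr",
    "kmeans_expr", "enrichment", "pipeline"))
  if (is.na(k)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 48271 + k * 97) %% 2147483647)
}

## data.frame (chrom, start, end; 0-based half-open) -> GRanges
as_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

gr_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

## Overlap width matrix-free: total bp of query covered by subject set
overlap_bp <- function(query_gr, subject_gr) {
  if (length(subject_gr) == 0 || length(query_gr) == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(query_gr), GenomicRanges::reduce(subject_gr)
  )))
}

## TSV with a provenance header comment (config hash), round-trip safe
write_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

## md5 of an R object via its serialised JSON (stable across sessions)
hash_object <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

stage_log <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
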