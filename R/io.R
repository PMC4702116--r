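# Plain-text I/O: segment tables (TSV), fold lists (BED-like), fold-back
# junctions (BEDPE) and rankings (TSV/JSON).  Genomic coordinates are
# 0-based half-open throughout.

#' Read a segmented amplicon summary
#'
#' @param path TSV with header `chrom, start, end, mean_depth, depth_var,
#'   n_bins` (one row per region, contiguous).
#' @param folds_path optional BED-like fold file: `chrom, start, end,
#'   facing` (no header; `facing` in `L`/`R`); fold position = `start`.
#' @return An [amplicon_segments()] table.
#' @examples
#' seg <- system.file("extdata", "pd4875_segments.tsv", package = "bfbspace")
#' fld <- system.file("extdata", "pd4875_folds.bed", package = "bfbspace")
#' read_segments(seg, fld)
#' @export
read_segments <- function(path, folds_path = NULL) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse segment file ", path, ": ", conditionMessage(e))
  )
  need <- c("chrom", "start", "end", "mean_depth", "depth_var", "n_bins")
  if (!all(need %in% names(df))) {
    stop("segment file must have header columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("segment file ", path, " contains no regions")
  for (col in c("start", "end", "mean_depth", "depth_var", "n_bins")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("segment file %s: non-numeric %s at data line %d", path, col, bad[1L]))
    }
  }
  df <- df[order(df$start), , drop = FALSE]
  folds <- NULL
  if (!is.null(folds_path)) folds <- read_folds(folds_path)
  amplicon_segments(df$chrom, df$start, df$end, df$mean_depth, df$depth_var,
                    df$n_bins, folds = folds)
}

#' @rdname read_segments
#' @export
read_folds <- function(folds_path) {
  if (!file.exists(folds_path)) stop("fold file not found: ", folds_path)
  bed <- utils::read.delim(folds_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("fold file needs columns: chrom, start, end, facing")
  facing <- toupper(as.character(bed[[4L]]))
  bad <- which(!facing %in% c("L", "R", "NA"))
  if (length(bad)) {
    stop(sprintf("fold file %s: facing must be L or R at line %d", folds_path, bad[1L]))
  }
  data.frame(pos = as.numeric(bed[[2L]]), facing = facing)
}

#' Write fold-back junctions as BEDPE
#'
#' Each fold is a fold-back inversion junction: both mates at the fold
#' position, strands `+/+` for right-facing folds and `-/-` for left-facing.
#'
#' @param folds data.frame with `chrom`, `pos`, `facing` (`"L"`/`"R"`), or a
#'   `"bfb_cascade"` plus a genomic mapping via `chrom`, `origin` and
#'   `orientation` (model coordinate 0 maps to the `origin`; `"right"` means
#'   the ends face increasing coordinates, so model positions run leftward).
#' @param path output file.
#' @param chrom,origin,orientation genomic mapping for cascade input.
#' @param scale bp per model-coordinate unit for cascade input.
#' @return Invisibly, the data.frame written.
#' @export
write_junctions <- function(folds, path, chrom = "chrS", origin = 0,
                            orientation = c("right", "left"), scale = 1e6) {
  orientation <- match.arg(orientation)
  if (inherits(folds, "bfb_cascade")) {
    casc <- folds
    surv <- casc$surviving
    x <- casc$x[surv]
    d <- casc$d[surv]
    gpos <- if (orientation == "right") origin - round(x * scale) else origin + round(x * scale)
    # d = +1: fold points away from the ends; ends face right => fold faces left
    facing <- if (orientation == "right") ifelse(d == 1, "L", "R") else ifelse(d == 1, "R", "L")
    folds <- data.frame(chrom = chrom, pos = gpos, facing = facing)
  }
  if (nrow(folds) == 0L) {
    file.create(path)
    return(invisible(folds))
  }
  if (is.null(folds$chrom)) folds$chrom <- chrom
  strand <- ifelse(folds$facing == "R", "+", "-")
  bedpe <- data.frame(
    chrom1 = folds$chrom, start1 = folds$pos, end1 = folds$pos + 1,
    chrom2 = folds$chrom, start2 = folds$pos, end2 = folds$pos + 1,
    name = sprintf("fold_%d", seq_len(nrow(folds))), score = 0,
    strand1 = strand, strand2 = strand
  )
  utils::write.table(bedpe, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bedpe)
}

#' Write a ranking as TSV and/or JSON
#'
#' @param ranking a `"ranked_inference"` data.frame.
#' @param tsv,json output paths (either may be `NULL`).
#' @param seed seed recorded in the JSON provenance block.
#' @return Invisibly, the ranking.
#' @export
write_ranking <- function(ranking, tsv = NULL, json = NULL, seed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(ranking), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(
      tool = "bfbspace",
      version = as.character(utils::packageVersion("bfbspace")),
      seed = seed,
      orientation = attr(ranking, "orientation"),
      n_candidates = attr(ranking, "n_candidates"),
      candidates = as.data.frame(ranking)
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(ranking)
}
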