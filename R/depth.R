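#' Construct a per-sample depth profile
#'
#' A depth profile holds raw (and, after [loess_gc_normalize()], normalized)
#' mean read depth per feature, where features are genome bins and/or gene
#' bodies, in a fixed order shared across the cohort.
#'
#' @param features data frame with columns `feature_id`, `feature_type`
#'   (`"bin"` or `"gene"`), `chrom`, `start`, `end` (0-based half-open),
#'   `gc`, `raw_depth`.
#' @param sample_id sample identifier.
#' @param total_reads total aligned reads behind the profile (`NA` if
#'   unknown, e.g. when depth came from a coverage table).
#' @return a `depth_profile` data frame with `norm_depth` and `flag` columns
#'   initialised, and `sample_id`/`total_reads` attributes.
#' @export
depth_profile <- function(features, sample_id, total_reads = NA_real_) {
  required <- c("feature_id", "feature_type", "chrom", "start", "end", "gc",
                "raw_depth")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0)
    stop_giscan("depth profile is missing columns: %s",
                paste(missing, collapse = ", "))
  if (any(features$raw_depth < 0, na.rm = TRUE))
    stop_giscan("raw_depth must be nonnegative")
  if (anyDuplicated(features$feature_id))
    stop_giscan("duplicate feature_id in depth profile")
  out <- features[required]
  if (!"norm_depth" %in% names(features)) out$norm_depth <- NA_real_
  else out$norm_depth <- features$norm_depth
  if (!"flag" %in% names(features)) out$flag <- NA_character_
  else out$flag <- features$flag
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "total_reads") <- as.numeric(total_reads)
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile '%s': %d features (%d bins, %d genes)%s\n",
              attr(x, "sample_id"), nrow(x),
              sum(x$feature_type == "bin"), sum(x$feature_type == "gene"),
              if (all(is.na(x$norm_depth))) ", not normalized" else ", normalized"))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

bin_feature_frame <- function(grid) {
  data.frame(
    feature_id = sprintf("bin_%s_%d", grid$chrom, as.integer(grid$start)),
    feature_type = "bin",
    chrom = grid$chrom, start = grid$start, end = grid$end, gc = grid$gc,
    stringsAsFactors = FALSE
  )
}

gene_feature_frame <- function(panel) {
  bed <- panel_to_bed(panel)
  data.frame(
    feature_id = panel$gene, feature_type = "gene",
    chrom = bed$chrom, start = bed$start, end = bed$end,
    gc = if ("gc" %in% names(panel)) panel$gc else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Aggregate a binned coverage table onto a bin grid
#'
#' Reads a bedGraph (4 columns, 0-based half-open, no header) or a headered
#' TSV (`chrom`, `start`, `end`, `depth`) whose intervals tile or subdivide
#' the grid, and computes the length-weighted mean depth per grid bin.
#' Positions not covered by any record count as depth 0, matching bedGraph
#' semantics where zero intervals are omitted.
#'
#' @param path coverage file path.
#' @param grid a [make_bin_grid()] tiling.
#' @param sample_id sample identifier (default: file name without extension).
#' @return a `depth_profile` over the grid bins.
#' @export
depth_from_table <- function(path, grid, sample_id = NULL) {
  if (!file.exists(path)) stop_giscan("coverage file not found: %s", path)
  sample_id <- sample_id %||%
    sub("\\.(bedgraph|bedGraph|tsv|txt)$", "", basename(path))
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  tab <- read.delim(path, header = has_header, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (!has_header) names(tab)[1:4] <- c("chrom", "start", "end", "depth")
  bin_size <- attr(grid, "bin_size")
  feats <- bin_feature_frame(grid)
  total <- setNames(numeric(nrow(feats)), feats$feature_id)

  chrom_ends <- tapply(grid$end, grid$chrom, max)
  for (ch in unique(tab$chrom)) {
    if (!ch %in% names(chrom_ends))
      stop_giscan("interval on unknown chromosome %s", ch)
    rec <- tab[tab$chrom == ch, ]
    rec <- rec[order(rec$start), ]
    if (any(rec$end > chrom_ends[[ch]] | rec$start < 0)) {
      bad <- rec[rec$end > chrom_ends[[ch]] | rec$start < 0, ][1, ]
      stop_giscan("interval outside grid: %s:%s-%s", ch,
                  format(bad$start, scientific = FALSE),
                  format(bad$end, scientific = FALSE))
    }
    if (nrow(rec) > 1 && any(rec$start[-1] < rec$end[-nrow(rec)])) {
      i <- which(rec$start[-1] < rec$end[-nrow(rec)])[1]
      stop_giscan("overlapping coverage records on %s near %d", ch, rec$end[i])
    }
    for (i in seq_len(nrow(rec))) {
      s <- rec$start[i]; e <- rec$end[i]; d <- rec$depth[i]
      ib <- seq(floor(s / bin_size), floor((e - 1) / bin_size))
      for (b in ib) {
        bs <- b * bin_size
        be <- min(bs + bin_size, chrom_ends[[ch]])
        ov <- min(e, be) - max(s, bs)
        id <- sprintf("bin_%s_%d", ch, as.integer(bs))
        total[id] <- total[id] + d * ov
      }
    }
  }
  feats$raw_depth <- as.numeric(total) / (feats$end - feats$start)
  depth_profile(feats, sample_id)
}

#' Per-bin and gene-body depth from an aligned BAM
#'
#' Computes mean read depth (aligned bases overlapping the feature divided by
#' feature length) for every grid bin and, optionally, every panel gene body,
#' from a coordinate-sorted, indexed BAM. Requires the Bioconductor
#' `GenomicAlignments`/`Rsamtools` stack.
#'
#' @param bam path to an indexed BAM file.
#' @param grid a [make_bin_grid()] tiling.
#' @param gene_panel optional `gene_panel`; gene-body features are appended
#'   after the bins.
#' @param sample_id sample identifier (default: BAM file name).
#' @return a `depth_profile` with `total_reads` set to the number of aligned
#'   reads used.
#' @export
depth_from_alignments <- function(bam, grid, gene_panel = NULL,
                                  sample_id = NULL) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE))
      stop_giscan("%s is required for BAM input", pkg)
  }
  sample_id <- sample_id %||% sub("\\.bam$", "", basename(bam))
  galn <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam))
  cvg <- GenomicAlignments::coverage(galn)
  have <- names(cvg)
  need <- unique(grid$chrom)
  if (!is.null(gene_panel)) need <- unique(c(need, gene_panel$chrom))
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stop_giscan("contigs absent from BAM header: %s",
                paste(missing, collapse = ", "))
  feats <- bin_feature_frame(grid)
  if (!is.null(gene_panel) && nrow(gene_panel) > 0)
    feats <- rbind(feats, gene_feature_frame(gene_panel))
  feats$raw_depth <- vapply(seq_len(nrow(feats)), function(i) {
    r <- cvg[[feats$chrom[i]]]
    s <- feats$start[i] + 1  # to 1-based inclusive
    e <- min(feats$end[i], length(r))
    if (s > length(r)) return(0)
    v <- IRanges::Views(r, start = s, end = e)
    IRanges::viewMeans(v) * (e - s + 1) / (feats$end[i] - feats$start[i])
  }, numeric(1))
  depth_profile(feats, sample_id, total_reads = length(galn))
}

#' Write / read a depth profile as TSV
#'
#' The on-disk form is a plain TSV with `#`-prefixed metadata lines
#' (`sample_id`, `total_reads`), the interchange format between pipeline
#' stages.
#'
#' @param profile a `depth_profile`.
#' @param path file path.
#' @return `path` (write) or a `depth_profile` (read).
#' @export
write_depth_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#giscan_depth_profile",
               sprintf("#sample_id=%s", attr(profile, "sample_id")),
               sprintf("#total_reads=%s", attr(profile, "total_reads"))), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_profile
#' @export
read_depth_profile <- function(path) {
  hdr <- readLines(path, n = 3)
  sample_id <- sub("^#sample_id=", "", hdr[grepl("^#sample_id=", hdr)])
  total_reads <- suppressWarnings(as.numeric(
    sub("^#total_reads=", "", hdr[grepl("^#total_reads=", hdr)])))
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  tab$flag <- as.character(tab$flag)
  tab$norm_depth <- as.numeric(tab$norm_depth)
  prof <- depth_profile(tab, sample_id,
                        if (length(total_reads)) total_reads else NA_real_)
  prof$norm_depth <- tab$norm_depth
  prof$flag <- tab$flag
  prof
}
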