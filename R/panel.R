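#' Load a gene panel table
#'
#' Reads a tab-separated gene panel (the packaged default is a 33-gene
#' ovarian-cancer panel with hg19 coordinates) and validates it. Each row
#' carries the gene's expected copy-number direction (`AMP` or `DEL`), taken
#' from the dominant alteration type in TCGA ovarian tumors, which drives the
#' directional 0/1 grouping in [group_by_direction()].
#'
#' Coordinates in the file are 1-based inclusive (as printed in the source
#' table); use [panel_to_bed()] for the 0-based half-open convention.
#'
#' @param path path to a panel TSV with header columns `chrom`, `start`,
#'   `end`, `gene`, `strand`, `cnv_direction`, `occurring_freq`, `tcga_freq`,
#'   `gene_class`. An optional `gc` column (gene-body GC fraction) is kept.
#' @return a `gene_panel` data frame, one row per gene.
#' @seealso [default_panel_path()] for the packaged panel.
#' @examples
#' panel <- load_gene_panel(default_panel_path())
#' nrow(panel)  # 33
#' @export
load_gene_panel <- function(path) {
  if (!file.exists(path)) stop_giscan("panel file not found: %s", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  if (nrow(raw) == 0) {
    warn_giscan("panel file %s has no rows", path)
    return(validate_gene_panel(empty_panel()))
  }
  required <- c("chrom", "start", "end", "gene", "strand", "cnv_direction",
                "occurring_freq", "tcga_freq", "gene_class")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_giscan("panel file %s is missing columns: %s", path,
                paste(missing, collapse = ", "))
  }
  start <- suppressWarnings(as.numeric(gsub(",", "", raw$start)))
  end <- suppressWarnings(as.numeric(gsub(",", "", raw$end)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0) {
    stop_giscan("malformed coordinates in %s at line %d (gene %s)",
                path, bad[1] + 1L, raw$gene[bad[1]])
  }
  panel <- data.frame(
    gene = raw$gene,
    chrom = raw$chrom,
    start = start,
    end = end,
    strand = raw$strand,
    direction = raw$cnv_direction,
    occurring_freq = as.numeric(raw$occurring_freq),
    tcga_freq = as.numeric(raw$tcga_freq),
    gene_class = raw$gene_class,
    stringsAsFactors = FALSE
  )
  if ("gc" %in% names(raw)) panel$gc <- as.numeric(raw$gc)
  validate_gene_panel(panel)
}

empty_panel <- function() {
  data.frame(gene = character(), chrom = character(), start = numeric(),
             end = numeric(), strand = character(), direction = character(),
             occurring_freq = numeric(), tcga_freq = numeric(),
             gene_class = character(), stringsAsFactors = FALSE)
}

validate_gene_panel <- function(panel) {
  if (nrow(panel) > 0) {
    if (any(panel$start >= panel$end))
      stop_giscan("panel rows with start >= end: %s",
                  paste(panel$gene[panel$start >= panel$end], collapse = ", "))
    if (anyDuplicated(panel$gene))
      stop_giscan("duplicate gene symbols in panel: %s",
                  paste(unique(panel$gene[duplicated(panel$gene)]), collapse = ", "))
    if (!all(panel$strand %in% c("+", "-")))
      stop_giscan("panel strand must be '+' or '-'")
    if (!all(panel$direction %in% c("AMP", "DEL")))
      stop_giscan("panel cnv_direction must be 'AMP' or 'DEL'")
    freqs <- c(panel$occurring_freq, panel$tcga_freq)
    if (any(!is.finite(freqs)) || any(freqs < 0 | freqs > 1))
      stop_giscan("panel frequencies must be fractions in [0, 1]")
  }
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Path to the packaged 33-gene ovarian-cancer panel
#'
#' @return file path of the panel TSV shipped with the package.
#' @export
default_panel_path <- function() {
  system.file("extdata", "ovarian_panel_hg19.tsv", package = "giscan",
              mustWork = TRUE)
}

#' Write a gene panel back to TSV
#'
#' Inverse of [load_gene_panel()]; a written panel re-loads field-for-field.
#'
#' @param panel a `gene_panel` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(panel, path) {
  out <- data.frame(
    chrom = panel$chrom,
    start = format(panel$start, scientific = FALSE, trim = TRUE),
    end = format(panel$end, scientific = FALSE, trim = TRUE),
    gene = panel$gene,
    strand = panel$strand,
    cnv_direction = panel$direction,
    occurring_freq = panel$occurring_freq,
    tcga_freq = panel$tcga_freq,
    gene_class = panel$gene_class,
    stringsAsFactors = FALSE
  )
  if ("gc" %in% names(panel)) out$gc <- panel$gc
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert panel coordinates to BED convention
#'
#' The panel stores 1-based inclusive coordinates; internal bin arithmetic is
#' 0-based half-open. The two converters are explicit so no silent off-by-one
#' can creep in.
#'
#' @param panel a `gene_panel`.
#' @return data frame with `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`, `strand`.
#' @export
panel_to_bed <- function(panel) {
  data.frame(chrom = panel$chrom, start = panel$start - 1, end = panel$end,
             name = panel$gene, strand = panel$strand,
             stringsAsFactors = FALSE)
}

#' @rdname panel_to_bed
#' @param bed data frame in BED convention with columns `chrom`, `start`,
#'   `end` and optionally `name`, `strand`.
#' @export
bed_to_1based <- function(bed) {
  out <- bed
  out$start <- bed$start + 1
  out
}

# ---- genome bin grid --------------------------------------------------------

#' Tile a genome into fixed-size bins
#'
#' Produces the half-open `[start, end)` tiling used as the feature set for
#' genome-wide Z-scores (default bin size 100 kb). The terminal bin of each
#' chromosome may be shorter. GC fraction per bin is attached from a reference
#' FASTA or a precomputed BED4-style table; it is required before LOESS GC
#' normalization.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), or a
#'   two-column TSV path / data frame (`chrom`, `size`).
#' @param bin_size bin width in bp (> 0); default 100,000.
#' @param gc_fasta optional path to a reference FASTA (needs `Biostrings`);
#'   GC is computed per bin from the sequence.
#' @param gc_table optional BED4 data frame or path (`chrom`, `start`, `end`,
#'   `gc`, 0-based half-open, matching the tiling).
#' @return a `bin_grid` data frame: `chrom`, `start`, `end`, `gc`, with
#'   attribute `bin_size`.
#' @examples
#' grid <- make_bin_grid(c(chrS1 = 250000), bin_size = 100000)
#' nrow(grid)          # 3 bins
#' grid$end - grid$start  # 100000 100000 50000
#' @export
make_bin_grid <- function(chrom_sizes, bin_size = 100000, gc_fasta = NULL,
                          gc_table = NULL) {
  if (bin_size <= 0) stop_giscan("bin_size must be > 0")
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (any(chrom_sizes <= 0)) stop_giscan("chromosome sizes must be positive")
  grids <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grids)
  grid$gc <- NA_real_
  if (!is.null(gc_fasta)) {
    grid$gc <- gc_from_fasta(grid, gc_fasta)
  } else if (!is.null(gc_table)) {
    grid$gc <- gc_from_table(grid, gc_table, names(chrom_sizes))
  }
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

as_chrom_sizes <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    tab <- read.delim(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("chrom", "size") %in% names(tab))) {
      tab <- read.delim(x, header = FALSE, sep = "\t",
                        col.names = c("chrom", "size"),
                        stringsAsFactors = FALSE)
    }
    return(setNames(as.numeric(tab$size), tab$chrom))
  }
  if (is.data.frame(x)) return(setNames(as.numeric(x$size), x$chrom))
  if (is.null(names(x)) || any(names(x) == ""))
    stop_giscan("chrom_sizes must be named")
  x
}

gc_from_fasta <- function(features, fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_giscan("Biostrings is required to compute GC from FASTA")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(features$chrom), names(seqs))
  if (length(missing) > 0)
    stop_giscan("FASTA lacks sequences for: %s", paste(missing, collapse = ", "))
  vapply(seq_len(nrow(features)), function(i) {
    s <- Biostrings::subseq(seqs[[features$chrom[i]]],
                            start = features$start[i] + 1,
                            end = features$end[i])
    counts <- Biostrings::alphabetFrequency(s, baseOnly = TRUE)
    acgt <- sum(counts[c("A", "C", "G", "T")])
    if (acgt == 0) return(NA_real_)
    sum(counts[c("G", "C")]) / acgt
  }, numeric(1))
}

gc_from_table <- function(grid, gc_table, known_chroms) {
  tab <- if (is.character(gc_table)) {
    read.delim(gc_table, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    gc_table
  }
  extra <- setdiff(unique(tab$chrom), known_chroms)
  if (length(extra) > 0)
    stop_giscan("GC table has chromosomes absent from chrom_sizes: %s",
                paste(extra, collapse = ", "))
  key_grid <- paste(grid$chrom, grid$start)
  key_tab <- paste(tab$chrom, tab$start)
  gc <- tab$gc[match(key_grid, key_tab)]
  as.numeric(gc)
}

validate_bin_grid <- function(grid) {
  for (ch in unique(grid$chrom)) {
    b <- grid[grid$chrom == ch, ]
    b <- b[order(b$start), ]
    if (any(b$start[-1] < b$end[-nrow(b)]))
      stop_giscan("bins overlap on %s", ch)
  }
  if (any(!is.na(grid$gc) & (grid$gc < 0 | grid$gc > 1)))
    stop_giscan("gc fractions outside [0, 1]")
  invisible(grid)
}
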