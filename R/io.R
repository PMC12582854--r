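# Standard-format I/O. Internal coordinates are 0-based half-open (BED
# native); GFF3 and VCF are converted on read/write (both are 1-based).

#' Read / write BED intervals
#'
#' @param path File path.
#' @return `read_bed`: data frame `scaffold`, `start`, `end` (0-based
#'   half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr_to_df(gr)
}

#' @rdname read_bed
#' @param df Data frame with `scaffold`, `start`, `end` (positions `pos` are
#'   written as width-1 intervals).
#' @export
write_bed <- function(df, path) {
  if (!is.null(df$pos) && is.null(df$start)) {
    df <- data.frame(scaffold = df$scaffold, start = df$pos, end = df$pos + 1)
  }
  rtracklayer::export(df_to_gr(df), path, format = "BED")
  invisible(path)
}

#' Read / write bedGraph rate tracks
#'
#' @param path File path.
#' @param units Unit label attached to the returned [rate_track()].
#' @export
read_bedgraph <- function(path, units = "rate") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- gr_to_df(gr)
  rate_track(df$scaffold, df$start, df$end, gr$score, units = units)
}

#' @rdname read_bedgraph
#' @param track A [rate_track()] or any data frame with `scaffold`, `start`,
#'   `end` and a value column (`rate`, `d`, `mu` or `pi`).
#' @param value Name of the value column to write as the bedGraph score.
#' @export
write_bedgraph <- function(track, path, value = NULL) {
  if (is.null(value)) {
    value <- intersect(c("rate", "mu", "d", "pi"), names(track))[1]
  }
  keep <- !is.na(track[[value]])
  gr <- df_to_gr(track[keep, , drop = FALSE])
  gr$score <- track[[value]][keep]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write annotations as GFF3
#'
#' @param annotations An `annotation_set`.
#' @param path File path.
#' @export
write_gff3 <- function(annotations, path) {
  gr <- df_to_gr(annotations)
  gr$type <- if (!is.null(annotations$type)) annotations$type else "exon"
  gr$source <- "ayemaps"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- gr_to_df(gr)
  df$type <- as.character(gr$type)
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Write a polymorphism set as VCF 4.2
#'
#' Minimal single-ALT VCF with GT fields (phased `|` when the set is phased).
#'
#' @param snps A `polymorphism_set`.
#' @param path Output path (plain text).
#' @param sample_names Optional individual names.
#' @export
write_vcf <- function(snps, path, sample_names = NULL) {
  n_ind <- ncol(snps$gt)
  if (is.null(sample_names)) sample_names <- paste0("ind", seq_len(n_ind))
  sep <- if (snps$phased) "|" else "/"
  gt_str <- if (snps$phased && !is.null(snps$hap)) {
    a1 <- t(snps$hap[seq(1, 2 * n_ind, by = 2), , drop = FALSE])
    a2 <- t(snps$hap[seq(2, 2 * n_ind, by = 2), , drop = FALSE])
    matrix(paste(a1, a2, sep = sep), nrow = length(snps$pos))
  } else {
    g <- snps$gt
    m <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
    m[g == 0] <- paste0("0", sep, "0")
    m[g == 1] <- paste0("0", sep, "1")
    m[g == 2] <- paste0("1", sep, "1")
    m
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ayemaps",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")), con)
  body <- cbind(snps$scaffold, snps$pos + 1, ".", snps$ref, snps$alt, ".",
                "PASS", ".", "GT", gt_str)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a polymorphism set
#'
#' Keeps biallelic SNPs only; unphased and phased GT are both accepted (the
#' set is marked phased only if every genotype is phased).
#'
#' @param path VCF path.
#' @return A `polymorphism_set`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  fix <- fix[biallelic, , drop = FALSE]
  gt_raw <- gt_raw[biallelic, , drop = FALSE]
  phased <- all(grepl("\\|", gt_raw), na.rm = TRUE)
  alt_count <- function(x) {
    a <- strsplit(x, "[|/]")
    vapply(a, function(z) {
      if (any(z == ".")) NA_integer_ else sum(as.integer(z))
    }, integer(1))
  }
  gt <- apply(gt_raw, 2, alt_count)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(gt_raw))
  hap <- NULL
  if (phased) {
    spl <- apply(gt_raw, 2, function(col) {
      do.call(rbind, strsplit(col, "\\|"))
    }, simplify = FALSE)
    hap <- do.call(rbind, lapply(spl, function(m) {
      rbind(as.integer(m[, 1]), as.integer(m[, 2]))
    }))
  }
  polymorphism_set(fix[, "CHROM"], as.integer(fix[, "POS"]) - 1,
                   fix[, "REF"], fix[, "ALT"], gt, phased = phased, hap = hap)
}

#' Write a recombination or rate map as tab-delimited text
#'
#' Columns: scaffold, start, end, rate (cM/Mb) and cumulative cM.
#'
#' @param map A `recomb_map`.
#' @param path Output path.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(
    map[, intersect(c("scaffold", "start", "end", "rate", "cum_cM"), names(map))],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  recomb_map(df$scaffold, df$start, df$end, df$rate)
}
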